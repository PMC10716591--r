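test_that("size factors hit their defining hand-computed values", {
  # median-of-ratios on the worked 3x2 example: factors prop to (1/sqrt2, sqrt2)
  m <- matrix(c(2, 3, 5, 4, 6, 10), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- compute_scale_factors(m, "DESeq")$size_factors
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  # total-count: column sums 100 vs 300 give a factor ratio of 3
  m2 <- matrix(c(50, 50, 150, 150), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  sf2 <- compute_scale_factors(m2, "TC")$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 3)

  # upper quartile: 75th percentile of nonzero counts, linear interpolation
  m3 <- matrix(c(0, 10, 20, 30, 40, 0, 20, 40, 60, 80), 5, 2,
               dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  sf3 <- compute_scale_factors(m3, "UQ")$size_factors
  expect_equal(unname(sf3[2] / sf3[1]),
               quantile(c(20, 40, 60, 80), 0.75)[[1]] /
                 quantile(c(10, 20, 30, 40), 0.75)[[1]])
})

test_that("every scaler is neutral on duplicated samples and geometric-mean 1", {
  set.seed(7)
  y <- rpois(200, 60)
  m <- cbind(s1 = y, s2 = y)
  rownames(m) <- paste0("g", 1:200)
  for (meth in c("none", "TC", "UQ", "TMM", "DESeq", "PoissonSeq")) {
    sf <- compute_scale_factors(m, meth)$size_factors
    expect_equal(unname(sf), c(1, 1), tolerance = 1e-8)
  }
  set.seed(8)
  m4 <- matrix(rpois(400 * 4, 50), 400, 4,
               dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  for (meth in c("TC", "UQ", "TMM", "DESeq", "PoissonSeq")) {
    sf <- compute_scale_factors(m4, meth)$size_factors
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-10)
  }
})

test_that("TMM against a doubled sample matches the brute-force trimmed mean", {
  set.seed(9)
  y <- rpois(300, 80) + 1
  m <- cbind(A = y, B = 2L * y)
  rownames(m) <- paste0("g", 1:300)
  sf <- compute_scale_factors(m, "TMM")$size_factors
  # all M-values are zero after library-size adjustment: factor ratio = 2
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-8)
})

test_that("size-factor methods are scale-equivariant", {
  set.seed(10)
  m <- matrix(rpois(500 * 4, 70), 500, 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  for (meth in c("TC", "UQ", "DESeq", "TMM", "PoissonSeq")) {
    sf0 <- compute_scale_factors(m, meth)$size_factors
    m2 <- m
    m2[, 2] <- m2[, 2] * 3L
    sf1 <- compute_scale_factors(m2, meth)$size_factors
    ratio <- (sf1 / sf0)[2] / (sf1 / sf0)[1]
    tol <- if (meth %in% c("TMM", "PoissonSeq")) 0.02 else 1e-8
    expect_equal(unname(ratio), 3, tolerance = tol)
  }
})

test_that("scaler-specific exclusion rules are reported", {
  m <- matrix(c(5, 0, 10, 8, 2, 12, 3, 1, 20, 6, 1, 15), 3, 4,
              dimnames = list(c("g1", "glow", "g3"), paste0("s", 1:4)))
  # "glow" carries a zero count (DESeq rule) and total count 4 < 5 (PoissonSeq)
  expect_identical(compute_scale_factors(m, "DESeq")$excluded_genes, "glow")
  expect_identical(compute_scale_factors(m, "PoissonSeq")$excluded_genes, "glow")
  # every gene has a zero somewhere but no library is empty
  mz <- matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0, 5, 5, 5), 3, 4,
               dimnames = dimnames(m))
  expect_error(compute_scale_factors(mz, "DESeq"), "nonzero")
})

test_that("procedure enumeration reproduces the combinatorial space", {
  procs <- enumerate_procedures()
  expect_equal(nrow(procs), 96)
  expect_equal(anyDuplicated(procs$name), 0)
  expect_equal(nrow(enumerate_procedures("TC", character(0), k_max = 1)), 2)
  expect_equal(nrow(enumerate_procedures("TC", "RUVg", k_max = 1)), 4)
  expect_error(enumerate_procedures(character(0)), "empty")
})

test_that("RUVg recovers exact low-rank control structure", {
  set.seed(12)
  u <- rnorm(40)
  v <- rnorm(10)
  Z <- matrix(rnorm(200 * 10, sd = 0.1), 200, 10)
  Z[1:40, ] <- Z[1:40, ] + u %o% v
  rownames(Z) <- paste0("g", 1:200)
  colnames(Z) <- paste0("s", 1:10)
  fit <- estimate_ruv_factors(Z, paste0("g", 1:40), "RUVg", k = 1)
  vc <- v - mean(v)
  ang <- abs(sum(fit$W[, 1] * vc)) / sqrt(sum(vc^2))
  expect_gt(ang, 0.99)   # principal angle near zero
  expect_error(estimate_ruv_factors(Z, paste0("g", 1:40), "RUVg", k = 0),
               "at least 1")
  expect_error(estimate_ruv_factors(Z, paste0("g", 1:40), "RUVg", k = 11),
               "samples")
})

test_that("RUVs/RUVse require valid replicate groups and ignore group-constant effects", {
  set.seed(13)
  Z <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  grp <- rep(c("a", "b"), each = 4)
  expect_error(estimate_ruv_factors(Z, rownames(Z)[1:20], "RUVs", k = 1,
                                    replicate_groups = c(grp[-1], "c")),
               "singleton")
  f1 <- estimate_ruv_factors(Z, rownames(Z)[1:20], "RUVs", k = 2,
                             replicate_groups = grp)
  # a planted effect constant within groups is removed by group centering
  Z2 <- Z
  Z2[, grp == "b"] <- Z2[, grp == "b"] + rnorm(50) %o% rep(1, 4)
  f2 <- estimate_ruv_factors(Z2, rownames(Z)[1:20], "RUVs", k = 2,
                             replicate_groups = grp)
  expect_equal(unname(abs(diag(cor(f1$W, f2$W)))), c(1, 1), tolerance = 1e-8)
})

test_that("control-gene residual variance is non-increasing in k", {
  ds <- shared_filtered
  gs <- shared_gene_sets
  scal <- compute_scale_factors(ds$counts, "TC")
  le <- sweep(log_transform(ds$counts), 2, scal$offsets, "-")
  resid_var <- vapply(1:5, function(k) {
    fit <- estimate_ruv_factors(le, gs$anchor, "RUVg", k = k)
    adj <- le - t(fit$W %*% fit$alpha)
    Zc <- adj[gs$anchor, ]
    sum((Zc - rowMeans(Zc))^2)
  }, numeric(1))
  expect_true(all(diff(resid_var) <= 1e-8))
})

test_that("adjustment arithmetic: identity, offsets, batch-shift removal", {
  ds <- shared_filtered
  le <- log_transform(ds$counts)
  ident <- adjust_counts(le)
  expect_identical(ident$values, le)

  adj <- adjust_counts(le, scaling = log2(c(1, 2, rep(1, ncol(le) - 2))))
  expect_equal(adj$values[, 2], le[, 2] - 1)
  expect_equal(adj$values[, 1], le[, 1])

  # planted additive shift on half the samples, clean controls, k = 1
  set.seed(14)
  n <- 10
  Z <- matrix(rnorm(300 * n, 5), 300, n,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:n)))
  delta <- 2
  half <- (n / 2 + 1):n
  Z[, half] <- Z[, half] + delta
  fit <- estimate_ruv_factors(Z, paste0("g", 1:100), "RUVg", k = 1)
  out <- adjust_counts(Z, fit)$values
  ctrl <- out[1:100, ]
  gap <- abs(mean(ctrl[, half]) - mean(ctrl[, -half]))
  expect_lt(gap, 0.05 * delta)
})

test_that("apply_procedure composes the pipeline and validates configuration", {
  ds <- shared_filtered
  gs <- shared_gene_sets
  raw <- apply_procedure(ds, list(scaling = "none", ruv_variant = "none", k = 0))
  expect_equal(raw$values, log_transform(ds$counts))

  withruv <- apply_procedure(ds, list(scaling = "DESeq", ruv_variant = "RUVg",
                                      k = 4), gs)
  batch <- ds$samples$batch
  noruv <- apply_procedure(ds, list(scaling = "DESeq", ruv_variant = "none",
                                    k = 0), gs)
  r2_with <- pc_covariate_r2(withruv, batch, 2)$r2[2]
  r2_without <- pc_covariate_r2(noruv, batch, 2)$r2[2]
  expect_lt(r2_with, r2_without)

  expect_error(apply_procedure(ds, list(scaling = "none",
                                        ruv_variant = "RUVg", k = 2),
                               list(anchor = character(0))),
               "anchor")
  expect_error(apply_procedure(ds, list(scaling = "none",
                                        ruv_variant = "RUVg", k = 0), gs),
               "k = 0")
})
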