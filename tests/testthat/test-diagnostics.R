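test_that("PC-covariate R2 hits analytic endpoints and the permutation null", {
  set.seed(22)
  vals <- matrix(rnorm(300 * 10), 300, 10,
                 dimnames = list(paste0("g", 1:300), paste0("s", 1:10)))
  pcs <- expr_pcs(vals, 1)
  cov_pc1 <- factor(ifelse(pcs[, 1] > 0, "hi", "lo"))
  r2 <- pc_covariate_r2(vals, cov_pc1, k_max = 3)
  expect_lt(r2$r2[1], 1)          # sign of PC1 is not PC1 itself
  exact <- pc_covariate_r2(vals, pcs[, 1], k_max = 2)
  expect_equal(exact$r2[1], 1, tolerance = 1e-10)
  expect_true(all(diff(r2$r2) >= -1e-12))

  # independent covariate: E[R2 at k=1] = 1/(n-1)
  set.seed(23)
  null_r2 <- replicate(100, {
    pc_covariate_r2(vals, sample(rep(c("a", "b"), 5)), k_max = 1)$r2[1]
  })
  expect_lt(abs(mean(null_r2) - 1 / 9), 0.03)
  expect_error(pc_covariate_r2(vals, rep("a", 10), k_max = 2), "constant")
  expect_error(pc_covariate_r2(vals, cov_pc1, k_max = 10), "samples - 1")
})

test_that("PC-covariate R2 equals an explicit least-squares fit", {
  set.seed(24)
  vals <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  batch <- factor(c("a", "a", "b", "b", "c", "c"))
  got <- pc_covariate_r2(vals, batch, k_max = 2)
  pcs <- expr_pcs(vals, 2)
  Y <- model.matrix(~batch)[, -1]
  Y <- sweep(Y, 2, colMeans(Y))
  for (k in 1:2) {
    sse <- sum(vapply(1:2, function(j)
      sum(resid(lm(Y[, j] ~ pcs[, 1:k]))^2), numeric(1)))
    expect_equal(got$r2[k], 1 - sse / sum(Y^2), tolerance = 1e-10)
  }
})

test_that("batch ANOVA count saturates under a global batch shift and skips constants", {
  set.seed(25)
  vals <- matrix(rnorm(100 * 9, 10), 100, 9,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:9)))
  batch <- rep(c("a", "b", "c"), each = 3)
  vals_shift <- sweep(vals, 2, 50 * rep(0:2, each = 3), "+")
  expect_equal(as.integer(anova_batch_count(vals_shift, batch)), 100)
  vals[1, ] <- 3
  cnt <- anova_batch_count(vals, batch)
  expect_equal(attr(cnt, "n_skipped"), 1L)
  expect_error(anova_batch_count(vals, rep(c("a", "b"), c(8, 1))), ">= 2")
})

test_that("per-gene Spearman correlation matches brute-force ranks", {
  batch <- c(1, 2, 3, 4, 5, 6)          # untied ordered encoding
  vals <- rbind(mono = c(10, 20, 30, 40, 50, 60),
                flat = rep(4, 6),
                wob = c(2, 1, 5, 3, 4, 6))
  colnames(vals) <- paste0("s", 1:6)
  rho <- gene_batch_spearman(vals, batch)
  expect_equal(rho[["mono"]], 1)
  expect_equal(rho[["flat"]], 0)
  expect_true("flat" %in% attr(rho, "constant_genes"))
  # brute force: Pearson correlation of average ranks, tied batch labels
  tied <- c(1, 1, 2, 2, 3, 3)
  rho2 <- gene_batch_spearman(vals, tied)
  expect_equal(rho2[["wob"]], cor(rank(vals["wob", ]), rank(tied)))
})

test_that("Rozeboom vector correlation matches canonical correlations", {
  set.seed(26)
  pcs <- matrix(rnorm(16), 8, 2)
  expect_equal(vector_correlation(pcs, pcs[, 1, drop = FALSE]), 1,
               tolerance = 1e-10)
  ortho <- qr.Q(qr(cbind(1, pcs, rnorm(8))))[, 4, drop = FALSE]
  expect_equal(vector_correlation(pcs, ortho), 0, tolerance = 1e-10)
  # explicit eigen-decomposition oracle
  Y <- matrix(rnorm(16), 8, 2)
  Xc <- scale(pcs, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  M <- solve(crossprod(Xc)) %*% crossprod(Xc, Yc) %*%
    solve(crossprod(Yc)) %*% crossprod(Yc, Xc)
  rho2 <- sort(Re(eigen(M)$values), decreasing = TRUE)[1:2]
  expect_equal(vector_correlation(pcs, Y), 1 - prod(1 - rho2),
               tolerance = 1e-8)
})

test_that("ARI separation: perfect split, permutation null, contingency oracle", {
  set.seed(27)
  vals <- matrix(rnorm(100 * 8), 100, 8,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  assay <- rep(c("input", "enrichment"), each = 4)
  vals[, assay == "enrichment"] <- vals[, assay == "enrichment"] + 3
  expect_equal(ari_separation(vals, assay), 1)

  null_ari <- replicate(100, {
    mclust::adjustedRandIndex(sample(assay), assay)
  })
  expect_lt(abs(mean(null_ari)), 0.1)

  x <- c(1, 1, 1, 2, 2, 2, 1, 2)
  y <- c("a", "a", "b", "b", "b", "b", "a", "a")
  expect_equal(mclust::adjustedRandIndex(x, y), brute_ari(x, y),
               tolerance = 1e-12)
})

test_that("Jensen-Shannon distance: identity, disjoint supports, hand value", {
  P <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0.5, 0))
  expect_equal(unname(jensen_shannon_distance(P)), c(0, 0))

  # centroid of two disjoint profiles: each is at the hand-computed distance
  Q <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  d <- jensen_shannon_distance(Q)
  # JSD((1,0),(0.5,0.5)) = 0.311278..., distance = sqrt(JSD) = 0.557922...
  expect_equal(unname(d), c(0.5579231, 0.5579231), tolerance = 1e-6)
  expect_error(jensen_shannon_distance(rbind(c(0, 0), c(1, 1))), "all-zero")
  neg <- rbind(c(-1, 2), c(0, 1))
  expect_error(jensen_shannon_distance(neg), "non-negative")
  expect_silent(jensen_shannon_distance(neg, shift_nonnegative = TRUE))
})

test_that("scaling-only baseline recovers planted enrichment factors", {
  # deterministic toy: identical input libraries; enrichment = input with the
  # ten high-abundance genes (the guaranteed top set) at exactly 3-fold
  ds <- make_toy_dataset(n_genes = 100, n_pairs = 3, seed = 62)
  counts <- ds$counts
  en_cols <- ds$samples$assay == "enrichment"
  counts[, !en_cols] <- rep(c(rep(1000L, 10), rep(50L, 90)), 3)
  counts[, en_cols] <- counts[, !en_cols]
  counts[1:10, en_cols] <- counts[1:10, en_cols] * 3L
  ds <- sn_dataset(counts, ds$samples, ds$genes)
  rb <- radar_baseline(ds, top_fraction = 0.1)
  sf <- rb$scaling$size_factors
  ratio <- mean(sf[en_cols]) / mean(sf[!en_cols])
  expect_equal(ratio, 3, tolerance = 1e-6)

  broken <- ds$samples
  broken$pair_id[broken$sample_id == "P1_en"] <- "orphan"
  ds2 <- sn_dataset(counts, broken, ds$genes)
  expect_error(radar_baseline(ds2), "unpaired")
})

test_that("standalone RUVg baseline is the compositional identity", {
  ds <- shared_filtered
  gs <- shared_gene_sets
  via_baseline <- ruvg_baseline(ds, gs, k = 3)
  via_procedure <- apply_procedure(ds, list(scaling = "none",
                                            ruv_variant = "RUVg", k = 3), gs)
  expect_equal(via_baseline$values, via_procedure$values)
  ident <- ruvg_baseline(ds, gs, k = 0)
  expect_equal(ident$values, log_transform(ds$counts))
})
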