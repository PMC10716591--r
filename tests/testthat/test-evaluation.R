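test_that("silhouette widths match the definition exactly", {
  # a = 0 within a coincident pair: width 1
  emb <- matrix(c(0, 0, 10), ncol = 1)
  s <- silhouette_widths(emb, c("A", "A", "B"))
  expect_equal(s[1:2], c(1, 1))
  # point equidistant between its own and the other cluster: width 0
  emb2 <- matrix(c(0, 2, 4), ncol = 1)
  s2 <- silhouette_widths(emb2, c("A", "A", "B"))
  expect_equal(s2[2], 0)
  # mislabeled point in a 5-point configuration is negative and matches brute force
  emb3 <- matrix(c(0, 0.5, 1, 10, 10.5), ncol = 1)
  lab3 <- c("A", "A", "B", "B", "B")
  expect_equal(silhouette_widths(emb3, lab3), brute_silhouette(emb3, lab3),
               tolerance = 1e-12)
  expect_lt(silhouette_widths(emb3, lab3)[3], 0)
  expect_error(silhouette_widths(emb3, rep("A", 5)), "single cluster")
})

test_that("silhouette agrees with the cluster package on random configurations", {
  set.seed(15)
  for (i in 1:20) {
    emb <- matrix(rnorm(8 * 2), 8, 2)
    lab <- sample(c(1, 1, 1, 2, 2, 3, 3, 3))
    ours <- silhouette_widths(emb, lab)
    ref <- cluster::silhouette(lab, dist(emb))[, "sil_width"]
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
})

test_that("similarity metrics respond to separation and randomness", {
  set.seed(16)
  n <- 10
  vals <- matrix(rnorm(200 * n), 200, n,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:n)))
  assay <- rep(c("input", "enrichment"), each = n / 2)
  vals[, assay == "enrichment"] <- vals[, assay == "enrichment"] + 20 / sqrt(200)
  samples <- data.frame(sample_id = colnames(vals), batch = "B1",
                        assay = assay, group = rep(c("G1", "G2"), n / 2),
                        pair_id = paste0("p", 1:n))
  m <- similarity_metrics(vals, samples)
  expect_gt(m[["EN_SIM"]], 0.5)
  expect_true(is.na(m[["BATCH_SIM"]]))   # single batch: metric absent
  expect_gte(m[["PAM_SIM"]], m[["EN_SIM"]] - 1e-9)

  # random labels: silhouette centered near zero
  set.seed(17)
  shuffles <- replicate(50, {
    lab <- sample(assay)
    mean(silhouette_widths(expr_pcs(vals, 3), lab))
  })
  expect_lt(abs(mean(shuffles)), 0.1)
})

test_that("weighted R2 equals the explicit least-squares computation", {
  set.seed(18)
  pcs <- matrix(rnorm(20), 10, 2)
  fac <- matrix(rnorm(10), 10, 1)
  ours <- weighted_r2(pcs, fac)
  sst <- ssr <- 0
  for (j in 1:2) {
    y <- pcs[, j]
    fit <- lm(y ~ fac)
    sst <- sst + sum((y - mean(y))^2)
    ssr <- ssr + sum((fitted(fit) - mean(y))^2)
  }
  expect_equal(ours, ssr / sst, tolerance = 1e-12)
  expect_equal(weighted_r2(pcs, pcs), 1)
  ortho <- qr.Q(qr(cbind(1, pcs, rnorm(10))))[, 4, drop = FALSE]
  expect_equal(weighted_r2(pcs, ortho), 0, tolerance = 1e-10)
})

test_that("weighted R2 is invariant to invertible transforms of the factors", {
  set.seed(19)
  pcs <- matrix(rnorm(24), 12, 2)
  fac <- matrix(rnorm(24), 12, 2)
  A <- matrix(c(2, 1, -1, 0.5), 2, 2)
  expect_equal(weighted_r2(pcs, fac), weighted_r2(pcs, fac %*% A),
               tolerance = 1e-12)
})

test_that("UV/WV correlation composes the primitives and flags planted removal", {
  ds <- shared_filtered
  gs <- shared_gene_sets
  raw_log <- log_transform(ds$counts)
  direct <- uv_wv_cor(raw_log, raw_log, gs)
  pcs <- expr_pcs(raw_log, 3)
  neg_f <- spikenorm:::eval_factors_from(raw_log, gs$negative_eval, 3)
  expect_equal(direct[["UV_COR"]], weighted_r2(pcs, neg_f), tolerance = 1e-12)
  empty <- gs
  empty$positive_eval <- character(0)
  expect_true(is.na(uv_wv_cor(raw_log, raw_log, empty)[["WV_COR"]]))
})

test_that("RLE metrics: identical samples, hand computation, shift invariance", {
  vals <- matrix(rep(c(1, 5, 9), 3), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(rle_metrics(vals)), c(0, 0))

  shifted <- vals
  shifted[, 2] <- shifted[, 2] + 1
  # per-gene medians: 1,5,9 -> RLE col2 = +1, cols 1,3 = 0
  # sample medians (0,1,0): RLE_MED = mean(c(0,1,0)^2) = 1/3; IQRs all 0
  got <- rle_metrics(shifted)
  expect_equal(got[["RLE_MED"]], 1 / 3)
  expect_equal(got[["RLE_IQR"]], 0)

  expect_equal(rle_metrics(vals + 7), rle_metrics(vals))
})

test_that("procedure scoring follows orientation, dominance and tie rules", {
  tab <- data.frame(name = c("A", "B"),
                    BIO_SIM = c(0.8, 0.2), BATCH_SIM = c(0.1, 0.9),
                    EN_SIM = c(0.9, 0.3), PAM_SIM = c(0.9, 0.4),
                    UV_COR = c(0.05, 0.8), WV_COR = c(0.9, 0.3),
                    RLE_MED = c(0.01, 0.5), RLE_IQR = c(0.01, 0.6))
  sc <- score_procedures(tab)
  expect_identical(sc$name[1], "A")
  expect_equal(sc$performance_score, c(2, 1))

  tied <- rbind(tab[1, ], tab[1, ])
  sc2 <- score_procedures(tied)
  expect_equal(sc2$performance_score, c(1.5, 1.5))
})

test_that("scoring matches a brute-force rank computation and ignores rescaling", {
  set.seed(20)
  metrics <- names(spikenorm:::METRIC_SIGNS)
  tab <- as.data.frame(matrix(runif(4 * 8), 4, 8,
                              dimnames = list(NULL, metrics)))
  tab$name <- paste0("p", 1:4)
  sc <- score_procedures(tab)
  brute <- rowMeans(vapply(metrics, function(m)
    rank(spikenorm:::METRIC_SIGNS[m] * tab[[m]]), numeric(4)))
  expect_equal(sort(sc$performance_score, decreasing = TRUE),
               sort(brute, decreasing = TRUE))
  expect_equal(sc$performance_score[match(tab$name, sc$name)], brute)

  # monotone rescaling of one column leaves ranks unchanged
  tab2 <- tab
  tab2$RLE_MED <- exp(5 * tab2$RLE_MED)
  sc2 <- score_procedures(tab2)
  expect_equal(sc2$performance_score[match(tab$name, sc2$name)],
               sc$performance_score[match(tab$name, sc$name)])
})
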