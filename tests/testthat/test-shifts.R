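test_that("shift vectors follow the mean-difference definition and are translation-equivariant", {
  set.seed(4)
  emb <- matrix(rnorm(100 * 5), 100, 5,
                dimnames = list(paste0("c", 1:100), NULL))
  a <- paste0("c", 1:40); b <- paste0("c", 41:100)
  sh <- compute_shift(emb, a, b)
  expect_equal(sh$vector, colMeans(emb[b, ]) - colMeans(emb[a, ]))
  expect_equal(sh$magnitude, sqrt(sum(sh$vector^2)))
  # identical groups -> zero vector
  expect_equal(compute_shift(emb, a, a)$magnitude, 0)
  # two single cells -> z2 - z1
  sh2 <- compute_shift(emb, "c1", "c2")
  expect_equal(sh2$vector, emb["c2", ] - emb["c1", ])
  # translation equivariance
  emb_t <- sweep(emb, 2, c(5, -2, 1, 0, 3), "+")
  expect_equal(compute_shift(emb_t, a, b)$vector, sh$vector)
  expect_error(compute_shift(emb, character(0), b), "empty")
})

test_that("zero shift reproduces the reconstruction; a shift and its negation invert", {
  b <- fix_vae_bundle()
  X <- b$joint[1:30, , drop = FALSE]
  zero <- rep(0, b$vcfg$latent_dim)
  expect_equal(apply_shift(b$model, X, zero),
               decode(b$model, encode(b$model, X)))
  set.seed(5)
  v <- rnorm(b$vcfg$latent_dim, 0, 0.5)
  # shift then unshift lands within reconstruction error of the original:
  # compare against the plain reconstruction baseline
  shifted <- apply_shift(b$model, X, v)
  back <- decode(b$model, sweep(encode(b$model, shifted), 2, v, "-"))
  rec <- decode(b$model, encode(b$model, X))
  expect_lt(mean((back - rec)^2), mean((rec - X)^2))
  expect_error(apply_shift(b$model, X, rnorm(3)), "latent_dim|width")
})

test_that("mean rank correlation matches hand-computed Spearman values", {
  mk <- function(v) matrix(v, 1, dimnames = list(NULL, paste0("g", seq_along(v))))
  A <- mk(c(1, 2, 3, 4, 5) + 0)
  expect_error(mean_rank_correlation(A, A), "10 genes")
  A <- mk(1:12); B <- mk(12:1)
  expect_equal(mean_rank_correlation(A, A), 1)
  expect_equal(mean_rank_correlation(A, B), -1)
  # 5-gene worked example: rho = 1 - 6*4/(5*24) = 0.8
  a5 <- c(1, 2, 3, 4, 5); b5 <- c(2, 1, 3, 5, 4)
  expect_equal(cor(a5, b5, method = "spearman"), 0.8)
  A12 <- mk(c(a5, 6:12)); B12 <- mk(c(b5, 6:12))
  expect_equal(mean_rank_correlation(A12, B12),
               cor(c(a5, 6:12), c(b5, 6:12), method = "spearman"))
  # non-zero filter drops genes with zero reference mean
  Bz <- mk(c(0, 2:12))
  expect_equal(mean_rank_correlation(A12, Bz, nonzero_filter_on = TRUE),
               cor(2:12, 2:12, method = "spearman"))
})

test_that("shift-pair geometry reports cosine, angle and planar layout", {
  g <- vector_geometry(c(1, 0), c(1, 0))
  expect_equal(g$cosine, 1); expect_equal(g$angle_deg, 0)
  g <- vector_geometry(c(1, 0), c(-1, 0))
  expect_equal(g$cosine, -1); expect_equal(g$angle_deg, 180)
  expect_equal(g$rescaled_similarity, 0)
  g <- vector_geometry(c(1, 0), c(0, 1))
  expect_equal(g$cosine, 0); expect_equal(g$angle_deg, 90)
  expect_equal(g$cyno_xy, c(0, 1))
  expect_equal(g$tmdt_xy, c(-1, 0))    # reference magnitude at 180 degrees
  g0 <- vector_geometry(c(0, 0), c(1, 1))
  expect_true(is.na(g0$cosine))
})

test_that("dataset splits partition cells as specified", {
  sim <- fix_sim_injected()
  sp <- split_dataset(sim$cells, "by_replicate")
  expect_setequal(c(sp$train, sp$test), sim$cells$cell_id)
  expect_length(intersect(sp$train, sp$test), 0)
  reps_tr <- unique(sim$cells$replicate[sim$cells$cell_id %in% sp$train])
  reps_te <- unique(sim$cells$replicate[sim$cells$cell_id %in% sp$test])
  expect_length(intersect(reps_tr, reps_te), 0)

  sp2 <- split_dataset(sim$cells, "random", test_fraction = 0.5, seed = 3)
  expect_setequal(c(sp2$train, sp2$test), sim$cells$cell_id)
  n <- nrow(sim$cells)
  expect_lt(abs(length(sp2$test) - 0.5 * n), 3 * sqrt(n * 0.25))
  expect_identical(sp2, split_dataset(sim$cells, "random",
                                      test_fraction = 0.5, seed = 3))
  one_rep <- sim$cells[sim$cells$replicate == "r1", ]
  expect_error(split_dataset(one_rep, "by_replicate"), "2 replicates")
})

test_that("sign concordance test equals brute-force binomial enumeration", {
  # brute-force oracle: enumerate the pmf directly
  brute <- function(k, n) {
    pmf <- choose(n, 0:n) / 2^n
    min(1, 2 * min(sum(pmf[1:(k + 1)]), sum(pmf[(k + 1):(n + 1)])))
  }
  for (n in c(1, 2, 5, 10, 13, 20)) {
    for (k in 0:n) {
      expect_equal(sign_concordance_test(k, n), brute(k, n), tolerance = 1e-12)
    }
  }
  # the printed headline case and closed forms
  expect_equal(round(sign_concordance_test(11, 13), 3), 0.022)
  expect_equal(sign_concordance_test(5, 10), 1)
  expect_equal(sign_concordance_test(13, 13), 2 * 0.5^13)
  expect_error(sign_concordance_test(0, 0), "positive")
})

test_that("importance/DGE correlation behaves at the identity, the null, and aggregates signs", {
  genes <- paste0("g", 1:1000)
  dge <- data.frame(gene = genes, p = seq(1e-8, 1, length.out = 1000),
                    logFC = rnorm(1000))
  imp_ident <- setNames(-log10(dge$p), genes)
  r <- importance_vs_dge(imp_ident, dge)
  expect_equal(r$rho, 1)
  # independent rankings are near zero for most seeds
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    imp_null <- setNames(runif(1000), genes)
    r0 <- importance_vs_dge(imp_null, dge)
    if (abs(r0$rho) < 0.08) hits <- hits + 1
  }
  expect_gte(hits, 17)   # ~95% of seeds
  agg <- concordance_summary(c(runif(11, 0.1, 0.9), -runif(2, 0.1, 0.9)))
  expect_equal(agg$n_positive, 11)
  expect_equal(round(agg$p, 3), 0.022)
  expect_error(importance_vs_dge(imp_ident[1:5], dge[1:5, ]), "10")
})

test_that("a no-op perturbation yields zero importance and importances are non-negative", {
  b <- fix_vae_bundle()
  X <- b$joint[1:40, , drop = FALSE]
  st <- species_gene_stats(X)
  # force a no-op on one gene: all cells exactly at the mean with zero sd
  g <- colnames(X)[5]
  X2 <- X; X2[, g] <- 1.234
  st2 <- species_gene_stats(X2)
  expect_equal(st2$sd[[g]], 0)
  imp <- feature_importance(b$model, X2, st2, genes = colnames(X)[c(2, 5, 9)])
  expect_equal(unname(imp[g]), 0)
  expect_true(all(imp >= 0))
  impc <- feature_importance(b$model, X2, st2, genes = colnames(X)[c(2, 5, 9)],
                             aggregate = "percell")
  expect_equal(unname(impc[g]), 0)
  expect_true(all(impc >= 0))
})

test_that("humanization improves cross-species rank correlation on held-out cells", {
  b <- fix_vae_bundle()
  split <- split_dataset(b$sim$cells, "by_replicate")
  ev <- evaluate_humanization(b$joint, b$sim$cells, "CD4 T", split, b$vcfg)
  expect_gt(ev$improvement, 0.05)
  expect_gt(ev$rho_humanized, ev$rho_raw)
})
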