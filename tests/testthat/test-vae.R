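test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- vae_config(latent_dim = 3, hidden_sizes = c(7, 5), dropout_p = 0,
                    batch_size = 4, seed = 9)
  G <- 11
  m <- build_model(cfg, paste0("g", 1:G))
  set.seed(42)
  X <- matrix(rnorm(4 * G), 4, G, dimnames = list(NULL, paste0("g", 1:G)))
  set.seed(1)
  fwd <- crossvae:::.vae_fwd(m, X, training = TRUE)
  gr <- crossvae:::.vae_bwd(m, X, fwd)
  f_loss <- function(mm) {
    set.seed(1)   # replay the same latent noise
    f <- crossvae:::.vae_fwd(mm, X, training = TRUE)
    crossvae:::.vae_loss(X, f, cfg$kl_weight)[["total"]]
  }
  eps <- 1e-5
  check <- function(getter, setter, ana) {
    m_p <- setter(m, eps); m_m <- setter(m, -eps)
    num <- (f_loss(m_p) - f_loss(m_m)) / (2 * eps)
    expect_equal(unname(ana), unname(num), tolerance = 1e-4)
  }
  check(NULL, function(mm, d) { mm$enc[[1]]$W[2, 3] <- mm$enc[[1]]$W[2, 3] + d; mm },
        gr$enc[[1]]$W[2, 3])
  check(NULL, function(mm, d) { mm$enc[[2]]$gamma[4] <- mm$enc[[2]]$gamma[4] + d; mm },
        gr$enc[[2]]$gamma[4])
  check(NULL, function(mm, d) { mm$head_mu$W[1, 2] <- mm$head_mu$W[1, 2] + d; mm },
        gr$head_mu$W[1, 2])
  check(NULL, function(mm, d) { mm$head_lv$W[3, 1] <- mm$head_lv$W[3, 1] + d; mm },
        gr$head_lv$W[3, 1])
  check(NULL, function(mm, d) { mm$dec[[1]]$W[2, 2] <- mm$dec[[1]]$W[2, 2] + d; mm },
        gr$dec[[1]]$W[2, 2])
  check(NULL, function(mm, d) { mm$out$b[5] <- mm$out$b[5] + d; mm },
        gr$out$b[5])
})

test_that("model construction is deterministic and parameter counts are closed-form", {
  cfg <- vae_config(latent_dim = 4, hidden_sizes = c(20, 12), seed = 3)
  genes <- paste0("g", 1:30)
  m1 <- build_model(cfg, genes)
  m2 <- build_model(cfg, genes)
  expect_identical(m1$enc[[1]]$W, m2$enc[[1]]$W)
  expect_identical(m1$out$W, m2$out$W)
  G <- 30; h1 <- 20; h2 <- 12; d <- 4
  enc_n <- (G * h1 + h1 + 2 * h1) + (h1 * h2 + h2 + 2 * h2)
  heads <- 2 * (h2 * d + d)
  dec_n <- (d * h2 + h2 + 2 * h2) + (h2 * h1 + h1 + 2 * h1)
  out_n <- h1 * G + G
  expect_equal(n_parameters(m1), enc_n + heads + dec_n + out_n)

  # linear decoder: exactly latent_dim*G + G decoder parameters
  cfgl <- vae_config(latent_dim = 4, hidden_sizes = c(20, 12),
                     decoder_mode = "linear", seed = 3)
  ml <- build_model(cfgl, genes)
  expect_length(ml$dec, 0)
  expect_equal(length(ml$out$W) + length(ml$out$b), 4 * G + G)
})

test_that("the linear decoder is affine up to output clipping", {
  cfg <- vae_config(latent_dim = 3, hidden_sizes = c(8), dropout_p = 0,
                    decoder_mode = "linear", seed = 4)
  m <- build_model(cfg, paste0("g", 1:12))
  set.seed(2)
  z1 <- matrix(rnorm(3), 1); z2 <- matrix(rnorm(3), 1)
  a <- 0.3
  lhs <- decode(m, a * z1 + (1 - a) * z2, clip = FALSE)
  rhs <- a * decode(m, z1, clip = FALSE) + (1 - a) * decode(m, z2, clip = FALSE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("training reduces loss, converges train/val, and beats the mean baseline", {
  b <- fix_vae_bundle()
  log <- b$model$log
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  expect_true(all(is.finite(log$train_loss)))
  expect_true(all(log$kl >= 0))
  # train and validation converge at similar levels
  final <- log[nrow(log), ]
  expect_lt(abs(final$val_loss - final$train_loss), 0.2 * final$train_loss)
  # reconstruction better than predicting the mean
  X <- b$joint
  rec <- decode(b$model, encode(b$model, X))
  mse <- mean((rec - X)^2)
  expect_lt(mse, mean(scale(X, scale = FALSE)^2))
})

test_that("a trained latent space separates two expression clusters", {
  bl <- fix_blobs(n_per = 60, g = 40, sep = 2, seed = 7)
  cfg <- vae_config(latent_dim = 2, hidden_sizes = c(16, 16), batch_size = 16,
                    max_epochs = 50, patience = 15, seed = 5)
  m <- train_model(build_model(cfg, colnames(bl$X)), bl$X)
  Z <- encode(m, bl$X)
  # silhouette-style check: between-cluster distance dominates within
  d <- as.matrix(dist(Z))
  within <- mean(d[1:60, 1:60])
  between <- mean(d[1:60, 61:120])
  expect_gt((between - within) / max(between, within), 0.5)
})

test_that("encode o decode o encode is stable when the latent captures the data rank", {
  # rank-2 data with a 2-dimensional latent: the autoencoding map is close
  # to the identity on the manifold, so re-encoding drifts little
  set.seed(11)
  z <- matrix(rnorm(240), 120, 2)
  W <- matrix(rnorm(80), 2, 40)
  X <- z %*% W + matrix(rnorm(120 * 40, 0, 0.05), 120, 40)
  colnames(X) <- paste0("g", 1:40)
  # dropout off: the stochastic regularizer attenuates the autoencoding map
  cfg <- vae_config(latent_dim = 2, hidden_sizes = c(32, 32), batch_size = 20,
                    max_epochs = 300, patience = 60, learning_rate = 2e-3,
                    dropout_p = 0, seed = 6)
  m <- train_model(build_model(cfg, colnames(X)), X)
  Z <- encode(m, X)
  Z3 <- encode(m, decode(m, Z, clip = FALSE))
  drift <- sqrt(sum((Z3 - Z)^2)) / sqrt(sum(Z^2))
  expect_lt(drift, 0.1)
})

test_that("encoding is deterministic, shape-correct, and refuses foreign gene sets", {
  b <- fix_vae_bundle()
  X <- b$joint[1:8, , drop = FALSE]
  Z <- encode(b$model, X)
  expect_equal(ncol(Z), b$vcfg$latent_dim)
  # identical input rows give identical latent rows
  X2 <- X[c(1, 1, 2), , drop = FALSE]
  Z2 <- encode(b$model, X2)
  expect_equal(Z2[1, ], Z2[2, ])
  # gene mismatch is fatal and names missing genes
  Xbad <- X[, -1, drop = FALSE]
  expect_error(encode(b$model, Xbad), "gene")
  # decode output is finite and non-negative
  z0 <- matrix(0, 1, b$vcfg$latent_dim)
  out <- decode(b$model, z0)
  expect_true(all(is.finite(out)) && all(out >= 0))
})

test_that("HVG selection excludes flat genes, favors planted markers, and bounds the union", {
  b <- fix_vae_bundle()
  nc <- normalized_layer(b$harm$cyno)
  nh <- normalized_layer(b$harm$human)
  # append an exactly constant synthetic gene
  nc2 <- cbind(nc, FLAT = 1); nh2 <- cbind(nh, FLAT = 1)
  sel <- select_hvg(list(cyno = nc2, human = nh2), 300)
  expect_false("FLAT" %in% sel)
  expect_gte(length(sel), 300)
  expect_lte(length(sel), 600)
  # temporally regulated genes (bimodal over timepoints) are enriched
  aff <- b$sim$truth$temporal[["CD4 T"]]$affected
  base_ids <- sub("[|].*$", "", sel)
  frac_aff_sel <- mean(aff %in% base_ids)
  frac_aff_all <- length(aff) / ncol(nc)
  expect_gt(frac_aff_sel, frac_aff_all)
})

test_that("grid search returns the single grid point and a reproducible MSE", {
  b <- fix_vae_bundle()
  X <- b$joint[1:220, , drop = FALSE]
  cfg <- vae_config(hidden_sizes = c(24, 24), batch_size = 32,
                    max_epochs = 8, patience = 8, latent_dim = 6, seed = 6)
  gs <- grid_search(X, latent_grid = 6, batch_grid = 32, n_cells = 200,
                    base_config = cfg, seed = 6)
  expect_equal(unname(gs$best), c(6, 32))
  expect_equal(nrow(gs$table), 1)
  # stored MSE equals recomputation on the stored test split
  Xte <- X[gs$test_idx, , drop = FALSE]
  rec <- decode(gs$best_model, encode(gs$best_model, Xte))
  expect_equal(mean((rec - Xte)^2), gs$table$test_mse, tolerance = 1e-12)
  expect_gt(gs$table$test_mse, 0)
})

test_that("checkpoints round-trip through the plain-text format", {
  cfg <- vae_config(latent_dim = 3, hidden_sizes = c(10), batch_size = 8,
                    max_epochs = 3, patience = 3, seed = 2)
  set.seed(1)
  X <- matrix(abs(rnorm(40 * 15)), 40, 15,
              dimnames = list(NULL, paste0("g", 1:15)))
  m <- train_model(build_model(cfg, colnames(X)), X)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(encode(m2, X), encode(m, X), tolerance = 1e-7)
  expect_equal(m2$config$latent_dim, 3)
})
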