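#' VAE configuration
#'
#' Defaults follow the scGen-style operating point used for the cross-species
#' models: 10 latent dimensions, two hidden layers of 800 nodes with batch
#' normalization, leaky ReLU (negative slope 0.01) and dropout (p = 0.2),
#' batch size 8, up to 100 epochs with early stopping at patience 25.
#' `decoder_mode = "linear"` replaces the decoder by a single affine map
#' (the linear-decoder variant).
#'
#' @param latent_dim latent width (>= 2).
#' @param hidden_sizes hidden layer widths for encoder (decoder mirrors).
#' @param leaky_relu_slope negative slope of the activation.
#' @param dropout_p dropout probability in \[0, 1).
#' @param batch_size minibatch size.
#' @param max_epochs,patience training schedule.
#' @param kl_weight weight of the KL term against the MSE reconstruction.
#' @param decoder_mode "nonlinear" or "linear".
#' @param learning_rate Adam step size.
#' @param val_fraction validation split used when no validation set is given.
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @return list of class VAEConfig.
#' @export
vae_config <- function(latent_dim = 10, hidden_sizes = c(800, 800),
                       leaky_relu_slope = 0.01, dropout_p = 0.2,
                       batch_size = 8, max_epochs = 100, patience = 25,
                       kl_weight = 5e-5,
                       decoder_mode = c("nonlinear", "linear"),
                       learning_rate = 1e-3, val_fraction = 0.1, seed = 1) {
  decoder_mode <- match.arg(decoder_mode)
  stopifnot(latent_dim >= 2, dropout_p >= 0, dropout_p < 1,
            patience <= max_epochs, batch_size >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "VAEConfig"
  cfg
}

.init_dense <- function(n_in, n_out, bn = TRUE) {
  l <- list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                       n_in, n_out),
            b = numeric(n_out))
  if (bn) {
    l$gamma <- rep(1, n_out); l$beta <- numeric(n_out)
    l$rmean <- numeric(n_out); l$rvar <- rep(1, n_out)
  }
  l
}

#' Build an untrained VAE model
#'
#' Encoder: input -> hidden blocks -> (mu, log-variance) of a diagonal
#' Gaussian posterior of width `latent_dim`. Each hidden block is
#' linear -> batch-norm -> leaky ReLU -> dropout. The nonlinear decoder
#' mirrors the encoder; the linear decoder is one affine map with exactly
#' `latent_dim * G + G` parameters.
#'
#' @param config VAEConfig.
#' @param gene_ids genes the model expects (input width).
#' @return object of class VAEModel.
#' @export
build_model <- function(config, gene_ids) {
  stopifnot(inherits(config, "VAEConfig"))
  set.seed(config$seed)
  G <- length(gene_ids)
  hs <- config$hidden_sizes
  enc <- list()
  dims <- c(G, hs)
  for (i in seq_along(hs)) enc[[i]] <- .init_dense(dims[i], dims[i + 1])
  head_mu <- .init_dense(hs[length(hs)], config$latent_dim, bn = FALSE)
  head_lv <- .init_dense(hs[length(hs)], config$latent_dim, bn = FALSE)
  head_lv$W <- head_lv$W * 0.01   # start near unit posterior variance
  dec <- list()
  if (config$decoder_mode == "nonlinear") {
    ddims <- c(config$latent_dim, rev(hs))
    for (i in seq_along(hs)) dec[[i]] <- .init_dense(ddims[i], ddims[i + 1])
    out <- .init_dense(hs[1], G, bn = FALSE)
  } else {
    out <- .init_dense(config$latent_dim, G, bn = FALSE)
  }
  model <- list(config = config, gene_ids = as.character(gene_ids),
                enc = enc, head_mu = head_mu, head_lv = head_lv,
                dec = dec, out = out, log = NULL, trained = FALSE)
  class(model) <- "VAEModel"
  model
}

#' Count the free parameters of a VAE model
#' @param model VAEModel.
#' @return integer parameter count (weights, biases, batch-norm scale/shift;
#'   running statistics excluded).
#' @export
n_parameters <- function(model) {
  cnt <- 0L
  acc <- function(l) length(l$W) + length(l$b) +
    length(l$gamma) + length(l$beta)
  for (l in model$enc) cnt <- cnt + acc(l)
  for (l in model$dec) cnt <- cnt + acc(l)
  cnt + acc(model$head_mu) + acc(model$head_lv) + acc(model$out)
}

.bn_eps <- 1e-5

.block_fwd <- function(X, l, slope, dropout_p, training) {
  Z <- X %*% l$W
  Z <- sweep(Z, 2, l$b, "+")
  if (training) {
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    istd <- 1 / sqrt(va + .bn_eps)
    Xh <- sweep(sweep(Z, 2, mu, "-"), 2, istd, "*")
  } else {
    istd <- 1 / sqrt(l$rvar + .bn_eps)
    Xh <- sweep(sweep(Z, 2, l$rmean, "-"), 2, istd, "*")
    mu <- l$rmean; va <- l$rvar
  }
  Y <- sweep(sweep(Xh, 2, l$gamma, "*"), 2, l$beta, "+")
  A <- ifelse(Y > 0, Y, slope * Y)
  if (training && dropout_p > 0) {
    mask <- matrix(stats::runif(length(A)) >= dropout_p, nrow(A)) / (1 - dropout_p)
    O <- A * mask
  } else {
    mask <- NULL
    O <- A
  }
  list(out = O, cache = list(X = X, Xh = Xh, istd = istd, Y = Y, mask = mask,
                             mu = mu, va = va))
}

.block_bwd <- function(dO, l, cache, slope) {
  if (!is.null(cache$mask)) dO <- dO * cache$mask
  dY <- dO * ifelse(cache$Y > 0, 1, slope)
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  dXh <- sweep(dY, 2, l$gamma, "*")
  n <- nrow(dXh)
  s1 <- colSums(dXh)
  s2 <- colSums(dXh * cache$Xh)
  dZ <- sweep(dXh * n, 2, s1, "-")
  dZ <- dZ - sweep(cache$Xh, 2, s2, "*")
  dZ <- sweep(dZ, 2, cache$istd / n, "*")
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- tcrossprod(dZ, l$W)
  list(dX = dX, grads = list(W = dW, b = db, gamma = dgamma, beta = dbeta))
}

.lin_fwd <- function(X, l) list(out = sweep(X %*% l$W, 2, l$b, "+"),
                                cache = list(X = X))
.lin_bwd <- function(dO, l, cache) {
  list(dX = tcrossprod(dO, l$W),
       grads = list(W = crossprod(cache$X, dO), b = colSums(dO)))
}

# Full forward pass; training mode reparameterizes, inference uses z = mu.
.vae_fwd <- function(model, X, training = FALSE) {
  cfg <- model$config
  caches <- list(enc = list(), dec = list())
  H <- X
  for (i in seq_along(model$enc)) {
    f <- .block_fwd(H, model$enc[[i]], cfg$leaky_relu_slope, cfg$dropout_p,
                    training)
    caches$enc[[i]] <- f$cache
    H <- f$out
  }
  fm <- .lin_fwd(H, model$head_mu); caches$mu <- fm$cache
  fl <- .lin_fwd(H, model$head_lv); caches$lv <- fl$cache
  mu <- fm$out
  lv <- pmin(pmax(fl$out, -10), 10)
  if (training) {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
    Z <- mu + exp(0.5 * lv) * eps
  } else {
    eps <- NULL
    Z <- mu
  }
  H <- Z
  for (i in seq_along(model$dec)) {
    f <- .block_fwd(H, model$dec[[i]], cfg$leaky_relu_slope, cfg$dropout_p,
                    training)
    caches$dec[[i]] <- f$cache
    H <- f$out
  }
  fo <- .lin_fwd(H, model$out); caches$out <- fo$cache
  list(Xhat = fo$out, mu = mu, lv = lv, eps = eps, Z = Z, caches = caches)
}

.vae_loss <- function(X, fwd, kl_weight) {
  rec <- sum((fwd$Xhat - X)^2) / nrow(X)
  kl <- -0.5 * sum(1 + fwd$lv - fwd$mu^2 - exp(fwd$lv)) / nrow(X)
  c(total = rec + kl_weight * kl, recon = rec, kl = kl)
}

# Backward pass: returns gradient lists mirroring the parameter structure.
.vae_bwd <- function(model, X, fwd) {
  cfg <- model$config
  n <- nrow(X)
  g <- list(enc = vector("list", length(model$enc)),
            dec = vector("list", length(model$dec)))
  dXhat <- 2 * (fwd$Xhat - X) / n
  bo <- .lin_bwd(dXhat, model$out, fwd$caches$out)
  g$out <- bo$grads
  dH <- bo$dX
  for (i in rev(seq_along(model$dec))) {
    bb <- .block_bwd(dH, model$dec[[i]], fwd$caches$dec[[i]],
                     cfg$leaky_relu_slope)
    g$dec[[i]] <- bb$grads
    dH <- bb$dX
  }
  dZ <- dH
  sig <- exp(0.5 * fwd$lv)
  dmu <- dZ + cfg$kl_weight * fwd$mu / n
  dlv <- dZ * 0.5 * sig * fwd$eps + cfg$kl_weight * 0.5 * (exp(fwd$lv) - 1) / n
  clip <- fwd$lv <= -10 | fwd$lv >= 10
  dlv[clip] <- 0
  bm <- .lin_bwd(dmu, model$head_mu, fwd$caches$mu)
  bl <- .lin_bwd(dlv, model$head_lv, fwd$caches$lv)
  g$head_mu <- bm$grads
  g$head_lv <- bl$grads
  dH <- bm$dX + bl$dX
  for (i in rev(seq_along(model$enc))) {
    bb <- .block_bwd(dH, model$enc[[i]], fwd$caches$enc[[i]],
                     cfg$leaky_relu_slope)
    g$enc[[i]] <- bb$grads
    dH <- bb$dX
  }
  g
}

.adam_init <- function(model) {
  zero_like <- function(l) lapply(l[intersect(names(l),
                                              c("W", "b", "gamma", "beta"))],
                                  function(p) p * 0)
  list(m = list(enc = lapply(model$enc, zero_like),
                dec = lapply(model$dec, zero_like),
                head_mu = zero_like(model$head_mu),
                head_lv = zero_like(model$head_lv),
                out = zero_like(model$out)),
       v = NULL, t = 0)
}

.adam_step <- function(model, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  if (is.null(state$v)) state$v <- state$m
  state$t <- state$t + 1
  upd <- function(layer, g, m, v) {
    for (nm in names(g)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^state$t)
      vhat <- v[[nm]] / (1 - b2^state$t)
      layer[[nm]] <- layer[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(layer = layer, m = m, v = v)
  }
  for (grp in c("enc", "dec")) {
    for (i in seq_along(model[[grp]])) {
      r <- upd(model[[grp]][[i]], grads[[grp]][[i]],
               state$m[[grp]][[i]], state$v[[grp]][[i]])
      model[[grp]][[i]] <- r$layer
      state$m[[grp]][[i]] <- r$m; state$v[[grp]][[i]] <- r$v
    }
  }
  for (grp in c("head_mu", "head_lv", "out")) {
    r <- upd(model[[grp]], grads[[grp]], state$m[[grp]], state$v[[grp]])
    model[[grp]] <- r$layer
    state$m[[grp]] <- r$m; state$v[[grp]] <- r$v
  }
  list(model = model, state = state)
}

.update_running <- function(model, fwd, momentum = 0.9) {
  for (grp in c("enc", "dec")) {
    for (i in seq_along(model[[grp]])) {
      c <- fwd$caches[[grp]][[i]]
      l <- model[[grp]][[i]]
      l$rmean <- momentum * l$rmean + (1 - momentum) * c$mu
      l$rvar <- momentum * l$rvar + (1 - momentum) * c$va
      model[[grp]][[i]] <- l
    }
  }
  model
}

.check_genes <- function(model, X) {
  gn <- colnames(X)
  if (is.null(gn) || !identical(gn, model$gene_ids)) {
    missing <- setdiff(model$gene_ids, gn)
    stop("input gene set does not match the model's training genes",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", ")))
  }
  invisible(TRUE)
}

#' Train a VAE
#'
#' Minimizes mean-squared reconstruction error on the log-normalized layer
#' plus `kl_weight` times the KL divergence of the latent posterior from
#' N(0, I), with Adam. Stops when the validation loss fails to improve for
#' `patience` epochs (the best parameters are restored) or at `max_epochs`.
#'
#' @param model VAEModel from [build_model()].
#' @param X_train cells x genes normalized matrix with colnames matching the
#'   model's gene ids.
#' @param X_val optional validation matrix; if NULL, `val_fraction` of the
#'   training rows is held out.
#' @param verbose print per-epoch losses.
#' @return trained VAEModel with `$log` (epoch, train_loss, val_loss,
#'   recon, kl).
#' @export
train_model <- function(model, X_train, X_val = NULL, verbose = FALSE) {
  .check_genes(model, X_train)
  cfg <- model$config
  set.seed(cfg$seed + 1L)
  if (is.null(X_val)) {
    n_val <- max(1, round(cfg$val_fraction * nrow(X_train)))
    vi <- sample.int(nrow(X_train), n_val)
    X_val <- X_train[vi, , drop = FALSE]
    X_train <- X_train[-vi, , drop = FALSE]
  } else {
    .check_genes(model, X_val)
  }
  n <- nrow(X_train)
  state <- .adam_init(model)
  best <- list(loss = Inf, model = model, epoch = 0)
  log <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- c(total = 0, recon = 0, kl = 0)
    nb <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      if (length(idx) < 2) next      # batch-norm needs >= 2 rows
      Xb <- X_train[idx, , drop = FALSE]
      fwd <- .vae_fwd(model, Xb, training = TRUE)
      loss <- .vae_loss(Xb, fwd, cfg$kl_weight)
      if (!all(is.finite(loss))) stop("non-finite loss at epoch ", epoch)
      grads <- .vae_bwd(model, Xb, fwd)
      st <- .adam_step(model, grads, state, cfg$learning_rate)
      model <- st$model; state <- st$state
      model <- .update_running(model, fwd)
      ep_loss <- ep_loss + loss
      nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    vf <- .vae_fwd(model, X_val, training = FALSE)
    vloss <- .vae_loss(X_val, vf, cfg$kl_weight)[["total"]]
    log[[epoch]] <- data.frame(epoch = epoch,
                               train_loss = ep_loss[["total"]],
                               val_loss = vloss,
                               recon = ep_loss[["recon"]],
                               kl = ep_loss[["kl"]])
    if (verbose) message(sprintf("epoch %3d train %.4f val %.4f",
                                 epoch, ep_loss[["total"]], vloss))
    if (vloss < best$loss - 1e-8) {
      best <- list(loss = vloss, model = model, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  model <- best$model
  model$log <- do.call(rbind, log)
  model$trained <- TRUE
  model
}

#' Encode expression into the latent space
#'
#' Deterministic at inference: returns the posterior mean, with dropout off
#' and batch normalization in running-statistics mode. Inputs whose gene set
#' differs from the training genes are refused.
#'
#' @param model trained VAEModel.
#' @param X cells x genes normalized matrix.
#' @return cells x latent_dim matrix (rownames preserved).
#' @export
encode <- function(model, X) {
  .check_genes(model, X)
  Z <- .vae_fwd(model, X, training = FALSE)$mu
  rownames(Z) <- rownames(X)
  Z
}

#' Decode latent coordinates back to expression
#'
#' Reconstruction on the normalized (log1p) scale, clipped below at 0.
#'
#' @param model trained VAEModel.
#' @param Z cells x latent_dim matrix.
#' @return cells x genes matrix.
#' @export
decode <- function(model, Z, clip = TRUE) {
  stopifnot(ncol(Z) == model$config$latent_dim)
  cfg <- model$config
  H <- Z
  for (i in seq_along(model$dec)) {
    H <- .block_fwd(H, model$dec[[i]], cfg$leaky_relu_slope, 0, FALSE)$out
  }
  X <- .lin_fwd(H, model$out)$out
  if (clip) X[X < 0] <- 0
  colnames(X) <- model$gene_ids
  rownames(X) <- rownames(Z)
  X
}

#' Select highly variable genes per species and take the union
#'
#' Genes are ranked per species by normalized dispersion: dispersion
#' (variance/mean of the log-normalized layer) standardized within 20
#' mean-quantile bins. Zero-variance genes are never selected. The union
#' across species is returned sorted.
#'
#' @param norm_by_species named list of cells x genes normalized matrices
#'   over a common gene space.
#' @param n_per_species genes per species (default 2000).
#' @return sorted character vector of selected genes.
#' @export
select_hvg <- function(norm_by_species, n_per_species = 2000) {
  sel <- character(0)
  for (sp in names(norm_by_species)) {
    X <- norm_by_species[[sp]]
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    va <- pmax(va, 0)
    disp <- ifelse(mu > 0, va / mu, 0)
    n_take <- min(n_per_species, ncol(X))
    if (n_take < n_per_species) {
      warning("fewer genes than requested; returning all for ", sp)
    }
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = 20, labels = FALSE)
    z <- disp
    for (b in unique(bins)) {
      in_b <- bins == b
      s <- stats::sd(disp[in_b])
      z[in_b] <- if (is.na(s) || s == 0) 0 else
        (disp[in_b] - mean(disp[in_b])) / s
    }
    z[va == 0] <- -Inf
    ord <- order(z, decreasing = TRUE)
    ord <- ord[va[ord] > 0]
    sel <- union(sel, colnames(X)[utils::head(ord, n_take)])
  }
  sort(sel)
}

#' Hyperparameter grid search on a random subsample
#'
#' Trains one model per (latent_dim, batch_size) grid point on a subsample
#' (default 1,000 cells, 80/20 train/test) and returns the combination with
#' the lowest reconstruction mean-squared error on the held-out cells,
#' together with the full MSE table.
#'
#' @param X normalized matrix (colnames = genes).
#' @param latent_grid,batch_grid integer vectors.
#' @param n_cells subsample size.
#' @param base_config VAEConfig supplying all other hyperparameters.
#' @param seed RNG seed for subsampling/splitting.
#' @return list(best = c(latent_dim, batch_size), table = data.frame,
#'   test_idx).
#' @export
grid_search <- function(X, latent_grid = c(10), batch_grid = c(8),
                        n_cells = 1000, base_config = vae_config(),
                        seed = 1) {
  if (!length(latent_grid) || !length(batch_grid)) stop("empty grid")
  set.seed(seed)
  n_cells <- min(n_cells, nrow(X))
  sub <- sample.int(nrow(X), n_cells)
  n_tr <- round(0.8 * n_cells)
  tr <- sub[seq_len(n_tr)]
  te <- sub[(n_tr + 1):n_cells]
  rows <- list()
  best_model <- NULL
  best_mse <- Inf
  for (ld in latent_grid) for (bs in batch_grid) {
    cfg <- base_config
    cfg$latent_dim <- ld
    cfg$batch_size <- bs
    model <- build_model(cfg, colnames(X))
    model <- train_model(model, X[tr, , drop = FALSE])
    rec <- decode(model, encode(model, X[te, , drop = FALSE]))
    mse <- mean((rec - X[te, , drop = FALSE])^2)
    if (mse < best_mse) {
      best_mse <- mse
      best_model <- model
    }
    rows[[length(rows) + 1]] <- data.frame(latent_dim = ld, batch_size = bs,
                                           test_mse = mse)
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.min(tab$test_mse), ]
  list(best = c(latent_dim = best$latent_dim, batch_size = best$batch_size),
       table = tab, test_idx = te, best_model = best_model)
}

#' Save / load a model checkpoint as plain text
#'
#' The checkpoint directory holds a JSON config, the gene list and one TSV
#' per parameter tensor.
#'
#' @param model trained VAEModel.
#' @param dir checkpoint directory.
#' @return invisibly `dir`.
#' @export
save_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(model$gene_ids, file.path(dir, "genes.txt"))
  flat <- .flatten_params(model)
  for (nm in names(flat)) {
    utils::write.table(flat[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(model$log)) write_table_tsv(model$log, file.path(dir, "log.tsv"))
  invisible(dir)
}

.flatten_params <- function(model) {
  out <- list()
  grab <- function(l, prefix) {
    for (nm in intersect(names(l), c("W", "b", "gamma", "beta", "rmean", "rvar"))) {
      out[[paste0(prefix, ".", nm)]] <<- as.matrix(l[[nm]])
    }
  }
  for (i in seq_along(model$enc)) grab(model$enc[[i]], paste0("enc", i))
  for (i in seq_along(model$dec)) grab(model$dec[[i]], paste0("dec", i))
  grab(model$head_mu, "head_mu"); grab(model$head_lv, "head_lv")
  grab(model$out, "out")
  out
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$hidden_sizes <- as.numeric(cfg$hidden_sizes)
  class(cfg) <- "VAEConfig"
  genes <- readLines(file.path(dir, "genes.txt"))
  model <- build_model(cfg, genes)
  fill <- function(l, prefix) {
    for (nm in intersect(names(l), c("W", "b", "gamma", "beta", "rmean", "rvar"))) {
      v <- as.matrix(utils::read.table(file.path(dir, paste0(prefix, ".", nm, ".tsv")),
                                       sep = "\t"))
      dimnames(v) <- NULL
      l[[nm]] <- if (is.matrix(l[[nm]])) v else as.numeric(v)
    }
    l
  }
  for (i in seq_along(model$enc)) model$enc[[i]] <- fill(model$enc[[i]], paste0("enc", i))
  for (i in seq_along(model$dec)) model$dec[[i]] <- fill(model$dec[[i]], paste0("dec", i))
  model$head_mu <- fill(model$head_mu, "head_mu")
  model$head_lv <- fill(model$head_lv, "head_lv")
  model$out <- fill(model$out, "out")
  lp <- file.path(dir, "log.tsv")
  if (file.exists(lp)) model$log <- utils::read.table(lp, sep = "\t", header = TRUE)
  model$trained <- TRUE
  model
}
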