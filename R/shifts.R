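#' Compute a latent shift vector between two cell groups
#'
#' The difference between mean latent representations,
#' `mean(to_group) - mean(from_group)`. For the species shift this is
#' human@0h minus cyno@0h; for a temporal shift it is timepoint t minus 0h
#' within one species. Translation-equivariant: adding a constant vector to
#' every embedding leaves the shift unchanged.
#'
#' @param embedding cells x d latent matrix (rownames = cell ids).
#' @param from_ids,to_ids cell ids of the two groups (non-empty).
#' @param kind "species" or "temporal" (metadata only).
#' @param cell_type,from_group,to_group descriptors stored on the result.
#' @return object of class ShiftVector: list(vector, kind, cell_type,
#'   from_group, to_group, magnitude).
#' @export
compute_shift <- function(embedding, from_ids, to_ids, kind = "species",
                          cell_type = NA_character_,
                          from_group = NA_character_,
                          to_group = NA_character_) {
  if (!length(from_ids)) stop("empty from-group (", from_group, ")")
  if (!length(to_ids)) stop("empty to-group (", to_group, ")")
  fi <- match(from_ids, rownames(embedding))
  ti <- match(to_ids, rownames(embedding))
  if (anyNA(fi) || anyNA(ti)) stop("cells missing from embedding")
  v <- colMeans(embedding[ti, , drop = FALSE]) -
    colMeans(embedding[fi, , drop = FALSE])
  obj <- list(vector = v, kind = kind, cell_type = cell_type,
              from_group = from_group, to_group = to_group,
              magnitude = sqrt(sum(v^2)))
  class(obj) <- "ShiftVector"
  obj
}

#' Apply a latent shift and decode ("in-silico humanization")
#'
#' Encodes the source cells, adds the shift vector in latent space, and
#' decodes back to expression — no retraining or fine-tuning on the target.
#'
#' @param model trained VAEModel.
#' @param X_source normalized expression over the model's genes.
#' @param shift ShiftVector (or bare numeric of latent width).
#' @return predicted expression matrix (normalized scale).
#' @export
apply_shift <- function(model, X_source, shift) {
  v <- if (inherits(shift, "ShiftVector")) shift$vector else shift
  if (length(v) != model$config$latent_dim) {
    stop("shift width ", length(v), " does not match latent_dim ",
         model$config$latent_dim)
  }
  Z <- encode(model, X_source)
  decode(model, sweep(Z, 2, v, "+"))
}

#' Spearman correlation of mean gene expression between two datasets
#'
#' Computes per-gene means in A and B; optionally drops genes with zero mean
#' in the reference B (the non-zero expression filter applied to the human
#' side); returns the Spearman rank correlation with average ranks for ties.
#'
#' @param exprA,exprB cells x genes matrices over the same gene space.
#' @param nonzero_filter_on drop genes with zero mean in B.
#' @return Spearman rho.
#' @export
mean_rank_correlation <- function(exprA, exprB, nonzero_filter_on = TRUE) {
  stopifnot(identical(colnames(exprA), colnames(exprB)))
  ma <- colMeans(exprA)
  mb <- colMeans(exprB)
  if (nonzero_filter_on) {
    keep <- mb > 0
    ma <- ma[keep]; mb <- mb[keep]
  }
  if (length(ma) < 10) stop("fewer than 10 genes after filter")
  stats::cor(ma, mb, method = "spearman")
}

#' Geometry of a pair of shift vectors
#'
#' Cosine similarity, its rescaled form (1+cos)/2, magnitudes, a planar
#' layout placing the reference (human) vector on the x-axis and the second
#' (cyno) vector at the cosine-derived angle, and the "theoretical maximum
#' difference in trajectory" vector: the human magnitude at 180 degrees.
#'
#' @param shift_h,shift_c ShiftVector (or numeric) of equal width; `shift_h`
#'   is the reference.
#' @return list(cosine, rescaled_similarity, magnitude_h, magnitude_c,
#'   angle_deg, human_xy, cyno_xy, tmdt_xy).
#' @export
vector_geometry <- function(shift_h, shift_c) {
  u <- if (inherits(shift_h, "ShiftVector")) shift_h$vector else shift_h
  v <- if (inherits(shift_c, "ShiftVector")) shift_c$vector else shift_c
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(list(cosine = NA_real_, rescaled_similarity = NA_real_,
                magnitude_h = nu, magnitude_c = nv, angle_deg = NA_real_,
                human_xy = c(nu, 0), cyno_xy = c(NA_real_, NA_real_),
                tmdt_xy = c(-nu, 0)))
  }
  cosv <- sum(u * v) / (nu * nv)
  cosv <- min(1, max(-1, cosv))
  ang <- acos(cosv)
  list(cosine = cosv,
       rescaled_similarity = (1 + cosv) / 2,
       magnitude_h = nu, magnitude_c = nv,
       angle_deg = ang * 180 / pi,
       human_xy = c(nu, 0),
       cyno_xy = c(nv * cosv, nv * sin(ang)),
       tmdt_xy = c(-nu, 0))
}

#' Split cells into train and test sets
#'
#' `by_replicate` puts whole replicates on one side (the first replicate of
#' each species in train, the second in test); `random` assigns each cell
#' independently with the given test fraction. Partitions are disjoint and
#' exhaustive.
#'
#' @param celltable CellTable.
#' @param mode "by_replicate" or "random".
#' @param test_fraction test share in random mode.
#' @param seed RNG seed (random mode).
#' @return list(train, test) of cell ids.
#' @export
split_dataset <- function(celltable, mode = c("by_replicate", "random"),
                          test_fraction = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "by_replicate") {
    train <- test <- character(0)
    for (sp in unique(celltable$species)) {
      sub <- celltable[celltable$species == sp, ]
      reps <- sort(unique(sub$replicate))
      if (length(reps) < 2) stop("by_replicate split needs >= 2 replicates for ", sp)
      train <- c(train, sub$cell_id[sub$replicate == reps[1]])
      test <- c(test, sub$cell_id[sub$replicate != reps[1]])
    }
    list(train = train, test = test)
  } else {
    set.seed(seed)
    in_test <- stats::runif(nrow(celltable)) < test_fraction
    list(train = celltable$cell_id[!in_test],
         test = celltable$cell_id[in_test])
  }
}

#' Per-species gene statistics for the perturbation heuristic
#'
#' @param norm cells x genes normalized matrix.
#' @return list(mean, sd) named numeric vectors.
#' @export
species_gene_stats <- function(norm) {
  mu <- colMeans(norm)
  n <- nrow(norm)
  if (n < 2) stop("need >= 2 cells for gene standard deviations")
  va <- colSums(sweep(norm, 2, mu)^2) / (n - 1)
  list(mean = mu, sd = sqrt(va))
}

#' Perturbation-based gene feature importance
#'
#' For each gene, every cell's input value is moved toward the
#' species-specific mean supplied in `stats`, capped at `alpha` times the
#' species-specific standard deviation
#' (`x' = x + clip(mu - x, -alpha*sd, +alpha*sd)`), all other genes
#' unchanged, and the latent embedding of the perturbed data is compared
#' with the unperturbed one. Passing the *other* species' statistics probes
#' the humanization direction: genes whose values must move coherently to
#' resemble the target species displace the embedding most.
#'
#' Two aggregations of the latent displacement are available:
#' `"centroid"` (default) is the Euclidean norm of the mean displacement
#' across cells — incoherent within-population (denoising) moves average
#' out, so the score isolates coherent shifts; `"percell"` is the mean over
#' cells of the per-cell Euclidean distance. A no-op perturbation (sd = 0
#' and all cells at the mean) yields importance 0 under both.
#'
#' @param model trained VAEModel.
#' @param X normalized expression (cells from one species).
#' @param stats list(mean, sd) from [species_gene_stats()] in model gene
#'   order (typically the target species of the comparison).
#' @param alpha cap multiplier (default 1).
#' @param genes optional subset of genes to score (default all).
#' @param aggregate "centroid" or "percell".
#' @return named numeric vector of importances (>= 0).
#' @export
feature_importance <- function(model, X, stats, alpha = 1, genes = NULL,
                               aggregate = c("centroid", "percell")) {
  .check_genes(model, X)
  aggregate <- match.arg(aggregate)
  stopifnot(alpha > 0)
  Z0 <- encode(model, X)
  if (is.null(genes)) genes <- model$gene_ids
  gi <- match(genes, model$gene_ids)
  if (anyNA(gi)) stop("unknown genes in feature_importance")
  imp <- numeric(length(gi))
  for (j in seq_along(gi)) {
    g <- gi[j]
    delta <- stats$mean[g] - X[, g]
    cap <- alpha * stats$sd[g]
    delta <- pmin(pmax(delta, -cap), cap)
    Xp <- X
    Xp[, g] <- X[, g] + delta
    Zp <- encode(model, Xp)
    imp[j] <- if (aggregate == "centroid") {
      sqrt(sum(colMeans(Zp - Z0)^2))
    } else {
      mean(sqrt(rowSums((Zp - Z0)^2)))
    }
  }
  stats::setNames(imp, genes)
}

#' Two-sided exact binomial sign-concordance test
#'
#' Tests whether the number of positive signs among `n_total` independent
#' directions exceeds chance (success probability 0.5):
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param n_positive,n_total counts.
#' @return two-sided p-value.
#' @export
sign_concordance_test <- function(n_positive, n_total) {
  if (n_total == 0) stop("n_total must be positive")
  stopifnot(n_positive >= 0, n_positive <= n_total)
  lo <- stats::pbinom(n_positive, n_total, 0.5)
  hi <- stats::pbinom(n_positive - 1, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Correlate VAE feature importance with DGE gene importance
#'
#' Spearman correlation between perturbation importances and a DGE-derived
#' ranking (-log10 p by default, |log2 FC| by flag) over the shared gene
#' universe.
#'
#' @param importance named numeric vector from [feature_importance()].
#' @param dge_table DGETable data.frame (gene, p, logFC).
#' @param dge_metric "neglog10p" or "abslogfc".
#' @return list(rho, p, direction, n_genes).
#' @export
importance_vs_dge <- function(importance, dge_table,
                              dge_metric = c("neglog10p", "abslogfc")) {
  dge_metric <- match.arg(dge_metric)
  shared <- intersect(names(importance), dge_table$gene)
  if (!length(shared)) stop("empty gene intersection")
  if (length(shared) < 10) stop("shared gene universe < 10")
  i <- match(shared, dge_table$gene)
  y <- if (dge_metric == "neglog10p") {
    -log10(pmax(dge_table$p[i], 1e-300))
  } else {
    abs(dge_table$logFC[i])
  }
  ct <- stats::cor.test(importance[shared], y, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value,
       direction = sign(unname(ct$estimate)), n_genes = length(shared))
}

#' Aggregate importance/DGE correlation signs across contexts
#'
#' Counts positive Spearman signs across cell types/conditions and applies
#' [sign_concordance_test()].
#'
#' @param correlations numeric vector of rho values.
#' @return list(n_positive, n_total, p).
#' @export
concordance_summary <- function(correlations) {
  correlations <- correlations[!is.na(correlations)]
  n_pos <- sum(correlations > 0)
  list(n_positive = n_pos, n_total = length(correlations),
       p = sign_concordance_test(n_pos, length(correlations)))
}

#' Evaluate in-silico humanization on a held-out split (proof of concept)
#'
#' Trains a cell-type-specific VAE on the training cells (both species, all
#' timepoints), computes the species shift at 0h on the training split,
#' humanizes the held-out cyno 0h cells, and reports the Spearman mean-rank
#' correlation against held-out human 0h cells before and after
#' humanization.
#'
#' @param norm joint normalized matrix (cells x genes, unified space).
#' @param celltable CellTable covering the rows of `norm`.
#' @param cell_type cell type to evaluate.
#' @param split list(train, test) from [split_dataset()].
#' @param config VAEConfig.
#' @return list(rho_raw, rho_humanized, improvement, n_train, n_test, model,
#'   delta_species).
#' @export
evaluate_humanization <- function(norm, celltable, cell_type, split,
                                  config = vae_config()) {
  ct <- celltable[celltable$label == cell_type & !is.na(celltable$label), ]
  tr <- intersect(split$train, ct$cell_id)
  te <- intersect(split$test, ct$cell_id)
  pick <- function(ids, sp, tp) {
    sub <- ct[ct$cell_id %in% ids & ct$species == sp & ct$timepoint == tp, ]
    sub$cell_id
  }
  model <- build_model(config, colnames(norm))
  model <- train_model(model, norm[tr, , drop = FALSE])
  emb_tr <- encode(model, norm[tr, , drop = FALSE])
  delta <- compute_shift(emb_tr,
                         from_ids = pick(tr, "cyno", "0h"),
                         to_ids = pick(tr, "human", "0h"),
                         kind = "species", cell_type = cell_type,
                         from_group = "cyno@0h", to_group = "human@0h")
  cyno_te <- pick(te, "cyno", "0h")
  human_te <- pick(te, "human", "0h")
  if (!length(cyno_te) || !length(human_te)) {
    stop("held-out split lacks 0h cells for ", cell_type)
  }
  X_cyno <- norm[cyno_te, , drop = FALSE]
  X_human <- norm[human_te, , drop = FALSE]
  humanized <- apply_shift(model, X_cyno, delta)
  list(rho_raw = mean_rank_correlation(X_cyno, X_human),
       rho_humanized = mean_rank_correlation(humanized, X_human),
       improvement = mean_rank_correlation(humanized, X_human) -
         mean_rank_correlation(X_cyno, X_human),
       n_train = length(tr), n_test = length(te),
       model = model, delta_species = delta)
}
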