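#' QC configuration
#'
#' @param nmads MAD multiplier for outlier bounds.
#' @param mito_threshold named per-species mito-fraction cutoffs. The
#'   defaults keep the asymmetric per-species values (0.0015 cyno, 0.15
#'   human) used in the motivating study; both are configurable.
#' @param cluster_bad_fraction cluster-level doublet/low-quality fraction
#'   above which a whole cluster is pruned.
#' @param doublet_vote_k votes needed to call a doublet.
#' @param qc_cluster_resolution,annot_cluster_resolution modularity
#'   resolutions for the QC and annotation clusterings.
#' @param expected_doublet_rate quantile used to threshold doublet scores.
#' @param n_pcs,knn_k embedding and graph parameters.
#' @return list of class QCConfig.
#' @export
qc_config <- function(nmads = 3,
                      mito_threshold = c(cyno = 0.0015, human = 0.15),
                      cluster_bad_fraction = 0.25,
                      doublet_vote_k = 2,
                      qc_cluster_resolution = 7,
                      annot_cluster_resolution = 4,
                      expected_doublet_rate = 0.06,
                      n_pcs = 50, knn_k = 15) {
  stopifnot(nmads > 0, cluster_bad_fraction >= 0, cluster_bad_fraction <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "QCConfig"
  cfg
}

#' MAD-based outlier bounds
#'
#' Bounds are median +- nmads * MAD with the unscaled MAD
#' `median(|x - median(x)|)`.
#'
#' @param values numeric vector (>= 3 finite values).
#' @param nmads multiplier.
#' @return c(lower, upper).
#' @export
mad_bounds <- function(values, nmads = 3) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("mad_bounds needs >= 3 finite values")
  med <- stats::median(v)
  mad <- stats::median(abs(v - med))
  if (mad == 0) warning("all values identical; bounds collapse to the median")
  c(lower = med - nmads * mad, upper = med + nmads * mad)
}

#' Flag low-quality cells by MAD thresholds and mito fraction
#'
#' A cell is flagged `low_quality` if log1p(genes detected) or log1p(total
#' counts) falls outside the MAD bounds computed per sample (species x
#' replicate), or if its mitochondrial count fraction (genes with the "MT-"
#' prefix) exceeds the per-species threshold.
#'
#' @param counts CountMatrix covering (at least) the cells of one species.
#' @param celltable CellTable.
#' @param config QCConfig.
#' @return updated CellTable with `low_quality` flags and refreshed
#'   `mito_fraction`.
#' @export
qc_flags <- function(counts, celltable, config = qc_config()) {
  idx <- celltable$cell_id %in% counts$cell_ids
  sub <- celltable[idx, , drop = FALSE]
  m <- counts$counts[sub$cell_id, , drop = FALSE]
  tot <- Matrix::rowSums(m)
  ngen <- Matrix::rowSums(m > 0)
  mito <- grepl("^MT-", counts$gene_ids)
  mf <- if (any(mito)) {
    ifelse(tot > 0, Matrix::rowSums(m[, mito, drop = FALSE]) / tot, 0)
  } else rep(0, nrow(sub))
  celltable$mito_fraction[match(sub$cell_id, celltable$cell_id)] <- mf

  flagged <- mf > config$mito_threshold[sub$species]
  sample_key <- paste(sub$species, sub$replicate)
  for (key in unique(sample_key)) {
    in_s <- sample_key == key
    if (sum(in_s) < 3) {
      warning("sample ", key, " has < 3 cells; MAD bounds skipped")
      next
    }
    for (metric in list(log1p(ngen), log1p(tot))) {
      b <- suppressWarnings(mad_bounds(metric[in_s], config$nmads))
      flagged[in_s] <- flagged[in_s] |
        metric[in_s] < b[1] | metric[in_s] > b[2]
    }
  }
  add_qc_flag(celltable, sub$cell_id[flagged], "low_quality")
}

#' Combine doublet calls by majority vote
#'
#' A cell is a doublet if at least `k` of the provided call tables mark it
#' positive. Cells missing from a table count as negative for that table.
#'
#' @param score_tables list of 1-3 data.frames with columns cell_id, call
#'   (logical or 0/1).
#' @param cell_ids cells to report on.
#' @param k votes required.
#' @return named logical vector over `cell_ids`.
#' @export
doublet_vote <- function(score_tables, cell_ids, k = 2) {
  stopifnot(length(score_tables) >= 1, length(score_tables) <= 3)
  votes <- rep(0L, length(cell_ids))
  for (tab in score_tables) {
    stopifnot(all(c("cell_id", "call") %in% names(tab)))
    i <- match(cell_ids, tab$cell_id)
    if (anyNA(i)) warning(sum(is.na(i)),
                          " cell(s) missing from a doublet table; treated as negative")
    call <- ifelse(is.na(i), FALSE, as.logical(tab$call[i]))
    votes <- votes + as.integer(call)
  }
  k_eff <- if (length(score_tables) == 1) 1 else k
  stats::setNames(votes >= k_eff, cell_ids)
}

#' PCA embedding of the normalized layer
#'
#' @param norm cells x genes normalized matrix.
#' @param n_pcs number of components.
#' @return cells x n_pcs score matrix.
#' @export
pca_embed <- function(norm, n_pcs = 50) {
  n_pcs <- min(n_pcs, nrow(norm) - 1, ncol(norm))
  p <- stats::prcomp(norm, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- p$x
  rownames(emb) <- rownames(norm)
  emb
}

#' Simulated-doublet kNN score
#'
#' The package's internal doublet scorer: simulate `n_sim` artificial
#' doublets by summing random cell pairs, embed observed cells and simulated
#' doublets jointly by PCA of the log-normalized counts, and score every
#' observed cell by the fraction of simulated doublets among its
#' `k_neighbors` nearest neighbors. Calls are made by thresholding scores at
#' the (1 - expected_rate) quantile.
#'
#' @param counts CountMatrix (>= 50 cells).
#' @param n_sim simulated doublets (default: one per observed cell).
#' @param k_neighbors kNN size.
#' @param expected_rate expected doublet fraction for the call threshold.
#' @param n_pcs PCA dimensions.
#' @param seed RNG seed.
#' @return data.frame(cell_id, score, call).
#' @export
synthetic_doublet_score <- function(counts, n_sim = NULL, k_neighbors = 25,
                                    expected_rate = 0.06, n_pcs = 30,
                                    seed = 1) {
  stopifnot(inherits(counts, "CountMatrix"))
  n <- length(counts$cell_ids)
  stopifnot(n >= 50)
  if (is.null(n_sim)) n_sim <- n
  if (n_sim == 0) {
    return(data.frame(cell_id = counts$cell_ids, score = 0, call = FALSE))
  }
  set.seed(seed)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- sample.int(n, n_sim, replace = TRUE)
  doub <- counts$counts[i1, , drop = FALSE] + counts$counts[i2, , drop = FALSE]
  all_norm <- normalize_log1p(rbind(counts$counts, doub))
  emb <- pca_embed(all_norm, n_pcs)
  obs <- emb[seq_len(n), , drop = FALSE]
  d2 <- .cross_dist2(obs, emb)
  score <- numeric(n)
  k <- min(k_neighbors, n + n_sim - 1)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]     # drop self (distance 0)
    score[i] <- mean(nb > n)
  }
  thr <- stats::quantile(score, 1 - expected_rate, names = FALSE)
  data.frame(cell_id = counts$cell_ids, score = score,
             call = score > thr | (score >= thr & score > 0))
}

.cross_dist2 <- function(a, b) {
  # squared Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' kNN-graph modularity clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding and runs Louvain
#' community detection at the given resolution. Cluster labels are
#' consecutive integers ordered by decreasing cluster size.
#'
#' @param embedding cells x d matrix (rownames = cell ids).
#' @param resolution modularity resolution (> 0).
#' @param k neighbors per cell.
#' @param seed RNG seed for the community search.
#' @return named integer vector of cluster ids.
#' @export
cluster_graph <- function(embedding, resolution = 1, k = 15, seed = 1) {
  n <- nrow(embedding)
  if (n < k + 1) stop("need at least k+1 = ", k + 1, " cells")
  stopifnot(resolution > 0)
  d2 <- .cross_dist2(embedding, embedding)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1)]
    edges[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, edges)
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(memb)])
  stats::setNames(out, rownames(embedding))
}

#' Prune flagged cells and contaminated clusters
#'
#' Removes (i) all flagged cells, (ii) whole clusters whose doublet fraction
#' exceeds `bad_fraction`, (iii) whole clusters whose low-quality fraction
#' exceeds `bad_fraction`. Idempotent; output is a subset of the input.
#'
#' @param clusters named integer vector of cluster ids per cell.
#' @param doublet_flag,lowq_flag named logical vectors per cell.
#' @param bad_fraction cluster-level threshold (default 0.25).
#' @return list with `kept` (cell ids), `removed` (data.frame cell_id,
#'   reason).
#' @export
prune_clusters <- function(clusters, doublet_flag, lowq_flag,
                           bad_fraction = 0.25) {
  ids <- names(clusters)
  stopifnot(!is.null(ids), all(ids %in% names(doublet_flag)),
            all(ids %in% names(lowq_flag)))
  db <- doublet_flag[ids]
  lq <- lowq_flag[ids]
  d_frac <- tapply(db, clusters, mean)
  l_frac <- tapply(lq, clusters, mean)
  bad_d <- as.integer(names(d_frac)[d_frac > bad_fraction])
  bad_l <- as.integer(names(l_frac)[l_frac > bad_fraction])
  reason <- rep(NA_character_, length(ids))
  reason[lq] <- "low_quality"
  reason[db] <- "doublet"
  reason[is.na(reason) & clusters %in% bad_l] <- "lowq_cluster"
  reason[is.na(reason) & clusters %in% bad_d] <- "doublet_cluster"
  keep <- is.na(reason)
  list(kept = ids[keep],
       removed = data.frame(cell_id = ids[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Full QC stage on a simulated or loaded two-species dataset
#'
#' Runs MAD/mito flagging, the internal doublet scorer, QC clustering at the
#' configured high resolution and cluster pruning, per species.
#'
#' @param sim list with `cyno`, `human` CountMatrix and `cells` CellTable.
#' @param config QCConfig.
#' @param seed RNG seed.
#' @return list with `kept` ids, `celltable` (flags set), `report`
#'   (per-species removal accounting), `removed` data.frame.
#' @export
run_qc <- function(sim, config = qc_config(), seed = 1) {
  ct <- sim$cells
  kept <- character(0)
  removed <- list()
  report <- list()
  for (sp in c("cyno", "human")) {
    cm <- sim[[sp]]
    ct <- qc_flags(cm, ct, config)
    sc <- synthetic_doublet_score(cm, expected_rate = config$expected_doublet_rate,
                                  seed = seed)
    db <- doublet_vote(list(sc), cm$cell_ids, k = config$doublet_vote_k)
    ct <- add_qc_flag(ct, names(db)[db], "doublet")
    sub <- ct[ct$cell_id %in% cm$cell_ids, ]
    lq <- stats::setNames(has_qc_flag(sub, "low_quality"), sub$cell_id)
    emb <- pca_embed(normalized_layer(cm), config$n_pcs)
    cl <- cluster_graph(emb, resolution = config$qc_cluster_resolution,
                        k = config$knn_k, seed = seed)
    pr <- prune_clusters(cl, db, lq, config$cluster_bad_fraction)
    ct <- add_qc_flag(ct, pr$removed$cell_id[pr$removed$reason == "doublet_cluster"],
                      "doublet_cluster")
    ct <- add_qc_flag(ct, pr$removed$cell_id[pr$removed$reason == "lowq_cluster"],
                      "lowq_cluster")
    kept <- c(kept, pr$kept)
    removed[[sp]] <- pr$removed
    report[[sp]] <- data.frame(
      species = sp, n_input = length(cm$cell_ids),
      n_removed = nrow(pr$removed),
      n_doublet = sum(pr$removed$reason %in% c("doublet", "doublet_cluster")),
      n_lowq = sum(pr$removed$reason %in% c("low_quality", "lowq_cluster")))
  }
  list(kept = kept, celltable = ct, removed = do.call(rbind, removed),
       report = do.call(rbind, report))
}
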