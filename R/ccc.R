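#' Score ligand-receptor interactions with magnitude and specificity ranks
#'
#' CellPhoneDB-style scorer: the magnitude of an interaction
#' (source_type, target_type, ligand, receptor) is the product of the mean
#' ligand expression in the source type and the mean receptor expression in
#' the target type (normalized layer). Specificity is a label-permutation
#' p-value with add-one correction, `p = (b + 1) / (n_perm + 1)` where b
#' counts permutations with magnitude >= observed. Magnitude rank is the
#' fractional rank of -magnitude over the table (ascending = stronger);
#' specificity rank likewise on p. Ties get average ranks.
#'
#' @param norm cells x genes normalized matrix (human gene space; cyno data
#'   mapped via [map_sum_by_human()] first).
#' @param celltypes named character vector of cell-type labels per cell.
#' @param lr_pairs data.frame(ligand, receptor) plus optional
#'   source_type/target_type restriction; by default every ordered type pair
#'   is scored for every LR pair.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return LRScoreTable data.frame: source_type, target_type, ligand,
#'   receptor, magnitude, p_specificity, magnitude_rank, specificity_rank.
#'   Pairs with a missing gene are excluded (attribute "excluded_pairs").
#' @export
score_interactions <- function(norm, celltypes, lr_pairs, n_perm = 1000,
                               seed = 1) {
  stopifnot(!is.null(rownames(norm)), all(names(celltypes) %in% rownames(norm)))
  norm <- norm[names(celltypes), , drop = FALSE]
  genes <- colnames(norm)
  present <- lr_pairs$ligand %in% genes & lr_pairs$receptor %in% genes
  excluded <- lr_pairs[!present, , drop = FALSE]
  lr <- lr_pairs[present, , drop = FALSE]
  types <- sort(unique(celltypes))
  need <- unique(c(lr$ligand, lr$receptor))
  sub <- norm[, need, drop = FALSE]
  lab <- factor(celltypes, levels = types)

  group_means <- function(labels) {
    s <- rowsum(sub, labels)
    sweep(s, 1, as.numeric(table(labels)[rownames(s)]), "/")
  }
  gm <- group_means(lab)

  if (all(c("source_type", "target_type") %in% names(lr)) && nrow(lr)) {
    combos <- lr
  } else {
    grid <- expand.grid(source_type = types, target_type = types,
                        stringsAsFactors = FALSE)
    combos <- merge(lr, grid)
  }
  mag <- gm[cbind(match(combos$source_type, rownames(gm)),
                  match(combos$ligand, colnames(gm)))] *
    gm[cbind(match(combos$target_type, rownames(gm)),
             match(combos$receptor, colnames(gm)))]

  set.seed(seed)
  b <- numeric(nrow(combos))
  for (i in seq_len(n_perm)) {
    pl <- sample(lab)
    pgm <- group_means(pl)
    pmag <- pgm[cbind(match(combos$source_type, rownames(pgm)),
                      match(combos$ligand, colnames(pgm)))] *
      pgm[cbind(match(combos$target_type, rownames(pgm)),
                match(combos$receptor, colnames(pgm)))]
    b <- b + (pmag >= mag)
  }
  p <- (b + 1) / (n_perm + 1)
  n <- nrow(combos)
  tab <- data.frame(source_type = combos$source_type,
                    target_type = combos$target_type,
                    ligand = combos$ligand, receptor = combos$receptor,
                    magnitude = mag, p_specificity = p,
                    magnitude_rank = rank(-mag) / n,
                    specificity_rank = rank(p) / n,
                    stringsAsFactors = FALSE)
  attr(tab, "excluded_pairs") <- excluded
  tab
}

#' Filter an LR score table on both ranks
#'
#' @param table LRScoreTable.
#' @param rank_cut keep rows with magnitude_rank and specificity_rank both
#'   <= rank_cut (0.01 for the conservation analysis, 0.001 for network
#'   views).
#' @return subset of `table`.
#' @export
filter_significant <- function(table, rank_cut = 0.01) {
  stopifnot(rank_cut > 0, rank_cut <= 1)
  table[table$magnitude_rank <= rank_cut &
          table$specificity_rank <= rank_cut, , drop = FALSE]
}

.lr_key <- function(tab) {
  paste(tab$source_type, tab$target_type, tab$ligand, tab$receptor, sep = "|")
}

#' Cross-species conservation of significant LR interactions
#'
#' Shared interactions are keyed by (source_type, target_type, ligand,
#' receptor). The shared percentage is reported against |A union B| by
#' default (per-species denominators also returned), and a one-sided Fisher
#' exact test over the common background asks whether membership in A and B
#' co-occurs more than chance.
#'
#' @param pairs_a,pairs_b LRScoreTables (already filtered for significance).
#' @param background LRScoreTable (or key vector) of all scored
#'   interactions, regardless of significance.
#' @return list(shared_count, shared_percent, shared_percent_a,
#'   shared_percent_b, fisher_p, shared_keys).
#' @export
conservation_test <- function(pairs_a, pairs_b, background) {
  bg <- if (is.character(background)) unique(background) else
    unique(.lr_key(background))
  if (!length(bg)) stop("empty background")
  a <- unique(.lr_key(pairs_a))
  b <- unique(.lr_key(pairs_b))
  stopifnot(all(a %in% bg), all(b %in% bg))
  inter <- intersect(a, b)
  uni <- union(a, b)
  x11 <- length(inter)
  x10 <- length(setdiff(a, b))
  x01 <- length(setdiff(b, a))
  x00 <- length(bg) - length(uni)
  fp <- stats::fisher.test(matrix(c(x11, x10, x01, x00), 2),
                           alternative = "greater")$p.value
  list(shared_count = x11,
       shared_percent = if (length(uni)) 100 * x11 / length(uni) else NA_real_,
       shared_percent_a = if (length(a)) 100 * x11 / length(a) else NA_real_,
       shared_percent_b = if (length(b)) 100 * x11 / length(b) else NA_real_,
       fisher_p = fp, shared_keys = inter)
}

#' Aggregate significant interactions into a cell-type network
#'
#' One directed edge per (source_type, target_type) over interactions
#' surviving `edge_cut` on both ranks; the weight is the sum of
#' log10(magnitude_rank) (more negative = stronger; `abs_weight` is its
#' absolute value for display). Activity counts interactions per cell type
#' in the source role (ligand-emitting) and the target role
#' (receptor-emitting).
#'
#' @param table LRScoreTable.
#' @param edge_cut rank threshold (default 0.001).
#' @return list(edges = data.frame(source, target, n_interactions, weight,
#'   abs_weight), activity = data.frame(cell_type, n_source, n_target,
#'   weight_source, weight_target)).
#' @export
network_summaries <- function(table, edge_cut = 0.001) {
  surv <- filter_significant(table, edge_cut)
  if (!nrow(surv)) {
    return(list(edges = data.frame(source = character(0),
                                   target = character(0),
                                   n_interactions = integer(0),
                                   weight = numeric(0),
                                   abs_weight = numeric(0)),
                activity = data.frame(cell_type = character(0),
                                      n_source = integer(0),
                                      n_target = integer(0),
                                      weight_source = numeric(0),
                                      weight_target = numeric(0))))
  }
  lw <- log10(surv$magnitude_rank)
  key <- paste(surv$source_type, surv$target_type, sep = "\r")
  agg <- tapply(lw, key, sum)
  cnt <- tapply(lw, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r"))
  edges <- data.frame(source = parts[, 1], target = parts[, 2],
                      n_interactions = as.integer(cnt),
                      weight = as.numeric(agg),
                      abs_weight = abs(as.numeric(agg)),
                      stringsAsFactors = FALSE)
  types <- sort(unique(c(surv$source_type, surv$target_type)))
  activity <- data.frame(
    cell_type = types,
    n_source = vapply(types, function(t) sum(surv$source_type == t), integer(1)),
    n_target = vapply(types, function(t) sum(surv$target_type == t), integer(1)),
    weight_source = vapply(types, function(t) sum(lw[surv$source_type == t]), numeric(1)),
    weight_target = vapply(types, function(t) sum(lw[surv$target_type == t]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(edges) <- rownames(activity) <- NULL
  list(edges = edges, activity = activity)
}
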