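#' Majority-vote cluster annotation
#'
#' Every cell receives its cluster's modal input label (ties broken
#' lexicographically); clusters whose labels are all missing are labelled
#' "unknown". Never invents a label absent from the input set.
#'
#' @param clusters named integer vector of cluster ids.
#' @param labels named character vector of per-cell (possibly noisy) labels;
#'   NA allowed.
#' @return named character vector of refined labels.
#' @export
majority_annotate <- function(clusters, labels) {
  ids <- names(clusters)
  stopifnot(!is.null(ids), all(ids %in% names(labels)))
  lab <- labels[ids]
  out <- character(length(ids))
  for (cl in unique(clusters)) {
    in_c <- clusters == cl
    tab <- table(lab[in_c], useNA = "no")
    if (!length(tab)) {
      out[in_c] <- "unknown"
    } else {
      top <- max(tab)
      out[in_c] <- sort(names(tab)[tab == top])[1]
    }
  }
  stats::setNames(out, ids)
}

.keep_level2_default <- c("Platelet", "NK Proliferating", "CD4 Proliferating",
                          "CD8 Proliferating", "CD14 Mono", "CD16 Mono",
                          "Plasmablast", "gdT", "MAIT", "dnT")

#' Intermediate "level 1.5" annotation
#'
#' Balances granularity and statistical power: cells keep their fine level-2
#' label when it belongs to `keep_level2`, and fall back to the broad
#' level-1 label otherwise.
#'
#' @param labels_l1,labels_l2 character vectors of equal length.
#' @param keep_level2 level-2 labels retained (default: the standard PBMC
#'   list of platelets, proliferating subsets, monocyte subsets, plasmablasts
#'   and unconventional T cells).
#' @return character vector of level-1.5 labels.
#' @export
relabel_granularity <- function(labels_l1, labels_l2,
                                keep_level2 = .keep_level2_default) {
  stopifnot(length(labels_l1) == length(labels_l2))
  ifelse(labels_l2 %in% keep_level2, labels_l2, labels_l1)
}

#' Cell-type proportions and relative change vs baseline
#'
#' Per species x timepoint, label proportions (summing to 1) and the
#' relative change `(p_t - p_0) / p_0` against the 0h baseline; labels
#' absent at 0h get a missing relative change.
#'
#' @param celltable CellTable with species, timepoint, label.
#' @return data.frame(species, timepoint, label, n, proportion,
#'   rel_change_vs_0h).
#' @export
proportions_table <- function(celltable) {
  rows <- list()
  for (sp in unique(celltable$species)) {
    sub <- celltable[celltable$species == sp, ]
    labs <- sort(unique(sub$label))
    base <- NULL
    for (tp in c("0h", "6h", "24h")) {
      st <- sub[sub$timepoint == tp, ]
      if (!nrow(st)) next
      n <- table(factor(st$label, levels = labs))
      p <- as.numeric(n) / sum(n)
      if (tp == "0h") base <- stats::setNames(p, labs)
      rel <- if (is.null(base)) rep(NA_real_, length(labs)) else {
        b <- base[labs]
        ifelse(!is.na(b) & b > 0, (p - b) / b, NA_real_)
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, timepoint = tp, label = labs,
        n = as.integer(n), proportion = p,
        rel_change_vs_0h = if (tp == "0h") 0 else rel,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Infer replicate sex from Y-chromosome marker expression
#'
#' A replicate is called male if the fraction of its cells with any
#' Y-marker count above zero exceeds `threshold`, female otherwise;
#' "undetermined" if no marker is present in the gene space.
#'
#' @param counts CountMatrix.
#' @param celltable CellTable.
#' @param y_markers marker gene symbols (default [y_markers_default()]).
#' @param threshold detection-fraction cutoff (default 0.2).
#' @return data.frame(species, replicate, frac_y_positive, sex).
#' @export
infer_sex <- function(counts, celltable, y_markers = y_markers_default(),
                      threshold = 0.2) {
  present <- intersect(y_markers, counts$gene_ids)
  if (!length(present)) {
    warning("no Y marker present in gene space; sex undetermined")
  }
  sub <- celltable[celltable$cell_id %in% counts$cell_ids, ]
  groups <- unique(sub[, c("species", "replicate")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    ids <- sub$cell_id[sub$species == g$species & sub$replicate == g$replicate]
    if (!length(present)) {
      frac <- NA_real_
      sex <- "undetermined"
    } else {
      m <- counts$counts[ids, present, drop = FALSE]
      frac <- mean(Matrix::rowSums(m) > 0)
      sex <- if (frac > threshold) "male" else "female"
    }
    out[[i]] <- data.frame(species = g$species, replicate = g$replicate,
                           frac_y_positive = frac, sex = sex,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
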