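#' Harmonize two species into a unified gene space by duplication
#'
#' Implements the n:m-preserving harmonization used as VAE input. For each
#' ortholog pair the cyno column enters under the human ortholog's name; a
#' cyno gene with k human orthologs therefore appears k times (once per human
#' name), and a human gene with k cyno orthologs is replicated k times to
#' align with each cyno source. Gene symbols present in both datasets but
#' absent from the table are retained once under the human name; genes in
#' neither category are dropped. Count values are never altered, only
#' duplicated and renamed.
#'
#' Unified column ids are the human names; where a human gene is matched to
#' several cyno sources (m:1) the replicated columns are disambiguated as
#' `"human|cyno"` so ids stay unique. Column order is sorted unified ids.
#'
#' @param counts_cyno,counts_human CountMatrix in each species' own gene
#'   space.
#' @param orthologs OrthologTable (source = cyno, target = human); may be
#'   empty.
#' @return list with `cyno`, `human` (CountMatrix over the unified space) and
#'   `unified_gene_ids`.
#' @export
harmonize_duplicating <- function(counts_cyno, counts_human, orthologs) {
  stopifnot(inherits(counts_cyno, "CountMatrix"),
            inherits(counts_human, "CountMatrix"))
  ot <- as.data.frame(orthologs)
  ot <- ot[ot$source_gene %in% counts_cyno$gene_ids &
             ot$target_gene %in% counts_human$gene_ids, , drop = FALSE]
  # m:1 disambiguation: human targets hit by >1 cyno source
  if (nrow(ot)) {
    multi <- names(which(table(ot$target_gene) > 1))
    uid <- ifelse(ot$target_gene %in% multi,
                  paste(ot$target_gene, ot$source_gene, sep = "|"),
                  ot$target_gene)
  } else {
    uid <- character(0)
  }
  shared <- intersect(setdiff(counts_cyno$gene_ids, ot$source_gene),
                      setdiff(counts_human$gene_ids, ot$target_gene))
  all_ids <- c(uid, shared)
  ord <- order(all_ids)
  unified <- all_ids[ord]
  cyno_src <- c(ot$source_gene, shared)[ord]
  human_src <- c(ot$target_gene, shared)[ord]
  if (anyDuplicated(unified)) stop("internal: unified ids not unique")
  mk <- function(cm, src) {
    idx <- match(src, cm$gene_ids)
    count_matrix(cm$counts[, idx, drop = FALSE], unified, cm$cell_ids)
  }
  list(cyno = mk(counts_cyno, cyno_src),
       human = mk(counts_human, human_src),
       unified_gene_ids = unified)
}

#' Collapse a matrix to a unique target gene space (1:1 regime)
#'
#' For analyses that count unique genes, each target gene with multiple
#' source orthologs keeps only the highest-expressed source (largest grand
#' total of raw counts over all cells; ties broken by lexicographically
#' smallest source id), renamed to the target name. Source genes without a
#' mapping are dropped.
#'
#' @param counts CountMatrix in the source species' gene space.
#' @param orthologs OrthologTable (source_gene in `counts`' space).
#' @return CountMatrix over unique target gene names.
#' @export
collapse_one_to_one <- function(counts, orthologs) {
  stopifnot(inherits(counts, "CountMatrix"))
  ot <- as.data.frame(orthologs)
  ot <- ot[ot$source_gene %in% counts$gene_ids, , drop = FALSE]
  if (!nrow(ot)) {
    return(count_matrix(counts$counts[, 0, drop = FALSE], character(0),
                        counts$cell_ids))
  }
  tot <- Matrix::colSums(counts$counts)
  ot$total <- tot[ot$source_gene]
  ot <- ot[order(ot$target_gene, -ot$total, ot$source_gene), , drop = FALSE]
  keep <- ot[!duplicated(ot$target_gene), , drop = FALSE]
  keep <- keep[order(keep$target_gene), , drop = FALSE]
  idx <- match(keep$source_gene, counts$gene_ids)
  count_matrix(counts$counts[, idx, drop = FALSE], keep$target_gene,
               counts$cell_ids)
}

#' Map counts into the human namespace, summing shared targets
#'
#' The cell-cell-communication regime: each source (cyno) gene contributes
#' its full counts to every mapped human name (rows duplicated), and
#' multiple cyno genes mapping to the same human name are summed. Mass is
#' conserved for 1:1 genes; a 1:k gene contributes k times its mass.
#'
#' @param counts_cyno CountMatrix in cyno gene space.
#' @param orthologs OrthologTable.
#' @return CountMatrix over the mapped human gene names (sorted).
#' @export
map_sum_by_human <- function(counts_cyno, orthologs) {
  stopifnot(inherits(counts_cyno, "CountMatrix"))
  ot <- as.data.frame(orthologs)
  ot <- ot[ot$source_gene %in% counts_cyno$gene_ids, , drop = FALSE]
  targets <- sort(unique(ot$target_gene))
  if (!length(targets)) {
    return(count_matrix(counts_cyno$counts[, 0, drop = FALSE], character(0),
                        counts_cyno$cell_ids))
  }
  # assignment matrix A (source-genes x targets): counts %*% A sums columns
  si <- match(ot$source_gene, counts_cyno$gene_ids)
  ti <- match(ot$target_gene, targets)
  A <- Matrix::sparseMatrix(i = si, j = ti, x = 1,
                            dims = c(length(counts_cyno$gene_ids),
                                     length(targets)))
  m <- counts_cyno$counts %*% A
  count_matrix(m, targets, counts_cyno$cell_ids)
}

#' Classify ortholog mapping relations
#'
#' @param counts_cyno,counts_human CountMatrix.
#' @param orthologs OrthologTable.
#' @return data.frame with counts of 1:1, 1:m, m:1, n:m pairs, shared
#'   unmapped symbols, unmapped genes, and the coverage fraction (cyno genes
#'   with >= 1 ortholog).
#' @export
orthology_report <- function(counts_cyno, counts_human, orthologs) {
  ot <- as.data.frame(orthologs)
  ot <- ot[ot$source_gene %in% counts_cyno$gene_ids &
             ot$target_gene %in% counts_human$gene_ids, , drop = FALSE]
  n_t_per_s <- table(ot$source_gene)[ot$source_gene]
  n_s_per_t <- table(ot$target_gene)[ot$target_gene]
  cls <- ifelse(n_t_per_s == 1 & n_s_per_t == 1, "1:1",
                ifelse(n_t_per_s > 1 & n_s_per_t == 1, "1:m",
                       ifelse(n_t_per_s == 1 & n_s_per_t > 1, "m:1", "n:m")))
  shared <- length(intersect(setdiff(counts_cyno$gene_ids, ot$source_gene),
                             setdiff(counts_human$gene_ids, ot$target_gene)))
  cov <- length(unique(ot$source_gene)) / length(counts_cyno$gene_ids)
  data.frame(
    class = c("1:1", "1:m", "m:1", "n:m", "shared_symbol", "unmapped_cyno",
              "coverage"),
    value = c(sum(cls == "1:1"), sum(cls == "1:m"), sum(cls == "m:1"),
              sum(cls == "n:m"), shared,
              length(setdiff(counts_cyno$gene_ids,
                             c(ot$source_gene,
                               intersect(counts_cyno$gene_ids,
                                         counts_human$gene_ids)))),
              cov))
}
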