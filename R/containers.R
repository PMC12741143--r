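#' Construct a CountMatrix
#'
#' The package's basic expression container: a cells x genes integer count
#' matrix with optional normalized layer (log1p of depth-scaled counts).
#' Orientation is fixed as cells in rows, genes in columns throughout the
#' package; the 10x on-disk MTX convention (genes x cells) is transposed on
#' load.
#'
#' @param counts cells x genes matrix (base or Matrix sparse) of non-negative
#'   integers.
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param normalized optional matrix of identical shape holding the
#'   log-normalized layer.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids, cell_ids, normalized = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match cell_ids/gene_ids lengths (",
         length(cell_ids), ", ", length(gene_ids), ")")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  obj <- list(counts = counts,
              gene_ids = as.character(gene_ids),
              cell_ids = as.character(cell_ids),
              normalized = normalized)
  class(obj) <- "CountMatrix"
  obj
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$cell_ids), "cells x", length(x$gene_ids),
      "genes;", if (is.null(x$normalized)) "no" else "with",
      "normalized layer\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells and/or genes
#'
#' @param x CountMatrix.
#' @param cells,genes character ids or integer/logical indices; NULL keeps all.
#' @return CountMatrix restricted to the selection (normalized layer carried
#'   along when present).
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else .resolve_idx(cells, x$cell_ids, "cell")
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else .resolve_idx(genes, x$gene_ids, "gene")
  norm <- if (!is.null(x$normalized)) x$normalized[ci, gi, drop = FALSE]
  count_matrix(x$counts[ci, gi, drop = FALSE],
               x$gene_ids[gi], x$cell_ids[ci], normalized = norm)
}

.resolve_idx <- function(sel, ids, what) {
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop("unknown ", what, " ids: ",
                         paste(utils::head(sel[is.na(idx)], 5), collapse = ", "))
    idx
  } else if (is.logical(sel)) {
    which(sel)
  } else {
    as.integer(sel)
  }
}

#' Construct a per-cell metadata table
#'
#' Validates the cell-level metadata used throughout the pipeline: species,
#' replicate, timepoint, optional cell-type label and cluster, QC flags and
#' mitochondrial count fraction.
#'
#' @param cell_id,species,replicate,timepoint character vectors (recycled
#'   rules not applied; all must have equal length). `species` must be one of
#'   "cyno"/"human", `timepoint` one of "0h"/"6h"/"24h".
#' @param label,cluster optional per-cell annotation (NA allowed).
#' @param mito_fraction numeric in \[0, 1\].
#' @return data.frame of class `CellTable` with a `qc_flags` character column
#'   (comma-joined flag set, "" = clean).
#' @export
cell_table <- function(cell_id, species, replicate, timepoint,
                       label = NA_character_, cluster = NA_integer_,
                       mito_fraction = NA_real_) {
  n <- length(cell_id)
  df <- data.frame(cell_id = as.character(cell_id),
                   species = as.character(species),
                   replicate = as.character(replicate),
                   timepoint = as.character(timepoint),
                   label = rep_len(as.character(label), n),
                   cluster = rep_len(as.integer(cluster), n),
                   qc_flags = "",
                   mito_fraction = rep_len(as.numeric(mito_fraction), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in cell table")
  bad_sp <- setdiff(unique(df$species), c("cyno", "human"))
  if (length(bad_sp)) stop("unknown species: ", paste(bad_sp, collapse = ", "))
  bad_tp <- setdiff(unique(df$timepoint), c("0h", "6h", "24h"))
  if (length(bad_tp)) stop("unknown timepoint: ", paste(bad_tp, collapse = ", "))
  mf <- df$mito_fraction
  if (any(!is.na(mf) & (mf < 0 | mf > 1))) stop("mito_fraction outside [0,1]")
  class(df) <- c("CellTable", "data.frame")
  df
}

#' Add QC flags to a cell table
#'
#' @param celltable CellTable.
#' @param cell_ids cells to flag.
#' @param flag one of "low_quality", "doublet", "doublet_cluster",
#'   "lowq_cluster".
#' @return updated CellTable.
#' @export
add_qc_flag <- function(celltable, cell_ids, flag) {
  flag <- match.arg(flag, c("low_quality", "doublet", "doublet_cluster",
                            "lowq_cluster"))
  i <- match(cell_ids, celltable$cell_id)
  if (anyNA(i)) stop("unknown cell ids in add_qc_flag")
  cur <- strsplit(celltable$qc_flags[i], ",", fixed = TRUE)
  celltable$qc_flags[i] <- vapply(cur, function(f) {
    paste(sort(unique(c(f[nzchar(f)], flag))), collapse = ",")
  }, character(1))
  celltable
}

#' Test whether cells carry a given QC flag
#' @param celltable CellTable.
#' @param flag flag name.
#' @return logical vector aligned with `celltable` rows.
#' @export
has_qc_flag <- function(celltable, flag) {
  vapply(strsplit(celltable$qc_flags, ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Construct an ortholog pair table
#'
#' @param source_gene,target_gene character vectors of equal length; n:m
#'   relations allowed, exact duplicate pairs are an error.
#' @return data.frame of class `OrthologTable` with columns
#'   source_gene/target_gene.
#' @export
ortholog_table <- function(source_gene, target_gene) {
  df <- data.frame(source_gene = as.character(source_gene),
                   target_gene = as.character(target_gene),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate ortholog pairs")
  class(df) <- c("OrthologTable", "data.frame")
  df
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (each non-empty, names unique).
#' @param source_db label of the originating database.
#' @return object of class `GeneSetCollection2` (list with `sets`, `source_db`).
#' @export
gene_set_collection <- function(sets, source_db = "custom") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene set names must be present and unique")
  if (any(lengths(sets) == 0)) stop("empty gene set")
  obj <- list(sets = lapply(sets, function(s) unique(as.character(s))),
              source_db = source_db)
  class(obj) <- "GeneSetCollection2"
  obj
}
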