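#' Load a 10x-style MTX triplet
#'
#' Reads a MatrixMarket sparse matrix plus one-gene-per-line and
#' one-cell-per-line TSVs. On disk the matrix is stored genes x cells (10x
#' convention); it is transposed to the package's cells x genes orientation.
#'
#' @param matrix_path path to the .mtx file.
#' @param genes_path path to the gene TSV (first column used as id).
#' @param cells_path path to the cell/barcode TSV (first column used as id).
#' @return CountMatrix.
#' @export
load_counts <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match gene/cell file line counts (",
         length(genes), ", ", length(cells), ")")
  }
  m <- as(Matrix::t(m), "CsparseMatrix")
  if (length(m@x) && any(m@x != round(m@x))) stop("non-integer entries in MTX")
  count_matrix(m, gene_ids = genes, cell_ids = cells)
}

#' Write a CountMatrix as an MTX triplet
#'
#' Inverse of [load_counts()]: stores the matrix genes x cells.
#'
#' @param x CountMatrix.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the three file paths.
#' @export
write_counts <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "genes.tsv", "cells.tsv")))
  m <- Matrix::t(x$counts)
  dimnames(m) <- NULL
  Matrix::writeMM(m, paths[1])
  writeLines(x$gene_ids, paths[2])
  writeLines(x$cell_ids, paths[3])
  invisible(paths)
}

#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' genes... Duplicate genes within a line are collapsed; lines with fewer
#' than 3 fields are skipped with a warning; duplicate set names are fatal.
#'
#' @param gmt_path path to the GMT file.
#' @param source_db database label stored on the collection.
#' @return GeneSetCollection2.
#' @export
load_gene_sets <- function(gmt_path, source_db = basename(gmt_path)) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    obj <- list(sets = stats::setNames(list(), character(0)), source_db = source_db)
    class(obj) <- "GeneSetCollection2"
    return(obj)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    warning(sum(short), " GMT line(s) with < 3 fields skipped")
    fields <- fields[!short]
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene set name in GMT: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, source_db = source_db)
}

#' Write a gene-set collection to GMT
#' @param gsc GeneSetCollection2.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_gene_sets <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$source_db, gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a typed TSV table with required columns
#'
#' Generic reader for the pipeline's tab-separated tables (ortholog pairs,
#' ligand-receptor pairs, per-cell labels, doublet-score tables). Unknown
#' columns are preserved.
#'
#' @param path TSV with a header row.
#' @param required character vector of required column names.
#' @return data.frame.
#' @export
load_table <- function(path, required = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a table as UTF-8 TSV
#' @param df data.frame.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_table_tsv <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load an ortholog table from TSV
#' @param path TSV with columns source_gene, target_gene.
#' @return OrthologTable.
#' @export
load_orthologs <- function(path) {
  df <- load_table(path, c("source_gene", "target_gene"))
  ortholog_table(df$source_gene, df$target_gene)
}

#' Depth-normalize and log1p-transform counts
#'
#' Each cell is scaled to `scale_per_cell` total counts, then log(1 + x) is
#' applied. All-zero cells map to all-zero rows. The result is invariant to
#' per-cell sequencing depth and monotone in counts within a cell.
#'
#' @param x CountMatrix (or bare matrix).
#' @param scale_per_cell target per-cell total (default 10,000).
#' @return if `x` is a CountMatrix, the same object with `$normalized` set
#'   (dense matrix); otherwise the normalized matrix.
#' @export
normalize_log1p <- function(x, scale_per_cell = 1e4) {
  stopifnot(scale_per_cell > 0)
  m <- if (inherits(x, "CountMatrix")) x$counts else x
  tot <- Matrix::rowSums(m)
  fac <- ifelse(tot > 0, scale_per_cell / tot, 0)
  norm <- as.matrix(Matrix::Diagonal(x = fac) %*% m)
  norm <- log1p(norm)
  dimnames(norm) <- dimnames(m)
  if (inherits(x, "CountMatrix")) {
    x$normalized <- norm
    x
  } else {
    norm
  }
}

#' Return the normalized layer, computing it if absent
#' @param x CountMatrix.
#' @param scale_per_cell depth target passed to [normalize_log1p()].
#' @return dense cells x genes matrix.
#' @export
normalized_layer <- function(x, scale_per_cell = 1e4) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(x$normalized)) x <- normalize_log1p(x, scale_per_cell)
  x$normalized
}
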