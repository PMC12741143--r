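#' Expression filter by detection rate
#'
#' A gene is kept if its detection rate (fraction of cells with count > 0)
#' reaches `min_prop` in at least one of the compared groups — a cell-level
#' analogue of the bulk `filterByExpr(min.prop = 0.7)` rule.
#'
#' @param counts CountMatrix (or sparse matrix).
#' @param groups list of cell-id vectors (the compared groups).
#' @param min_prop detection threshold (default 0.7).
#' @return character vector of kept genes.
#' @export
filter_genes <- function(counts, groups, min_prop = 0.7) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  keep <- rep(FALSE, ncol(m))
  for (g in groups) {
    det <- Matrix::colMeans(m[g, , drop = FALSE] > 0)
    keep <- keep | det >= min_prop
  }
  if (min_prop == 0) keep <- keep & Matrix::colSums(m > 0) > 0
  if (!any(keep)) stop("no genes survive the expression filter (0/", ncol(m), ")")
  colnames(m)[keep]
}

#' Per-gene differential expression between two cell groups
#'
#' Default engine: two-sided Wilcoxon rank-sum test on the log-normalized
#' layer, with log2 fold changes of depth-normalized group means
#' (pseudocount 1) and Benjamini-Hochberg FDR. `method = "nb_glm"` fits a
#' per-gene negative-binomial GLM on counts with library-size offsets and a
#' likelihood-ratio test (slower; intended for small gene sets).
#'
#' @param counts CountMatrix with a normalized layer (computed on demand).
#' @param groupA,groupB cell ids (A = from/baseline, B = to); logFC is B
#'   over A.
#' @param genes genes to test (default: all).
#' @param method "wilcoxon" or "nb_glm".
#' @param min_cells minimal group size (both groups).
#' @param context named list attached to the table (species, cell_type,
#'   comparison).
#' @return DGETable data.frame: gene, logFC, p, fdr, mean_A, mean_B plus
#'   context columns.
#' @export
dge_test <- function(counts, groupA, groupB, genes = NULL,
                     method = c("wilcoxon", "nb_glm"), min_cells = 5,
                     context = list()) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "CountMatrix"))
  if (length(groupA) < min_cells || length(groupB) < min_cells) {
    stop("group below minimum size (", min_cells, " cells): ",
         paste(unlist(context), collapse = "/"))
  }
  if (is.null(genes)) genes <- counts$gene_ids
  gi <- match(genes, counts$gene_ids)
  norm <- normalized_layer(counts)
  na <- norm[groupA, gi, drop = FALSE]
  nb <- norm[groupB, gi, drop = FALSE]
  cntA <- counts$counts[groupA, gi, drop = FALSE]
  cntB <- counts$counts[groupB, gi, drop = FALSE]
  # depth-normalized (counts-per-10k) means with pseudocount 1
  cpA <- Matrix::colMeans(.depth_scale(cntA))
  cpB <- Matrix::colMeans(.depth_scale(cntB))
  logfc <- log2((cpB + 1) / (cpA + 1))
  p <- numeric(length(gi))
  if (method == "wilcoxon") {
    for (j in seq_along(gi)) {
      p[j] <- .ranksum_p(na[, j], nb[, j])
    }
  } else {
    la <- log(Matrix::rowSums(counts$counts[groupA, , drop = FALSE]))
    lb <- log(Matrix::rowSums(counts$counts[groupB, , drop = FALSE]))
    off <- c(la, lb)
    grp <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))
    for (j in seq_along(gi)) {
      y <- c(cntA[, j], cntB[, j])
      p[j] <- .nb_lrt_p(y, grp, off)
    }
  }
  df <- data.frame(gene = genes, logFC = logfc, p = p,
                   fdr = stats::p.adjust(p, method = "BH"),
                   mean_A = cpA, mean_B = cpB, stringsAsFactors = FALSE)
  for (nm in names(context)) df[[nm]] <- context[[nm]]
  rownames(df) <- NULL
  df
}

.depth_scale <- function(m, scale = 1e4) {
  tot <- Matrix::rowSums(m)
  fac <- ifelse(tot > 0, scale / tot, 0)
  Matrix::Diagonal(x = fac) %*% m
}

# Wilcoxon rank-sum with normal approximation, tie correction and
# continuity correction (the large-sample path of wilcox.test).
.ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((na + nb + 1) -
                            sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
  if (sig2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

.nb_lrt_p <- function(y, grp, off) {
  fit1 <- tryCatch(MASS::glm.nb(y ~ grp + offset(off)),
                   error = function(e) NULL, warning = function(w) NULL)
  fit0 <- tryCatch(MASS::glm.nb(y ~ 1 + offset(off)),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit1) || is.null(fit0)) return(NA_real_)
  lr <- 2 * (stats::logLik(fit1) - stats::logLik(fit0))
  stats::pchisq(as.numeric(lr), df = 1, lower.tail = FALSE)
}

#' Fraction of the transcriptome differentially regulated
#'
#' Storey-type estimate: pi0(lambda) = #(p > lambda) / (m (1 - lambda)) on
#' the grid lambda = 0.05, 0.10, ..., 0.95, smoothed with a cubic smoothing
#' spline (df = 3) and evaluated at the largest lambda. The regulated
#' fraction is 1 - pi0, clipped to \[0, 1\].
#'
#' @param p_values >= 100 p-values.
#' @return estimated regulated fraction.
#' @export
fraction_regulated <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 100) stop("need >= 100 p-values")
  if (length(unique(p)) == 1) {
    warning("degenerate p-value distribution")
    return(if (p[1] < 0.5) 1 else 0)
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0 <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0, df = 3)
  pi0_hat <- stats::predict(fit, x = max(lambda))$y
  min(1, max(0, 1 - min(1, max(0, pi0_hat))))
}

#' Cross-species overlap of significantly regulated genes
#'
#' Intersects the significant sets of the two species at `fdr_cut`, counts
#' species-specific and shared genes, and tests whether the fraction of
#' shared genes with the same logFC sign departs from 0.5 — by default the
#' chi-square proportion test with continuity correction (two-sided), with
#' an exact binomial alternative.
#'
#' @param dge_a,dge_b DGETables over a shared 1:1 gene space.
#' @param fdr_cut significance cutoff (default 0.20).
#' @param direction_test "prop" or "binomial".
#' @return list(n_a_only, n_b_only, n_shared, frac_same_direction,
#'   p_direction, shared_genes).
#' @export
cross_species_overlap <- function(dge_a, dge_b, fdr_cut = 0.20,
                                  direction_test = c("prop", "binomial")) {
  direction_test <- match.arg(direction_test)
  sig_a <- dge_a$gene[dge_a$fdr <= fdr_cut]
  sig_b <- dge_b$gene[dge_b$fdr <= fdr_cut]
  shared <- intersect(sig_a, sig_b)
  out <- list(n_a_only = length(setdiff(sig_a, sig_b)),
              n_b_only = length(setdiff(sig_b, sig_a)),
              n_shared = length(shared),
              frac_same_direction = NA_real_, p_direction = NA_real_,
              shared_genes = shared)
  if (!length(shared)) return(out)
  sa <- sign(dge_a$logFC[match(shared, dge_a$gene)])
  sb <- sign(dge_b$logFC[match(shared, dge_b$gene)])
  k <- sum(sa == sb)
  n <- length(shared)
  out$frac_same_direction <- k / n
  out$p_direction <- if (direction_test == "prop") {
    stats::prop.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  } else {
    sign_concordance_test(k, n)
  }
  out
}

#' Select the enrichment foreground from a DGE table
#'
#' Significant genes at `fdr_cut` ranked by |logFC| descending (ties: smaller
#' p, then lexicographic gene id), truncated at `top_n`.
#'
#' @param dge_table DGETable.
#' @param fdr_cut FDR threshold (default 0.20).
#' @param top_n cap (default 200).
#' @return character vector of foreground genes.
#' @export
select_foreground <- function(dge_table, fdr_cut = 0.20, top_n = 200) {
  sig <- dge_table[dge_table$fdr <= fdr_cut, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  ord <- order(-abs(sig$logFC), sig$p, sig$gene)
  utils::head(sig$gene[ord], top_n)
}

#' One-sided Fisher over-representation with the study's filters
#'
#' Per pathway, a one-sided Fisher exact test on the 2x2 table
#' (in pathway / not) x (foreground / background rest), restricted to
#' pathway genes present in the background. The odds ratio uses a
#' Haldane-Anscombe 0.5 correction when any cell is zero; the enrichment
#' factor is its natural log. BH correction across pathways, then rows with
#' fdr > `fdr_cut` or fewer than `min_hits` foreground hits are dropped, and
#' among pathways with identical hit sets only the one with the largest odds
#' ratio is retained.
#'
#' @param foreground gene list (subset of background).
#' @param background tested gene universe.
#' @param gene_sets GeneSetCollection2.
#' @param fdr_cut default 0.05.
#' @param min_hits default 2.
#' @return EnrichmentTable data.frame: pathway, source_db, n_pathway, n_hits,
#'   hits (comma-joined), odds_ratio, enrichment_factor, p, fdr.
#' @export
enrich_fisher <- function(foreground, background, gene_sets,
                          fdr_cut = 0.05, min_hits = 2) {
  stopifnot(all(foreground %in% background))
  fg <- unique(foreground)
  bg <- unique(background)
  rows <- list()
  for (nm in names(gene_sets$sets)) {
    pw <- intersect(gene_sets$sets[[nm]], bg)
    if (!length(pw)) next
    a <- length(intersect(pw, fg))                   # pathway & foreground
    b <- length(pw) - a                              # pathway & rest
    c_ <- length(fg) - a                             # non-pathway & fg
    d <- length(bg) - length(pw) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                            alternative = "greater")$p.value
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    rows[[length(rows) + 1]] <- data.frame(
      pathway = nm, source_db = gene_sets$source_db,
      n_pathway = length(pw), n_hits = a,
      hits = paste(sort(intersect(pw, fg)), collapse = ","),
      odds_ratio = or, enrichment_factor = log(or), p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pathway = character(0), source_db = character(0),
                      n_pathway = integer(0), n_hits = integer(0),
                      hits = character(0), odds_ratio = numeric(0),
                      enrichment_factor = numeric(0), p = numeric(0),
                      fdr = numeric(0)))
  }
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[tab$fdr <= fdr_cut & tab$n_hits >= min_hits, , drop = FALSE]
  if (nrow(tab)) {
    tab <- tab[order(-tab$odds_ratio, tab$pathway), , drop = FALSE]
    tab <- tab[!duplicated(tab$hits), , drop = FALSE]
    tab <- tab[order(tab$p, tab$pathway), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Jaccard co-enrichment of pathway hit sets between species
#'
#' For pathways enriched in both species, the Jaccard index of the two
#' foreground hit sets, plus summary counts (shared pathways, identical
#' foregrounds, disjoint foregrounds).
#'
#' @param table_a,table_b EnrichmentTables from the two species.
#' @return list(per_pathway = data.frame(pathway, jaccard, n_a, n_b,
#'   n_intersect), n_shared, n_identical, n_disjoint).
#' @export
co_enrichment_jaccard <- function(table_a, table_b) {
  shared <- intersect(table_a$pathway, table_b$pathway)
  rows <- lapply(shared, function(nm) {
    ha <- strsplit(table_a$hits[table_a$pathway == nm], ",")[[1]]
    hb <- strsplit(table_b$hits[table_b$pathway == nm], ",")[[1]]
    inter <- length(intersect(ha, hb))
    uni <- length(union(ha, hb))
    data.frame(pathway = nm, jaccard = if (uni) inter / uni else NA_real_,
               n_a = length(ha), n_b = length(hb), n_intersect = inter,
               stringsAsFactors = FALSE)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = character(0), jaccard = numeric(0),
               n_a = integer(0), n_b = integer(0), n_intersect = integer(0))
  list(per_pathway = per, n_shared = length(shared),
       n_identical = sum(per$jaccard == 1),
       n_disjoint = sum(per$jaccard == 0))
}
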