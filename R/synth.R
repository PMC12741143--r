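#' Simulation configuration for the two-species synthetic PBMC generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: two species
#' (cyno, human) sharing an incomplete n:m ortholog map, several cell types
#' with marker programs, three timepoints (0h/6h/24h) with per-species
#' temporal log-fold-change vectors of controllable cross-species cosine
#' similarity, two replicates per species with individual random effects,
#' negative-binomial counts with library-size variation, planted
#' ligand-receptor interactions, Y-chromosome markers for sex inference and
#' a reserved "MT-" mitochondrial gene block.
#'
#' @param n_genes total genes per species (>= 50; includes reserved mito and
#'   Y-marker blocks).
#' @param cell_types named integer vector: cells per species x replicate x
#'   timepoint group for each cell type.
#' @param n_replicates replicates per species.
#' @param ortholog_coverage fraction of cyno genes with >= 1 human ortholog.
#' @param frac_one_to_many fraction of mapped cyno genes given a second human
#'   target (and, symmetrically, of human genes given a second cyno source).
#' @param species_effect_sd sd (log scale) of the planted cyno-vs-human
#'   baseline effect on affected genes.
#' @param species_frac_affected fraction of genes carrying a species effect.
#' @param temporal_n_affected genes per cell type carrying the temporal
#'   program.
#' @param temporal_effect_size RMS log-fold change of the 24h temporal vector;
#'   the 6h vector is `temporal_frac_6h` times the 24h vector.
#' @param temporal_frac_6h scale of the 6h response relative to 24h.
#' @param temporal_target_cosine target cosine similarity between the human
#'   and cyno 24h log-FC vectors (exact by construction).
#' @param replicate_effect_sd sd of per-replicate gene-level intercepts.
#' @param nb_dispersion negative-binomial size parameter (variance
#'   mu + mu^2/size).
#' @param libsize_lognormal c(meanlog, sdlog) of per-cell library size.
#' @param doublet_rate,lowq_rate artifact rates used by [inject_artifacts()].
#' @param n_markers marker genes per cell type.
#' @param marker_effect log-scale boost of marker genes in their own type.
#' @param n_mito reserved mitochondrial genes ("MT-" prefix).
#' @param mito_frac named fractions c(cyno=, human=) of expression allotted
#'   to the mito block (kept far below/near the per-species QC thresholds).
#' @param sex named list: for each species a character vector of per-replicate
#'   sex assignments ("male"/"female").
#' @param lr_truth "auto" (plant default pairs) or a data.frame with columns
#'   ligand, receptor, source_type, target_type, boost, species
#'   ("both"/"cyno"/"human").
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = c("CD4 T" = 170, "CD8 T" = 170, "NK" = 170),
                       n_replicates = 2,
                       ortholog_coverage = 0.813,
                       frac_one_to_many = 0.05,
                       species_effect_sd = 1,
                       species_frac_affected = 0.25,
                       temporal_n_affected = 150,
                       temporal_effect_size = 1,
                       temporal_frac_6h = 0.4,
                       temporal_target_cosine = 1,
                       replicate_effect_sd = 0.1,
                       nb_dispersion = 2,
                       libsize_lognormal = c(log(2000), 0.3),
                       doublet_rate = 0.05,
                       lowq_rate = 0.05,
                       n_markers = 40,
                       marker_effect = 2,
                       n_mito = 10,
                       mito_frac = c(cyno = 2e-4, human = 0.03),
                       sex = list(cyno = c("male", "male"),
                                  human = c("male", "female")),
                       lr_truth = "auto",
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_genes < 50) stop("n_genes must be >= 50")
  fr <- c(ortholog_coverage, frac_one_to_many, species_frac_affected,
          doublet_rate, lowq_rate, temporal_frac_6h)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (any(c(species_effect_sd, replicate_effect_sd) < 0)) stop("sds must be >= 0")
  if (abs(temporal_target_cosine) > 1) stop("target cosine must be in [-1,1]")
  if (temporal_n_affected > n_genes) stop("more temporal DE genes than genes")
  if (is.null(names(cell_types))) stop("cell_types must be named")
  class(cfg) <- "SimConfig"
  cfg
}

.y_markers_default <- c("DDX3Y", "KDM5D", "USP9Y", "UTY", "ZFY", "EIF1AY",
                        "NLGN4Y", "RPS4Y1")

#' Default Y-chromosome marker genes used for sex inference
#' @return character vector of non-PAR Y-marker gene symbols.
#' @export
y_markers_default <- function() .y_markers_default

# Gene naming: reserved mito block "MT-Gk" and Y markers share symbols across
# species; remaining ("regular") genes are "G%04d" (human) / "C%04d" (cyno).
.gene_names <- function(cfg) {
  n_y <- length(.y_markers_default)
  n_reg <- cfg$n_genes - cfg$n_mito - n_y
  if (n_reg < 20) stop("n_genes too small for reserved blocks")
  idx_mito <- seq_len(cfg$n_mito)
  idx_y <- cfg$n_mito + seq_len(n_y)
  idx_reg <- (cfg$n_mito + n_y + 1):cfg$n_genes
  human <- cyno <- character(cfg$n_genes)
  human[idx_mito] <- cyno[idx_mito] <- paste0("MT-G", seq_len(cfg$n_mito))
  human[idx_y] <- cyno[idx_y] <- .y_markers_default
  human[idx_reg] <- sprintf("G%04d", idx_reg)
  cyno[idx_reg] <- sprintf("C%04d", idx_reg)
  list(human = human, cyno = cyno,
       idx_mito = idx_mito, idx_y = idx_y, idx_reg = idx_reg)
}

# Ortholog structure: hits the configured coverage exactly (+-1 gene) while
# planting pure 1:2 and 2:1 relations among mapped genes.
.build_orthology <- function(cfg, nm) {
  n_map <- round(cfg$ortholog_coverage * cfg$n_genes)
  n_12 <- round(cfg$frac_one_to_many * n_map / 2)
  n_21 <- n_12
  reg <- sample(nm$idx_reg)            # random assignment of roles
  stopifnot(n_map + 2 * n_12 + n_21 <= length(reg))
  g12 <- reg[seq_len(n_12)]                                   # cyno 1:2 sources
  p12 <- reg[n_12 + seq_len(n_12)]                            # their extra human targets
  g21 <- reg[2 * n_12 + seq_len(n_21)]                        # 2:1 human targets
  p21 <- reg[2 * n_12 + n_21 + seq_len(n_21)]                 # extra cyno sources
  n_11 <- n_map - n_12 - 2 * n_21
  g11 <- reg[(2 * n_12 + 2 * n_21 + 1):(2 * n_12 + 2 * n_21 + n_11)]
  pairs <- rbind(
    data.frame(source_gene = nm$cyno[g11], target_gene = nm$human[g11]),
    data.frame(source_gene = nm$cyno[g12], target_gene = nm$human[g12]),
    data.frame(source_gene = nm$cyno[g12], target_gene = nm$human[p12]),
    data.frame(source_gene = nm$cyno[g21], target_gene = nm$human[g21]),
    data.frame(source_gene = nm$cyno[p21], target_gene = nm$human[g21]))
  list(table = ortholog_table(pairs$source_gene, pairs$target_gene),
       one_to_one = g11, one_to_two = g12, two_to_one = g21,
       mapped_cyno_idx = sort(c(g11, g12, g21, p21)))
}

# Cross-species temporal vectors with exact target cosine t:
# v_h = u, v_c = t*u + sqrt(1-t^2)*w with w orthogonal to u, both supported on
# the affected gene set and scaled to RMS = effect_size over that set.
.temporal_vectors <- function(cfg, affected, n_genes) {
  k <- length(affected)
  u <- stats::rnorm(k)
  w <- stats::rnorm(k)
  w <- w - sum(w * u) / sum(u * u) * u
  u <- u / sqrt(mean(u^2)) * cfg$temporal_effect_size
  w <- w / sqrt(mean(w^2)) * cfg$temporal_effect_size
  t <- cfg$temporal_target_cosine
  vh <- vc <- numeric(n_genes)
  vh[affected] <- u
  vc[affected] <- t * u + sqrt(max(0, 1 - t^2)) * w
  list(human = vh, cyno = vc)
}

.default_lr_truth <- function(one_to_one, nm, types) {
  g <- nm$human[sort(one_to_one)]
  stopifnot(length(g) >= 10)
  k <- length(types)
  wrap <- function(i) types[(i - 1) %% k + 1]
  data.frame(
    ligand = g[1:5], receptor = g[6:10],
    source_type = wrap(c(1, 1, 2, 2, 3)),
    target_type = wrap(c(2, 3, 1, 3, 1)),
    boost = 2.5,
    species = c("both", "both", "both", "cyno", "human"),
    stringsAsFactors = FALSE)
}

#' Simulate a two-species single-cell dataset with planted ground truth
#'
#' Counts are drawn as NegativeBinomial with mean
#' `libsize_c * exp(base_g + celltype + species + temporal + replicate)` and
#' the configured dispersion. The returned truth object records every planted
#' quantity so downstream stages can be scored against it.
#'
#' @param cfg SimConfig from [sim_config()].
#' @return list with elements `cyno`, `human` (CountMatrix), `cells`
#'   (CellTable covering both species), `orthologs` (OrthologTable) and
#'   `truth` (list of class SimTruth).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  nm <- .gene_names(cfg)
  G <- cfg$n_genes
  types <- names(cfg$cell_types)
  orth <- .build_orthology(cfg, nm)

  # Baseline relative expression; mito block pinned to the species budget,
  # Y markers get a visible male-only share.
  w <- stats::rlnorm(length(nm$idx_reg), 0, 1.2)
  y_share <- 0.002
  base <- list()
  for (sp in c("cyno", "human")) {
    mf <- cfg$mito_frac[[sp]]
    b <- numeric(G)
    b[nm$idx_reg] <- log(w / sum(w) * (1 - mf - y_share))
    b[nm$idx_mito] <- log(mf / cfg$n_mito)
    b[nm$idx_y] <- log(y_share / length(nm$idx_y))  # males; zeroed for females
    base[[sp]] <- b
  }

  # Cell-type marker programs: disjoint blocks of regular genes.
  marker_idx <- list()
  pool <- setdiff(nm$idx_reg, integer(0))
  ct_effect <- matrix(0, G, length(types), dimnames = list(NULL, types))
  for (k in seq_along(types)) {
    mi <- sample(pool, cfg$n_markers)
    pool <- setdiff(pool, mi)
    marker_idx[[types[k]]] <- mi
    ct_effect[mi, k] <- cfg$marker_effect
  }

  # Species effect (on cyno, relative to human) on a random affected subset.
  n_sp <- round(cfg$species_frac_affected * length(nm$idx_reg))
  sp_affected <- sort(sample(nm$idx_reg, n_sp))
  species_effect <- numeric(G)
  species_effect[sp_affected] <- stats::rnorm(n_sp, 0, cfg$species_effect_sd)

  # Temporal programs per cell type with exact cross-species cosine.
  temporal <- list()
  for (ty in types) {
    aff <- sort(sample(nm$idx_reg, cfg$temporal_n_affected))
    temporal[[ty]] <- c(.temporal_vectors(cfg, aff, G), list(affected = aff))
  }

  # Replicate intercepts.
  reps <- paste0("r", seq_len(cfg$n_replicates))
  rep_effect <- list()
  for (sp in c("cyno", "human")) for (r in reps) {
    rep_effect[[paste(sp, r)]] <- stats::rnorm(G, 0, cfg$replicate_effect_sd)
  }

  # Planted ligand-receptor interactions.
  lr <- cfg$lr_truth
  if (identical(lr, "auto")) lr <- .default_lr_truth(orth$one_to_one, nm, types)
  lr_boost <- list(cyno = matrix(0, G, length(types), dimnames = list(NULL, types)),
                   human = matrix(0, G, length(types), dimnames = list(NULL, types)))
  if (NROW(lr)) {
    for (i in seq_len(nrow(lr))) {
      li <- match(lr$ligand[i], nm$human)
      ri <- match(lr$receptor[i], nm$human)
      if (is.na(li) || is.na(ri)) stop("lr_truth gene not in human gene space")
      for (sp in c("cyno", "human")) {
        if (lr$species[i] %in% c("both", sp)) {
          lr_boost[[sp]][li, lr$source_type[i]] <-
            lr_boost[[sp]][li, lr$source_type[i]] + lr$boost[i]
          lr_boost[[sp]][ri, lr$target_type[i]] <-
            lr_boost[[sp]][ri, lr$target_type[i]] + lr$boost[i]
        }
      }
    }
  }

  tps <- c("0h", "6h", "24h")
  mats <- list(cyno = list(), human = list())
  meta <- list()
  for (sp in c("cyno", "human")) {
    for (r_i in seq_along(reps)) {
      male <- cfg$sex[[sp]][r_i] == "male"
      b <- base[[sp]]
      if (!male) b[nm$idx_y] <- -Inf
      for (tp in tps) {
        for (ty in types) {
          n_c <- cfg$cell_types[[ty]]
          eta <- b + ct_effect[, ty] + rep_effect[[paste(sp, reps[r_i])]] +
            lr_boost[[sp]][, ty]
          if (sp == "cyno") eta <- eta + species_effect
          tv <- temporal[[ty]][[sp]]
          if (tp == "6h") eta <- eta + cfg$temporal_frac_6h * tv
          if (tp == "24h") eta <- eta + tv
          lib <- stats::rlnorm(n_c, cfg$libsize_lognormal[1],
                               cfg$libsize_lognormal[2])
          mu <- outer(lib, exp(eta))          # n_c x G
          cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                       size = cfg$nb_dispersion),
                        nrow = n_c)
          ids <- sprintf("%s_%s_%s_%s_%03d", sp, reps[r_i], tp,
                         gsub(" ", "", ty), seq_len(n_c))
          rownames(cnt) <- ids
          mats[[sp]][[length(mats[[sp]]) + 1]] <- cnt
          meta[[length(meta) + 1]] <- data.frame(
            cell_id = ids, species = sp, replicate = reps[r_i],
            timepoint = tp, label = ty, stringsAsFactors = FALSE)
        }
      }
    }
  }

  meta <- do.call(rbind, meta)
  out <- list()
  for (sp in c("cyno", "human")) {
    m <- do.call(rbind, mats[[sp]])
    cm <- count_matrix(m, gene_ids = nm[[sp]], cell_ids = rownames(m))
    out[[sp]] <- cm
  }
  mito_frac <- c(.mito_fraction(out$cyno), .mito_fraction(out$human))
  cells <- cell_table(meta$cell_id, meta$species, meta$replicate,
                      meta$timepoint, label = meta$label,
                      mito_fraction = mito_frac[meta$cell_id])

  truth <- list(
    gene_names = nm,
    species_effect = stats::setNames(species_effect, nm$human),
    species_affected = nm$human[sp_affected],
    temporal = lapply(temporal, function(tl) list(
      human = stats::setNames(tl$human, nm$human),
      cyno = stats::setNames(tl$cyno, nm$human),
      affected = nm$human[tl$affected],
      planted_cosine = cfg$temporal_target_cosine)),
    marker_genes = lapply(marker_idx, function(i) nm$human[i]),
    orthology = orth[c("one_to_one", "one_to_two", "two_to_one",
                       "mapped_cyno_idx")],
    lr_pairs = lr,
    sex = cfg$sex,
    doublet_ids = character(0),
    lowq_ids = character(0),
    config = cfg)
  class(truth) <- "SimTruth"
  list(cyno = out$cyno, human = out$human, cells = cells,
       orthologs = orth$table, truth = truth)
}

.mito_fraction <- function(cm) {
  mito <- grepl("^MT-", cm$gene_ids)
  tot <- Matrix::rowSums(cm$counts)
  mt <- if (any(mito)) Matrix::rowSums(cm$counts[, mito, drop = FALSE]) else 0
  stats::setNames(ifelse(tot > 0, mt / tot, 0), cm$cell_ids)
}

#' Inject doublets and low-quality cells into a simulated dataset
#'
#' Doublets are created by summing the counts of two random cells from the
#' same sample (species x replicate x timepoint) and appended as new cells.
#' Low-quality cells are existing cells whose non-mito counts are multiplied
#' by u ~ Uniform(0.05, 0.2) and whose mito fraction is pushed above the
#' species QC threshold. The truth object records all injected ids.
#'
#' @param sim output of [simulate_dataset()].
#' @param mito_threshold named per-species mito QC thresholds used to place
#'   injected low-quality cells above threshold.
#' @return the modified `sim` list (counts, cells and truth updated).
#' @export
inject_artifacts <- function(sim, mito_threshold = c(cyno = 0.0015, human = 0.15)) {
  cfg <- sim$truth$config
  stopifnot(cfg$doublet_rate < 0.5, cfg$lowq_rate < 0.5)
  set.seed(cfg$seed + 1L)
  cells <- sim$cells
  for (sp in c("cyno", "human")) {
    cm <- sim[[sp]]
    sp_cells <- cells[cells$species == sp, ]
    n <- nrow(sp_cells)
    n_d <- round(cfg$doublet_rate * n)
    n_l <- round(cfg$lowq_rate * n)

    if (n_d > 0) {
      sample_key <- paste(sp_cells$replicate, sp_cells$timepoint)
      new_rows <- vector("list", n_d)
      new_meta <- vector("list", n_d)
      for (i in seq_len(n_d)) {
        key <- sample(unique(sample_key), 1)
        pool <- sp_cells$cell_id[sample_key == key]
        pair <- sample(pool, 2)
        row <- cm$counts[pair[1], , drop = FALSE] + cm$counts[pair[2], , drop = FALSE]
        id <- sprintf("DBL_%s_%03d", sp, i)
        rownames(row) <- id
        new_rows[[i]] <- row
        pm <- sp_cells[sp_cells$cell_id == pair[1], ]
        new_meta[[i]] <- data.frame(cell_id = id, species = sp,
                                    replicate = pm$replicate,
                                    timepoint = pm$timepoint,
                                    label = pm$label,
                                    stringsAsFactors = FALSE)
      }
      m2 <- rbind(cm$counts, do.call(rbind, new_rows))
      cm <- count_matrix(m2, cm$gene_ids, rownames(m2))
      nmta <- do.call(rbind, new_meta)
      add <- cell_table(nmta$cell_id, nmta$species, nmta$replicate,
                        nmta$timepoint, label = nmta$label)
      cells <- rbind(cells, add)
      class(cells) <- c("CellTable", "data.frame")
      sim$truth$doublet_ids <- c(sim$truth$doublet_ids, nmta$cell_id)
    }

    if (n_l > 0) {
      lq <- sample(sp_cells$cell_id, n_l)
      mito <- grepl("^MT-", cm$gene_ids)
      m <- as.matrix(cm$counts[lq, , drop = FALSE])
      u <- stats::runif(n_l, 0.05, 0.2)
      m[, !mito] <- round(m[, !mito, drop = FALSE] * u)
      thr <- mito_threshold[[sp]]
      target <- pmin(0.6, thr * stats::runif(n_l, 2, 6))
      nonmito_tot <- rowSums(m[, !mito, drop = FALSE])
      mito_new <- pmax(1, round(target / (1 - target) * pmax(nonmito_tot, 20)))
      m[, mito] <- 0
      m[cbind(seq_len(n_l), rep(which(mito)[1], n_l))] <- mito_new
      full <- cm$counts
      full[lq, ] <- m
      cm <- count_matrix(full, cm$gene_ids, cm$cell_ids)
      sim$truth$lowq_ids <- c(sim$truth$lowq_ids, lq)
    }
    sim[[sp]] <- cm
  }
  mf <- c(.mito_fraction(sim$cyno), .mito_fraction(sim$human))
  cells$mito_fraction <- mf[cells$cell_id]
  sim$cells <- cells
  sim
}

#' Summarize the planted truth of a simulation
#'
#' @param truth SimTruth.
#' @return data.frame with one row per planted quantity (DE counts per cell
#'   type, recomputed and planted cosines, LR pairs, artifact counts).
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "SimTruth"))
  rows <- list()
  for (ty in names(truth$temporal)) {
    tl <- truth$temporal[[ty]]
    cosi <- .cosine(tl$human, tl$cyno)
    rows[[length(rows) + 1]] <- data.frame(
      item = "temporal_program", cell_type = ty,
      value = length(tl$affected),
      detail = sprintf("planted_cosine=%.3f recomputed=%.3f",
                       tl$planted_cosine, cosi))
  }
  if (length(truth$species_affected)) {
    rows[[length(rows) + 1]] <- data.frame(
      item = "species_effect", cell_type = "all",
      value = length(truth$species_affected),
      detail = sprintf("sd=%.3f", stats::sd(
        truth$species_effect[truth$species_affected])))
  }
  if (NROW(truth$lr_pairs)) {
    for (i in seq_len(nrow(truth$lr_pairs))) {
      p <- truth$lr_pairs[i, ]
      rows[[length(rows) + 1]] <- data.frame(
        item = "lr_pair", cell_type = p$source_type, value = p$boost,
        detail = sprintf("%s->%s to %s [%s]", p$ligand, p$receptor,
                         p$target_type, p$species))
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    item = "doublets", cell_type = "all",
    value = length(truth$doublet_ids), detail = "")
  rows[[length(rows) + 1]] <- data.frame(
    item = "lowq_cells", cell_type = "all",
    value = length(truth$lowq_ids), detail = "")
  do.call(rbind, rows)
}

.cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Write a simulated dataset as the MTX/TSV bundle the readers consume
#' @param sim simulate_dataset() output.
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$cyno, dir, prefix = "cyno_")
  write_counts(sim$human, dir, prefix = "human_")
  write_table_tsv(sim$cells, file.path(dir, "cells.tsv"))
  write_table_tsv(as.data.frame(sim$orthologs), file.path(dir, "orthologs.tsv"))
  invisible(dir)
}
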