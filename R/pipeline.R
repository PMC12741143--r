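#' Default end-to-end pipeline configuration
#'
#' @param seed global seed; every stochastic stage derives from it.
#' @param run_vae run the VAE-dependent stages (humanization, geometry,
#'   feature importance).
#' @param sim arguments passed to [sim_config()].
#' @param vae arguments passed to [vae_config()] (desk-scale defaults here:
#'   hidden 64x64, batch 64, 40 epochs).
#' @param n_hvg HVG count per species for the VAE input.
#' @param lr_n_perm permutations for the CCC scorer.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, run_vae = TRUE, sim = list(),
                                    vae = list(hidden_sizes = c(64, 64),
                                               batch_size = 64,
                                               max_epochs = 40, patience = 10),
                                    n_hvg = 1000, lr_n_perm = 200) {
  list(seed = seed, run_vae = run_vae, sim = sim, vae = vae,
       n_hvg = n_hvg, lr_n_perm = lr_n_perm)
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> artifact injection -> QC -> annotation -> sex
#' inference -> ortholog harmonization -> (optional) VAE humanization and
#' trajectory geometry and feature importance -> DGE + cross-species overlap
#' + enrichment co-analysis -> CCC conservation, writing per-stage TSV/JSON
#' outputs under `run_dir`.
#'
#' @param config list from [default_pipeline_config()] or a path to a JSON
#'   file with the same structure.
#' @param run_dir output directory.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), run_dir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  seed <- config$seed %||% 1
  res <- list()
  st_dir <- function(s) {
    d <- file.path(run_dir, s)
    if (!dir.exists(d)) dir.create(d)
    d
  }

  # --- simulate ---------------------------------------------------------
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  sim <- inject_artifacts(simulate_dataset(cfg))
  res$sim <- sim
  d <- st_dir("simulate")
  write_table_tsv(truth_summary(sim$truth), file.path(d, "truth_summary.tsv"))
  write_table_tsv(sim$cells, file.path(d, "cells.tsv"))

  # --- qc ---------------------------------------------------------------
  qc <- run_qc(sim, qc_config(), seed = seed)
  res$qc <- qc
  d <- st_dir("qc")
  write_table_tsv(qc$report, file.path(d, "qc_report.tsv"))
  write_table_tsv(qc$removed, file.path(d, "removed_cells.tsv"))
  kept_cells <- qc$celltable[qc$celltable$cell_id %in% qc$kept, ]

  # --- annotate + proportions + sex ------------------------------------
  d <- st_dir("annotate")
  ann <- list()
  for (sp in c("cyno", "human")) {
    cm <- subset_cells(sim[[sp]],
                       cells = intersect(sim[[sp]]$cell_ids, qc$kept))
    emb <- pca_embed(normalized_layer(cm), 30)
    cl <- cluster_graph(emb, resolution = qc_config()$annot_cluster_resolution,
                        k = 15, seed = seed)
    labs <- stats::setNames(kept_cells$label, kept_cells$cell_id)
    ann[[sp]] <- majority_annotate(cl, labs[names(cl)])
  }
  refined <- c(ann$cyno, ann$human)
  kept_cells$label_refined <- refined[kept_cells$cell_id]
  props <- proportions_table(
    within(kept_cells, label <- label_refined))
  write_table_tsv(props, file.path(d, "proportions.tsv"))
  sex <- rbind(infer_sex(sim$cyno, kept_cells),
               infer_sex(sim$human, kept_cells))
  write_table_tsv(sex, file.path(d, "sex_inference.tsv"))
  res$annotation <- kept_cells
  res$sex <- sex

  # --- orthology --------------------------------------------------------
  d <- st_dir("orthology")
  harm <- harmonize_duplicating(sim$cyno, sim$human, sim$orthologs)
  rep_tab <- orthology_report(sim$cyno, sim$human, sim$orthologs)
  write_table_tsv(rep_tab, file.path(d, "ortholog_classes.tsv"))
  res$harmonized <- harm
  res$ortholog_report <- rep_tab

  # --- vae: humanization + geometry + importance -----------------------
  if (isTRUE(config$run_vae %||% TRUE)) {
    d <- st_dir("vae")
    vargs <- config$vae %||% list()
    vargs$seed <- seed
    vcfg <- do.call(vae_config, vargs)
    hc <- subset_cells(harm$cyno, cells = intersect(harm$cyno$cell_ids, qc$kept))
    hh <- subset_cells(harm$human, cells = intersect(harm$human$cell_ids, qc$kept))
    hvg <- select_hvg(list(cyno = normalized_layer(hc),
                           human = normalized_layer(hh)),
                      n_per_species = config$n_hvg %||% 1000)
    joint <- rbind(normalized_layer(hc)[, hvg, drop = FALSE],
                   normalized_layer(hh)[, hvg, drop = FALSE])
    ctab <- kept_cells
    rows <- list()
    geo_rows <- list()
    imp_summary <- NULL
    for (ty in names(cfg$cell_types)) {
      for (mode in c("by_replicate", "random")) {
        split <- split_dataset(ctab, mode = mode, seed = seed)
        ev <- evaluate_humanization(joint, ctab, ty, split, vcfg)
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ty, split = mode, rho_raw = ev$rho_raw,
          rho_humanized = ev$rho_humanized, improvement = ev$improvement,
          n_train = ev$n_train, n_test = ev$n_test)
        if (mode == "by_replicate") {
          emb <- encode(ev$model, joint[intersect(ctab$cell_id, rownames(joint)), ])
          g <- temporal_geometry(emb, ctab, ty, timepoint = "24h")
          geo_rows[[length(geo_rows) + 1]] <- data.frame(
            cell_type = ty, timepoint = "24h", cosine = g$cosine,
            magnitude_h = g$magnitude_h, magnitude_c = g$magnitude_c)
          if (is.null(imp_summary)) {
            sp_ids <- ctab$cell_id[ctab$species == "cyno" & ctab$label == ty]
            sp_ids <- intersect(sp_ids, rownames(joint))
            sub <- joint[utils::head(sp_ids, 150), , drop = FALSE]
            st <- species_gene_stats(sub)
            imp <- feature_importance(ev$model, sub, st)
            imp_summary <- data.frame(gene = names(imp), importance = imp)
          }
        }
      }
    }
    ev_tab <- do.call(rbind, rows)
    write_table_tsv(ev_tab, file.path(d, "humanization_eval.tsv"))
    geo_tab <- do.call(rbind, geo_rows)
    write_table_tsv(geo_tab, file.path(d, "trajectory_geometry.tsv"))
    write_table_tsv(imp_summary, file.path(d, "feature_importance.tsv"))
    res$humanization <- ev_tab
    res$geometry <- geo_tab
    res$importance <- imp_summary
  }

  # --- dge + enrichment -------------------------------------------------
  d <- st_dir("dge")
  cyno11 <- collapse_one_to_one(sim$cyno, sim$orthologs)
  dge_rows <- list()
  overlap_rows <- list()
  for (ty in names(cfg$cell_types)) {
    tabs <- list()
    for (sp in c("cyno", "human")) {
      cm <- if (sp == "cyno") cyno11 else sim$human
      ids <- function(tp) {
        kept_cells$cell_id[kept_cells$species == sp &
                             kept_cells$label == ty &
                             kept_cells$timepoint == tp &
                             kept_cells$cell_id %in% cm$cell_ids]
      }
      g0 <- ids("0h"); g24 <- ids("24h")
      genes <- filter_genes(cm, list(g0, g24), min_prop = 0.7)
      tabs[[sp]] <- dge_test(cm, g0, g24, genes = genes,
                             context = list(species = sp, cell_type = ty,
                                            comparison = "0h_vs_24h"))
      dge_rows[[paste(sp, ty)]] <- tabs[[sp]]
    }
    ov <- cross_species_overlap(tabs$cyno, tabs$human)
    overlap_rows[[ty]] <- data.frame(
      cell_type = ty, n_cyno_only = ov$n_a_only, n_human_only = ov$n_b_only,
      n_shared = ov$n_shared, frac_same_direction = ov$frac_same_direction,
      p_direction = ov$p_direction)
  }
  dge_all <- do.call(rbind, dge_rows)
  write_table_tsv(dge_all, file.path(d, "dge_tables.tsv"))
  overlap_tab <- do.call(rbind, overlap_rows)
  write_table_tsv(overlap_tab, file.path(d, "cross_species_overlap.tsv"))
  res$dge <- dge_rows
  res$overlap <- overlap_tab

  # --- ccc --------------------------------------------------------------
  d <- st_dir("ccc")
  lr_db <- unique(sim$truth$lr_pairs[, c("ligand", "receptor")])
  cons_rows <- list()
  for (tp in c("0h", "24h")) {
    sig <- list()
    bg_keys <- NULL
    for (sp in c("cyno", "human")) {
      cm <- if (sp == "cyno") map_sum_by_human(sim$cyno, sim$orthologs) else sim$human
      ids <- kept_cells$cell_id[kept_cells$species == sp &
                                  kept_cells$timepoint == tp &
                                  kept_cells$cell_id %in% cm$cell_ids]
      cm <- subset_cells(cm, cells = ids)
      labs <- stats::setNames(kept_cells$label[match(ids, kept_cells$cell_id)], ids)
      tab <- score_interactions(normalized_layer(cm), labs, lr_db,
                                n_perm = config$lr_n_perm %||% 200,
                                seed = seed)
      sig[[sp]] <- filter_significant(tab, 0.25)
      bg_keys <- union(bg_keys, .lr_key(tab))
    }
    ct <- conservation_test(sig$cyno, sig$human, bg_keys)
    cons_rows[[tp]] <- data.frame(timepoint = tp,
                                  shared_count = ct$shared_count,
                                  shared_percent = ct$shared_percent,
                                  fisher_p = ct$fisher_p)
  }
  cons_tab <- do.call(rbind, cons_rows)
  write_table_tsv(cons_tab, file.path(d, "conservation.tsv"))
  res$ccc <- cons_tab

  jsonlite::write_json(list(seed = seed, stages = names(res)),
                       file.path(run_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-species temporal-shift geometry within one cell type
#'
#' Computes the per-species temporal shift (0h -> timepoint) in the given
#' embedding and returns the pair geometry from [vector_geometry()].
#'
#' @param embedding latent matrix (rownames = cell ids).
#' @param celltable CellTable.
#' @param cell_type cell type.
#' @param timepoint target timepoint ("6h" or "24h").
#' @return [vector_geometry()] output.
#' @export
temporal_geometry <- function(embedding, celltable, cell_type,
                              timepoint = "24h") {
  ct <- celltable[celltable$label == cell_type &
                    celltable$cell_id %in% rownames(embedding), ]
  sh <- list()
  for (sp in c("human", "cyno")) {
    from <- ct$cell_id[ct$species == sp & ct$timepoint == "0h"]
    to <- ct$cell_id[ct$species == sp & ct$timepoint == timepoint]
    sh[[sp]] <- compute_shift(embedding, from, to, kind = "temporal",
                              cell_type = cell_type, from_group = "0h",
                              to_group = timepoint)
  }
  vector_geometry(sh$human, sh$cyno)
}

#' Ensemble estimate of cross-species temporal-shift geometry
#'
#' The cosine between species' temporal shifts measured in a single VAE's
#' latent space carries model-to-model variability: the latent geometry of
#' an individual fit can rotate or attenuate one species' displacement
#' (narrow layers with a strongly polarizing species axis are the worst
#' case). Training several models that differ only in initialization seed
#' and averaging their cosine estimates removes most of that variance.
#'
#' @param joint normalized cells x genes matrix over the unified space.
#' @param celltable CellTable covering the rows of `joint`.
#' @param cell_type cell type to evaluate.
#' @param timepoint target timepoint.
#' @param config VAEConfig (its seed is offset per ensemble member).
#' @param n_models ensemble size (default 3).
#' @return list(cosine = mean estimate, per_model = data.frame, models =
#'   list of trained models).
#' @export
temporal_geometry_ensemble <- function(joint, celltable, cell_type,
                                       timepoint = "24h",
                                       config = vae_config(), n_models = 3) {
  rows <- list()
  models <- list()
  for (k in seq_len(n_models)) {
    cfg <- config
    cfg$seed <- config$seed + 100L * k
    model <- train_model(build_model(cfg, colnames(joint)), joint)
    g <- temporal_geometry(encode(model, joint), celltable, cell_type,
                           timepoint)
    rows[[k]] <- data.frame(member = k, cosine = g$cosine,
                            magnitude_h = g$magnitude_h,
                            magnitude_c = g$magnitude_c)
    models[[k]] <- model
  }
  per <- do.call(rbind, rows)
  list(cosine = mean(per$cosine), per_model = per, models = models)
}

#' Summarize a completed pipeline run
#'
#' Collates the stage TSVs of a [run_pipeline()] run directory into one
#' human-readable summary table; sections whose stage output is missing are
#' marked absent.
#'
#' @param run_dir run directory.
#' @return data.frame(section, metric, value); also written to
#'   `run_dir/report.tsv`.
#' @export
write_report <- function(run_dir) {
  rows <- list()
  put <- function(section, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(section = section,
                                            metric = metric,
                                            value = as.character(value))
  }
  rd <- function(p) if (file.exists(p))
    utils::read.table(p, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  qc <- rd(file.path(run_dir, "qc", "qc_report.tsv"))
  if (is.null(qc)) put("qc", "status", "absent") else {
    for (i in seq_len(nrow(qc))) {
      put("qc", paste0(qc$species[i], "_removed"),
          sprintf("%d/%d (doublets %d)", qc$n_removed[i], qc$n_input[i],
                  qc$n_doublet[i]))
    }
  }
  ot <- rd(file.path(run_dir, "orthology", "ortholog_classes.tsv"))
  if (is.null(ot)) put("orthology", "status", "absent") else {
    put("orthology", "coverage", ot$value[ot$class == "coverage"])
  }
  hv <- rd(file.path(run_dir, "vae", "humanization_eval.tsv"))
  if (is.null(hv)) put("humanization", "status", "absent") else {
    for (i in seq_len(nrow(hv))) {
      put("humanization", paste(hv$cell_type[i], hv$split[i]),
          sprintf("rho_raw=%.3f rho_humanized=%.3f", hv$rho_raw[i],
                  hv$rho_humanized[i]))
    }
  }
  ge <- rd(file.path(run_dir, "vae", "trajectory_geometry.tsv"))
  if (is.null(ge)) put("geometry", "status", "absent") else {
    for (i in seq_len(nrow(ge))) {
      put("geometry", paste(ge$cell_type[i], ge$timepoint[i]),
          sprintf("cosine=%.3f |h|=%.2f |c|=%.2f", ge$cosine[i],
                  ge$magnitude_h[i], ge$magnitude_c[i]))
    }
  }
  ov <- rd(file.path(run_dir, "dge", "cross_species_overlap.tsv"))
  if (is.null(ov)) put("dge_overlap", "status", "absent") else {
    for (i in seq_len(nrow(ov))) {
      put("dge_overlap", ov$cell_type[i],
          sprintf("shared=%d same_dir=%.2f", ov$n_shared[i],
                  ov$frac_same_direction[i]))
    }
  }
  cc <- rd(file.path(run_dir, "ccc", "conservation.tsv"))
  if (is.null(cc)) put("ccc", "status", "absent") else {
    for (i in seq_len(nrow(cc))) {
      put("ccc", cc$timepoint[i],
          sprintf("shared=%d (%.1f%%) p=%.2g", cc$shared_count[i],
                  cc$shared_percent[i], cc$fisher_p[i]))
    }
  }
  rep <- do.call(rbind, rows)
  write_table_tsv(rep, file.path(run_dir, "report.tsv"))
  rep
}
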