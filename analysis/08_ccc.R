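#!/usr/bin/env Rscript
# Stage 8 — ligand-receptor interaction scoring (mean-product magnitude +
# permutation specificity), significance filtering, cross-species
# conservation testing and network/activity summaries.

library(crossvae)

cfg <- sim_config(seed = 5)
sim <- simulate_dataset(cfg)
lr_db <- unique(sim$truth$lr_pairs[, c("ligand", "receptor")])

cons <- list()
for (tp in c("0h", "24h")) {
  sig <- list(); bg <- NULL; tabs <- list()
  for (sp in c("cyno", "human")) {
    cm <- if (sp == "cyno") map_sum_by_human(sim$cyno, sim$orthologs)
          else sim$human
    ids <- sim$cells$cell_id[sim$cells$species == sp &
                               sim$cells$timepoint == tp &
                               sim$cells$cell_id %in% cm$cell_ids]
    cm <- subset_cells(cm, cells = ids)
    labs <- setNames(sim$cells$label[match(ids, sim$cells$cell_id)], ids)
    tab <- score_interactions(normalized_layer(cm), labs, lr_db,
                              n_perm = 500, seed = 5)
    tabs[[sp]] <- tab
    sig[[sp]] <- filter_significant(tab, 0.25)
    bg <- union(bg, paste(tab$source_type, tab$target_type, tab$ligand,
                          tab$receptor, sep = "|"))
  }
  ct <- conservation_test(sig$cyno, sig$human, bg)
  cons[[tp]] <- data.frame(timepoint = tp, shared_count = ct$shared_count,
                           shared_percent = ct$shared_percent,
                           fisher_p = ct$fisher_p)
  message(sprintf("%s: %d shared significant interactions (%.0f%% of the union), Fisher p = %.2g",
                  tp, ct$shared_count, ct$shared_percent, ct$fisher_p))
  ns <- network_summaries(tabs$human, edge_cut = 0.25)
  write_table_tsv(ns$edges, paste0("results/ccc_network_human_", tp, ".tsv"))
}
write_table_tsv(do.call(rbind, cons), "results/ccc_conservation.tsv")
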