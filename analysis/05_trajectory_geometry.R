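#!/usr/bin/env Rscript
# Stage 5 — temporal trajectory geometry: per-species temporal shift vectors
# in VAE latent space, their cross-species cosine similarity, and recovery of
# the planted cosine across three scenarios (0, 0.5, 1).

library(crossvae)

rows <- list()
for (tc in c(0, 0.5, 1)) {
  cfg <- sim_config(n_genes = 1200, cell_types = c("CD4 T" = 150),
                    temporal_target_cosine = tc, seed = 2)
  sim <- simulate_dataset(cfg)
  h <- harmonize_duplicating(sim$cyno, sim$human, sim$orthologs)
  hvg <- select_hvg(list(cyno = normalized_layer(h$cyno),
                         human = normalized_layer(h$human)), 600)
  joint <- rbind(normalized_layer(h$cyno)[, hvg, drop = FALSE],
                 normalized_layer(h$human)[, hvg, drop = FALSE])
  vcfg <- vae_config(hidden_sizes = c(128, 128), batch_size = 64,
                     max_epochs = 30, patience = 10, seed = 2)
  ens <- temporal_geometry_ensemble(joint, sim$cells, "CD4 T", "24h", vcfg,
                                    n_models = 3)
  for (tp in c("6h", "24h")) {
    per <- if (tp == "24h") ens$per_model else {
      do.call(rbind, lapply(ens$models, function(m) {
        g <- temporal_geometry(encode(m, joint), sim$cells, "CD4 T", tp)
        data.frame(cosine = g$cosine, magnitude_h = g$magnitude_h,
                   magnitude_c = g$magnitude_c)
      }))
    }
    rows[[length(rows) + 1]] <- data.frame(
      planted_cosine = tc, timepoint = tp, est_cosine = mean(per$cosine),
      rescaled = (1 + mean(per$cosine)) / 2,
      magnitude_h = mean(per$magnitude_h),
      magnitude_c = mean(per$magnitude_c),
      cosine_sd = sd(per$cosine))
  }
  message(sprintf("planted cosine %.1f: estimated 24h cosine %.3f (ensemble of 3), |h| %.2f |c| %.2f",
                  tc, rows[[length(rows)]]$est_cosine,
                  rows[[length(rows)]]$magnitude_h,
                  rows[[length(rows)]]$magnitude_c))
}
tab <- do.call(rbind, rows)
write_table_tsv(tab, "results/trajectory_geometry.tsv")
est24 <- tab$est_cosine[tab$timepoint == "24h"]
message("Estimated 24h cosines are ",
        if (all(diff(est24) > 0)) "strictly increasing" else "NOT monotone",
        " in the planted cosine; 24h magnitudes exceed 6h magnitudes for ",
        sum(tab$magnitude_h[tab$timepoint == "24h"] >
              tab$magnitude_h[tab$timepoint == "6h"]), "/3 scenarios (human).")
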