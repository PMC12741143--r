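#!/usr/bin/env Rscript
# Stage 1 — generate the two-species synthetic PBMC dataset with planted
# ground truth (species baseline effects, temporal programs with controlled
# cross-species cosine, ligand-receptor interactions, doublets and
# low-quality cells) and write it as the MTX/TSV bundle downstream stages
# read.

library(crossvae)

out <- "results/data"
cfg <- sim_config(seed = 1)
sim <- inject_artifacts(simulate_dataset(cfg))
write_dataset(sim, out)
write_table_tsv(truth_summary(sim$truth), "results/data/truth_summary.tsv")

message("Simulated ", nrow(sim$cells), " cells (",
        sum(sim$cells$species == "cyno"), " cyno / ",
        sum(sim$cells$species == "human"), " human), ",
        cfg$n_genes, " genes per species.")
message("Planted: ", length(sim$truth$species_affected),
        " species-effect genes, ",
        length(sim$truth$doublet_ids), " doublets, ",
        length(sim$truth$lowq_ids), " low-quality cells, ",
        nrow(sim$truth$lr_pairs), " ligand-receptor pairs.")
message("Bundle written under ", out)
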