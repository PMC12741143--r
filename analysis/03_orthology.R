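#!/usr/bin/env Rscript
# Stage 3 — ortholog handling in its three regimes: duplicating n:m
# harmonization (VAE input), 1:1 collapse (unique-gene analyses) and
# duplicate-then-sum mapping (cell-cell communication).

library(crossvae)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)

rep <- orthology_report(sim$cyno, sim$human, sim$orthologs)
write_table_tsv(rep, "results/ortholog_classes.tsv")
print(rep)

h <- harmonize_duplicating(sim$cyno, sim$human, sim$orthologs)
message("Unified (duplicating) gene space: ", length(h$unified_gene_ids),
        " columns from ", length(sim$cyno$gene_ids), " cyno + ",
        length(sim$human$gene_ids), " human genes.")

c11 <- collapse_one_to_one(sim$cyno, sim$orthologs)
message("1:1 collapse: ", length(c11$gene_ids), " unique human-named genes.")

cs <- map_sum_by_human(sim$cyno, sim$orthologs)
message("Duplicate-then-sum mapping: ", length(cs$gene_ids), " human names; ",
        "mass ratio vs input ",
        round(sum(cs$counts) / sum(sim$cyno$counts), 3),
        " (> 1 reflects 1:m duplication).")
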