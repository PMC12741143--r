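# Shared fixtures, built once per test run and memoised.

.fix_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- builder()
  .fix_env[[name]]
}

# Small injected dataset for QC tests: 3 well-separated types.
fix_sim_injected <- function() get_fixture("sim_injected", function() {
  cfg <- sim_config(n_genes = 800,
                    cell_types = c("CD4 T" = 60, "CD8 T" = 60, "NK" = 60),
                    seed = 41)
  inject_artifacts(simulate_dataset(cfg))
})

# Clean single-type dataset plus a trained joint VAE over HVGs,
# reused by the VAE/shift/importance tests.
fix_vae_bundle <- function() get_fixture("vae_bundle", function() {
  cfg <- sim_config(n_genes = 1200, cell_types = c("CD4 T" = 150), seed = 31)
  sim <- simulate_dataset(cfg)
  h <- harmonize_duplicating(sim$cyno, sim$human, sim$orthologs)
  hvg <- select_hvg(list(cyno = normalized_layer(h$cyno),
                         human = normalized_layer(h$human)), 600)
  joint <- rbind(normalized_layer(h$cyno)[, hvg, drop = FALSE],
                 normalized_layer(h$human)[, hvg, drop = FALSE])
  vcfg <- vae_config(hidden_sizes = c(64, 64), batch_size = 64,
                     max_epochs = 30, patience = 10, seed = 31)
  model <- train_model(build_model(vcfg, colnames(joint)), joint)
  list(cfg = cfg, sim = sim, harm = h, joint = joint, model = model,
       vcfg = vcfg)
})

# Two separated Gaussian blobs with labels, for clustering/latent tests.
fix_blobs <- function(n_per = 60, g = 40, sep = 2, seed = 7) {
  set.seed(seed)
  mu1 <- stats::rnorm(g)
  mu2 <- mu1 + stats::rnorm(g, 0, sep)
  X <- rbind(matrix(stats::rnorm(n_per * g, mu1, 0.3), n_per, g, byrow = TRUE),
             matrix(stats::rnorm(n_per * g, mu2, 0.3), n_per, g, byrow = TRUE))
  colnames(X) <- paste0("g", seq_len(g))
  rownames(X) <- paste0("c", seq_len(2 * n_per))
  list(X = X, labels = rep(c(1, 2), each = n_per))
}

# Tiny CountMatrix from a dense integer matrix.
toy_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(nrow(m)))
  count_matrix(m, genes, cells)
}

# Adjusted Rand index (independent oracle for cluster agreement).
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
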