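test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 300, cell_types = c(A = 30, B = 30), seed = 3)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(s1$cyno$counts), as.matrix(s2$cyno$counts))
  expect_identical(as.matrix(s1$human$counts), as.matrix(s2$human$counts))
  expect_identical(s1$cells, s2$cells)
  expect_identical(as.data.frame(s1$orthologs), as.data.frame(s2$orthologs))
})

test_that("negative-binomial sampling is consistent with its planted mean/dispersion", {
  # null config: no effects, fixed library size -> cells at one timepoint are
  # iid draws from NB(mu_g, size); split-half Monte-Carlo comparison
  cfg <- sim_config(n_genes = 200, cell_types = c(A = 600),
                    species_effect_sd = 0, species_frac_affected = 0,
                    temporal_effect_size = 0, replicate_effect_sd = 0,
                    libsize_lognormal = c(log(2000), 0), n_replicates = 1,
                    doublet_rate = 0, lowq_rate = 0,
                    lr_truth = data.frame(), seed = 8)
  sim <- simulate_dataset(cfg)
  cells0 <- sim$cells$cell_id[sim$cells$species == "human" &
                                sim$cells$timepoint == "0h"]
  m <- as.matrix(sim$human$counts[cells0, ])
  h1 <- colMeans(m[1:300, ]); h2 <- colMeans(m[301:600, ])
  se <- sqrt((h2 + h2^2 / cfg$nb_dispersion) / 300)
  ok <- abs(h1 - h2) <= 4 * sqrt(2) * se + 1e-9
  expect_gt(mean(ok), 0.98)
  # dispersion sanity: variance ~ mu + mu^2/size, far from Poisson for high mu
  v <- apply(m, 2, var)
  mu <- colMeans(m)
  hi <- mu > 5
  expect_gt(median((v / (mu + mu^2 / cfg$nb_dispersion))[hi]), 0.7)
  expect_lt(median((v / (mu + mu^2 / cfg$nb_dispersion))[hi]), 1.3)
})

test_that("with all effect sds zero, species differ only by sampling noise", {
  cfg <- sim_config(n_genes = 300, cell_types = c(A = 250),
                    species_effect_sd = 0, species_frac_affected = 0,
                    temporal_effect_size = 0, replicate_effect_sd = 0,
                    mito_frac = c(cyno = 0.01, human = 0.01),
                    lr_truth = data.frame(),
                    n_replicates = 1, seed = 12)
  sim <- simulate_dataset(cfg)
  nc <- normalized_layer(sim$cyno)
  nh <- normalized_layer(sim$human)
  # same gene order by construction (cyno names differ, index aligned)
  d <- colMeans(nc) - colMeans(nh)
  # exclude Y markers (sex composition differs between species by design)
  y <- colnames(nh) %in% y_markers_default()
  expect_lt(max(abs(d[!y])), 0.2)
  expect_gt(cor(colMeans(nc)[!y], colMeans(nh)[!y]), 0.99)
})

test_that("planted temporal vectors have exactly the target cosine", {
  for (tc in c(0, 0.5, 1)) {
    cfg <- sim_config(n_genes = 300, cell_types = c(A = 5),
                      temporal_target_cosine = tc, seed = 5)
    sim <- simulate_dataset(cfg)
    tl <- sim$truth$temporal$A
    cs <- sum(tl$human * tl$cyno) /
      (sqrt(sum(tl$human^2)) * sqrt(sum(tl$cyno^2)))
    expect_equal(cs, tc, tolerance = 1e-10)
  }
})

test_that("naive log-mean differences recover planted temporal log-FCs", {
  cfg <- sim_config(n_genes = 500, cell_types = c(A = 220),
                    temporal_effect_size = 1, n_replicates = 1,
                    species_effect_sd = 0, species_frac_affected = 0,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  ct <- sim$cells[sim$cells$species == "human", ]
  n <- normalized_layer(sim$human)
  d <- colMeans(n[ct$cell_id[ct$timepoint == "24h"], ]) -
    colMeans(n[ct$cell_id[ct$timepoint == "0h"], ])
  planted <- sim$truth$temporal$A$human[colnames(n)]
  aff <- planted != 0
  expect_gt(cor(d[aff], planted[aff], method = "spearman"), 0.5)
})

test_that("emitted ortholog coverage equals the configured value within one gene", {
  for (cov in c(0.6, 0.813)) {
    cfg <- sim_config(n_genes = 400, cell_types = c(A = 5),
                      ortholog_coverage = cov, seed = 2)
    sim <- simulate_dataset(cfg)
    n_mapped <- length(unique(sim$orthologs$source_gene))
    expect_lte(abs(n_mapped - cov * 400), 1)
  }
})

test_that("artifact injection plants the advertised doublets and low-quality cells", {
  cfg0 <- sim_config(n_genes = 200, cell_types = c(A = 30), doublet_rate = 0,
                     lowq_rate = 0, seed = 4)
  sim0 <- inject_artifacts(simulate_dataset(cfg0))
  expect_length(sim0$truth$doublet_ids, 0)
  expect_length(sim0$truth$lowq_ids, 0)

  sim <- fix_sim_injected()
  cfg <- sim$truth$config
  n_per_sp <- sum(cfg$cell_types) * cfg$n_replicates * 3
  expect_length(sim$truth$doublet_ids, 2 * round(cfg$doublet_rate * n_per_sp))
  expect_length(sim$truth$lowq_ids, 2 * round(cfg$lowq_rate * n_per_sp))

  # a doublet's total counts equal the sum of two cells' totals: doublet
  # totals are in the upper tail of the per-sample distribution
  ct <- sim$cells
  tot <- Matrix::rowSums(sim$human$counts)
  dbl <- intersect(sim$truth$doublet_ids, names(tot))
  singlet <- setdiff(ct$cell_id[ct$species == "human"],
                     c(sim$truth$doublet_ids, sim$truth$lowq_ids))
  expect_gt(median(tot[dbl]), 1.5 * median(tot[singlet]))

  # low-quality cells have high mito fraction and shrunken counts
  lq <- intersect(sim$truth$lowq_ids, ct$cell_id[ct$species == "human"])
  mf <- ct$mito_fraction[match(lq, ct$cell_id)]
  expect_gt(min(mf), 0.15)
})

test_that("truth summary tabulates planted quantities consistently", {
  sim <- fix_sim_injected()
  ts <- truth_summary(sim$truth)
  expect_true(all(c("temporal_program", "lr_pair", "doublets") %in% ts$item))
  expect_equal(ts$value[ts$item == "doublets"],
               length(sim$truth$doublet_ids))
  # recomputed cosine in the detail string matches the planted one
  tp <- ts[ts$item == "temporal_program", ]
  expect_true(all(grepl("planted_cosine=1.000 recomputed=1.000", tp$detail)))
})

test_that("male replicates express Y markers and females do not", {
  sim <- fix_sim_injected()
  ct <- sim$cells
  ym <- intersect(y_markers_default(), sim$human$gene_ids)
  h2 <- ct$cell_id[ct$species == "human" & ct$replicate == "r2" &
                     !(ct$cell_id %in% sim$truth$lowq_ids)]
  h1 <- ct$cell_id[ct$species == "human" & ct$replicate == "r1"]
  expect_equal(sum(sim$human$counts[h2, ym]), 0)      # female replicate
  expect_gt(sum(sim$human$counts[h1, ym]), 0)         # male replicate
})
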