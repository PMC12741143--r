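test_that("interaction magnitudes and ranks follow the scorer definition", {
  set.seed(31)
  n <- 60
  m <- matrix(rpois(n * 4, 5), n, 4,
              dimnames = list(paste0("c", 1:n), c("L1", "R1", "L2", "R2")))
  m[, "L1"] <- 0                      # ligand silent everywhere
  norm <- normalize_log1p(m)
  ct <- setNames(rep(c("A", "B"), each = n / 2), rownames(m))
  lr <- data.frame(ligand = c("L1", "L2", "LX"), receptor = c("R1", "R2", "R2"))
  tab <- score_interactions(norm, ct, lr, n_perm = 100, seed = 1)
  # missing-gene pair excluded but reported
  expect_false(any(tab$ligand == "LX"))
  expect_equal(attr(tab, "excluded_pairs")$ligand, "LX")
  # silent ligand: magnitude 0, specificity p ~ 1
  l1 <- tab[tab$ligand == "L1", ]
  expect_true(all(l1$magnitude == 0))
  expect_true(all(l1$p_specificity > 0.9))
  # hand-check one magnitude: mean ligand in source x mean receptor in target
  r <- tab[tab$ligand == "L2" & tab$source_type == "A" &
             tab$target_type == "B", ]
  expect_equal(r$magnitude,
               mean(norm[ct == "A", "L2"]) * mean(norm[ct == "B", "R2"]))
  # fractional ranks live in (0, 1] and are order-invariant
  expect_true(all(tab$magnitude_rank > 0 & tab$magnitude_rank <= 1))
  tab2 <- score_interactions(norm, ct, lr[c(2, 1, 3), ], n_perm = 100, seed = 1)
  key <- function(t) paste(t$source_type, t$target_type, t$ligand, t$receptor)
  expect_equal(tab$magnitude_rank[order(key(tab))],
               tab2$magnitude_rank[order(key(tab2))])
})

test_that("permutation specificity p-values are calibrated under a label null", {
  set.seed(32)
  n <- 200; G <- 60
  m <- matrix(rnbinom(n * G, mu = 3, size = 2), n, G,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:G)))
  norm <- normalize_log1p(m)
  ct <- setNames(sample(c("A", "B"), n, replace = TRUE), rownames(m))
  lr <- data.frame(ligand = paste0("g", 1:30), receptor = paste0("g", 31:60))
  tab <- score_interactions(norm, ct, lr, n_perm = 400, seed = 6)
  rej <- mean(tab$p_specificity <= 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.09)
})

test_that("rank filtering is monotone and bounded by the input", {
  set.seed(33)
  tab <- data.frame(source_type = "A", target_type = "B",
                    ligand = paste0("L", 1:50), receptor = paste0("R", 1:50),
                    magnitude = runif(50), p_specificity = runif(50))
  tab$magnitude_rank <- rank(-tab$magnitude) / 50
  tab$specificity_rank <- rank(tab$p_specificity) / 50
  expect_equal(nrow(filter_significant(tab, 1.0)), 50)
  f1 <- filter_significant(tab, 0.1)
  f2 <- filter_significant(tab, 0.3)
  expect_true(all(rownames(f1) %in% rownames(f2)))
  expect_equal(nrow(filter_significant(tab[0, ], 0.5)), 0)
})

test_that("conservation statistics match brute-force hypergeometric expectations", {
  bg <- paste0("p", 1:100)
  a <- bg[1:20]; b <- bg[c(1:15, 21:25)]
  mk <- function(keys) {
    parts <- data.frame(source_type = keys, target_type = "T",
                        ligand = "L", receptor = "R")
    parts
  }
  # use key vectors directly
  ct <- conservation_test(mk(a), mk(b), c(outer(bg, "|T|L|R", paste0)))
  expect_equal(ct$shared_count, 15)
  expect_equal(ct$shared_percent, 100 * 15 / 25)
  expect_equal(ct$shared_percent_a, 75)
  # brute-force one-sided hypergeometric: P(X >= 15) drawing 20 from 100 with 20 marked
  brute <- sum(dhyper(15:20, 20, 80, 20))
  expect_equal(ct$fisher_p, brute, tolerance = 1e-10)
  # identical sets: 100% shared; disjoint: zero
  expect_equal(conservation_test(mk(a), mk(a),
                                 c(outer(bg, "|T|L|R", paste0)))$shared_percent, 100)
  dis <- conservation_test(mk(bg[1:10]), mk(bg[11:20]),
                           c(outer(bg, "|T|L|R", paste0)))
  expect_equal(dis$shared_count, 0)
  expect_error(conservation_test(mk(a), mk(b), character(0)), "background")
})

test_that("network summaries aggregate weights and conserve interaction counts", {
  tab <- data.frame(source_type = c("A", "A", "B"),
                    target_type = c("B", "B", "A"),
                    ligand = c("L1", "L2", "L3"),
                    receptor = c("R1", "R2", "R3"),
                    magnitude = c(3, 2, 1),
                    p_specificity = c(1e-4, 1e-4, 1e-4),
                    magnitude_rank = c(0.001, 0.0005, 0.2),
                    specificity_rank = c(0.001, 0.001, 0.001))
  ns <- network_summaries(tab, edge_cut = 0.001)
  expect_equal(nrow(ns$edges), 1)      # only the two A->B rows survive
  expect_equal(ns$edges$weight, log10(0.001) + log10(0.0005))
  # single interaction at rank 0.001 gives weight -3
  ns1 <- network_summaries(tab[1, ], edge_cut = 0.001)
  expect_equal(ns1$edges$weight, -3)
  # summed source activity equals surviving interaction count
  expect_equal(sum(ns$activity$n_source), 2)
  expect_equal(sum(ns$activity$n_target), 2)
  # nothing surviving: empty structures
  ns0 <- network_summaries(tab, edge_cut = 1e-6)
  expect_equal(nrow(ns0$edges), 0)
})

test_that("planted ligand-receptor pairs are recovered as conserved; species-specific ones are not", {
  sim <- fix_sim_injected()
  lr_truth <- sim$truth$lr_pairs
  lr_db <- unique(lr_truth[, c("ligand", "receptor")])
  clean <- setdiff(sim$cells$cell_id,
                   c(sim$truth$doublet_ids, sim$truth$lowq_ids))
  sig <- list()
  for (sp in c("cyno", "human")) {
    cm <- if (sp == "cyno") map_sum_by_human(sim$cyno, sim$orthologs) else sim$human
    ids <- sim$cells$cell_id[sim$cells$species == sp &
                               sim$cells$timepoint == "0h" &
                               sim$cells$cell_id %in% clean]
    cm <- subset_cells(cm, cells = ids)
    labs <- setNames(sim$cells$label[match(ids, sim$cells$cell_id)], ids)
    tab <- score_interactions(normalized_layer(cm), labs, lr_db,
                              n_perm = 300, seed = 2)
    sig[[sp]] <- filter_significant(tab, 0.3)
    if (sp == "human") sig$human_strict <- filter_significant(tab, 0.12)
  }
  keys <- function(t) paste(t$source_type, t$target_type, t$ligand, t$receptor)
  truth_key <- function(rows) paste(rows$source_type, rows$target_type,
                                    rows$ligand, rows$receptor)
  both <- lr_truth[lr_truth$species == "both", ]
  shared <- intersect(keys(sig$cyno), keys(sig$human))
  expect_gte(mean(truth_key(both) %in% shared), 2 / 3)
  cyno_only <- lr_truth[lr_truth$species == "cyno", ]
  expect_false(any(truth_key(cyno_only) %in% keys(sig$human_strict)))
})
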