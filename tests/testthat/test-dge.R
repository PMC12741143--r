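test_that("expression filter applies the detection-rate rule", {
  set.seed(2)
  m <- matrix(0L, 20, 3, dimnames = list(paste0("c", 1:20),
                                         c("gHigh", "gLow", "gZero")))
  m[1:16, "gHigh"] <- 1L          # 80% detection in group A
  m[1:2, "gLow"] <- 1L            # 10% detection
  cm <- toy_counts(m, genes = colnames(m), cells = rownames(m))
  gA <- paste0("c", 1:20)
  expect_equal(filter_genes(cm, list(gA), 0.7), "gHigh")
  # min_prop 0 keeps all genes detected anywhere
  expect_setequal(filter_genes(cm, list(gA), 0), c("gHigh", "gLow"))
  expect_error(filter_genes(cm, list(gA), 1.0), "no genes")
})

test_that("the Wilcoxon engine agrees with wilcox.test and recovers planted effects", {
  set.seed(14)
  n <- 200; G <- 400
  lfc <- c(rep(1, 60), rep(-1, 60), rep(0, G - 120))
  mu0 <- rlnorm(G, 1, 0.7)
  mA <- matrix(rnbinom(n * G, mu = rep(mu0, each = n), size = 2), n, G)
  mB <- matrix(rnbinom(n * G, mu = rep(mu0 * 2^lfc, each = n), size = 2), n, G)
  m <- rbind(mA, mB)
  dimnames(m) <- list(paste0("c", 1:(2 * n)), paste0("g", 1:G))
  cm <- toy_counts(m, genes = colnames(m), cells = rownames(m))
  gA <- rownames(m)[1:n]; gB <- rownames(m)[(n + 1):(2 * n)]
  dt <- dge_test(cm, gA, gB)

  # dual route: package rank-sum p equals stats::wilcox.test on a spot check
  norm <- normalized_layer(cm)
  for (g in c("g1", "g100", "g300")) {
    ref <- suppressWarnings(stats::wilcox.test(norm[gA, g], norm[gB, g],
                                               exact = FALSE))$p.value
    expect_equal(dt$p[dt$gene == g], ref, tolerance = 1e-10)
  }

  planted <- colnames(m)[lfc != 0]
  recovered <- dt$gene[dt$fdr <= 0.05]
  expect_gte(mean(planted %in% recovered), 0.8)
  hit <- intersect(recovered, planted)
  sign_ok <- sign(dt$logFC[match(hit, dt$gene)]) ==
    sign(lfc[match(hit, colnames(m))])
  expect_gte(mean(sign_ok), 0.95)
  # BH column consistent with p.adjust
  expect_equal(dt$fdr, p.adjust(dt$p, "BH"))
})

test_that("null p-values are uniform (permuted labels on one population)", {
  set.seed(15)
  n <- 240; G <- 1200
  mu <- rlnorm(G, 1, 0.8)
  m <- matrix(rnbinom(n * G, mu = rep(mu, each = n), size = 2), n, G,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:G)))
  cm <- toy_counts(m, genes = colnames(m), cells = rownames(m))
  gA <- rownames(m)[1:120]; gB <- rownames(m)[121:240]
  genes <- filter_genes(cm, list(gA, gB), 0.7)
  dt <- dge_test(cm, gA, gB, genes = genes)
  ks <- suppressWarnings(stats::ks.test(dt$p, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("the regulated-fraction estimator is calibrated and monotone", {
  set.seed(16)
  expect_lte(fraction_regulated(runif(10000)), 0.05)
  alt <- c(runif(3000, 0, 1e-3), runif(7000))
  expect_lt(abs(fraction_regulated(alt) - 0.30), 0.05)
  expect_warning(f1 <- fraction_regulated(rep(1e-10, 200)), "degenerate")
  expect_equal(f1, 1)
  # monotone in the planted fraction
  fr <- vapply(c(0, 0.1, 0.3), function(f) {
    set.seed(17)
    fraction_regulated(c(runif(round(f * 5000), 0, 1e-3),
                         runif(round((1 - f) * 5000))))
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_error(fraction_regulated(runif(50)), "100")
})

test_that("cross-species overlap counts, direction fractions and tests are exact on toys", {
  mk <- function(genes, fdr, lfc) data.frame(gene = genes, p = fdr, fdr = fdr,
                                             logFC = lfc)
  a <- mk(paste0("g", 1:20), c(rep(0.01, 10), rep(0.9, 10)),
          c(rep(1, 9), -1, rep(1, 10)))
  b <- mk(paste0("g", 1:20), c(rep(0.01, 10), rep(0.9, 10)), rep(1, 20))
  ov <- cross_species_overlap(a, b, fdr_cut = 0.2, direction_test = "binomial")
  expect_equal(ov$n_shared, 10)
  expect_equal(ov$frac_same_direction, 0.9)
  expect_equal(round(ov$p_direction, 3), 0.021)   # 2*P(X>=9 | n=10, p=.5)
  # identical tables: all shared, same direction
  ov2 <- cross_species_overlap(a, a)
  expect_equal(ov2$n_shared, 10)
  expect_equal(ov2$frac_same_direction, 1)
  # disjoint significant sets
  b3 <- mk(paste0("g", 1:20), c(rep(0.9, 10), rep(0.01, 10)), rep(1, 20))
  ov3 <- cross_species_overlap(a, b3)
  expect_equal(ov3$n_shared, 0)
  expect_true(is.na(ov3$frac_same_direction))
  # prop.test route matches stats::prop.test
  ovp <- cross_species_overlap(a, b, direction_test = "prop")
  expect_equal(ovp$p_direction,
               prop.test(9, 10, p = 0.5)$p.value)
})

test_that("foreground selection ranks by |logFC| with p and id tie-breaks, order-invariantly", {
  d <- data.frame(gene = c("gA", "gB", "gC", "gD", "gE"),
                  logFC = c(2, -2, 1.5, 1.5, 0.5),
                  p = c(1e-4, 2e-4, 1e-3, 1e-5, 1e-2),
                  fdr = c(0.01, 0.01, 0.05, 0.05, 0.5))
  fg <- select_foreground(d, fdr_cut = 0.2, top_n = 3)
  expect_equal(fg, c("gA", "gB", "gD"))   # |2| ties broken by p; gD beats gC on p
  # fewer significant than the cap: all returned
  expect_length(select_foreground(d, fdr_cut = 0.2, top_n = 200), 4)
  # invariance to row order
  set.seed(3)
  for (i in 1:5) {
    expect_equal(select_foreground(d[sample(5), ], 0.2, 3), fg)
  }
})

test_that("BH agrees with the brute-force step-up definition for n <= 20", {
  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(1, adj)
    out
  }
  set.seed(21)
  for (n in c(1, 5, 12, 20)) {
    for (rep in 1:5) {
      p <- runif(n)
      expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
    }
  }
})

test_that("Fisher enrichment matches hypergeometric summation and applies the study filters", {
  # worked toy: |bg| = 100, |fg| = 10, pathway of 10 with 5 hits
  bg <- paste0("g", 1:100)
  fg <- paste0("g", 1:10)
  pw <- paste0("g", c(1:5, 51:55))
  gsc <- gene_set_collection(list(P = pw), "toy")
  tab <- enrich_fisher(fg, bg, gsc, fdr_cut = 1, min_hits = 0)
  # brute-force hypergeometric tail P(X >= 5)
  brute <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(tab$p, brute, tolerance = 1e-10)
  expect_equal(tab$p, 6.716277e-4, tolerance = 1e-4)
  expect_equal(tab$enrichment_factor, log(tab$odds_ratio))

  # property: Fisher p equals direct tail summation over random small tables
  set.seed(22)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    K <- sample(2:min(30, N - 1), 1)
    nn <- sample(2:min(30, N - 1), 1)
    bgi <- paste0("g", 1:N)
    fgi <- paste0("g", 1:nn)
    pwi <- paste0("g", sample(N, K))
    ti <- enrich_fisher(fgi, bgi, gene_set_collection(list(P = pwi), "t"),
                        fdr_cut = 1, min_hits = 0)
    a <- length(intersect(pwi, fgi))
    tail <- sum(dhyper(a:min(K, nn), K, N - K, nn))
    expect_equal(ti$p, tail, tolerance = 1e-10)
  }

  # pathways below min_hits are dropped
  gsc2 <- gene_set_collection(list(P1 = pw, P0 = paste0("g", 90:99)), "toy")
  tab2 <- enrich_fisher(fg, bg, gsc2, fdr_cut = 1, min_hits = 2)
  expect_equal(tab2$pathway, "P1")

  # identical hit sets deduplicated, keeping the larger odds ratio
  gsc3 <- gene_set_collection(list(Small = paste0("g", 1:3),
                                   Big = paste0("g", c(1:3, 60:89))), "toy")
  tab3 <- enrich_fisher(fg, bg, gsc3, fdr_cut = 1, min_hits = 2)
  expect_equal(tab3$pathway, "Small")   # same hits {g1,g2,g3}; smaller set, larger OR
})

test_that("co-enrichment Jaccard matches set arithmetic", {
  ta <- data.frame(pathway = c("P1", "P2", "P3"),
                   hits = c("A,B,C", "X,Y", "Q"))
  tb <- data.frame(pathway = c("P1", "P2", "P4"),
                   hits = c("B,C,D", "X,Y", "Z"))
  cj <- co_enrichment_jaccard(ta, tb)
  expect_equal(cj$n_shared, 2)
  expect_equal(cj$per_pathway$jaccard[cj$per_pathway$pathway == "P1"], 0.5)
  expect_equal(cj$per_pathway$jaccard[cj$per_pathway$pathway == "P2"], 1)
  expect_equal(cj$n_identical, 1)
  expect_equal(cj$n_disjoint, 0)
  # disjoint hit sets give 0
  tc <- data.frame(pathway = "P1", hits = "E,F")
  expect_equal(co_enrichment_jaccard(ta, tc)$per_pathway$jaccard, 0)
})
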