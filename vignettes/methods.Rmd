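---
title: "Cross-species single-cell comparison with a variational autoencoder: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species single-cell comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Translating immunological findings from cynomolgus monkey to human requires
knowing which parts of a transcriptomic response are conserved and which are
species-specific. `crossvae` implements a comparison framework for paired
two-species single-cell RNA-seq time courses (here: PBMCs at 0h/6h/24h after
T-cell activation, two replicates per species): ortholog-aware gene-space
harmonization, quality control, a variational autoencoder (VAE) whose latent
arithmetic performs *in-silico humanization*, perturbation-based feature
importance, cross-species differential-expression and pathway co-enrichment
statistics, and ligand-receptor (LR) conservation analysis. Because suitable
public two-species time courses are large and heterogeneous, the package
ships a synthetic data generator with planted ground truth; every downstream
claim in the test suite is scored against that truth.

# The VAE and latent shift arithmetic

The model is an MLP VAE in the scGen tradition. The encoder maps
log-normalized expression $x \in \mathbb{R}^G$ through two hidden layers to
the mean and log-variance of a diagonal Gaussian posterior
$q(z\mid x) = N(\mu(x), \sigma^2(x))$ over a $d$-dimensional latent space;
the decoder mirrors the encoder. Each hidden layer is linear →
batch-normalization → leaky ReLU (negative slope 0.01) → dropout. Training
minimizes

$$\mathcal{L} = \lVert x - \hat{x}\rVert^2 + \lambda_{KL}\,
  \mathrm{KL}\!\left(q(z\mid x)\,\Vert\, N(0, I)\right)$$

with Adam, reparameterized sampling, and early stopping on a validation
split. Defaults follow the study's operating point: $d = 10$, hidden
$800{\times}800$, batch size 8, up to 100 epochs with patience 25. Choices
the source description leaves open, and how we resolved them:

* **Dropout probability.** The architecture description contains an
  impossible dropout value; we use $p = 0.2$, the conventional scGen-family
  setting, exposed in `vae_config()`.
* **Loss weighting.** No KL weight is stated; the default
  $\lambda_{KL} = 5\times 10^{-5}$ keeps the model close to a deterministic
  autoencoder while regularizing the latent scale, and is configurable. No
  KL annealing is applied.
* **Optimizer.** Adam at learning rate $10^{-3}$ (configurable).
* **Linear-decoder mode.** `decoder_mode = "linear"` replaces the decoder
  with a single affine map ($dG + G$ parameters), the LDVAE-style variant,
  as a configuration switch rather than a separate model class.

The implementation is plain R matrix algebra with hand-derived
backpropagation; the test suite checks every gradient against central finite
differences, which is the strongest correctness oracle available for this
component.

**Shift vectors.** For a cell type, the species shift
$\delta_{species}$ is the difference between mean latent representations of
human and cyno cells at baseline; temporal shifts $\delta_{temporal}$ are
within-species differences between a later timepoint and baseline.
Humanization is `decode(encode(X) + delta)` with no retraining on the target
side. Generalization is evaluated on held-out cells under two splits: whole
replicates (tests transfer across individuals) and random 50% of cells
(tests sampling noise only). The evaluation metric is the Spearman
correlation of mean gene expression ranks against held-out human cells,
after dropping genes with zero mean in the human reference.

**Idempotence caveat.** `encode(decode(z))` is only approximately $z$: the
posterior noise and dropout act as stochastic regularizers that attenuate
the autoencoding map by roughly 10% per pass at the default settings. The
stability test therefore runs with dropout disabled on data whose intrinsic
rank matches the latent width; shift-inversion is asserted in expression
space relative to reconstruction error, which is the scale on which the
humanization claims live.

**Temporal-geometry estimation.** The cross-species cosine between
$\delta_{temporal}$ vectors is measured in latent coordinates, and a single
fitted model's latent geometry is not reliable enough for it at desk scale:
hidden units polarized by the dominant species axis pass the
minority-region variation only through the 0.01 leaky slope, which can
attenuate and rotate one species' temporal displacement even when the
gene-space displacements agree almost perfectly. We verified on generator
truth that the raw gene-space cosine estimator is clean while single-model
latent estimates scatter by ±0.2–0.3. `temporal_geometry_ensemble()`
therefore trains several models differing only in initialization (default
3, hidden width 128 in the analysis scripts) and averages their cosine
estimates; the per-model table is returned so the spread is visible.
The planted-versus-estimated relationship remains compressed toward zero —
the latent cosine is a biased but monotone readout of the gene-space
similarity.

# Feature importance

The importance heuristic perturbs one gene at a time toward a
species-specific mean, capped by the species-specific spread:
$x' = x + \mathrm{clip}(\mu_g - x,\ \pm\alpha\sigma_g)$ with $\alpha = 1$ by
default, and measures the displacement of the latent embedding. Two genuinely
open choices are resolved as follows and exposed as arguments:

* **Which species' statistics.** Passing the *target* species' statistics
  (for cyno cells, the human mean and sd) probes the humanization direction:
  genes that must move coherently for the population to resemble the other
  species displace the embedding most. Passing the cells' own statistics
  probes within-species denoising sensitivity instead.
* **Aggregation.** The default score is the norm of the *mean* displacement
  across cells ("centroid"). Incoherent, cell-specific denoising moves
  average out, so the score isolates coherent shifts; this is the reading
  under which planted species-effect genes are recovered (top-quartile
  median rank; positive rank correlation with planted effect size). The
  mean per-cell distance ("percell") is also available; it is dominated by
  the product of per-gene spread and encoder gain and does not separate
  species-effect genes from equally variable neutral genes — we verified
  this on generator truth before fixing the default.

Agreement between importance and DGE rankings is summarized per context by
Spearman correlation, and signs are aggregated with a two-sided exact
binomial test ($p = \min(1, 2\min(P(X\le k), P(X\ge k)))$, null 0.5); 11
positive out of 13 gives $p = 0.022$.

# Orthology regimes

Three regimes serve different analyses:

* **Duplicating harmonization** (VAE input): every ortholog pair contributes
  a column under the human name; a cyno gene with $k$ human orthologs
  appears $k$ times, a human gene with $k$ cyno orthologs is replicated
  $k$ times. Values are never altered. Symbols present in both species but
  absent from the table are kept once under the human name. Where a human
  gene is replicated against several cyno sources the column ids are
  disambiguated as `human|cyno`, keeping ids unique; duplicated columns are
  *not* re-deduplicated before HVG selection, so redundant signal is kept
  and left to the latent bottleneck to compress.
* **1:1 collapse** (unique-gene analyses such as DGE): for each target gene
  the source with the largest grand total of raw counts is kept (ties:
  lexicographically smallest source id). Grand total was chosen as the
  "highest expressed" statistic because it is scale-free across datasets.
* **Duplicate-then-sum** (CCC): each cyno gene contributes its counts to
  every mapped human name; names receiving several sources are summed. Mass
  is conserved for 1:1 genes and multiplied $k$-fold for 1:$k$ genes — a
  documented property of the mapping, asserted in tests.

# Quality control and annotation

Low-quality cells are flagged per sample (species × replicate) when
log1p(genes detected) or log1p(total counts) leaves median ± 3·MAD (unscaled
MAD), or when the mito fraction ("MT-" prefix) exceeds the per-species
threshold. The thresholds default to the study's printed asymmetric pair —
0.0015 (cyno) and 0.15 (human) — which differ by a factor of 100; we expose
both without resolving whether that asymmetry was intentional. Doublets are
scored by an internal simulated-doublet kNN scorer (sum random cell pairs,
embed jointly by PCA, score by the simulated-doublet fraction among 25
nearest neighbors, call at the (1 − expected rate) quantile) and combined by
a k-of-n vote (k = 2 when three call tables are supplied, pass-through for
one). Clustering is a kNN graph (k = 15) with Louvain community detection at
resolution 7 for QC and 4 for annotation; clusters with more than 25%
doublets or low-quality cells are removed wholesale, on the rationale that
neighborhoods of compromised cells are themselves suspect. Annotation
assigns each cluster its modal input label (ties: lexicographic), with a
"level 1.5" relabeling that keeps a fixed list of informative fine labels
and falls back to broad labels otherwise. Sex is inferred per replicate from
non-PAR Y-marker detection (male if >20% of cells have any Y count).

# DGE, enrichment and CCC statistics

The default DGE engine is the two-sided Wilcoxon rank-sum test on the
log-normalized layer with log2 fold changes of depth-normalized means
(pseudocount 1) and BH FDR; a per-gene NB-GLM with library-size offsets is
available for small gene sets. We deliberately did not re-implement
edgeR-style TMM/dispersion machinery: the cross-species comparison
statistics are the point, the engine is pluggable, and external DGE tables
can be imported through the same schema. Cells are the test units; p-values
are therefore anti-conservative for strongly replicate-structured real data,
a caveat that matters less on the generator whose replicate effects are
small intercepts.

The regulated fraction is $1 - \hat\pi_0$ with Storey's estimator
($\lambda$ grid 0.05–0.95, cubic smoothing spline, evaluated at
$\lambda = 0.95$). Cross-species overlap intersects FDR ≤ 20% sets; the
same-direction proportion is tested against 0.5 with `prop.test` (exact
binomial by flag). Foregrounds are the top 200 significant genes by |log2
FC| (ties: smaller p, then gene id). Enrichment is a one-sided Fisher exact
test per pathway with the tested genes as background, BH across pathways,
FDR ≤ 5%, ≥ 2 hits, and deduplication of identical hit sets keeping the
largest odds ratio (Haldane–Anscombe 0.5 correction when a margin is zero;
enrichment factor = log OR). Co-enrichment is the Jaccard index of hit sets
for pathways enriched in both species.

LR interactions are scored CellPhoneDB-style: magnitude = mean ligand
expression in the source type × mean receptor expression in the target
type; specificity = label-permutation p with add-one correction; both
converted to fractional ranks (ascending = stronger). Significance requires
both ranks ≤ 0.01 (0.001 for network views) — on the small synthetic tables
the analysis scripts use looser cuts, stated inline, because a 45-row table
cannot resolve a 1% rank. Conservation intersects significant sets keyed by
(source, target, ligand, receptor) and tests co-membership over the
all-scored background with a one-sided Fisher test; the shared percentage is
reported against the union by default and per species as alternatives, since
the figure convention is not printed. Network edge weights sum log10
magnitude ranks; "source" activity counts ligand-emitting roles, "target"
receptor-emitting roles.

# The synthetic generator: what it emulates, and what it does not

Counts are NB($\mu$, size) with
$\mu = \text{libsize} \cdot \exp(\text{base} + \text{celltype} +
\text{species} + \text{temporal} + \text{replicate})$, library sizes
log-normal around 2,000 counts. Defaults, chosen once as desk-scale
study conditions: 2,000 genes; three cell types × 170 cells per species ×
replicate × timepoint (≈ 3,000 cells/species, ~2,000 per cell type, matching
the scale at which the humanization evaluation is specified); two replicates;
NB size 2; ortholog coverage 0.813 — the coverage printed for the real data —
with 5% 1:2/2:1 relations; species effect N(0, 1) on 25% of genes; temporal
programs of 150 genes per cell type at RMS 1 log-unit (6h = 0.4 × 24h, so
24h responses dominate, as observed); replicate intercepts N(0, 0.1);
marker programs of 40 genes at +2 log-units; 5% doublets (summed same-sample
pairs) and 5% low-quality cells (counts shrunk ×U(0.05, 0.2), mito pushed
above threshold); cyno/human mito baselines 2×10⁻⁴ vs 0.03, consistent with
the asymmetric QC thresholds; cyno replicates male, human replicates one
male one female. Cross-species temporal cosines are exact by construction:
$v_h = u$, $v_c = t\,u + \sqrt{1-t^2}\,w$ with $w \perp u$ on the affected
set.

The generator does **not** emulate gene-gene correlation beyond the planted
programs, ambient RNA, batch effects beyond replicate intercepts, UMI
saturation, or multi-subunit ligand complexes. Passing tests therefore show
that the algorithms recover planted structure of realistic magnitude under
NB noise — not that they are robust to every artifact of real droplet data.

# Numerical choices and problem sizes

Determinism: a single seed drives structure, sampling, initialization,
shuffling, dropout and permutations; reruns are byte-identical. Tests and
the analysis scripts run the VAE at desk scale — hidden 64×64, batch 64,
30–40 epochs, 600–1,000 HVGs — which trains in seconds per model while
leaving the full-scale defaults untouched in `vae_config()`. The log-var
head is clamped to ±10; batch-norm uses ε = 10⁻⁵ and momentum 0.9; batches
of size 1 are skipped (batch-norm needs ≥ 2 rows). Zero-total cells
normalize to zero rows; zero-magnitude shift vectors report missing cosine;
degenerate (all-identical) p-value vectors warn and saturate. The Wilcoxon
p uses the normal approximation with tie and continuity corrections — exact
enumeration is pointless at n ≥ 100 cells and the approximation's null
uniformity is verified by KS on generator nulls.

# Known limitations

Single-gene LR pairs only; no compositional credibility model for
proportions (descriptive changes are reported); cells (not replicates) are
DGE units; the VAE runs on CPU and is sized for desk-scale inputs; the
1:1-collapse tie rule and the `human|cyno` id scheme are package conventions
that need not match any upstream tool byte-for-byte.
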