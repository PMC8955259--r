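---
title: "Methods: diversity, co-occurrence and community assembly in coral-habitat seawater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, co-occurrence and community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefwater)
```

# Scope and model

`reefwater` implements the statistical chain used to analyse seawater
bacterial and carbon-fixing (cbbL) bacterial communities sampled around a
small coral habitat: three stations along a coral-coverage and nutrient
gradient, each sampled in a surface and a bottom water layer with
replicate samples.  The pipeline takes an OTU abundance table, a rooted
phylogeny with branch lengths whose tips match the OTU ids, and a sample
metadata table; upstream read processing (quality filtering, OTU
clustering, taxonomy) is out of scope, as is building the phylogeny
itself — the tree is an explicit input precisely because nothing in the
downstream mathematics constrains how it was estimated.

The stages are:

1. **Alpha diversity** — richness, bias-corrected Chao1, Shannon
   entropy, Gini–Simpson.
2. **Beta diversity and ordination** — Bray–Curtis dissimilarity, NMDS,
   ANOSIM, Mantel and partial Mantel tests.
3. **Environment–community association** — Hellinger-transformed RDA
   (tb-RDA) with stepwise forward selection.
4. **Key-taxon selection** — Random-Forest importance ranking of OTUs
   discriminating stations, per water layer.
5. **Co-occurrence networks** — an ensemble association network between
   the key OTUs and carbon-fixer clusters with a
   compositionality-corrected permutation null.
6. **Community assembly** — abundance-weighted βMNTD, a tip-shuffle
   null model, βNTI, and deterministic/stochastic classification.

A synthetic-data module generates all of these inputs with known ground
truth, so every stage is testable without any download.

# Community assembly: βMNTD, the tip-shuffle null, and βNTI

For two communities $i$ and $j$ on a shared phylogeny, the
abundance-weighted β mean nearest taxon distance is

$$\beta\mathrm{MNTD}(i,j) = \tfrac12\Big[
  \sum_{k \in i} f_{ik}\, \min_{l \in j} d(k,l)
+ \sum_{l \in j} f_{jl}\, \min_{k \in i} d(k,l) \Big],$$

where $d$ is the patristic distance between tips and $f$ are relative
abundances within each community (equal weights $1/S$ with
`weighted = FALSE`).  The null model shuffles the taxon↔tip assignment
uniformly over **all** tips of the tree — not only the tips present in
the pair — and recomputes βMNTD; with `n_null` such draws (default
999),

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} -
  \overline{\beta\mathrm{MNTD}}_{null}}{\mathrm{sd}(\beta\mathrm{MNTD}_{null})}.$$

Standardisation by the null standard deviation is the single most
important interpretation decision in the package: the conventional
$|\beta\mathrm{NTI}| > 2$ threshold for deterministic (selection-driven)
assembly is only meaningful on the standardised scale, so the package
always divides by the null sd.  $|\beta\mathrm{NTI}|$ exactly 2 is
classified stochastic (the deterministic rule is the strict
inequality).  Pairs whose null distribution collapses (e.g. a star
phylogeny, where every tip-to-tip distance is equal and no shuffle can
change βMNTD) get an `NA` βNTI with a warning and are excluded from
group fractions rather than silently scored.

βMNTD is scale-covariant: multiplying all branch lengths by a constant
multiplies the observed value and every null draw by the same constant
and leaves βNTI unchanged, so the time units of the tree are
irrelevant.  The implementation is cross-checked in the test suite
against `picante::comdistnt` (exact agreement) and against full
enumeration of all tip permutations on small trees (the sampled null's
βNTI agrees with the exhaustive one within 0.15 at 9,999 draws).
Per-pair nulls are drawn independently, and every pair's classification
is deterministic given the seed.

Group summaries count within-group sample pairs: a group of $n$
samples contributes $n(n-1)/2$ pairs, so with 6 replicates the reported
fractions are multiples of $1/15$; percentages are rounded to one
decimal to match that granularity.

# The synthetic community generator

The generator emulates the study design: a Yule (pure-birth) phylogeny
of `n_tips` OTUs; a niche-optimum trait evolved along it by Brownian
motion with rate `trait_sigma2`; a lognormal metacommunity (shape
parameter `metacommunity_shape`, default 1 — the right-skewed abundance
distribution typical of 16S surveys); and per-sample multinomial
sequencing draws of `sequencing_depth` reads with per-OTU probability

$$p_k \propto m_k \cdot
  \Big[\exp\big(-(o_k - e)^2 / 2\sigma_b^2\big)\Big]^{\lambda},$$

with metacommunity abundance $m_k$, optimum $o_k$, local environment
$e$, niche breadth $\sigma_b$ and filtering strength $\lambda$.
$\lambda = 0$ is exactly neutral (the environment has no effect);
increasing $\lambda$ monotonically increases between-station
Bray–Curtis turnover.  A Brownian trait under Gaussian filtering is the
*minimal* structure that makes the tip-shuffle null informative: the
null only detects selection when phylogeny predicts niche, so a
phylogenetically random trait would make the whole inference vacuous.

Default design values mirror the field design: 3 stations × 2 layers ×
6 replicates, an evenly spaced station gradient `env_values = (-2, 0,
2)` on the scale of the trait standard deviation, a coral-coverage
covariate of 20 %, 5 % and 0 % across stations, a bottom-layer
environmental offset of 0.5, and nuisance metadata columns (ammonium,
nitrate, phosphate, silicate, Chla, DOC, DIC, salinity, pH) that are
pure noise — they exist so that forward selection has something to
reject.  A random 10 % of tips is labelled "carbon fixer" and grouped
into clade-based clusters (average-linkage cut of their patristic
distances, default 4 clusters), emulating cbbL clusters defined on a
separate marker phylogeny; the cbbL community is then sampled on those
tips under the same niche model.

Two calibration regimes anchor the simulator:

* **Strong selection**: `filtering_strength = 5` with the default
  gradient.  Between the two *extreme* stations (the contrasting ends
  of the gradient) the deterministic fraction
  $\Pr(|\beta\mathrm{NTI}| > 2)$ is ≥ 0.8 — in practice ≈ 1 — across
  simulator seeds.  Pairs involving the middle station sit between the
  regimes, which is the expected behaviour of a gradient, so the
  calibration is defined on the contrast.  Filtering much stronger than
  this actually *weakens* the phylogenetic signal: communities collapse
  onto a handful of extreme-trait tips whose placement is
  idiosyncratic.
* **Neutrality**: `filtering_strength = 0`.  Within one simulated
  dataset all samples are draws from the same metacommunity, so
  pairwise βNTI values are strongly correlated — the whole dataset
  behaves like a single draw from the null.  The neutral
  false-detection rate is therefore estimated by pooling pairs across
  several independent assemblies (different tree, trait and
  metacommunity realisations), where it sits near the nominal two-sided
  exceedance of ≈ 0.046 and below 0.10.

What the generator does **not** emulate: sequence-level artefacts (PCR
bias, chimeras), taxonomic structure, temporal autocorrelation, and any
dependence between the 16S and cbbL markers beyond the shared niche
model.  Passing tests on synthetic data therefore demonstrate the
statistical machinery, not robustness to upstream artefacts in real
amplicon data.

# Ordination and matrix-association statistics

Standard steps ride on `vegan`: `monoMDS` (Kruskal stress-1, primary
tie treatment) for NMDS, run from the metric-scaling start plus
`n_restarts - 1` random starts with the best solution returned and a
`converged` flag rather than an error on non-convergence; `anosim`,
`mantel` and `mantel.partial` for the permutation tests (all p-values
carry the +1 correction and can never be exactly zero; 999 permutations
by default, matching the null-model count used for βNTI); `decostand`
for the Hellinger transform; and `rda` for constrained ordination.
Constraint variables are z-scored internally, so results are invariant
to variable rescaling; collinear constraints (condition number of the
scaled design above $10^{10}$) are an error naming the offending pair.
A constant *comparison* matrix makes a Mantel correlation undefined and
is an error; a constant *control* matrix degenerates the partial Mantel
test to the plain one, which is returned with a warning.

The RDA report includes both raw and adjusted $R^2$ and per-axis
proportions both of total community variance and of the constrained
variance, since conventions differ between publications.

**Forward selection** follows the double stopping criterion: a
permutation test of the *full* model gates the entire selection
(nothing is selected when the data carry no signal); then, at each
step, the candidate with the largest adjusted-$R^2$ gain is admitted
only if its marginal permutation test (conditioning on the variables
already selected) gives $p \le \alpha$, and selection stops once the
current model's adjusted $R^2$ reaches that of the full model.  A model
that leaves no residual variance is scored at the permutation floor
$1/(n_{perm}+1)$, since no permutation can beat it.  Under planted
two-variable signal this recovers exactly the true pair in > 90 % of
simulations; under pure noise it returns an empty selection in ≈ 95 %.

# Key taxa and the co-occurrence network

Key OTUs are ranked by Random-Forest importance (mean decrease in Gini
impurity by default; permutation importance available, being less
biased toward high-variance features) for the station labels, fitted on
relative abundances, separately per water layer.  Ties are broken
lexicographically by OTU id so rankings are reproducible; the top 30 by
rank form the heterotroph node set of the network.

The network is a documented, simplified ensemble in the CoNet family —
the original tool's exact defaults are not recoverable from its
published description, so this package fixes its own definition with
every threshold in configuration: three association measures (Pearson, Spearman,
Bray–Curtis similarity) are computed for every key-OTU×key-OTU and
key-OTU×cluster pair (cluster×cluster pairs are not tested); each
measure is scored against a renormalised-permutation null in which the
two features' values are permuted independently across samples and
every sample total is renormalised over the feature set before the
measure is recomputed — the "ReBoot" style compositionality
correction, implemented in C++ since the pipeline evaluates millions of
permuted measures.  Edge signs come from the sign of the observed score
minus the null mean (for Bray–Curtis the null mean is the natural
centre; for the correlations it is ≈ 0).  Per-measure two-sided
p-values are merged with Brown's method, with the covariance of the
$-2\log p$ terms estimated from the per-draw empirical p-values of the
null scores and a Fisher fallback when that estimate degenerates; BH
correction runs across all tested pairs, and an edge requires at least
`min_support = 2` sign-agreeing measures and merged $q \le$ `fdr`.

Per-measure p-values are **empirical** by default,
$p = (1 + \#\{|null - c| \ge |obs - c|\})/(n_{iter}+1)$: with
heavy-tailed abundance data the permutation null of a correlation is
far from Gaussian in its tails, and a parametric tail fit
(`p_method = "gaussian"`, offered as an option on the Fisher-z scale)
proved anti-conservative by an order of magnitude in exactly the tail
region that matters under multiple testing.  The price of the
calibrated empirical p is resolution: its floor is $1/(n_{iter}+1)$, so
`n_iter` must grow with the number of tested pairs — around 5,000
iterations for ~1,500 pairs at FDR 0.05.  At those settings a planted
correlated block among noise features is recovered with precision and
recall above 0.8, and pure-noise tables yield far fewer than 5 % false
edges.

# Numerical and design choices

* **Chao1** uses the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined for all inputs including
  $F_2 = 0$.  **Shannon** uses the natural logarithm; **Simpson** is
  reported as Gini–Simpson $1-\sum p_i^2$ (the usual "Simpson index"
  of vegan-style workflows) — both conventions are stated prominently
  because neither is universal.
* No rarefaction anywhere; depth normalisation exists only as the
  explicit `to_relative()` conversion.
* OTU tables are stored rows = OTUs, columns = samples (the amplicon
  convention); every function that needs the transpose does it
  internally and documents the orientation.  TSV is the canonical
  format (desk-scale data, diffable tests); floats are written with 12
  significant digits so write∘read is an identity for all practical
  purposes.
* Permutation counts: 999 for ANOSIM/Mantel/βNTI nulls, 199 for
  forward-selection marginal tests, 1,000 for network nulls — each
  overridable in the pipeline configuration.
* Every stage seed is derived deterministically from one global seed
  and the stage name, so adding a stage never perturbs another stage's
  random stream, and the full synthetic pipeline is bit-reproducible.
* The Random-Forest target is the station label *within* a layer; the
  alternative (station × layer jointly) is a judgement call, and the
  per-layer choice matches how the key-taxon figures are organised in
  this literature.
* Problem sizes used by the test suite and the acceptance script —
  100-tip trees, 36 samples, 999-draw nulls, 50-pair βNTI panels,
  20-simulation network recovery — were chosen so the whole suite runs
  on a laptop-class single core in minutes while keeping every
  statistical check well-powered.

# Known limitations

* βNTI inference stops at the deterministic/stochastic dichotomy; the
  further partition of the stochastic fraction (dispersal limitation
  versus homogenising dispersal via RCbray) is out of scope.
* The ensemble network deliberately omits mutual-information and
  KLD-type measures and any topology statistics beyond counts and
  degrees.
* The pipeline treats the phylogeny as known; uncertainty in the tree
  propagates into βNTI unexamined.
* Within one synthetic dataset, βNTI values of different pairs share
  the tree and metacommunity realisation and are therefore correlated;
  rate-style summaries should be read per dataset, or pooled across
  independent seeds as the neutral calibration does.

# Interfaces

All functionality is exposed as documented R functions; the pipeline is
their composition, driven by one YAML configuration
(`validate_config()` / `run_pipeline()`), with a commented template in
`inst/extdata/pipeline-config.yaml` and a thin command-line wrapper in
`inst/scripts/reefwater-pipeline.R`.  Stage outputs are plain TSV files
plus a JSON manifest with per-file MD5 checksums; identical
configurations reproduce identical checksums.
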