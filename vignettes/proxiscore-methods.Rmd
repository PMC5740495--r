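---
title: "Scoring proximity-labeling screens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring proximity-labeling screens: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiscore)
```

`proxiscore` scores BioID proximity-labeling screens of bait panels —
prototypically nuclear transport receptors (NTRs) fused to the BirA\*
biotin ligase — from label-free protein-group intensities. This vignette
is the package's own account of the statistics it implements: what each
stage assumes, which parameters matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open.

## Study design

The canonical screen measures each fusion cell line and each control line
in biological quadruplicate and technical duplicate. With 28 fusion
samples (N- and C-terminal fusions of a bait panel) and 4 control lines
this gives `32 * 4 * 2 = 256` MS runs, and `4 * 4 = 16` pooled control
experiments. `simulate_design()` reproduces exactly this geometry;
`read_design()` ingests a real one. Technical replicates are kept as
separate runs by the readers and merged (mean of observed log2 values)
by `merge_technical()`, so merging is an explicit, lossless preprocessing
step rather than an I/O side effect.

## Missing values: classification before imputation

Label-free proteomics data are missing for two different reasons, and the
pipeline treats them differently *per pairwise comparison*:

* **MNAR** (missing not at random): the protein fell below the detection
  limit in one condition. Operationally — with 4-replicate groups — one
  group has at most one observed value while the other has at least
  three. These cells are imputed deterministically with **MinDet**: the
  minimum observed value of the run (column). The defensible but
  aggressive assumption is that absence reflects genuinely low abundance.
* **MAR** (missing at random): sporadic peptide-sampling dropouts; both
  groups are at most one value short. These cells are imputed with
  **kNN**: the mean of the same-run values of the 10 nearest protein
  profiles, with root-mean-square distance over mutually observed runs so
  profiles sharing few runs are not favoured, and the requirement that a
  neighbour be observed in the target run.
* Everything else (e.g. 2-of-4 in both groups) is **excluded** from that
  comparison — there is not enough information for a robust test. A
  protein excluded from one comparison can still be tested in another.

For group sizes other than 4 (the pooled control set has 16 experiments)
the thresholds scale proportionally: "mostly missing" is
`floor(n/4)` observed, "nearly complete" is `ceiling(3n/4)`, which
reproduces the 4-replicate rules exactly. Classification is a pure
function of the two observed counts and is symmetric in the groups.

One reading note: we classify a protein observed 4-of-4 vs 3-of-4 as MAR
(the single missing value is imputed). The alternative — requiring
exactly one missing value in *each* group and excluding such proteins —
would discard nearly complete data for no statistical gain.

After imputation the completed two-group submatrix is **quantile
normalized** (ties receive the mean of their rank range). Normalization
is per comparison, consistent with the per-comparison imputation
footprint; a global mode would mix runs that never meet in a test.

## Moderated one-sided tests

Per protein, `fit_groups()` returns the log2 fold change (difference of
group means) and the pooled within-group variance `s2` on
`d = nA + nB - 2` df. `estimate_prior()` fits a scaled inverse chi-square
prior for the true variances by the method of moments on log variances:
with `e_g = ln s2_g - digamma(d/2) + ln(d/2)`, the prior df `d0` solves

```
trigamma(d0/2) = mean((e - mean(e))^2 * n/(n-1)) - trigamma(d/2)
```

by bisection of the strictly decreasing trigamma on half-df in
`(1e-3, 1e3)` (tolerance 1e-10), and
`s0^2 = exp(mean(e) + digamma(d0/2) - ln(d0/2))`. When the dispersion of
the log variances is no larger than chi-square sampling noise (target
below `eps = 1e-8`) the prior is degenerate: `d0 = Inf` and every protein
uses `s0^2`. The moderated statistic divides the fold change by the
posterior-shrunk standard error and is referred to a t distribution on
`d0 + d` df (normal for infinite `d0`); `d0 = 0` recovers the classical
pooled t-test exactly, which the tests verify against `t.test()`. The
hyperparameter fit is cross-checked against an independent
implementation of the same moment equations in the test suite.

Hyperparameters are fitted per comparison: comparisons differ in their
imputation footprint, and a global fit would let heavily imputed
comparisons contaminate clean ones. All proteins within a comparison
share the residual df because the preprocessing guarantees complete
cases.

## Calling the interacting proteome

Each fusion sample is compared one-sidedly against the pooled control
columns, in both directions. Per protein and direction the available
p-values (a protein excluded from a comparison simply contributes
nothing) are combined with the **Simes** statistic,
`min_i m p_(i) / i`, then BH-adjusted across proteins within the
direction; labels are assigned at adjusted p < 0.1. The Simes statistic
is small when the protein is truly enriched in at least one comparison,
which is the intended semantics of "interacts with the panel at all".

A caution that the test suite makes precise: the global Simes p-value is
a *lower bound* for the minimum closed-testing-adjusted elementary
p-value (brute-force enumeration over all intersection hypotheses), with
equality whenever a single comparison carries dominant evidence — the
regime in which calls are actually made — but not universally. The
pipeline uses the global Simes statistic, accepting this mild liberality
for proteins with diffuse evidence.

## Specificity scores

All fusion samples are compared against each other (both directions per
unordered pair, so `S(S-1)` directed comparisons). For sample *s* and
protein *g*, the comparisons in which *g* is significantly *s*-enriched
contribute their p-value and fold change; then

* `score = -log10( prod p_i )` — the multiplicative specificity score;
* `avg_fc` — the arithmetic mean of the matching log2 fold changes;
* `X2 = -2 sum ln p_i ~ chi2(2k)` — Fisher's combination, whose upper
  tail gives a per-(protein, sample) p-value, BH-adjusted over the full
  protein-by-sample table and flagged at adjusted p < 0.01.

A protein enriched in every sample collects no significant pairwise
evidence anywhere (all its between-bait fold changes are ~0), so its
score is 0 in every sample: promiscuous interactors such as nucleoporins
are penalized by construction, while bait self-biotinylation surfaces as
a highly specific self-hit.

**What counts as "significant" in the selection?** By default a pairwise
p-value enters the score when its BH-adjusted value *within that
directed comparison* is below 0.01 (`adjust_within = TRUE`), and the
adjusted value is what is multiplied. Selecting on raw p-values is
available but anticonservative in a way that matters: a chance
biological-replicate offset of one cell line recurs in *every* pairwise
comparison of that sample, and Fisher's method — which assumes
independent inputs — compounds this correlated evidence. In reference
simulations this inflates the pair-level false-discovery proportion from
well under 0.1 (adjusted selection) to ~0.15 (raw selection) at equal
sensitivity. Fisher's combination of *selected* p-values remains
anticonservative by design in either mode; the final BH pass operates on
these selected combinations, which is inherited from the method being
modelled and documented rather than repaired.

## Network smoothing with topology-bias correction

Specificity scores are mapped onto a weighted undirected interaction
network (STRING-style combined scores; scores on the 0–1000 scale are
divided by 1000, and edges with normalized weight strictly above 0.7 are
kept). The adjacency matrix is symmetrically normalized,
`W~ = D^(-1/2) W D^(-1/2)` (zero rows for isolated nodes), and scores
are propagated by

```
F <- alpha * W~ %*% F + (1 - alpha) * F0,    alpha = 0.5, 30 iterations
```

starting from `F0`. Because the spectral radius of `W~` is at most 1,
the iteration converges geometrically to
`(1 - alpha) (I - alpha W~)^(-1) F0`; at `alpha = 0.5` the 30-iteration
error is below `0.5^31 * ||F0||`, and the tests verify agreement with a
direct linear solve to 1e-6 on graphs of up to 200 nodes.

Raw propagation systematically favours well-connected nodes. The
**topology bias** of each node is measured by propagating a constant
vector equal to the mean initial score; the result is subtracted. With
constant initial scores the corrected scores are identically zero (an
exact identity the tests assert), and on a hub-and-leaves graph the
correction removes the hub's excess.

Per sample, the top `floor(0.02 * n)` corrected-score nodes are
extracted (ties broken by ascending node id, so 15,478 nodes yield
exactly 309), the induced subgraph is decomposed into connected
components (largest first, with densities) — a deliberately simple stand
-in for heavier clustering apps — and planted complexes surface as
single components.

Isolated nodes keep `(1 - alpha) * F0` and are corrected by their own
bias only; proteins absent from the network simply carry no smoothed
score. The mapping from protein ids to network node ids is user-supplied
(`mapping` argument) because identifier namespaces differ between
quantification and network resources.

## Biotinylation sites

Site-level analysis mirrors the protein level with lighter filtering: a
site is kept when observed in at least 2 of 4 biological replicates of
some cell line. Intensities are then location-normalized per run (median
subtraction on the log2 scale — the minimal normalization that respects
the heavy-tailed site distributions; a quantile mode is available via the
protein-level tools) and median-centred per site, making the output
exactly invariant to per-run additive shifts. Sites are keyed by residue
position — peptides sharing a modified residue are summed at read time —
and mapped inclusively onto 1-based domain annotations, with overlapping
domains all reported and unannotated positions labelled
`linker/disordered`. `site_count_vs_abundance()` pairs per-line site
counts with protein abundance and reports per-protein Spearman
correlations (undefined below 3 paired lines or at zero variance),
reflecting that more abundant proteins yield more detectable sites.
Replicate means are used for display-level summaries; the centering
itself operates on runs.

## The synthetic generator

`sim_config()` bundles the generative model:

| parameter | default | meaning |
|---|---|---|
| `n_ntrs`, `n_controls` | 28, 4 | fusion samples (paired N/C termini) and control lines |
| `n_bio`, `n_tech` | 4, 2 | biological x technical replicates |
| `mu`, `tau` | 25, 2 | mean and SD of per-protein baseline log2 abundance |
| `sigma_b`, `sigma_t` | 0.5, 0.2 | biological / technical noise SD (log2) |
| `delta`, `delta_ctrl` | 2, 2 | planted cargo / background enrichment (log2) |
| `cargo_fraction`, `control_fraction` | 0.30, 0.15 | planted fractions, matching a screen where roughly a third of identified proteins are bait-enriched and a sixth control-enriched |
| `mnar_mid`, `mnar_steep` | 20, 1.5 | logistic intensity-dependent dropout |
| `mar_rate` | 0.02 | random dropout |
| `p_in`, `p_out` | 0.8, 0.002 | planted-partition network edge probabilities |

The value of protein *g* in run *r* is
`a_g + delta * [g is cargo of bait(r)] + delta_ctrl * [g background and r
control] + b_(g, line, bio) + t_(g, r)`; technical-replicate correlation
arises solely through the shared biological term. Dropout acts on the
log2 scale after noise: missing with probability
`plogis(-mnar_steep * (x - mnar_mid))` plus an independent
`Bernoulli(mar_rate)`. The logistic MNAR form is this package's choice of
generative model for the MNAR/MAR taxonomy. The dropout location and
steepness were calibrated once, together, so that overall missingness is
a realistic ~4–5% *and* the partial-dropout band is narrow: a wide band
puts many proteins into a "missingness lottery" where chance-asymmetric
dropout is classified MNAR, MinDet-imputed, and read as spurious
specificity — an artifact level at which no scoring method meeting the
package's recovery targets could operate. Real screens differ from this
generator in ways the tests therefore cannot probe: correlated
contaminant structure, intensity-dependent variance, batch effects
beyond quantile differences, and peptide-level identification artifacts.

Reference problem sizes used throughout the tests and the acceptance
script: 1,000 proteins, 6 baits as 12 N/C fusion samples plus 2 control
lines, 4 x 2 replicates for recovery; one 10,000-protein two-group
comparison for null calibration; 5,000 variances for prior recovery.
These sizes give stable Monte-Carlo behaviour while the whole suite runs
in well under a minute.

## Degenerate inputs and numerical conventions

* Intensity zeros and empty cells both mean "missing"; no distinction is
  preserved.
* A run with no observed values cannot be MinDet-imputed and raises an
  error naming the run; kNN with no eligible neighbour falls back to the
  row mean with a warning.
* p-values are clamped into `(0, 1]` before log-product combinations.
* `estimate_prior()` drops non-positive variances (warning) and warns
  below 50 usable values.
* Self-loops in networks are dropped with a warning; duplicate
  undirected edges keep their maximum weight; negative weights are
  errors. Score scales are auto-detected: any weight above 1 implies the
  0–1000 convention.
* Top-fraction selection uses `floor` and breaks ties by ascending node
  identifier, so results are deterministic.
* All simulation randomness flows from one master seed through named
  per-stage substreams; `run_pipeline()` with a fixed seed reproduces
  byte-identical outputs, recorded with md5 checksums in its manifest.

## Limitations

The pipeline models exactly two-group contrasts (no multi-factor
designs); Fisher's combination over selected, correlated pairwise
p-values is anticonservative by construction and is controlled
empirically rather than analytically; MinDet imputation concentrates
mass at column minima, which makes extremely low-abundance proteins'
calls sensitive to the detection-limit model; and the interacting-
proteome label rests on the global Simes statistic, which is mildly
liberal for proteins with diffuse multi-comparison evidence. These are
properties of the method family being implemented; the vignette and
tests quantify rather than hide them.
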