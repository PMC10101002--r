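---
title: "Co-occurrence networks, keystone taxa, and community assembly: models and design choices"
author: "fermnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks, keystone taxa, and community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermnet)
```

# The scientific problem

Solid-state fermentations such as strong-flavor Baijiu are driven by mixed
bacterial and fungal communities whose composition shifts over a month-long
cycle. Two kinds of taxa matter for the product: *dominant* taxa, which shape
metabolite pools through sheer relative abundance, and *keystone* taxa, which
occupy topologically critical positions in the community's co-occurrence
network and whose diversity — not abundance — tracks flavor outcomes. A
second, orthogonal question is what *assembles* these communities: neutral
processes (drift plus immigration) or deterministic selection by the
fermentation environment.

`fermnet` implements this full analysis chain on paired bacterial (16S) and
fungal (ITS) abundance tables with sample metadata and metabolite panels, and
ships a synthetic-data generator with planted ground truth so that every
stage can be validated end to end without access to any particular study's
raw reads.

# Models and procedures

## Co-occurrence networks

Taxa are first screened: a taxon is kept when detected in strictly more than
20% of samples *and* its mean relative abundance strictly exceeds 0.01%
(`filter_taxa()`, both thresholds strict because the conventions are stated
as strict inequalities). Bacterial and fungal relative abundances are
normalized *per domain* — each domain's block sums to 1 within a sample —
because the two amplicon libraries are sequenced and scaled separately;
`merge_domains(normalize = "global")` gives the joint renormalization for
sensitivity analyses. Spearman correlations are computed for all remaining
taxon pairs; p-values use the t approximation for n >= 10 samples and the
exact permutation distribution below that (ties handled by average ranks).
After Benjamini-Hochberg adjustment over all pairs, an edge is kept iff
|rho| >= 0.8 and adjusted p <= 0.01.

Modules ("ecological clusters") are detected on the unweighted, sign-agnostic
skeleton by three algorithms — greedy modularity agglomeration, Louvain, and
label propagation — and the partition with the highest Newman-Girvan
modularity wins, ties resolved in that fixed order. Community detection runs
unweighted because edge signs color interpretation, not connectivity; a
|rho|-weighted mode is available (`detect_modules(weighted = TRUE)`). Module
IDs are relabeled 0, 1, 2, ... by decreasing size, so "module 0" is always
the largest cluster.

## Keystone classification (Zi/Pi)

For each node, `zi_pi()` computes the within-module degree z-score
$Z_i = (k_{i,\mathrm{within}} - \bar k) / \sigma_k$ (mean and *population*
standard deviation over the node's module — the population form keeps
singleton and zero-variance modules classifiable by defining $Z_i = 0$
there) and the participation coefficient
$P_i = 1 - \sum_s (k_{is}/k_i)^2$. Roles use the standard grid with
inclusive thresholds: network hubs ($Z_i \ge 2.5$, $P_i \ge 0.62$), module
hubs ($Z_i \ge 2.5$ only), connectors ($P_i \ge 0.62$ only), peripherals
otherwise; keystone taxa are the union of the first three. A geometric
consequence worth keeping in mind: a node whose links touch only two modules
has $P_i \le 0.5$, so connectors are by necessity nodes linking at least
three modules.

## Robustness

Network stability is quantified by simulated extinction (`robustness()`):
for each removal fraction f (default grid 0.005 to 1 in steps of 0.005, 200
replicates), `round(f N)` nodes are removed uniformly at random (round half
up), then nodes left with no surviving edge die iteratively to a fixed point
(secondary extinction). Nodes isolated in the *original* network are exempt
by default — they had no links to lose — with a flag to include them. The
curve reports the mean and sd of the surviving proportion. A degree-ordered
"targeted attack" mode exists; no dynamics beyond isolation are modeled.

## Module diversity and metabolites

`module_profiles()` computes, per module and sample, the Shannon index over
module members with abundances renormalized *within* the module. The
renormalization is deliberate: Shannon on the raw sub-vector would conflate
the module's total abundance with its internal evenness. Metabolite
concentrations are regressed on these per-sample profiles by ordinary least
squares (`diversity_metabolite_regression()`), with BH adjustment across all
(module, metabolite) pairs; when the three classic higher-alcohol components
(isoamyl alcohol, phenethyl alcohol, isobutanol) are present their sum is
added as a derived response. Regressions pool all samples by default; group
subsets can be passed explicitly.

## Sloan neutral model

`fit_neutral_model()` fits the neutral expectation that a taxon with
metacommunity relative abundance $p$ is detected in a local community of
size $N$ (mean reads per sample, rounded; detection limit $d = 1/N$) with
frequency $f(p) = 1 - \mathrm{Beta}(d;\, Nmp,\, Nm(1-p))$, with immigration
rate $m$ estimated by least squares on the frequency scale (a
binomial-likelihood option is provided). The 95% band bootstraps taxa with
replacement, refits $m$, and draws each replicate's occurrence frequency
from the binomial sampling distribution at the observed number of samples
$S$. That last step matters: the percentile band of the refitted *curves*
alone reflects only parameter uncertainty and is far too narrow to call any
taxon "neutral" — the meaningful question is whether an observed frequency
is consistent with binomial sampling around the neutral curve. Taxa above
the band are classified `above`, below it `below`, inside it `neutral`, and
counts plus cumulative relative abundance per class are reported.

`simulate_neutral()` inverts the model — local compositions drawn
$\mathrm{Dirichlet}(Nm\,p)$, counts multinomial at depth $N$ — and the
simulate/fit round trip is part of the test suite (median fitted $m$ within
[0.07, 0.13] of a true 0.1 at $N = 10^4$, 500 taxa, 24 samples; the small
upward bias is the cost of the threshold approximation to multinomial
detection). The beta-CDF self-consistency of simulated occurrence
frequencies is asserted at the generator's default depth (40,000 reads, 48
samples), where the mean absolute deviation is ~0.03; at 24 samples the
irreducible binomial noise alone approaches 0.05.

## Normalized stochasticity ratio

`nst()` compares observed within-group pairwise dissimilarities $D_{ij}$
(quantitative Jaccard/Ruzicka by default, Bray-Curtis optional) with their
expectation $E_{ij}$ under a null model of stochastic assembly. The per-pair
stochasticity ratio is
$SS_{ij} = (1-E_{ij})/(1-D_{ij})$ if $D_{ij} < E_{ij}$,
$E_{ij}/D_{ij}$ if $D_{ij} > E_{ij}$, and 1 at equality; `ST` is the pair
average.

Two design decisions here were genuinely open:

* **The null model.** The proportional-proportional family (occupancy by
  occurrence frequency, abundance by mean relative abundance, per-sample
  richness and depth fixed) is parameterized so that the *observed marginals
  are fixed points of the randomization*: occupied sets are drawn with
  inclusion probabilities exactly proportional to occurrence frequency
  (capped at 1; randomized systematic PPS sampling), and the remaining reads
  are allocated with weights equal to the mean relative abundance
  *conditional on presence* ($p/f$). The naive alternatives — weighted
  sampling without replacement, unconditional abundance weights — distort
  the occupancy and abundance marginals at each re-estimation, so that even
  data generated by the null scores well below 100%.
* **The normalization.** Published NST variants differ in their scaling
  constant. The default here calibrates per pair against the null's own
  spread: $NST_{ij} = (SS_{ij} - SS^{\min}_{ij}) / (\overline{SS}^{null}_{ij}
  - SS^{\min}_{ij})$, where $SS^{\min}_{ij}$ is the all-deterministic extreme
  ($1-E_{ij}$ or $E_{ij}$ by direction) and $\overline{SS}^{null}_{ij}$
  averages the same ratio over the null draws themselves. Clamped to [0, 1]
  and averaged, this reads 100% for null-generated data and 0 at the
  deterministic extremes; `variant = "simple"` gives the uncalibrated form.

The 50% line separates predominantly deterministic (<50%) from predominantly
stochastic (>50%) assembly. NST values are null-model dependent by
construction; the variant and null parameters are always recorded in the
result.

## PERMANOVA, Mantel, enrichment

PERMANOVA is computed from the Gower-centered inner-product matrix
($G = -\tfrac12 J D^2 J$) with sequential (Type I) term decomposition in
formula order (marginal via `by = "margin"`), unrestricted permutations, and
the add-one convention $p = (1+b)/(1+n_{perm})$; per-term $R^2$ plus the
residual sum to 1 exactly. The in-package implementation exists because the
test suite demands seeded permutation streams and exact agreement with
exhaustive enumeration on small instances; it is cross-checked against
`vegan::adonis2` in the tests. The Mantel test correlates lower triangles
with one-sided permutation p-values (the community-ecology convention).
Per-taxon enrichment between two groups uses a two-sided Wilcoxon rank-sum
test on relative abundances (robust on compositional data; Welch t option),
BH adjustment, log2 fold changes with a pseudo-count of half the smallest
nonzero relative abundance, and a strict >0.1% mean-RA dominance flag. The
per-taxon test is a deliberate choice — the upstream convention names only
"volcano plot analysis" — and its type-I calibration is asserted in the
acceptance tests.

## Indicator metabolites

`indicator_select()` fits a random forest on metabolite profiles, ranks
features by permutation importance (mean decrease in accuracy), and builds
an `rfcv`-style curve: on a halving grid of feature counts, features are
re-ranked *within each training fold* (avoiding selection bias) and the
held-out error recorded over stratified 10-fold CV, repeated 5 times. The
curve "stabilizes" at the smallest k whose mean error is within one standard
error of the global minimum. Two statistical points drove the details: with
~7-sample folds a raw fold-SD has granularity 1/7 and would admit k = 1
almost always, so the SE uses the fold count as effective sample size; and
repeated CV is required to keep the curve smooth enough for the rule to be
stable. Both OOB and CV error are reported, since "accuracy" in this
literature can mean either.

# The synthetic-data generator

`generate_dataset()` produces the study design the package assumes: 2
workshops x 6 time points (days 0, 2, 5, 10, 15, 30) x 4 replicates = 48
samples; 400 bacterial and 200 fungal taxa at mean depths 40,000 and 43,000
reads (the order of magnitude of typical amplicon surveys of this system).
It plants, with stored ground truth:

* a lognormal metacommunity (sdlog = 2, matching the wide abundance range
  these communities show) sampled under Sloan dynamics with m = 0.1;
* 20 selected taxa whose log-abundance follows the workshop-specific
  temperature trajectory;
* five correlation blocks (sizes 14-10; three bacterial, two fungal) driven
  by per-module lognormal latent factors (factor sd 1.0, taxon noise sd 0.2,
  multiplicative on abundances *before* multinomial sampling so
  compositional noise stays realistic), inducing within-block Spearman
  correlations above the 0.8 edge threshold while the background stays near
  zero;
* connector taxa loading on the three bacterial module factors. The factors
  of those three modules are themselves correlated (0.8) — necessarily so: a
  variable cannot correlate at 0.8 with three mutually independent factors
  (the squared loadings would exceed 1), and a node linking only two modules
  cannot reach $P_i \ge 0.62$. The chosen geometry puts connector-member
  correlations near 0.86 and cross-block member-member correlations near
  0.67, below the edge threshold;
* metabolites generated as linear functions of module 0's per-sample Shannon
  diversity — ethyl acetate with slope -1.5, each higher-alcohol component
  with slope +2/3 (so the summed higher alcohols have slope +2.0) — with
  Gaussian noise calibrated to |r| ~ 0.7, plus 30 uninformative lognormal
  metabolites.

`simulate_indicator_metabolites()` provides the separate two-group design
for classifier validation (36 samples per group, 4 informative features
shifted 1.5 sd each — a combined separation of ~3 sd — among 30 noise
features). `truth_report()` scores any stage's output against the planted
truth (ARI for modules, precision/recall for connectors/enrichment/
indicators, migration-rate and slope errors).

What the generator does *not* emulate: sequencing error and chimeras,
phylogenetic structure, time autocorrelation within a fermentation, and
taxon-taxon interactions beyond shared latent factors. Passing tests
therefore demonstrate that the estimators recover the structures they claim
to recover under realistic compositional sampling noise — not that any
particular real fermentation satisfies the models.

# Numerical choices and degenerate inputs

* Strict inequalities at all screening thresholds; inclusive inequalities at
  the Zi/Pi role thresholds (both as conventionally written).
* Permutation p-values always use the add-one convention; seeds fix every
  ensemble, and no stage reads wall-clock entropy. `run_pipeline()` derives
  per-stage seeds from one global seed so stages are independently
  reproducible.
* Constant taxa are excluded from correlation testing (warning), never
  edges; constant module predictors are skipped in regressions (warning);
  zero-abundance subsets give Shannon 0 with a warning.
* Removal counts round half up; fraction 1.0 removes all nodes.
* The neutral fit errors out on non-integer input (relative abundances
  cannot carry detection information) and on boundary optima.
* Module size ties in relabeling break by original label; algorithm ties in
  modularity break in the fixed order greedy, Louvain, label propagation.

# Validation problem sizes

The acceptance tests run at sizes chosen to make their Monte-Carlo bands
tight while staying desk-scale: 20 replicate neutral round trips (500 taxa,
24 samples, N = 10,000, 1000 bootstrap replicates); NST with 1000 null draws
on 300-taxon, 24-sample communities (20 null-consistency replicates, 20
paired neutral-vs-selection replicates); 100 slope-recovery replicates at
the default generator design; 25 indicator-selection replicates; 200-fold
null calibrations for PERMANOVA and enrichment. The headline quantities a
fresh run produces are recomputed by `scripts/acceptance.R`.

# Known limitations

* Spearman co-occurrence on relative abundances carries compositional bias;
  SparCC-style inference is out of scope by design, and very sparse taxa can
  show tie-inflated correlations — the prevalence filter is the guard.
* The NST value depends on the null model; comparisons are meaningful within
  one parameterization only.
* The neutral fit's m is mildly biased upward (threshold approximation);
  the round-trip tests quantify the effect.
* Exact permutation p-values for correlations are enumerated only below 10
  samples; above that the t approximation is used.
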