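---
title: "Entropy-based saturation testing: model, calibration, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based saturation testing: model, calibration, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The saturation model

Substitution saturation is the erosion of historical signal when substitutions
hit the same sites repeatedly. At the limit of full saturation, the nucleotide
carried by each sequence at a site is independent of every other sequence, so
the count vector of A, C, G, T at a site is one draw from a multinomial
distribution with $n$ trials (the taxa) and probabilities $p$ (the overall
base frequencies of the alignment). `expected_full_entropy()` evaluates the
exact entropy of that distribution in bits:

$$H(X) = -\log_2 n! - n\sum_i p_i \log_2 p_i +
\sum_i \sum_{x=0}^{n}\binom{n}{x} p_i^{x}(1-p_i)^{n-x}\log_2 x!$$

Categories with $p_i = 0$ contribute nothing; all factorials go through
`lgamma`, and the inner expectation of $\log_2 x!$ is a finite, exact sum over
$x = 0..n$ — no approximation is involved, which the test suite verifies
against exhaustive enumeration of all count vectors.

`site_information()` evaluates $I(x) = -\log_2 P(X = x)$, the information
content of an observed column under the same multinomial. The key structural
fact — worth stating because it fixes every sign convention downstream — is
that columns retaining phylogenetic structure are *improbable* under the
saturation model. A conserved column of $n$ identical states has probability
$p_i^n$ (information far above $H$); a column split cleanly between two clades
likewise sits in the low-probability tail. Saturated columns, by contrast,
look like typical multinomial draws, whose average information *is* $H$.

## The test statistic

`entropy_t_statistic()` standardizes the distance between the mean per-site
information and the full-saturation entropy:

$$t = \frac{\bar I - H}{s_I / \sqrt{S}}$$

with the sample standard deviation on $S-1$ degrees of freedom. Far from
saturation $t$ is large and positive; at full saturation it is near zero. The
statistic is invariant to the logarithm base (numerator and denominator scale
together), so the choice of bits is cosmetic but fixed for reporting. A locus
is flagged saturated when $t_{\mathrm{obs}} < t_{\mathrm{crit}}$, with
$t_{\mathrm{crit}}$ supplied by the simulation calibration described below —
not by the t distribution, because inference is already being misled well
before the signal is fully erased, so the relevant threshold is empirical.

Two modes are provided. `all_sites` uses every column. `informative_sites`
(the default, and the mode the screening tool uses) restricts both the base
composition and the tested columns to parsimony-informative sites — at least
two states each present in at least two sequences. Slowly evolving sites
otherwise dominate the composition estimate and distort the reference
entropy; restricting to informative sites removes that influence, at a price
discussed under *Limitations*.

Missing data (gaps and IUPAC ambiguity codes) are excluded cell-wise: a
column's information uses its own count of observed states, and the reference
entropy is evaluated at the modal per-column count across the selected sites
(the full taxon count for complete matrices). This keeps the reference
matched to typical columns without discarding partially missing ones.

## The simulator

`simulate_dataset()` generates the study conditions used everywhere in the
package: calibration, power checks, and the test suite.

* **Topologies** are the two shape extremes: complete binary trees
  (*balanced*) and caterpillars (*imbalanced*), for taxon counts that are
  powers of two.
* **Branch lengths**: all internal branches share one length and all external
  branches another, chosen so the mean branch length equals its target exactly
  and internal branches contribute a proportion *s* (the *stemminess*) of the
  total tree length. Stemminess is interpreted as
  internal/(internal + external) in (0, 1): the calibration levels 0.1/0.5/0.9
  only make sense on that scale, and low stemminess (short internal branches
  relative to external ones) is the classically hard regime.
* **Substitution models**: Jukes–Cantor, or GTR+Γ with the six
  exchangeabilities drawn from a symmetric Dirichlet with concentration 5,
  continuous (not discretized) gamma rate multipliers with shape 1, and
  uniform base frequencies by default (configurable); rate matrices are scaled
  to mean rate 1 so branch lengths are expected substitutions per site. An
  invariant-site mask (Bernoulli per site) is applied before simulation.
  GTR+Γ data analysed under JC probes model underparameterization.
* Transition probabilities come from the eigendecomposition of the
  symmetrized reversible rate matrix, evaluated per branch and per site-rate;
  every replicate records its own integer seed and reproduces exactly.

What the simulator does **not** emulate: indels and alignment error,
heterotachy, covarion-like switching, compositional heterogeneity across
lineages or CAT-style site-specific frequency classes, and recombination
within loci. Passing tests therefore demonstrate calibrated behavior under
time-homogeneous reversible models; processes that push alignment-wide base
frequencies away from the multinomial ideal (covarion, CAT-like mixtures) can
mislead any entropy-based saturation test and are outside what these
simulations certify.

## The inference engine

Calibration needs positives — replicates where inference got the tree wrong —
which requires re-inferring trees by the thousand. The package deliberately
uses its own JC-corrected neighbor-joining engine (`jc_distance_matrix()`,
`nj_tree()`) rather than wrapping an external maximum-likelihood program, so
that calibration is self-contained and runs at desk scale. p-distances of
0.749 and above are capped before the JC correction so saturated pairs yield
finite, large distances — the calibration deliberately explores saturation,
where the correction diverges. Negative NJ branch estimates are clamped to
zero. Accuracy is scored with the unweighted/normalized Robinson–Foulds
distance on unrooted bipartitions and the signed proportional tree-length
error; both are checked against brute-force oracles in the tests. Users who
prefer ML-inferred trees can score their own records and feed them to
`compute_roc()`/`fit_crit_model()` unchanged — all calibration functions
operate on plain record tables.

## Calibration design

`run_gradient_experiment()` samples scenarios from uniform ranges — mean
branch length U(0.01, 0.65), stemminess U(0.1, 0.9), constant-site proportion
U(0, 0.8), sequence length over a configurable range — crossed with random
taxon count, tree shape, and generating model. Per replicate it records both
statistics, the RF distance, and the tree-length error. *Topology positives*
are replicates with any topological error (normalized RF > 0); *tree-length
positives* are estimates at least 50% longer or shorter than the truth.

`compute_roc()` traverses every distinct observed statistic value, flagging
"saturated" below the threshold; `select_tcrit()` picks the threshold
maximizing TP − FP (counts, not rates), breaking ties toward the smallest
threshold — the conservative choice that flags fewer loci. Thresholds are
chosen per (taxon count × length bin) cell — four equal-width bins by default
— and `fit_crit_model()` regresses them on $\sqrt{\text{taxa}}$ and
$\sqrt{\text{length}}$ by OLS, recording the adjusted $R^2$ and each cell's
TPR/FPR so screening decisions can report their expected error rates.
`predict_tcrit()` flags queries outside the calibrated range as
extrapolations. Replicates whose statistics cannot be computed (fewer than
two informative sites, degenerate variance) are recorded as not testable and
excluded from ROC construction but never silently dropped.

**Problem sizes.** The shipped default calibration
(`default_crit_model()`, regenerable with `calibrate_crit_model()`) uses taxa
{8, 32, 128}, lengths 250–1250 in four bins, and 1200 replicates (~100 per
cell) — sizes chosen so a full calibration runs in about a minute on one CPU,
which we consider the right default for a screening tool meant to be
recalibrated casually. The factorial machinery (`factorial_experiment()`,
`interaction_regression()` with Benjamini–Hochberg adjustment — BH chosen as
the standard FDR procedure) exposes the full crossed design with levels for
taxa up to 512 and 100 replicates per cell as configuration, but runs of that
size are cluster-scale and not exercised by the default test suite. The test
suite's heavier checks use 100–2000 replicates per claim.

## Numerical and design choices

* Logarithms in bits throughout; the t statistic is base-invariant.
* 1-based site indices, as in R; reports use 1-based positions.
* All IUPAC ambiguity codes and `-`, `?`, `.` map to missing; missing cells
  are excluded from counts and compositions.
* Relaxed PHYLIP dialect (whitespace-delimited full-length labels, sequential
  or interleaved) to avoid the 10-character name truncation.
* Screening filters (≥ 30 informative sites; no informative-site base
  frequency above 0.5) are evaluated *before* the test and produce
  `not_testable` rows with a reason, so report accounting always matches the
  input inventory. The frequency bound is evaluated on the informative-site
  composition — the composition the test actually uses.
* NJ tie-breaks follow the standard lowest-index rule of the underlying
  implementation; `calibrate`d models serialize to a flat text format that
  round-trips exactly.

## Limitations

* **Small-taxon bias of the informative-sites mode.** Conditioning on
  parsimony-informativeness excludes the patterns with the smallest
  multinomial coefficients (constant and near-constant columns), which carry
  the *highest* information. At small taxon counts a non-negligible share of
  saturated draws is non-informative, so under full saturation the
  informative-sites statistic centres slightly *below* zero rather than at
  zero (at 8 taxa, around −2 on the t scale), and the effect vanishes as the
  taxon count grows. This is precisely why critical values are calibrated by
  simulation instead of taken from the t distribution; but it means the raw
  informative-mode statistic should not be read as a textbook one-sample t at
  desk-scale taxon counts.
* **Order-statistic noise in the chosen thresholds.** In calibration cells
  where topology positives dominate (large trees with the NJ engine at
  moderate lengths), TP − FP keeps rising with the threshold and the chosen
  $t_{\mathrm{crit}}$ degenerates toward the cell's largest observed
  statistic — an extreme order statistic with high variance. The adjusted
  $R^2$ of the critical-value regression at the default desk-scale profile is
  therefore modest (typically 0.5–0.8 across seeds) and the predicted
  thresholds at 32–128 taxa are aggressive. Larger calibrations and/or
  stronger inference engines tighten this; the regression form itself is kept.
* **Step-like power curves.** At fixed taxon count and length, the
  conditional spread of the statistic is small relative to the branch-length
  effect, so the flagged fraction jumps from ~0 to ~1 across a narrow
  branch-length window rather than rising gradually.
* Decisions depend on the calibration supplied; the shipped model covers
  8–128 taxa and 250–1250 sites, and predictions outside that range are
  flagged as extrapolations rather than refused.
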