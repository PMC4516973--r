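---
title: "Dynamical network biomarkers: model, estimation and design choices"
author: "DNBdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical network biomarkers: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNBdetect)
```

## The model

A biological process approaching a critical transition passes through
three stages: a stable before-transition state, a low-resilience
pre-transition state just before the tipping point, and a stable
after-transition state. The pre-transition state is hard to see in mean
expression — the system has not yet moved — but it is visible in the
*second moments*. As the dominant eigenvalue of the linearised dynamics
approaches criticality, a specific group of genes (the dynamical network
biomarker, DNB) satisfies three conditions simultaneously: its members'
fluctuations grow sharply; its members become strongly mutually
correlated; and its correlation with all other genes weakens. The
remaining genes show no drastic change.

`DNBdetect` turns these conditions into one statistic. For a module $M$
of $m$ genes inside a measured universe of $n$ genes, estimated on a
window of case samples at time $t$:

$$
I(M, t) \;=\; \frac{\overline{\mathrm{SD}}_{\,g \in M}(t)\;\cdot\;
\overline{|\mathrm{PCC}|}_{\,g,h \in M}(t)}
{\max\!\big(\overline{|\mathrm{PCC}|}_{\,g \in M,\, h \notin M}(t),\;
\varepsilon\big)},
\qquad \varepsilon = 10^{-3}.
$$

The numerator grows under the fluctuation and internal-correlation
conditions, the denominator shrinks under the external-correlation
condition, so $I$ spikes exactly when all three act together. Absolute
correlations are used throughout because the conditions concern
correlation *strength*, not sign. The three conditions pin $I$ only up to
monotone transformations; this ratio form is the standard composite index
of the DNB literature, and the ingredients (`sdIn`, `pccIn`, `pccOut`)
are always reported alongside `ci` so any monotone-equivalent variant can
be derived from the output.

## Estimation pipeline

1. **Preprocessing** (`readSeriesMatrix()`, `collapseProbes()`,
   `normalizeExpression()`): probes without a gene symbol are dropped;
   probes of the same gene are averaged; rows with more than 20% missing
   values are dropped and remaining gaps imputed by the row median;
   values are log2-transformed (`log2(x+1)`) when the matrix maximum
   exceeds 50 — a conventional heuristic separating linear-scale arrays
   from already-logged ones. Each decision is reported via `message()`.
   Gene symbols are matched case-insensitively and upper-cased.
2. **Differential pre-filter** (`differentialFilter()`): the composite
   index is insensitive for genes that do not respond to the perturbation
   at all, so genes are pre-filtered by a per-gene Welch test, pooling
   all case against all control samples (a per-time-point variant with
   Bonferroni correction across time points sits behind `perTime =
   TRUE`). A location test is the minimal reading of "differentially
   expressed"; it implies the simulator must give its planted block a
   mean offset (below).
3. **Candidate modules** (`clusterCandidates()`): at every time point the
   filtered genes are clustered by average-linkage hierarchical
   clustering under $d = 1 - |\mathrm{PCC}|$, tree cut at `cut`;
   singletons are discarded. Structure is re-estimated at every window
   because the DNB's correlation structure is itself transient.
4. **Dominant group** (`selectDominantGroup()`): every candidate of at
   least `minSize` genes is scored against the filtered universe and the
   global maximiser over all (module, time) pairs wins; ties resolve to
   the earliest time point, since an earlier warning is the more useful
   one. If a network is supplied, candidates are intersected with its
   nodes and split into components of the union of network edges and
   strong correlation edges ($|\mathrm{PCC}| \ge 0.8$) — network support
   is optional because interactome coverage varies wildly.
5. **Transition detection** (`detectTransition()`): the series maximum is
   flagged when it exceeds the mean of the remaining points by $k$ of
   their standard deviations ($k = 2$ by default; see Limitations).
6. **Validation** (`bootstrapNull()`, `crossScore()`): `nGroups` random
   gene sets, size-matched to the observed module and drawn from the
   measured universe excluding it, are scored identically (the observed
   module is re-scored with the same settings so the comparison is
   exact); the exceedance is the fraction of null maxima reaching the
   observed maximum. `crossScore()` scores a fixed, previously identified
   gene list on an independent dataset.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `w` | 1 | window half-width (time points) around each estimate; `w = 0` uses replicates only. With few replicates per array, `w = 1` triples the per-window sample count at the cost of smearing the peak by up to one point. |
| `cut` | 0.5 | tree-cut dissimilarity; genes joining a module have average $|\mathrm{PCC}| > 0.5$ within it |
| `alpha` | 0.05 | Welch pre-filter level |
| `minSize` | 5 | smallest module eligible for dominance — pairs of noise genes can reach high $I$ by chance |
| `k` | 2 | transition standout threshold, in SDs of the non-peak scores |
| $\varepsilon$ | $10^{-3}$ | floor of the external-correlation denominator |

## The simulator

`simulateDNBDataset()` draws, for each time point $k$, case replicates
from a multivariate normal with block-compound-symmetry covariance: the
planted block of `nDNB` genes has SD `sigmaBackground * sigmaSchedule[k]`
and pairwise correlation `rhoInSchedule[k]`; the background is
uncorrelated with SD `sigmaBackground`; and the block couples to a subset
of background genes at `rhoOutSchedule[k]`. Controls are stationary
background draws at every time point. Sampling moments are therefore
*exact by construction*, which is what makes planted-truth recovery
testable; an explicit dynamical simulator would only add nuisance
approximation error around the same second-moment structure.

Default schedules are piecewise-linear ramps peaking at `tStar` (index 7
of a 17-point, 10 min–72 h course) and returning to baseline three points
later: SD multiplier $1 \to 3$, intra-block correlation $0.1 \to 0.8$,
block-background correlation $0.1 \to 0$; 1000 genes, 30 planted, 5
replicates per point. Two defaults deserve their own justification:

* **`meanShift` (default 1 SD unit).** The pre-filter is a location test,
  so a planted block with background means would be filtered *out*
  regardless of its variance ramp. Response genes of a real perturbation
  are up- or down-regulated, so the case-group block carries a constant
  mean offset. A constant (rather than scheduled) offset is deliberate:
  it leaves every scheduled moment — per-window SDs and correlations —
  exactly as specified, because a constant shift contributes nothing to
  any central second moment, even across pooled windows.
* **`nOutCoupled` (default 10).** A *uniform* block-background
  correlation $\rho_{out}$ against an uncorrelated background is not
  positive semi-definite once the background is large: the Schur
  complement of the background block requires
  $n_{DNB} \cdot n_{bg} \cdot \rho_{out}^2 < 1 + (n_{DNB}-1)\rho_{in}$,
  which $\rho_{out} = 0.1$ violates beyond roughly a dozen background
  genes. The coupling is therefore planted against a bounded neighbour
  subset — the natural reading anyway, since a DNB decouples from its
  *network neighbours*, not from thousands of unrelated genes.
  `SimulationParams()` validates the bound and names the offending time
  point; `populationScoreSeries()` weights the cross-pair expectation
  accordingly.

The simulator emulates the covariance structure the method detects —
nothing else. It does **not** model probe-level artifacts, missingness,
batch effects, heavy-tailed expression noise, or secular mean trends in
the background. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's own
assumptions, not robustness to real-array pathology; the preprocessing
layer (imputation, log transform, probe collapse) is tested separately
on constructed fixtures.

## Closed-form expectations

`populationScoreSeries()` computes the expected trajectory of the
composite index from the true schedules at a given per-window sample
count $n$: expected sample SD $\sigma_k \, c_4(n)$ with the exact chi
correction $c_4$, and the expected mean absolute correlation from the
folded-normal approximation $r \sim N(\rho, (1-\rho^2)^2/(n-1))$. The
folding matters: at $\rho = 0$ the mean *absolute* sample correlation
converges to $\sqrt{2/(\pi(n-1))} \approx 0.056$ at $n = 200$, not to 0,
so the naive plug-in of $|\rho|$ is not the large-replicate limit of the
estimator and would be off by orders of magnitude at the
external-correlation trough.

Agreement between sampled and expected trajectories is exact in
expectation but limited by Monte-Carlo dispersion: the mean-$|r|$
estimator over the within-module pairs shares the common-factor
realisation across all pairs, a component that does not average out.
At $s = 200$ this leaves roughly $\pm 20\%$ relative dispersion at the
small-correlation baseline points (shrinking as $1/\sqrt{s}$), while the
SD and external-correlation components agree to a few percent everywhere
and the peak of the trajectory — where the signal lives — is tight. The
test suite asserts the trajectory at these honest tolerances and the
acceptance script reports the measured maximum relative error.

## Numerical and degenerate-input choices

* Zero-variance genes get correlation 0 to every other gene (diagonal
  kept at 1) and their count is reported; a fully constant module scores
  $I = 0$ through `sdIn`, never `NaN`.
* Windows with fewer than 3 samples are refused with advice to raise `w`.
* `ci` ties in the dominant-group search and in `which.max` resolve to
  the earliest time point.
* All simulation randomness flows from one explicit integer seed; the
  same parameters and seed reproduce datasets bit for bit.
* p-values from the Welch filter are computed vectorised per gene;
  degenerate rows (both groups constant) get $p = 1$ when means agree
  and $p = 0$ otherwise.

## Test problem sizes

Unit tests run the generator at 60–300 genes with 5–200 replicates —
large enough that planted-moment checks have negligible estimation bias,
small enough to keep the suite fast. The end-to-end acceptance tests use
the full default conditions (1000 genes, 20 seeded runs for recovery and
bootstrap experiments, 100 runs for null calibration, 50 for exceedance
calibration); these sizes are the package's chosen operating point for
stable rate estimates.

## Known limitations

* **The standout rule at $k = 2$ is anticonservative on stationary
  data.** The rule compares the series maximum against the mean and SD of
  the remaining points, ignoring that the maximum was selected among $T$
  candidates. For $T = 17$ near-independent window statistics, a 2-SD
  standout is roughly a coin-flip event under the null (the acceptance
  script's `null_false_alarm_rate` measures it directly), and even the
  milder "any point above the series mean + 2 series SDs" occurs in a
  substantial minority of null runs. Detection at $k = 2$ is therefore
  only meaningful *jointly* with the bootstrap null, which calibrates
  against the same maximum-selection effect; users wanting a standalone
  calibrated detector should raise `k` to about 3.
* The dominant-group score is a maximum over many candidate modules and
  time points and is biased upward; it must not be interpreted as a
  calibrated effect size. The bootstrap exceedance is the honest
  significance summary.
* With `w = 1`, trajectories are smeared over adjacent time points, so a
  detected transition is accurate to about one time point.
* Enrichment analysis uses the measured-gene universe, not the genome:
  arrays only ever measure a bounded universe, and results are
  background-sensitive. Raw p-values are reported alongside BH-adjusted
  ones.
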