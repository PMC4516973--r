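# DNBdetect

Early-warning detection of critical transitions in time-course gene
expression, via dynamical network biomarkers (DNBs).

Many biological processes — disease deterioration, stimulus-driven cell
differentiation — proceed smoothly until they cross a tipping point
(a bifurcation of the underlying regulatory dynamics) and shift abruptly to
a new state. Just before that transition, while the mean state still looks
unremarkable, dynamical systems theory predicts a specific signature in a
*subset* of genes, the DNB: their expression fluctuations grow sharply,
they become strongly correlated with one another, and they decouple from
the rest of the transcriptome. `DNBdetect` estimates these three
signatures from case/control time-course expression data, combines them
into a composite index, and uses it to identify the dominant module and
the pre-transition time point.

For a module *M* of *m* genes at time *t*, estimated on a sliding window
of case samples:

&nbsp;&nbsp;&nbsp;&nbsp;*I(M, t)* = SD<sub>in</sub> · PCC<sub>in</sub> / max(PCC<sub>out</sub>, ε)

where SD<sub>in</sub> is the mean per-gene sample standard deviation over
*M*, PCC<sub>in</sub> the mean absolute Pearson correlation over the
*m(m−1)/2* within-module pairs, PCC<sub>out</sub> the mean absolute
Pearson correlation over the *m(n−m)* module-to-outside pairs, and
ε = 10⁻³ a guard against division by zero. A module whose *I* spikes and
stands out from its own trajectory (maximum above the mean of the other
time points by *k* = 2 of their standard deviations) flags an imminent
transition.

The package is organised Bioconductor-style around a
`TimeCourseExperiment` (extending `SummarizedExperiment`) and covers the
whole workflow: GEO series-matrix parsing and probe-to-gene collapsing,
Welch differential-expression pre-filtering, per-time-point correlation
clustering into candidate modules, dominant-group selection, transition
detection, a size-matched bootstrap null, fixed-module cross-dataset
scoring, hypergeometric over-representation analysis, and SIF/GraphML
network export. A multivariate-normal simulator with scheduled
covariance (`simulateDNBDataset()`) plants a ground-truth DNB block so
that every stage is verifiable end to end; see the methods vignette
(`vignettes/dnb-methods.Rmd`) for the model and all design choices.

## Worked example

Simulate the default study conditions (1000 genes, a 30-gene planted
block, 17 time points from 10 min to 72 h, 5 replicates per point, with
fluctuation/correlation schedules peaking at time point 7 = 1.5 h), then
identify the dominant group blind to the truth:

```r
library(DNBdetect)

sim <- simulateDNBDataset(SimulationParams(seed = 11))
dg  <- selectDominantGroup(sim$dataset, w = 1, cut = 0.5,
                           alpha = 0.05, minSize = 5)
dg
#> DominantGroup: 29 genes selected at time 7
#> DNBScoreSeries: 29-gene module over 17 time points (w=1)
#>   peak ci 7.487 at time 7 (1.5h); transition: time 7 (1.5h)

scores(dg)[4:10, ]
#>  time timeLabel  sdIn pccIn pccOut   ci nSamples
#>     4     30min 1.802 0.405  0.203 3.59       15
#>     5     45min 1.950 0.419  0.206 3.96       15
#>     6        1h 1.895 0.433  0.222 3.69       15
#>     7      1.5h 2.482 0.688  0.228 7.49       15
#>     8        2h 2.339 0.691  0.233 6.94       15
#>     9        3h 2.198 0.673  0.217 6.81       15
#>    10        4h 1.208 0.230  0.220 1.26       15
```

The composite index rises into the pre-transition point and collapses
after it: the module's fluctuation (`sdIn`, expression units) and internal
coherence (`pccIn`) peak together at 1.5 h while its coupling to the rest
of the transcriptome (`pccOut`) stays flat. The recovered 29-gene module
overlaps the planted 30-gene truth at Jaccard 0.967, and the detected
transition index (7) equals the planted one.

Validation against a size-matched random-gene null, and enrichment of the
module against a gene-set collection:

```r
bootstrapNull(sim$dataset, dg@series, nGroups = 10, seed = 2)
#> BootstrapResult: 10 null groups (size 29), exceedance = 0.000

sets <- makeGmtFixture(rownames(sim$dataset), sim$truth, nSets = 6, seed = 3)
head(hypergeometricORA(moduleGenes(dg), sets, rownames(sim$dataset)), 1)
#>           setName overlap setSize moduleSize universeSize       pValue    pAdjusted
#>  planted_enriched      23      30         29         1000 3.094952e-35 1.856971e-34
```

An exceedance of 0 means no random group's score maximum reached the
observed one; the planted-enriched set dominates the over-representation
ranking.

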