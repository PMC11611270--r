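# velokin

Absolute RNA kinetics and time-resolved RNA velocity from
metabolic-labeling single-cell RNA-seq, inferred through stochastic models
of the measured counts.

## The problem and who this is for

Metabolic-labeling scRNA-seq (scEU-seq, scNT-seq, sci-fate, scSLAM-seq,
...) tags transcripts made during a known labeling window of `t` hours,
splitting each gene's counts into new/labeled versus old layers — and,
with splicing-aware chemistry, into the four layers `uu`, `ul`, `su`,
`sl`. Because the clock is physical, these data identify *absolute* rates:
transcription α (molecules/h), splicing β (1/h), degradation of total and
spliced mRNA γ<sub>t</sub>, γ<sub>s</sub> (1/h), and the promoter
off-probability p<sub>off</sub>. velokin is for computational biologists
who want those rates, and velocities derived from them, estimated from the
discrete counts themselves rather than from least squares on smoothed
expression.

## The models

Solving the chemical master equation of each reaction scheme from an empty
initial state and composing it with per-cell binomial capture noise
p<sub>j</sub> (the size factor) yields closed-form measured-count laws:

| model | reactions | measured-count law |
|---|---|---|
| baseline | α transcription, γ<sub>t</sub> degradation | `l_j ~ Pois(p_j a(t))`, `a(t) = α(1−e^{−γ_t t})/γ_t` |
| splicing | α, β splicing, γ<sub>s</sub> spliced degradation | `ul_j ⊥ sl_j ~ Pois(p_j b(t)), Pois(p_j c(t))` |
| switching | slow promoter on/off, else baseline | zero-inflated: `p_off + (1−p_off)·Pois(p_j a(t))` |

On top of these the package provides: a modified chi-square
goodness-of-fit test for samples with cell-specific parameters
(`cellSpecificChi2`, verdicts accept / reject / UTD); closed-form and
two-stage estimators for one-shot designs (`fitOneshotSteady`,
`fitOneshot`); bounded maximum-likelihood fits across multiple labeling
durations with profiled transcription rates (`fitKinetics`); an adjusted
deviance R² for model comparison and gene selection
(`adjustedDevianceR2`, `selectGenes`); a likelihood-flatness robustness
index for γ<sub>t</sub> (`robustnessMeasure`); kNN-based cell-specific
rates with fixed gene-wise degradation (`cellwiseBaseline`,
`cellwiseSplicing`, `cellwiseSwitching`); total and spliced RNA velocity
with evaluation metrics (`computeVelocity`, `velocityCorrectness`,
`velocityConsistency`, `phaseDurations`); and exact Gillespie simulators
of the labeling process (`gillespieLabel`, `simulateOneshotBifurcation`,
`simulateKineticsPulse`).

Data live in a `LabelingExperiment`, a `SingleCellExperiment` subclass
with genes in rows, cells in columns, count layers as assays and the
per-cell labeling duration in `colData`; `readLabelingExperiment` loads
MTX/CSV layer files plus a cell metadata table.

## Worked example

Three genes with known rates, four labeling durations, 500 cells each;
counts drawn from the baseline law with stationary totals:

```r
library(velokin)
set.seed(1)
durations <- c(0.25, 0.5, 1, 2)          # hours
t <- rep(durations, each = 500)
truth <- data.frame(alpha = c(2, 5, 1), gamma_t = c(0.3, 1, 0.6))
new <- t(sapply(1:3, function(g)
    rcsp(length(t), p = 1, a = meanNewBaseline(truth$alpha[g],
                                               truth$gamma_t[g], t))))
old <- t(sapply(1:3, function(g)
    rpois(length(t), (truth$alpha[g] / truth$gamma_t[g]) *
                      exp(-truth$gamma_t[g] * t))))
le <- LabelingExperiment(list(new = new, total = new + old),
                         labelingTime = t)
le  <- computeSizeFactors(le)
fit <- fitKinetics(le, model = "baseline", robustness = TRUE)
cbind(round(fit[, c("alpha", "gamma_t", "r2", "robustness")], 3), truth)
#>   alpha gamma_t    r2 robustness alpha gamma_t
#> 1 1.859   0.243 0.370      127.7     2     0.3
#> 2 4.767   0.962 0.390      206.9     5     1.0
#> 3 0.994   0.549 0.185       43.7     1     0.6
```

Estimated α (molecules/h) and γ<sub>t</sub> (1/h) sit close to the
generating rates; `r2` is the adjusted deviance R² against the
intercept-only model, and `robustness` grows with how sharply the
likelihood pins γ<sub>t</sub> — the fastest-degrading gene is also the
best identified. The distributional assumption itself is testable per
gene and duration:

```r
testCellDistribution(le, model = "csp", duration = 1)
#>   gene  chi2 df pvalue verdict
#> 1    1 10.76  6 0.0962  accept
#> 2    2 14.13 10 0.1672  accept
#> 3    3  4.02  4 0.4039  accept
```

For velocity, build duration-stratified neighborhoods, smooth, and
evaluate the affine formula with cell-specific transcription rates:

```r
reps <- pcaRepresentation(le, nPCs = 2)
nb   <- buildKNN(reps, labelingTime(le), k = 30)
le   <- knnSmooth(le, nb, layers = c("new", "total"))
le   <- computeVelocity(le, "baseline", fit, nb)
SummarizedExperiment::assay(le, "velocity_T")[, 1:3]   # molecules/hour
```

The methods vignette (`vignettes/velokin-methods.Rmd`) documents the
three master-equation models, the test construction, every estimator's
initialization, bounds and numerical tolerances, and what the bundled
simulators do and do not emulate.

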