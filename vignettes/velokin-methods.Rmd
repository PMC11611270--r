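---
title: "Stochastic models for metabolic-labeling RNA kinetics and velocity"
author: "velokin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic models for metabolic-labeling RNA kinetics and velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velokin)
```

# The problem

Metabolic-labeling single-cell RNA-seq (tscRNA-seq) feeds cells a nucleoside
analogue such as 4sU for a known duration $t$, so that each sequenced
transcript can be classified as *new* (synthesized during the labeling
window) or *old*. Some protocols additionally resolve splicing, giving four
layers per gene and cell: unspliced-unlabeled (`uu`), unspliced-labeled
(`ul`), spliced-unlabeled (`su`) and spliced-labeled (`sl`). Because the
labeling duration is measured in hours, these data identify *absolute*
kinetic rates — transcription $\alpha$ (molecules/h), splicing $\beta$
(1/h), degradation $\gamma_t$ (total mRNA) and $\gamma_s$ (spliced mRNA),
and the promoter off-probability $p_{off}$ — where conventional
spliced/unspliced RNA velocity only identifies relative ones.

Counts in single cells are small, so velokin models them as the discrete
random variables they are, rather than fitting least squares to smoothed
expression.

# The three stochastic models

Each gene is treated independently (the standard assumption in this
literature) with constant rates. Solving the chemical master equation of
each reaction scheme from an empty initial state, and composing the
solution with per-cell binomial capture noise of probability $p_j$ (the
size factor), gives three measured-count laws:

* **Baseline** (transcription + degradation): the new count of cell $j$ at
  duration $t$ is Poisson with mean $p_j a(t)$,
  $a(t) = \alpha(1 - e^{-\gamma_t t})/\gamma_t$ — the *cell-specific
  Poisson* (CSP) law.
* **Splicing** (transcription + splicing + spliced degradation): labeled
  unspliced and spliced counts are *independent* Poissons with means
  $p_j b(t)$ and $p_j c(t)$, where $b(t) = \alpha(1 - e^{-\beta t})/\beta$
  and $c(t)$ is the two-exponential convolution (with a distinct branch at
  $\beta = \gamma_s$) — the ICSP law.
* **Switching** (slow promoter on/off): cells are silent with probability
  $p_{off}$, otherwise CSP — the cell-specific zero-inflated Poisson
  (CSZIP) law. The closed form assumes switching is slow compared with
  $\alpha$ and $\gamma_t$, so each cell is entirely on or entirely off
  during the experiment; no quantitative threshold for "slow" is enforced,
  only documented.

Binomial thinning of a Poisson is Poisson, which is why technical noise
folds into the single factor $p_j$; this is the crucial property that a
negative-binomial noise model would not share. Size factors are
$p_j = n_j/\mathrm{median}(n)$ by default; using the maximum instead
rescales every $p_j$ — and hence $\alpha$ — by one constant while leaving
degradation and splicing rates untouched, so velocity directions are
unchanged.

All probability computations run in log space (`dcsp`, `dicsp`,
`dcszip`), and the mean functions are evaluated in cancellation-safe
forms: $(1 - e^{-x})/x$ via `expm1` with a series below $10^{-8}$, and
the $\beta \approx \gamma_s$ branch of $c(t)$ switched at a relative
tolerance of $10^{-8}$, keeping $c(t)$ continuous across the boundary.

# Testing the distributional claims

`cellSpecificChi2` implements a chi-square goodness-of-fit statistic for
samples that share a distribution *family* but not parameters: each cell
contributes its own class-probability vector, the statistic is the
Mahalanobis norm of the mean indicator deviation under the averaged
multinomial covariance, and its null law is chi-square with
$c - 1 - (\text{fitted parameters})$ degrees of freedom. Count values are
binned greedily from zero, merging rightward until each class has total
expected count at least 0.25 (the merge direction is our choice; the
threshold is the standard one). When merging leaves fewer than two
classes, or the parameter correction exhausts the degrees of freedom, the
verdict is "UTD" — unable to determine — rather than a sham p-value. A
near-singular averaged covariance is ridge-regularized by
$10^{-10}\,\mathrm{tr}/(c-1)$. Parameters are fitted on the same cells
being tested, matching the per-duration workflow the test is used in; we
fit CSZIP parameters per duration rather than sharing them across
durations. `testTotalIndependence` is the companion contingency test of
binned total counts against duration labels, used to check the
steady-state assumption on total RNA.

# Parameter inference

**One-shot, new/total only.** Under stationarity of total RNA the MLE is
closed-form: $\hat\gamma_t = -\log(1 - \langle l\rangle/\langle r\rangle)/t$,
$\hat\alpha = \hat\gamma_t \langle r\rangle / \langle p\rangle$, with raw
count means. Degenerate inputs ($\langle l\rangle \ge \langle r\rangle$)
are an error; $\langle l \rangle = 0$ returns the zero boundary with a
warning; negative old counts are clipped to zero with a warning.

**One-shot, four layers.** `fitOneshot` avoids the steady-state assumption
in two stages. Stage one fits a minimal deterministic
induction-then-repression trajectory to the (unspliced, spliced) phase
portrait, assigning latent times by nearest trajectory point. Absolute
time is not identifiable from a phase portrait, so the switching time is
gauge-fixed to 1; only the ratio $\rho = \beta/\gamma_s$, the on-state set
$S_{on}$ and the fit quality $R^2$ (computed after excluding cells with
both coordinates below max/5; the maxima are taken once over all cells)
are consumed downstream, and an external dynamical-model fit can be
plugged in instead. The fitter is two-pass (coarse then fine trajectory
grids, with Nelder-Mead restarts until the loss stabilizes) because
discretization otherwise flattens the loss in $\rho$; populations above
500 cells are thinned deterministically for the loss only. Stage two pins
the absolute scale: pooled on-state moments $b_{obs}, c_{obs}$ plus
$\gamma_s = \beta/\rho$ reduce to one scalar equation in $\beta$, solved
by bracketed root-finding on $[10^{-4}, 50]/t$ to a residual of
$10^{-10}$.

**Kinetics (multiple durations).** Per-gene bounded MLE per model, with
$\alpha$ profiled out in closed form wherever the likelihood is linear in
it (baseline and splicing), a 1-D/2-D/3-D `L-BFGS-B` search over the
remaining rates under the constraints $0 < \theta < 10\,\theta_0$ and
$0 < p_{off} < 1$, and deterministic jittered restarts (fixed factors, no
RNG) so results are bit-reproducible and independent of gene order.
Initial values: the steady-state closed form applied within each duration
and averaged when a total (or unlabeled) layer is available; otherwise a
coarse log-spaced grid over the profiled loss — a self-contained fallback
for data that carry only labeled layers. The switching model is
initialized by the moment estimators for $(p_{off,0}, \alpha_0)$, clipped
into their admissible ranges with a warning when outside.

**Goodness of fit.** `adjustedDevianceR2` compares each fit to the
saturated (one parameter per observation) and intercept-only models on
the deviance scale, with degrees of freedom $N-2$/$N-1$ (baseline,
switching) and $2N-3$/$2N-2$ (splicing). We use the standard saturated
Poisson log-likelihood $\sum \log P(l \mid l)$, under which a perfect fit
gives exactly $D = 0$ and $\bar R^2_D = 1$. `selectGenes` keeps the top
fraction (default 40%) by this index, ranking missing values last and
breaking ties by gene index. `robustnessMeasure` quantifies how well
$\gamma_t$ is identified as the $l_1$ norm of the likelihood slope along
the profile curve on $[0, 1.5]$ /h — the bound corresponds to a half-hour
half-life, about the fastest turnover seen for total mRNA; genes whose
durations are all short against that range have flat profiles and
near-zero measure.

# Cell-specific rates and velocity

Gene-wise constant rates are a convenient fiction; velokin relaxes every
rate except degradation to be cell-specific, assuming only that cells
with similar expression have similar rates. Neighborhoods come from
`buildKNN` on the top principal components of log1p depth-normalized
totals (30 PCs, $k = 30$ by default; Euclidean distance; deterministic
tie-breaks by cell index) and are **stratified by labeling duration**,
because every local estimator pools counts at a single $t_k$. The PCA
space is our documented default — any cells-by-dimensions matrix can be
substituted. Within a neighborhood the pooled MLE
$\hat l_j = \sum_i l_i / \sum_i p_i$ inverts the mean function in closed
form (baseline and switching; for switching only the product
$\alpha_j(1 - p_{off,j})$ is identified, via a moment estimator — a
neighborhood straddling the on/off boundary silently averages the two
regimes, which we document rather than resolve); the splicing model solves
a per-cell ratio equation in $\beta_j$ by bisection after geometric
bracket expansion around the gene-wise estimate (tolerance $10^{-10}$),
falling back to the gene-wise $\beta$ when no root exists in
$[10^{-4}, 100\,\hat\beta]$.

Velocities are the deterministic mean-field reductions evaluated at the
kNN-smoothed expressions $\bar r, \bar u, \bar s$ (means of
count/size-factor over the neighborhood): $v = \alpha_j - \gamma_t \bar
r_j$ (baseline), $v = \alpha_j - \gamma_s \bar s_j$ (splicing default;
the $\gamma_t \bar r$ form is available via `useTotal` together with
`gammaTotalFromSpliced`, which estimates $\gamma_s/\gamma_t$ as the
zero-intercept regression slope of $\bar r$ on $\bar s$ — since total
includes spliced, the slope is at least 1 and $\gamma_t \le \gamma_s$),
$v = \alpha_j(1 - p_{off,j}) - \gamma_t \bar r_j$ (switching), and
$v_s = \beta_j \bar u_j - \gamma_s \bar s_j$ for the spliced pool.
A side consequence: baseline and splicing models cannot *both* have
constant degradation rates unless $\beta = \gamma_t$, so disagreement
between them on real data is expected, not a bug.

**Evaluation.** `velocityCorrectness` extrapolates each cell one step and
asks whether the nearest *other* cell ranks later in a supplied temporal
ordering; excluding the cell itself means the final cells of a trajectory
can never be correct, so even a perfect field scores slightly below 1.
`velocityConsistency` is the mean Pearson correlation between a cell's
velocity vector and its neighbors' mean (neighborhood size 30 by
default — the literature does not fix one; zero-variance cells are
excluded). `phaseDurations` integrates the field through the data
(groups of $k = 300$ cells, $dt = 0.01$ h, stopping at the 0.88 quantile
of relative position), timing each phase by its majority-label steps;
working with cell groups suppresses noise, at the cost of blurring phase
boundaries by roughly half a group width, and a stalled field
($\|v\| < 10^{-12}$) aborts with partial results.

# The simulators

`gillespieLabel` is an exact direct-method SSA of each reaction scheme
with a label flag on molecules born in the final labeling window;
degradation and splicing treat labeled and unlabeled molecules
identically, and transcription can shut off at a switching time. It is
the package's independent route to the closed-form laws: the labeled
count distribution at any observation time must match Poisson($a(t_l)$),
and the labeled splicing layers must match independent
Poisson($b$, $c$) — properties the test suite asserts with the package's
own goodness-of-fit test.

Two experiment-scale generators reproduce the validation designs:

* `simulateOneshotBifurcation`: a trunk-plus-two-fates topology. Half the
  cells sit on the trunk with observation times uniform on $[t_l, T/2]$,
  a quarter on each branch uniform on $[T/2, T]$. Cell-gene transcription
  rates come from latent extrinsic-variability factors interpolated
  piecewise-linearly along the three-branch tree with Gaussian jitter
  (dimension 5, jitter SD 0.15, effect scale 0.5 — our fully specified,
  self-contained replacement for external latent-factor simulators), as
  $\alpha_{ij} = \exp(\text{scale}\,\langle f_j, e_i\rangle)$ clipped to
  $[0.5, 20]$. Gene-wise $\beta \sim U[0, 0.5]$ and
  $\gamma_s \sim U[0, 5]$. Defaults $T = 2$ h, $t_l = 0.4$ h.
* `simulateKineticsPulse`: gene-wise $\alpha \sim U[0.5, 1]$,
  $\gamma_t \sim U[0, 0.5]$, induction until $t_s = 0.5\rho/\gamma_t$
  ($\rho \sim U[0, 1]$) then silence — our reading of the two-phase
  dynamical model; the source design does not spell out the post-switch
  rate. Durations default to $\{0.25, 0.5, 0.75, 1\}$ h with observation
  times uniform on $[1, 2]$ h: the window is deliberately commensurate
  with the typical switching times so the snapshot is genuinely
  non-stationary — pushing observation far past $t_s$ would instead
  produce extinct genes and no kinetic signal.

Neither generator injects technical noise; size factors are emitted as 1.
What passing tests on these data do show: the estimators invert their own
generative laws at realistic count depths, selection by deviance
goodness-of-fit enriches for well-estimated genes, and the velocity field
points forward in time. What they do not show: robustness to ambient RNA,
labeling-efficiency miscalibration (inputs are assumed
chemistry-corrected counts), doublets, or cell-cycle structure absent
from the generators.

# Problem sizes and numerical choices

The shipped test and acceptance workloads use 1 500–10 000 cells, 30–50
genes, 500–1 000 cells per duration and 500 calibration replicates —
sizes chosen so every distributional claim is tested at meaningful power
on a single core. Optimizers stop at a projected-gradient factor of
$10^2$ (machine-epsilon scaled) or 500 iterations; root-finders at
$10^{-10}$; quadrature at relative $10^{-8}$. Known limitations worth
restating: the degradation-rate MLE's relative error under weak rates
(half-lives beyond the longest labeling duration) is information-limited,
not implementation-limited — the profile likelihood is nearly flat there,
which is exactly what `robustnessMeasure` quantifies; the bundled
relative-dynamics fitter is intentionally minimal, and the two-stage
one-shot rates inherit its ratio error, so an external dynamical-model
backend is recommended when one is available; and the switching model's
closed form degrades when promoter switching is not slow relative to
transcription and degradation.
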