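---
title: "Models and methods behind spoarcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spoarcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spoarcnet)
```

# The scientific problem

When people hold a verbal sequence in working memory, responses made with
the left hand are faster for items early in the list and right-hand
responses are faster for late items — the SPoARC (Spatial Position
Association of Response Codes) effect. On the "mental whiteboard" account,
verbal sequences are spatialized left-to-right on an internal spatial
medium, so the effect indexes how strongly a person recruits spatial
processing for serial order.

`spoarcnet` implements two individual-differences pipelines around a single
statistic, the **SPoARC magnitude**: within a participant, reaction times of
correct positive-probe trials are regressed on the probe's serial position
separately per responding hand, and the magnitude is the right-hand slope
minus the left-hand slope (ms/position). Negative values mean the effect is
present; more negative means a larger effect.

* **Behavioral pipeline.** Trial trimming and exclusion rules produce seven
  level-2 cognitive measures per participant (breadth of attention `boa`;
  exogenous/endogenous cueing effects `exo`, `endo`; verbal and spatial item
  and serial-order WM capacities `viwm`, `vsowm`, `siwm`, `ssowm`). A
  multilevel mixed-effects model then asks which of these moderate the
  trial-level Hand x Position interaction (the SPoARC effect), probing
  significant cross-level interactions with Johnson-Neyman regions and
  pick-a-point simple slopes.
* **Network pipeline.** Multi-run node time series are converted to Pearson
  functional-connectivity matrices per run, averaged, thresholded to a fixed
  edge density, binarized, and partitioned by modularity maximization. The
  modularity of networks at several scales is correlated with the SPoARC
  magnitude, and scales are compared with Steiger dependent-correlation
  tests.

Because the underlying human RT and fMRI data are not publicly available,
the package ships a fully seeded synthetic-data generator whose defaults are
the published cohort conditions, so every stage is testable against known
ground truth.

# The generating model

## Level-2 measures

The seven cognitive measures are drawn from a Gaussian copula. The published
pairwise associations are Spearman rank correlations, so the copula's latent
Pearson matrix is obtained through the exact bivariate-normal inversion
`rho = 2 sin(pi rho_s / 6)` (`spearman_to_pearson()`); marginals are
Gaussian at the published means and SDs, truncated to the published
observed ranges by re-drawing violating rows. Re-drawing (rather than
clamping) keeps the marginal moments close to their targets while honoring
the ranges; the residual clamp after 200 rounds only ever triggers for
pathological configurations. Demographic covariates use the study codings
(handedness 1 = left / 2 = right with 93% right-handers, gender 1 = male /
2 = female at the cohort ratio, `altL` at 6/160, site code and education
years at plausible values for an undergraduate sample — the last two are not
published and were chosen once).

## Item-probe trials

Reaction times follow the multilevel model

```
RT = gamma_00 + gamma_10 Hand + gamma_20 Position + g3_i Hand*Position
   + gamma_40 Task + gamma_50 Task*Hand*Position
   + (level-2 main effects) + u0_i + u3_i Hand*Position + u4_i Task
   + u5_i Task*Hand*Position + e
```

with `Hand` coded +1/-1, `Position` 1-5, `Task` 1/2, and the
participant-specific SPoARC slope

```
g3_i = gamma_30 + sum_j gamma_3j c_ij + gamma_347 c_siwm,i c_ssowm,i
```

over the grand-mean-centered cognitive measures `c_ij`. Random effects
`(u0, u3, u4, u5)` are multivariate normal with the published unstructured
4x4 covariance `tau`; the residual is Gaussian with the published `sigma2`
(the residual RT distribution is not otherwise specified, so Gaussian — the
assumption of the fitted model — is used; an ex-Gaussian option was
considered and deliberately left out). Trial counts are uniform on 44-79
per participant. Non-positive RTs (vanishingly rare at the default
parameters) are re-drawn by default, because flooring would bias means; the
choice and tally are recorded in the returned ground truth.

One intentional detail: the generator centers the cognitive predictors at
the **realized sample mean**, exactly as the analysis model does at fit
time. Centering at the population mean instead would shift the estimand of
the Hand x Position coefficient by the sampling error of the moderator means
and distort coverage experiments.

## Task batteries and time-series panels

The attention/WM battery mirrors the published trial structure: 132
breadth-of-attention trials (33 cluster separations x 4; the printed grid
parameters — 33 separations, 0.5 cm steps, 86.8 cm maximum — are not
mutually consistent, so the package uses 33 equally spaced separations up to
86.8 cm); 168 cueing trials per task split 126 valid / 22 invalid / 20
catch; 120 sequence-matching WM trials per domain in equal thirds of
identical, item-change and order-swap trials (the published text fixes the
total but not the mix). Breadth-of-attention accuracy is a decreasing
logistic `0.5 + 0.5 plogis((boa_i - d)/s)` crossing the 75% criterion
exactly at the participant's breadth; cueing RTs differ between invalid and
valid trials by the participant's cueing effect; WM accuracy is Bernoulli at
the participant's capacity.

Time-series panels plant community structure directly: each node's signal
coupling `cw` is decomposed into a module-specific part and a globally
shared part, `x = (cw - cb) * latent_module + cb * global + noise`, with
fresh latents per run (three runs of 420 time points by default, the
acquisition geometry of the study). The decomposition — rather than adding
an independent global signal on top of a fixed module signal — is what makes
the between-coupling a true structure dial: at `cb = 0` the network is
purely modular, and as `cb` approaches `cw` within- and between-module
correlations coincide, the planted partition's modularity tends to zero,
and the optimized modularity of the thresholded graph falls to the sparse
random-graph baseline. (An additive independent global signal would leave
the within/between correlation ranking intact at every coupling level, so
density thresholding would always recover the blocks and modularity would
not respond to the coupling at all.)

# Analysis choices

## Trimming and exclusions

Trimming applies a fixed per-task RT window first (100-3000 ms for
item-probe, breadth-of-attention and WM tasks; 100-1200 ms for cueing
tasks), then interquartile fences `Q1 - 3 IQR` / `Q3 + 3 IQR` computed on
the window survivors. The quantile convention (linear interpolation, R type
7) is not stated in the source material; it is configurable. The rule is
applied once, as in the original procedure; on realistic RT distributions a
second application is a no-op, which the suite checks property-style.

Guessing screens use the exact one-sided binomial rule: the chance threshold
for `n` trials is `k*/n` with `k* = max{k : P(X >= k) > alpha}`,
`X ~ Binomial(n, 1/2)` — reproducing 70% at n = 20, 58.75% at n = 80 and
57.5% at n = 120. (For n = 168 the exact rule gives 95/168 = 56.55%, not
the published 56.6%; the exact value is used.) The WM screen is a
conjunction — low accuracy AND a mean RT below the group-level fast fence —
so slow-but-inaccurate participants are retained.

The breadth-of-attention rule ("largest distance beyond which accuracy no
longer exceeds 75%") is ambiguous for non-monotonic accuracy profiles. The
package implements the literal reading — the largest tested distance with
accuracy above threshold — and exposes `monotone = TRUE` for the
conservative reading (the largest distance such that all smaller distances
also pass).

## The SPoARC statistic

Raw-trial OLS of RT on position per hand (not per-position means), matching
the description of the single-level analysis; both material types are pooled
after per-material trimming. Participants with fewer than two distinct
positions for a hand get a missing slope; fewer than five usable trials per
hand flags the participant without dropping them. The statistic is invariant
to any per-hand intercept shift and is negated by swapping hand labels —
both are tested, and the slopes are checked against a normal-equations
oracle at 1e-10 relative error.

## The multilevel model

`fit_lmm()` delegates estimation to `lme4`/`lmerTest`: REML for estimates
and standard errors, FIML (via refit) for deviance/AIC/BIC and nested-model
chi-squared comparisons, Satterthwaite degrees of freedom for per-coefficient
t-tests — the same estimation/reporting split as the original analysis. The
random structure is the unstructured 4x4 covariance over (intercept,
Hand x Position, Task, Task x Hand x Position). At 60 participants this is a
rich structure and REML frequently lands on a singular boundary (about
three-quarters of scaled-down replicates); such fits are flagged, not
discarded, and fixed-effect inference remains well calibrated (coverage of
the Satterthwaite-Wald intervals for the Hand x Position and
vsowm x Hand x Position coefficients stays within 95 +- 3% in the suite's
300-replicate experiment at 60 participants x 30 trials — a size chosen so
the whole experiment stays in a few minutes while leaving Monte-Carlo error
near one percentage point).

Johnson-Neyman boundaries solve the usual quadratic in the moderator
`(gamma_c^2 - t^2 v_cc) w^2 + 2 (gamma_f gamma_c - t^2 v_fc) w +
(gamma_f^2 - t^2 v_ff) = 0` and classify the sub-ranges by evaluating the
t-ratio at interval midpoints; the critical value is a t quantile at the
interaction coefficient's Satterthwaite df (the source is silent here; a
normal reference is available via `use_t = FALSE`). The closed form is
validated against a dense grid search at 1e-4 of the moderator SD. Simple
slopes are linear contrasts of the fixed effects with delta-method SEs,
evaluated by default at the moderator's mean - SD / mean / mean + SD and at
the sample-mean Task value.

## The network stack

Connectivity is per-run Pearson correlation; runs are averaged on the raw
correlation scale (matching the described procedure; Fisher-z averaging is
available behind a flag). Thresholding retains `k = ceiling(density *
n(n-1)/2)` edges — the ceiling is the unique rounding consistent with all
seven published retained-edge counts at density 0.1147 — ranked by signed
correlation by default ("strongest" is ambiguous; absolute-value ranking is
a flag), with ties at the cutoff broken in lexicographic node order so runs
are reproducible.

Modularity of a partition is

```
M = (1/2e) * sum_modules sum_{i,j in module} (A_ij - a_i a_j / 2e)
```

summed over ordered pairs including i = j, so a single all-node module
scores exactly 0 and two disjoint triangles split by component score exactly
1/2. The optimizer is a pinned Newman-style variant: greedy agglomeration
from singletons on the modularity-gain matrix (tracking the best partition
along the merge path), followed by single-node move refinement to a local
optimum, plus seeded random-restart refinements (20 by default). Several
variants of the classic algorithm exist; rather than claim implementation
identity with any one of them, the package validates behavior — the
optimizer matches exhaustive enumeration over all partitions on graphs of up
to 8 nodes and recovers planted two-block partitions in at least 95/100
seeds. Isolated nodes remain singleton modules; module labels are contiguous
from 1.

## Brain-behavior comparisons

Pearson correlations come with two-sided t-tests. Scale comparisons use
Steiger's Z1* for dependent correlations sharing the behavior variable:
Fisher-z difference scaled by the dependent-samples covariance with the
pooled correlation in the covariance term. Two-sided by default; the
one-sided option exists because published values of the original comparisons
read as one-sided. Under a simulated trivariate null the statistic holds its
5% size within Monte-Carlo error at n = 25, and its p-values pass a
Kolmogorov-Smirnov uniformity check.

A note on signs: the SPoARC magnitude is signed (more negative = larger
effect), so a **positive** modularity-magnitude correlation means lower
modularity accompanies a larger SPoARC effect.

# What the synthetic data do and do not show

The generators reproduce the statistical skeleton the analyses assume —
moment structure, rank correlations, the multilevel RT model, planted
community structure — under exactly the published sample sizes and
parameters. They do not emulate BOLD hemodynamics, head motion,
preprocessing artifacts, response-time skew, practice or fatigue effects, or
task-specific stimulus idiosyncrasies. Passing tests therefore demonstrate
that the implementations are correct and well calibrated under the model
assumptions, not that those assumptions hold in real data; in particular the
published headline coefficients and correlations derive from unavailable
human data and are not reproduction targets.

# Numerical details and limitations

* Quantile type 7 for all fences; configurable.
* The latent copula matrix is checked for positive semi-definiteness and
  repaired by eigenvalue clipping (with a warning) or rejected, per config.
* Thresholding requires finite weights; constant node series make
  correlations undefined and raise an error by default.
* The modularity optimizer is heuristic beyond the exhaustively validated
  sizes; restarts trade time for reliability and are a parameter.
* All generators consume one seeded RNG stream per call; identical seed and
  config reproduce outputs bit for bit.
* Experiment-scale defaults (160 participants; 84/66/72-node panels) run in
  minutes; the test suite uses smaller cohorts chosen to keep each
  experiment's Monte-Carlo error well inside the tolerance it asserts.
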