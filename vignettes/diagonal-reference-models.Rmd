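---
title: "Estimating mobility effects on health with diagonal reference models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mobility effects on health with diagonal reference models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagref)
```

## The model

A square mobility table cross-classifies a person's social position of
origin (here: the highest educational level of either parent, collapsed
from ISCED 2011 to low/medium/high) against their position of destination
(own attainment). Three questions about a health outcome — here binary
overweight/obesity, BMI ≥ 25 kg/m² — have to be separated: the effect of
origin, the effect of destination, and the effect of *having moved*.

The logistic diagonal reference model writes the log-odds of the outcome
in cell (i, j) as

$$\eta_{ij} = w\,\gamma_{ii} + (1 - w)\,\gamma_{jj}
  + \delta\,\mathbf{1}[\text{mobile}] + x'\beta ,$$

where $\gamma_{kk}$ is the diagonal intercept — the log-odds for immobile
individuals at level $k$ (reported as odds) — and $w \in [0,1]$ weights
the origin diagonal against the destination diagonal. Off-diagonal cells
have no free intercept of their own: their baseline is an interpolation of
the two immobile baselines they connect. That restriction is what
identifies the additional mobility term $\delta$, which a free 3×3 cell
parameterisation could never separate from position. Covariates $\beta$
(centred age, nativity, marital status with `no_partner` as reference) act
as in ordinary logistic regression. There is no global intercept: the K
diagonal intercepts absorb it.

Assumptions worth stating: mobile individuals are a *mixture* of their two
reference groups with a single mixing weight shared across all off-diagonal
cells; the outcome is Bernoulli given cell and covariates (no extra
dispersion parameter exists in the binary case — the residual term of the
general model formulation has no analogue here and is documented rather
than modelled); and only two generations enter (the model cannot represent
three-generation trajectories).

## Why not the conventional designs

`fit_mobility_group_model()` implements the nine-group dummy design
(reference: immobile high, the always-advantaged). Each mobile group's
dummy measures mobility *and* the difference in positions — under any
social gradient in the $\gamma$'s it picks up gradient, not movement.
`fit_origin_control_model()` implements mobility status with origin
controls, which removes origin but not destination conflation. The fully
adjusted alternative does not exist: `demonstrate_linear_dependency()`
builds intercept + origin + destination + a mobility regressor and shows
by pivoted QR that, under the classical coding of mobility as the number
of levels moved, the mobility column equals the destination score minus
the origin score — rank 5 of 6 on *every* dataset containing all levels,
a structural not a numerical deficiency. A full set of trajectory dummies
alongside the margins is likewise dependent. One coding deserves a note:
two bare up/down indicators are *not* additive in origin and destination,
so that particular design is numerically full rank on a 3-level table —
its defect is that the indicators remain conflated with destination (and
the design is nearly saturated), not that it fails to invert. The package
reports each coding's rank as found. The DRM's conditional design
(`build_conditional_design()`) is full rank.

## Estimation

Conditional on $w$ the DRM is a GLM on the design whose level-k column is
$w\,\mathbf{1}[\text{origin}=k] + (1-w)\,\mathbf{1}[\text{destination}=k]$.
`fit_drm()` therefore profiles: an outer one-dimensional search over
$w \in [0,1]$ (21-point grid, then bounded refinement via `optimize()` to
tolerance 1e-7, candidates compared against the boundary values so
$\hat w = 0$ or $1$ is attainable and flagged) with a hand-written IRLS
logistic fit inside (convergence when the maximum absolute score falls
below 1e-8 or the relative log-likelihood change below 1e-10; coefficients
beyond 15 on the logit scale trigger a separation warning). The grid was
chosen dense enough that the profile — which is one-dimensional, bounded
and in practice unimodal — cannot hide a second mode between adjacent
points; a fine-grid oracle in the test suite verifies the optimiser to
1e-3.

Standard errors come from the observed information of the *joint*
log-likelihood in $(\gamma, w, \delta, \beta)$, computed by central
differences of the analytic score with step $10^{-5}\max(1,|\theta_j|)$ —
differencing the exact gradient rather than the function value costs
$2p$ gradient evaluations and is accurate to the same order as a
second-difference Hessian. The Wald interval for $w$ is deliberately
unconstrained and may extend outside $[0,1]$; no p-value is printed for
$w$ because the boundary constraint invalidates the usual two-sided test
(the supplementary `test_w_against()` compares an interior estimate to an
interior null such as 0.5). Degenerate cases are handled explicitly: an
all-diagonal table makes $w$ unidentifiable (error); a perfectly flat
profile (e.g. all cells balanced) is flagged and reported as the midpoint
of the argmax set; boundary fits are flagged and their delta-method $w$ CI
marked unreliable. A non-invertible information matrix falls back to a
pseudo-inverse, flagged in `convergence$vcov_pseudo`.

Two interpolation scales could be defended for the logistic variant:
combining the diagonal *odds* directly, or combining the diagonal
*log-odds* inside the link. The package generates and fits on the
log-odds (linear-predictor) scale — the only choice under which the model
is a GLM conditional on $w$ and under which generator and fitter coincide —
and exposes `interpolate_odds()` for the odds-scale arithmetic, noting the
two differ numerically (weights 0.35 over odds 0.41 and 0.73 give 0.618
versus 0.596). An identity-link variant for continuous outcomes (BMI
itself) reuses the same machinery with a weighted-least-squares inner
solver; it is provided as a variant and validated only against its own
generator, with joint inference obtained by differencing the concentrated
Gaussian log-likelihood.

## The synthetic-cohort generator

No microdata ship with the package, so every downstream stage is exercised
on synthetic cohorts whose structure mirrors the reference survey of Dutch
adults aged 18–45 (2009): (origin, destination) drawn from the packaged
3×3 count tables normalised (grand totals 1569 male, 1771 female); age
from a normal truncated to [18, 45] whose underlying location and scale
are solved numerically so the *truncated* distribution has the documented
sample moments (mean 34.95, SD 6.88); nativity Bernoulli(0.526); marital
status categorical (19.1/56.4/17.0/7.5%); outcomes Bernoulli through the
DRM linear predictor with diagonal odds 0.73/0.74/0.41 and $w = 0.35$
(males; 0.98/0.55/0.31 and 0.32 for females). Mobility and covariate
effects default to zero so structural tests are unconfounded;
`realistic_betas()` supplies typical covariate effects for integration
tests. One master seed expands to per-replicate substreams, so studies are
bitwise reproducible and each replicate individually re-runnable.

What the generator does *not* emulate: the survey's two-stage municipality
sampling and oversampling design (case weights are exercised through
synthetic weight columns instead), item nonresponse patterns, reporting
error in self-reported height and weight, and any dependence of covariates
on table cell. Passing tests therefore show that the estimators are
correct *under the model and these marginals* — not that the model is true
of any real cohort.

## The simulation studies

`run_type1_study()` generates cohorts with $\delta = 0$, fits the selected
methods, and records rejection rates: for the DRM, the Wald p-value of the
mobility covariate; for the group design, "any of the six mobile-group
dummies significant at $\alpha$" — the unadjusted family-wise rule that
mirrors how such tables are read, with a Holm-adjusted variant reported
alongside since even an honest baseline inflates over six tests; for the
origin-control design, "any mobility-status term significant". Convergence
failures are excluded from denominators and counted separately (a failed
fit is not a decision). The per-replicate decision matrix is retained so
every rate is recomputable. At the survey-scale defaults (n = 1569, 1000
replicates) the DRM test sits inside the nominal band while the group
design rejects in roughly nine cohorts out of ten — the conflation
phenomenon made quantitative. `run_power_study()` and
`run_recovery_study()` complete the operating-characteristic picture
(power in $|\delta|$ and n; bias/RMSE/coverage for $\hat w$, the diagonal
odds and $\hat\delta$).

Problem sizes used by the test suite and the acceptance script — 200
replicates of n = 50,000 for recovery, 1000 replicates of n = 1569 for
type-I rates, n = 2,000 fixed-seed data for the dual-route oracles — were
chosen so Monte-Carlo error is small relative to the bands being checked
while a full run stays in the minutes range on a single core.

## Known limitations

Only two generations; a single shared $w$ (no level-specific origin
weights, no random effects); Wald inference throughout — and the
simulation studies show its usual small price here: the likelihood is
mildly non-quadratic in $w$, so Wald intervals for the mobility effect
cover slightly below nominal (roughly 0.93–0.94 for a 95% interval at the
default designs, per the recovery study; `confint(..., method =
"profile")` provides a likelihood-ratio interval for $w$, and the same
construction for $\delta$ would be the natural remedy); no
multiple-imputation support (listwise deletion with accounting); the
linear DRM variant is untested against external results. The ISCED
collapse leaves categories 0 and 5 unassigned in the three-way scheme;
the package maps 0 → low and 5 → high by default, warns when it does, and
leaves both overridable, because the choice is substantive and should be
auditable rather than silent.
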