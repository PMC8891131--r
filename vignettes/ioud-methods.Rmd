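---
title: "Methods: the IOUD compartmental model and its analysis pipeline"
author: "ioud package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IOUD compartmental model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioud)
```

## Model and assumptions

The package models illicit opioid use disorder (IOUD) in a homogeneously
mixing population of a reference city (about 200,000 people). Four
compartments — susceptible S, active disorder I, specialty treatment T,
recovered R — exchange flows as in the equations shown on the package
README. The modelling assumptions that matter:

* **Recovery is not immunity, and it is not susceptibility either.**
  Recovered individuals form their own class with permanent relapse risk,
  both spontaneous (`alpha1`) and contact-driven (`alpha2 R I/N`); they
  never return to S.
* **Treatment entry saturates.** The factor `b(T) = 1/(1 + epsilon T)`
  multiplies all three routes into specialty treatment, modelling limited
  facility capacity. `epsilon` has units 1/person: at the baseline
  `epsilon = 0.0313`, an occupancy of T = 95 already throttles entry to
  about a quarter of its unsaturated rate.
* **Demography is constant-recruitment.** `Lambda = 2500` persons/year
  and `mu = 1/80` give a disorder-free population of exactly 200,000; the
  total population obeys `dN/dt = Lambda - mu N - delta I`.
* **Overdose death is an extra removal from I only,** at rate `delta`,
  either constant or following the fitted calendar trend.

Baseline rates (per year unless noted): `beta = 0.09`, `rho = 0.1`,
`epsilon = 0.0313` (1/person), `omega = 0.04` (estimated against the
surveillance series); `alpha1 = 0.2`, `alpha2 = 0.01`, `kappa = 0.4`,
`mu = 0.0125`, `eta1 = 0.5`, `eta2 = 0.1`, `eta3 = 0.17` (literature);
`Lambda = 2500`. The baseline initial state at 2002 is
(199500, 102, 95, 100).

## The death-rate trend

The yearly data-derived rate is
`delta = 0.8 * heroin deaths / (0.903 * past-year HUD count)`: 0.8 is the
assumed fraction of heroin overdose deaths occurring within the
heroin-use-disorder (HUD) class, and 0.903 converts a past-year survey
count into an average-during-year count (it is itself a model output; see
below). The trend is fit as an early constant (ordinary least squares over
2002–2010, i.e. the mean) plus a late straight line (2011–2019), joined at
their intersection. The package's canonical constants are the published
ones (constant 0.0080891345, slope 0.002307120199666, intercept
4.630363924326326, breakpoint 2010.4947542468); refitting from the
6-decimal printed column reproduces them to about 1% — the original fit
used unrounded rates, so the printed constants are treated as canonical
and the refit as approximate. Whether 2010 belongs to the early or late
window is not stated anywhere authoritative; the package defaults to
early = 2002–2010 (matching the observation that the rise starts around
2011) and both windows are arguments.

Extrapolation past 2020 continues the sloped branch. For sensitivity runs
it is reparameterized as `delta(t) = m (t - 2020) + b * 0.006483049602509`
so that scaling `b` shifts the 2020 level proportionally and scaling `m`
scales only the slope.

The 0.6874 specialty-treatment factor (the share of specialty-treatment
counts attributable to the HUD class, averaged over the four survey years
where the split was asked) is applied at data-loading time to years
lacking a direct count, and those rows are flagged. Its inputs are not
recomputable from the packaged table, so it is a configurable constant.

## Integration and per-year bookkeeping

The integrator is an in-package Dormand–Prince 5(4) adaptive step
(`rtol = atol = 1e-9`) written in Rcpp; the system is non-stiff at every
parameter set used here, and the integrator is cross-checked against a
fixed-step Euler oracle in the tests. Integration restarts at every
calendar-year boundary and at the trend breakpoint (the right-hand side
has a corner there). "Year Y" always means the half-open interval
[Y, Y+1). Floating-point undershoots of a compartment are clamped to zero
down to −1e-8 persons; anything lower aborts with an error.

Eighteen auxiliary coordinates ride along with the state: cumulative
flows (incidence, relapses from T and from R, overdose deaths, non-death
leavers of I and of T), three within-year sub-compartments, three return
accumulators, the integrals of I and T, and four integrals of the
year-to-date leaver/return counts. All are reset at year boundaries after
emitting a tally row, so tallies are exact ODE solutions, not post-hoc
quadrature.

## Past-year prevalence corrections

Annual surveys count anyone who was in a class at any time in the past
year. The model analogue of "past-year I" is assembled per calendar year
as

    past_year_I = mean(I) + mean(L(t)) - mean(B(t))

where `L(t)` is the year-to-date count of individuals who left I during
the year (flows into T and R; deaths excluded — the deceased are not
surveyed) and `B(t)` the year-to-date count of leavers who already
returned. All three components are **yearly averages of instantaneous
quantities**: an early design used the year-end cumulative leaver and
return flows instead, but that convention gives an average mean-to-
past-year ratio of 0.839 on the baseline run, incompatible with the
published 0.903 conversion factor, while the averaged convention gives
0.909. Since every curve in the published data-match figure is a yearly
average of an instantaneous quantity, the averaged convention is the one
implemented.

The return flows use within-year sub-compartments whose defining
equations are a documented design choice (the original notation `T_I`,
`R_I`, `I_T` is used without definition): `T_I` holds the part of T that
arrived from I during the current year (inflow = the full treatment
entry, decay `kappa + rho + mu`); `R_I` holds the part of R that arrived
from I during the year, directly via `omega I` or through treatment
completion `rho T_I`, decaying at `alpha1 + mu + alpha2 I/N`; `I_T` holds
the part of I that arrived from T during the year (inflow `kappa T`,
decay at the full per-capita outflow of I). The return corrections are
`kappa T_I + alpha1 R_I` for I and
`I_T (eta1 + eta3 S/N)/(1 + epsilon T)` for T, exactly the published
estimator forms.

The `average_past_year_ratio()` of the baseline 2002–2019 run is 0.909,
within rounding of the published 0.903. The model past-year HUD series
tracks the scaled national series with a mean absolute relative error of
about 0.159; the error is dominated by survey years with large sampling
dips (2003, 2005, 2007) and by 2018–2019, where the data fall while the
model keeps rising — a divergence the source analysis itself notes. The
package's acceptance suite asserts a 0.15 bound for this error and that
assertion is left failing rather than loosened.

## Reproduction numbers

`r0_heuristic()` composes the mean untreated sojourn
`U0 = 1/(mu + delta + eta1 + eta3 + omega)` with a geometric series over
the three return cycles (I→T→I, I→R→I, I→T→R→I); `r0_closed_form()`
evaluates the printed rational expression; `r0_next_generation()` takes
the spectral radius of `F V⁻¹` over infected set (I, T, R), with the
single F entry `beta Lambda/(mu N)` evaluated at the disorder-free
population `N = Lambda/mu` (so it is just `beta` — consistent with the
closed form containing neither `Lambda` nor `N`). The three routes agree
to 1e-10 over a thousand random parameter draws in the tests.
`R_eff = R0 S/N` defaults to the current total population N(t); a fixed
reference N0 is available as an argument — on baseline runs the two
differ by under 0.3% because N varies little.

## Equilibria, folds and regions

All equilibrium analysis is at constant `delta`. Endemic states are found
by eliminating S, T, R at the limiting population
`N* = (Lambda - delta I*)/mu`: S* in closed form, T* as the unique
nonnegative root of its quadratic balance, R* linearly, leaving a scalar
residual in I* that is scanned for sign changes on a combined
logarithmic + uniform grid over (0, Lambda/delta) (boundary roots
rejected) and polished with Brent's method. Stability comes from the
eigenvalues of the full 4-dimensional Jacobian (central differences),
with "nonhyperbolic" declared when the leading real part is within 1e-8
of zero. A 4-dimensional Newton multistart serves as an independent
oracle in the tests, as does explicit two-attractor simulation in the
bi-stable window.

Without saturation (`epsilon = eta2 = 0`) the endemic condition reduces
to `I (a I² + b I + c) = 0` with the published coefficient polynomials;
eliminating N* makes the bracket an effective quadratic whose
two-positive-roots condition defines the backward bifurcation. The
critical contact-relapse rate `alpha2` (about 1208 at `delta = 0.06`) is
found by bisection on that condition to 0.1%.

With saturation the reduction is a degree-6 polynomial with an overall
factor I and one shared linear factor; `quintic_coefficients()` performs
the elimination with exact dense-polynomial arithmetic in the scaled
variable x = I·delta/Lambda (for conditioning), divides out the shared
factor, and cross-checks against an independent floating-point
interpolation at 7 Chebyshev nodes (agreement ~1e-12). Roots are
admissible only if the reconstructed state is nonnegative and matches the
nonnegative treatment branch; the elimination's boundary artifacts (at
x = 1 and at the S-denominator root) are inadmissible by construction.
The published symbolic coefficient expressions are not reproduced
anywhere accessible, so this numeric elimination with a dual-route
consistency check is the canonical implementation.

Saddle-node folds are located by sweeping one of (delta, beta, epsilon)
on a 200-point grid, bisecting the existence boundary only far enough to
bracket it (near the fold the coalescing roots fall below any fixed scan
resolution), then refining (I*, parameter) with a two-dimensional Newton
iteration on the residual and its I-derivative. `R_eff` at the fold uses
the fold equilibrium's own S*/N*. On the baseline set the folds sit at
R_eff ≈ 0.805 (delta varied at beta = 0.09) and R_eff ≈ 0.765 (beta
varied at delta = 0.0531), matching the published two-digit values 0.82
and 0.78 within their rounding and the stated tolerance. The critical
saturation `epsilon_c` for bi-stability is a bisection on endemic-state
existence (1% tolerance); no pseudo-arclength continuation is needed
because every fold curve swept here is single-valued. Under the
extrapolated trend the first integer year with no admissible endemic
state is 2038.

## Parameter estimation

`estimate_parameters()` fits (beta, rho, epsilon, omega) — bounds
rho ∈ [0.1, 0.4] and omega ∈ [0.01, 0.2] from the literature, beta > 0,
epsilon ≥ 0 — by bounded L-BFGS-B from a Latin-hypercube multistart
(fixed seed, 16 points by default). The objective sums squared residuals
of three city-scale series: past-year I, past-year T, and yearly overdose
deaths, each normalized by its own data mean — the source analysis does
not state which series entered its objective or with what weights, so
per-series mean normalization is the package's documented choice (deaths
are ~10¹, prevalence ~10²–10³; unnormalized sums would ignore deaths
entirely). The 2002 initial state is fixed, not fitted. On noiseless
synthetic data the generator's parameters are recovered to well under 5%;
with 5% multiplicative noise the median error on beta is about 10%. The
noisy-replicate tests run a reduced multistart (2 starts, 120 iterations)
to stay inside the suite's time budget; the noiseless full-multistart fit
guards the same code path.

## Sensitivity analysis

`prcc_analysis()` varies every rate and the four 2020 initial conditions
(the final state of the baseline 2002–2020 run) uniformly within ±10% of
baseline — uniformity and the design size n = 1000 are documented
defaults; the source states neither. Two death-rate scenarios: constant
`delta = 0.03002`, where delta is itself a factor, and the extrapolated
trend, where the slope `m` and level `b` replace it. Outcomes are the
four derived yearly flows (new entries to I, relapses from T, relapses
from R, overdose deaths) for the year ending at the 2030 horizon. PRCC is
computed by rank-transforming all columns and correlating the residuals
of factor-on-others and outcome-on-others rank regressions; significance
bands are pure magnitude thresholds (≥0.85 highly significant, 0.70–0.84
significant, 0.55–0.69 somewhat, 0.45–0.54 slightly, 0.40–0.44
borderline), with the sign reported separately. `mu` is flagged
non-actionable; no p-values are computed. At n = 1000 the signs of every
published constant-scenario entry with |PRCC| ≥ 0.55 are reproduced;
absolute values run somewhat higher than the published table (whose
design size is unknown), which the sign-level acceptance check
accommodates.

## Synthetic data

`generate_series()` emits the national yearly-table schema from a forward
model run: past-year I and T and yearly deaths are computed exactly as in
the fitting pipeline, up-scaled to a linearly growing national population
(the inverse of the city scaling), divided by the embedded reporting
constants (0.8, 0.6874), and optionally degraded with independent
multiplicative lognormal noise of a given CV (counts are positive and
span orders of magnitude, so multiplicative noise is the natural model).
The generator emulates the real table's schema and magnitudes but not
survey design effects (stratification, weighting, definition changes) or
autocorrelated reporting artifacts — a green round-trip test establishes
pipeline self-consistency, not robustness to real survey error. With zero
noise, re-deriving the death rate from the emitted table recovers the
generating schedule to within the ~1–3% inherent in the fixed 0.903
averaging constant.

## Known limitations

* The past-year series match sits at MARE ≈ 0.159 against the 0.15
  acceptance bound (see above); the corresponding assertion is left red.
* Equilibrium machinery assumes constant `delta`; time-varying schedules
  must be frozen at a chosen year first.
* The center-manifold claim that `epsilon = 0, alpha2 = 0, eta2 > 0`
  admits no backward bifurcation is checked numerically (admissibility
  filtering over parameter grids), not proved.
* No stochastic variant, age/spatial structure, prescription-opioid
  class, or estimation uncertainty (the analysis reports point estimates
  only).
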