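---
title: "Methods: seasonal-spatial optimization of cropland and nitrogen use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal-spatial optimization of cropland and nitrogen use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroplan)
```

`nitroplan` chains three models — a nutrient-transport stage, an
econometric land-use model, and a constrained nonlinear program — to ask
how much nitrogen runoff a country with strong seasonal and spatial
variation in cropping could avoid without losing farm revenue or food
security. This vignette documents the modelling assumptions, the tunable
parameters, the synthetic data-generating process used for testing, and
the numerical choices, in that order.

## 1. Nutrient transport and delivery ratios

The transport stage is deliberately minimal. A digital elevation model
defines a D8 flow field: each cell drains entirely to its lowest
8-neighbor, with ties broken by a fixed E, SE, S, SW, W, NW, N, NE scan so
routing is deterministic. A cell with no strictly lower neighbor is
accepted as an outlet only on the grid boundary; interior pits are an
error rather than being filled — the synthetic DEMs are constructed
pit-free, which keeps the stage free of a pit-filling algorithm whose
details would never matter downstream.

The delivery ratio of a pixel is the product of (1 − retention) over the
strictly downstream pixels on its flow path, stopping at the first stream
pixel; stream pixels deliver fully. Two conventions deserve note:

* the loading pixel's own retention is **not** applied (removal begins at
  the first downstream cell), which makes the one-intermediate-cell case
  exactly (1 − retention of that cell);
* the stream mask is supplied explicitly rather than derived from a
  flow-accumulation threshold, avoiding an extra, weakly identified
  parameter.

Pixel export is load × delivery ratio, and district export/load are zonal
sums. Because export is linear in load, running the model with and without
cropland fertilizer and differencing district totals isolates the
fertilizer-attributable delivery ratio θ exactly, independently of the
magnitude of the natural background load — a property the test suite
asserts. Districts with zero fertilizer load are flagged rather than
silently dropped. Subsurface transport is omitted: the optimizer consumes
only θ, and a landscape-constant subsurface pathway would not change the
district ranking that drives reallocation.

## 2. The land-use share system

Seasonal land-use shares (rice, non-rice, idle; idle is the residual
category) follow a logistic system. Its log-odds linearization gives six
linear equations — three seasons × two crops — whose errors are allowed to
correlate across equations. Estimation is iterated feasible GLS (seemingly
unrelated regression): OLS first, residual covariance with a
degrees-of-freedom correction (n − 4 per equation; the sample is only 64
districts), GLS, iterate until the covariance changes by less than 1e-8
(relative), at most 100 iterations.

Three design points were genuinely open:

* **One system, not three.** The six equations are stacked into a single
  system rather than three season-wise pairs. A single system yields one
  system-weighted R² and lets all cross-equation error correlations —
  including inter-seasonal ones, which are the stated reason for using SUR
  at all — improve the estimates.
* **The shared inertia coefficient.** The coefficient on the
  difference-in-initial-share regressor is restricted equal across the two
  crop equations of a season, implemented by giving both equations the
  same design column. The restriction reflects the inertia term's role as
  a season-level persistence parameter rather than a crop-specific one.
* **Zero shares.** A district–season with a zero crop or idle share has no
  finite log-odds. Rows are floored at a configurable ε = 1e-4 (with
  renormalization) rather than dropped: dropping would bias exactly the
  seasonal equations where idle land is rare, which are the economically
  interesting ones. The number of floored rows is reported.

When the residual covariance is numerically zero (noiseless data), GLS
weights are undefined and the estimator returns the exact least-squares
solution — this is what makes the noiseless-recovery tests meaningful
rather than fragile.

Price marginal effects at baseline shares are analytic,
∂s_rj/∂x_rk = s_rj(1{j=k} − s_rk)β_rk, with the derived idle response
closing each block to zero. Coefficients insignificant at the 10% level
(two-sided) are zeroed — only the price coefficients; zeroing is a policy
statement about which demand responses one is willing to act on, not a
model-selection step, and it is applied nowhere else.

## 3. Yield function, calibration, and nitrogen cost

Yield is Cobb–Douglas in nitrogen, y = δN^ρ, all other inputs absorbed
into δ. The elasticities ρ are estimated per season × crop cell from
household data, regressing asinh(yield) on asinh(urea), asinh(labor) and
the hybrid/HYV area shares with district fixed effects absorbed by
within-demeaning. The inverse hyperbolic sine is exact at zero, so zero
input records need no ad-hoc shifting; for the magnitudes in the data
(kg/acre, hours/acre) it differs from log(2x) by under 1e-4. A regressor
that is collinear after demeaning — the canonical case being an HYV share
that is one minus the hybrid share in cells where every plot is improved —
is dropped with a warning and reported. Insignificant ρ̂ are *not* zeroed;
zeroing a production elasticity would silently flatten the optimizer's
trade-off surface.

δ is calibrated per district cell as δ̂ = y_b / N_b^ρ̂, making the
calibrated function reproduce every baseline yield to machine precision
(an identity the acceptance tests check at 1e-12).

Urea is converted to nitrogen with a configurable factor (default 0.46 kg
N per kg urea) applied consistently on the input-cost and transport sides.
The nitrogen cost change Δc(N) = p_N·N/y(N) − c_b is zero at baseline and,
for ρ < 1, strictly increasing in N — diminishing returns make each
marginal kilogram buy less output — which together with the concavity of
p·y(N) keeps the optimizer's trade-off well posed.

## 4. The optimization scenarios

All scenarios minimize national export Σ θ_ir N_irj L_irj. Constraints:
revenue (district-wise in the *seasonal* scenario, national in
*seasonal–spatial* and *integrated*), national rice production at or above
baseline (kept in **all** scenarios as a standing food-security floor),
seasonal cropland potential per district, and annual harvested area at the
baseline cropping intensity. The synthetic baseline satisfies every
constraint with the revenue, rice, and annual-land constraints exactly
binding, so the baseline point is always a feasible incumbent and the
reported objective can never exceed the baseline export.

In the integrated scenario the areas are replaced by the linearized
response L_irj(x) = L̄_i(s_b + Σ_k ∂s/∂x_k · x_k) to net-price changes x,
the implied shares are kept inside [0, 1] by explicit constraints (not
post-hoc truncation, which would hide an out-of-range response from the
solver), and the revenue constraint uses the effective price
p + x + Δc(N). That bracket is implemented exactly as stated even though
the sign convention of folding a cost *increase* into a price *increase*
is debatable; with x interpreted as a net-price instrument the bracket is
the farmgate price consistent with the baseline net-price definition. Note
one consequence: the price instrument enters revenue directly, so even
when all marginal effects are zero the instrument can buy constraint
slack; the pure nitrogen-only reduction is obtained by setting the
instrument bounds to zero.

**Bounds.** N_irj ∈ [0.05·N_b, 2·max N_b]: the lower bound keeps the
Cobb–Douglas form away from its degenerate N → 0 limit, the upper bound
caps extrapolation beyond observed rates. |x| is capped at 25% of the
baseline price so the linearized area response stays in its validity
range. Both are configurable in `nitroplan_control()`.

**Solver.** The program is smooth but non-convex (bilinear objective,
power-function revenue). Small instances (≤ 60 variables) are solved by
SLSQP; larger ones by an augmented Lagrangian with an L-BFGS inner solver,
whose per-iteration cost scales linearly where SQP's grows cubically.
Analytic gradients and constraint Jacobians are supplied throughout, with
the constant (linear) Jacobian rows precomputed. Every solve is a
5-point multistart: the baseline plus seeded multiplicative jitters; every
candidate (including the raw starts) is screened by the constraint
functions and the best feasible one is kept. The contract is
solver-agnostic: the independent audit, not the solver's exit code, is the
source of truth — it re-evaluates every constraint from the raw decision
values in a separate code path at 1e-6 relative tolerance and recomputes
the objective to 1e-8.

**Verification oracle.** On 2-district × 2-season instances an exhaustive
grid search provides an independent check. Two details matter. The search
refines by re-enumerating the incumbent's cross-product neighborhood,
keeping the spacing while it improves and halving on stalls, so refining
never worsens. And it runs in two parameterizations of the area decision,
keeping the better: plain areas (cropland caps are then box edges the grid
hits exactly) and per-cell revenue u = L·y(N)·p (binding revenue
constraints are then coordinate sums the search can walk along exactly).
A single parameterization demonstrably stalls a few percent short whenever
the optimum sits on the respective curved constraint. All area (or
revenue) coordinates share one grid range, so equal-sum pair moves between
cells preserve a binding total exactly.

## 5. The synthetic study system

The generator is first-class code, not a fixture: its defaults define the
study conditions every test and the acceptance script run under.

* 64 districts × 3 seasons × (rice, non-rice, idle), the setting the
  modelling chain targets; module tests use 4–16 districts for speed and
  the acceptance checks use the stated sizes (200 replicates × 64
  districts for the share system; 500 households per cell for the yield
  function; 8×8 rasters for routing oracles; 2×2 instances for the
  optimizer oracle).
* Share noise enters on the log-odds scale (s.d. 0.15), so the SUR
  estimator is correctly specified — noise on the share scale would break
  the linearization the estimator relies on. Lagged shares come from a
  seeded latent logistic draw; the generating process of the pre-period is
  otherwise left unspecified by the framework, and a latent draw is the
  least structured choice.
* True coefficients are round numbers at empirically sensible magnitudes
  (inertia 2.5–5.0, price responses 0.04–0.40, elasticities 0.06–0.13);
  delivery ratios are drawn uniformly on [0.05, 0.35], bracketing
  plausible watershed values.
* Household yields are generated from the inverse-hyperbolic-sine form of
  the Cobb–Douglas model — asinh(yield) linear in asinh(urea),
  asinh(labor), hybrid and HYV shares plus a district effect (s.d. 0.15
  around a level that puts yields in the low thousands of kg/acre) and
  noise (s.d. 0.3). Generating in the estimator's own transform is what
  makes exact noiseless recovery a meaningful test; at the generated
  magnitudes the sample is simultaneously Cobb–Douglas in levels to about
  one part in 10⁴, and the test suite asserts that approximate identity
  separately. A configurable 5% of urea and labor records are exact zeros
  to exercise the asinh path.
* Baseline district revenue, national revenue and national rice production
  are computed *from* the generated panel rather than drawn, so the
  baseline is feasible by construction; the seasonal cropping-intensity
  potential is the baseline cultivated share plus a positive headroom
  draw, and the annual intensity equals the summed seasonal cultivated
  share (so the annual land constraint binds at baseline).
* Toy DEMs are east-tilted planes with roughness bounded below half the
  guaranteed neighbor drop — strictly pit-free by construction — with the
  stream along the last column; fertilizer loads sit on cropland pixels
  with seasonal multipliers (winter > spring > summer, dry-season cropping
  being fertilizer-intensive).

What the generator does **not** emulate: spatial autocorrelation across
districts, measurement error in shares or prices, household survey
weights, real rainfall or land-cover structure, and market-clearing price
feedback. Passing tests therefore demonstrate that the estimators and
optimizers recover the truth *under the assumed data-generating process*,
not that the assumptions hold in any particular country's data.

## 6. Degenerate inputs and edge behavior

Interior DEM pits, paths that never reach a stream, negative loads,
retention outside [0, 1], zero-fertilizer districts, all-zero share
equations, singular regressor blocks, zero baseline nitrogen with positive
yield, and misaligned marginal-effects tables all raise typed errors
naming the offending unit. The logistic transform is overflow-safe
(largest predictor factored out), so predicted shares are probability
vectors for any finite input, including log-odds of ±800.

## 7. Known limitations

* The NLP is non-convex; multistart local optimization carries no global
  certificate. The structural orderings (optimized ≤ baseline;
  seasonal–spatial ≤ seasonal) are enforced by incumbent screening and
  verified per run, and tiny instances agree with the exhaustive oracle to
  1%, but large-instance optima are best-found, not proven.
* The integrated scenario's linearized area response is only locally
  valid; the ±25% price-change bounds are a guardrail, not a structural
  estimate.
* θ is constant within district × season (linear export-input relation);
  nonlinear in-stream processes are out of scope.
* The grid oracle supports at most 4 cells with free areas — beyond that,
  exhaustive enumeration at useful resolution is not computable.
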