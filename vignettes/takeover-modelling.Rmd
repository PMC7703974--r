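---
title: "Modelling takeover responses to silent automation failures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling takeover responses to silent automation failures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An automated vehicle that silently stops steering correctly — no warning, no
chime — drifts towards the road edge until its supervising driver notices and
takes over. How quickly drivers notice, how much safety margin they keep, and
how hard they then steer, all depend on how severe the failure is and on what
else occupies the driver. This package implements the full analysis pipeline
for studying that question: the kinematics that define failure severity, a
synthetic study generator, two hierarchical Bayesian distributional models,
and a posterior-predictive layer that turns fitted models into road-departure
risk estimates.

Severity is expressed as time-to-lane-crossing at failure onset, `TLC_F`: how
long the (point) vehicle would take to cross a lane edge if the driver did
nothing. The response measure is the criticality adopted at takeover,
`TLC_T = TLC_F − RT`, the margin still in hand when the driver disengages the
automation.

## Failure geometry

A silent failure is modelled as a constant yaw-rate offset added to the
curvature-following yaw rate on a straight-plus-constant-curvature track
(16 m straight, 80 m bend, 3 m road width, 8 m/s in the default geometry).
The offset is ramped in over 0.5 s with the quintic smootherstep polynomial
$6u^5 - 15u^4 + 10u^3$; any C1 ramp would do — this one also has zero
second derivatives at its ends, so the yaw-rate derivative is smooth and the
onset is not detectable as a jerk.

The integrator (`simulate_failure()`) advances the vehicle along exact
circular arcs for the piecewise-constant yaw rate within each 1/60 s step,
matching the 60 Hz record rate of the driving simulator this emulates. The
only discretisation error is in the ramp and in locating the crossing, which
is linearly interpolated between samples. Against the closed-form off-tangent
crossing time $\sqrt{2Rd + d^2}/v$ (half lane width $d$, radius $R$, speed
$v$) the integrator agrees to well under 0.02 s across radii 80–2000 m.

Crossing uses a point-vehicle criterion — `|lateral offset| >= road_width/2`
on either edge — which is practically similar to tracking when half the
vehicle crosses the boundary. Sign convention: negative lateral offset is the
understeer side (outside of the bend). No chassis extent, wheel slip or tyre
model is included; those belong to vehicle dynamics, not to this analysis.

Two inverse tools complete the module. `solve_offset_for_tlc()` bisects on
the offset magnitude (bracket `[0, 4x the tangential offset]`, tolerance
1e-4 deg/s), exploiting that crossing time is monotone non-increasing in the
offset. `sobol_conditions()` draws failure conditions from an unscrambled
4-dimensional Sobol sequence (criticality, onset, trajectory index quantised
by quartiles, drift direction thresholded at a 70% understeer fraction). The
Sobol generator is implemented in the package (Gray-code construction with
standard Joe–Kuo direction numbers) because no quasi-Monte-Carlo package is
part of the package's dependency set; its output is pinned to reference
values in the test suite.

The four Repeated conditions (TLC_F = 2.23, 4.68, 7.12, 9.55 s at a 6 s
onset, yaw offsets 5.73, 1.20, 0.52, 0.30 deg/s) are design *inputs*: they
derive from pre-recorded automation trajectories whose state at onset is not
reproducible from the road geometry alone, so the package treats them as
given rather than recomputing them. The most critical of them is tangential —
5.73 deg/s exactly cancels 8 m/s on an 80 m bend.

## The statistical models

### Takeover timing

Observed takeover criticality in trial $i$ by participant $j$ is modelled as

$$TLC_{T,i} \sim \mathrm{Normal}(\mu_i, \sigma_i), \quad
  \mu_i = \beta_{0j} + \beta_{Fj} F_i + \beta_{Lj} L_i + \beta_{FLj} F_i L_i$$

$$\ln \sigma_i = \alpha_{0j} + \alpha_{Fj} \ln F_i + \alpha_{Lj} L_i
  \;\;\Leftrightarrow\;\;
  \sigma_i = e^{\alpha_0} F_i^{\alpha_F} e^{\alpha_L L_i}$$

with $F$ the failure criticality and $L \in \{0, 1\}$ the cognitive-load
indicator. The response is *truncated* above at each trial's own $F_i$ — a
driver cannot keep more margin than the failure allows — and *censored*
below at $E_i = F_i - (\text{trial length} - \text{onset})$: takeovers
slower than trial end are recorded only as "not observed". The likelihood is
the two-branch form

$$\text{observed: } \frac{\phi((T-\mu)/\sigma)/\sigma}{\Phi((F-\mu)/\sigma)}
  \qquad
  \text{censored: } \frac{\Phi((E-\mu)/\sigma)}{\Phi((F-\mu)/\sigma)}$$

evaluated in log space so that trials with strongly negative $E$ (the
vehicle would leave the road long before trial end) contribute vanishing
censored mass without underflow. The generator draws from exactly this
process by inverse-CDF sampling and latent-scale censoring, so generator and
likelihood agree by construction; a quadrature test confirms observed
density plus censored mass integrates to one within 1e-4.

The log-sigma submodel uses natural logarithms; $\alpha_F$ near 1 means the
spread grows essentially linearly with criticality, with $e^{\alpha_0}$ the
proportionality constant (about 8% of $F$ at the default values).

### Maximum steering correction

The magnitude of the initial steering correction, `SWA_Max` (the largest
unsigned steering-wheel-angle deviation within 2 s of takeover, see
`swa_max_from_trace()`), follows a lognormal power law in the criticality at
takeover $T$:

$$\ln SWA_{Max,i} \sim \mathrm{Normal}(\gamma_{0j} + \gamma_{Tj} \ln T_i +
  \gamma_{Lj} L_i + \gamma_{TLj} \ln T_i L_i,\; \sigma)$$

On the arithmetic scale the coefficients are multiplicative: $e^{\gamma_0}$
is the geometric-mean correction at $T = 1$ s, $2^{\gamma_T}$ the factor per
doubling of $T$, and $e^{\gamma_L}$ the load multiplier (0.88 at the default
values — a 12% attenuation under load).

### Hierarchy, priors, and sampling

Participant coefficients are modelled as normal random effects centred on
the population values. Two design choices depart from common defaults and
deserve justification:

* **Independent random effects.** The population description publishes
  between-participant SDs but not their correlations, and the generator's
  default is therefore zero correlation. The fitted model mirrors that:
  each coefficient gets an independent normal random effect. This makes the
  fitted model exactly the generating model, which is what the calibration
  tests require; fitting an unidentified correlation structure would add
  noise without a target to recover. The correlation matrices in
  `population_params()` remain configurable for sensitivity analyses.

* **Centred parameterisation.** With 192 trials per participant the random
  effects are data-dominated, which is the regime where the centred
  parameterisation mixes well and the non-centred one mixes poorly (the
  opposite of the sparse-data funnel regime). This was confirmed empirically
  at full design size: non-centred chains stalled (split-R̂ ≈ 8 on the mean
  submodel), centred chains converge (split-R̂ ≈ 1.01) in about a minute.

Priors are weakly informative and configurable via `prior_spec()`:
Normal(0, 2) on fixed effects (seconds / log scales), half-Normal(0, 1) on
random-effect SDs and on the steering residual SD.

Sampling is Gibbs/slice MCMC in JAGS, which supports the
truncated-and-censored normal natively (`T(,)` bounds plus interval
censoring with latent responses for censored trials). The model density is
the package's contribution — `loglik_tlc()` and `loglik_swa()` spell it out
and the tests verify it against quadrature and lognormal oracles — while the
sampler is infrastructure. Default settings (2 chains, 1000 adaptation,
1000 burn-in, 500 retained draws thinned by 3) fit the full 20 x 192 design
in roughly two minutes on one CPU. The convergence gate warns when split-R̂
exceeds 1.05; diagnostics are always attached to the fit and reported by
`print()`.

## The synthetic-data generator

`generate_study()` is the stand-in for raw simulator data and is itself
first-class, tested code. Its defaults *are* the study conditions: 20
participants, 192 trials each (2 loads x 2 bend directions x (6 repetitions
x 4 Repeated + 24 Non-Repeated conditions)), 15 s trials, Non-Repeated
criticalities spanning 2.95–19.51 s and onsets 5–9 s from the Sobol design,
generating coefficients at the published posterior means with their
published between-participant SDs.

Two generator parameters are package assumptions rather than published
values: the steering model's residual SD (0.35 on the log scale — chosen to
give realistic trial-level scatter of roughly ±40% around the power law,
comparable to the spread visible in published log-log scatter plots) and the
zero random-effect correlations discussed above. Both are configurable and
flagged as such in the documentation.

What the generator deliberately does not emulate: continuous steering traces
(SWA_Max is generated at the scalar level the model uses), the auditory
distraction task itself (load is a design indicator), pre-onset takeovers
(the generative model is conditional on a valid response; the exclusion rule
for them is still implemented and tested against hand-built records), and
any bend-direction asymmetry (directions are treated as exchangeable, as in
the models). Passing recovery tests therefore show that the inference
machinery is correct and calibrated for data with this structure — they do
not validate the behavioural assumptions against real drivers.

The exclusion rules mirror the study's bookkeeping: pre-onset takeovers are
dropped from all analyses; takeovers within 0.25 s of trial end keep their
timing observation but lose their steering observation (the correction
cannot complete). `apply_exclusions()` reports counts for both rules plus
the censoring rate.

## Posterior prediction and risk

`predictive_tlc()` nests three uncertainty sources, each separately
switchable: *estimation* (draw population parameters from the posterior;
otherwise posterior medians), *between* (draw a new driver from the
random-effect distribution; otherwise the population means), *within* (draw
a trial from the driver's truncated normal; otherwise return the mean).

`cv_decompose()` attributes the predictive coefficient of variation
sequentially — CV(within), CV(within+between) − CV(within), CV(all) −
CV(within+between) — so components sum to the total exactly. The ordering
within → between → estimation follows the convention of reporting
within-trial noise as the base layer and estimation uncertainty as the
increment over a median-parameter prediction. Common random numbers are
shared across the three nested simulations, otherwise the differences would
be dominated by Monte Carlo noise. One consequence of the zero-correlation
default is worth noting: under cognitive load the extra load random effects
add uncorrelated between-driver variance, which brings the between component
close to (and depending on the fitted posterior, occasionally level with)
the within component; without load, within-participant variability is
clearly the largest share.

`p_exit()` defines an unsafe outcome as takeover criticality below a safety
threshold (default 0.5 s — roughly the smallest margin at which drivers who
stayed in lane have been observed to recover, chosen conservatively).
Per simulated driver the exit probability is the truncated-normal CDF mass
below `threshold + delay`, normalised over the truncated support on which
the model is defined; the population value averages over drivers (and,
through the driver sample, over the posterior), and 68.3%/95.5% bands are
quantiles of the driver-level distribution. Additional response delay is
handled by shifting the threshold, which is equivalent to delaying every
response and numerically simpler. `exit_risk_curve()` shares one driver
sample across the criticality grid so curves are smooth, and flags grid
points outside the fitted criticality range as extrapolation.

A fitted posterior is not required: `point_posterior()` wraps published
point parameters as a degenerate posterior so the same machinery runs from
a parameter table, with the caveat (documented on the object) that
random-effect correlations are unavailable and taken as zero.

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse-CDF transform; at the default
  parameter values the truncation point sits several SDs above the mean, so
  no special tail handling is needed. `sigma = 0` short-circuits to the
  (clamped) mean, which the structural tests rely on.
* `hdi()` is the shortest sorted window containing the requested mass;
  constant samples give a zero-width interval.
* Exponentiated summaries ($e^{\alpha_0}$, $e^{\gamma_L}$, ...) are computed
  draw-wise and then summarised — never the exponential of a summary — so
  Jensen's inequality is respected.
* Empty data with proper priors reproduces the prior (tested); single
  participants can be fitted with `hierarchical = FALSE`, which matches a
  flat maximum-likelihood fit within sampling error.
* Trials with negative censoring bounds are handled in log space and are
  effectively uncensorable.

## Problem sizes used in the checks

The packaged checks fit the full 20 x 192 design with 2 chains x 500
retained draws (about two minutes for the timing model, seconds for the
steering model), and assess HDI calibration over 20 reduced studies
(6 participants x 48 trials, short chains), sizes chosen to exercise the
full pipeline at desk scale. Recovery at this scale is limited by the
finite participant sample: the posterior mean tracks the *sample* mean of
the 20 drawn participants, whose SE is roughly $sd_j/\sqrt{20} \approx$
0.02–0.07 per coefficient. Deviations of recovered values from the
generating constants at a single seed are of exactly that order and are not
evidence of bias; across seeds the recoveries centre on the truth.

## Known limitations

* The point-vehicle TLC ignores vehicle extent and dynamics, and `TLC_T`
  treats the takeover instant as the end of the story; post-takeover
  steering quality is outside the model.
* The within-participant spread grows without bound in $F$ under the
  log-linear submodel; censoring at trial end makes any upper bound on
  $\sigma$ unidentifiable from data of this design, so predictions far
  beyond the fitted criticality range should not be trusted (the risk-curve
  machinery flags extrapolation).
* Random-effect correlations are zero by assumption, which inflates
  between-driver spread relative to a correlated truth; absolute CV shares
  and risk magnitudes inherit that assumption, orderings are more robust.
* The four Repeated criticalities are design inputs tied to unpublished
  automation trajectories and are not re-derivable from geometry alone.
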