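# silentfail

Modelling how supervising drivers detect and respond to **silent failures**
of automated lane keeping — faults that produce no alert, so the vehicle
simply drifts towards the road edge until the human notices and takes over.
The package is aimed at human-factors and road-safety researchers who need
to (a) design takeover experiments with controlled failure criticality,
(b) fit distributional models of takeover behaviour that respect the
truncation and censoring such experiments impose, and (c) turn fitted models
into applied predictions such as road-departure probabilities for real road
designs.

## The models

Failure severity is expressed as time-to-lane-crossing at failure onset,
`TLC_F`: the time until the (point) vehicle would cross a lane edge with no
intervention. The response is the criticality adopted at takeover,
`TLC_T = TLC_F − RT`.

**Takeover timing** is a hierarchical heteroscedastic normal model,
truncated above at each trial's own `TLC_F` (you cannot keep more margin
than the failure allows) and censored below at the trial-end threshold
`TLC_End` (slower takeovers are never observed):

    TLC_T[i] ~ Normal(mu[i], sigma[i])          truncated at F[i], censored at E[i]
    mu[i]    = beta0[j] + betaF[j] F[i] + betaL[j] L[i] + betaFL[j] F[i] L[i]
    ln sigma[i] = alpha0[j] + alphaF[j] ln F[i] + alphaL[j] L[i]

with `L` the cognitive-load indicator and `j` the participant; participant
coefficients get normal random effects.

**Maximum steering correction** `SWA_Max` (largest steering-wheel deflection
within 2 s of takeover) follows a lognormal power law in the criticality at
takeover `T`:

    ln SWA_Max[i] ~ Normal(gamma0[j] + gammaT[j] ln T[i] + gammaL[j] L[i]
                           + gammaTL[j] ln T[i] L[i], sigma)

Both models are fitted by MCMC (JAGS, which handles the truncated/censored
normal natively). A posterior-predictive layer provides predictive intervals
for unseen drivers, a within/between/estimation decomposition of predictive
variability, and `P(Exit)` — the probability that a failure ends with less
takeover margin than a safety threshold (default 0.5 s).

A synthetic-study generator (`generate_study()`) reproduces the full study
design — 20 participants x 192 trials over 28 failure conditions, with
truncation, censoring and the study's exclusion rules — so the entire
pipeline runs without any raw data.

## Worked example

```r
library(silentfail)

## Where do real road designs sit on the criticality axis?
scenario_tlc(500, 60, 3.65, "mph")   # rural bend      -> 1.59 s
scenario_tlc(2000, 70, 3.65, "mph")  # motorway bend   -> 2.73 s

## Synthetic study at the default generating values, study exclusion rules
trials <- generate_study(seed = 42)
ex <- apply_exclusions(trials)
#> Exclusions: 0/3840 trials pre-onset (0.0%) removed;
#>   47 takeovers within the final window (SWA_Max invalidated);
#>   729 censored trials (takeover observed in 81.0% of trials)

## Fit the takeover-timing model
fit <- fit_tlc(ex$trials, control = mcmc_control(seed = 1))
fit
#> Hierarchical Bayesian model of takeover timing (truncated/censored normal)
#>   3111 observed trials + 729 censored, 20 participants
#>   2 chains x 500 draws; max split-Rhat 1.014, min ESS 130
#>
#> Posterior means of fixed effects:
#>  beta0  betaF  betaL betaFL alpha0 alphaF alphaL
#>  0.350  0.333 -0.066 -0.003 -2.393  0.945  0.057
```

`beta0` ≈ 0.35 s is the floor on adopted margin; `betaF` ≈ 0.33 means each
extra second of failure budget adds about a third of a second of margin
(reaction times slow by the remaining two thirds); negative `betaL` says
cognitive load erodes the margin. `summary(fit)` adds 95% HDIs and the
multiplicative twins (`exp(alpha0)` ≈ 0.09: trial-to-trial spread is about
9% of `TLC_F`).

```r
## Road-departure risk for an off-tangent failure on a 2 s bend
p_exit(fit, tlc_f = 2, load = 0, seed = 1)
#> P(Exit) at TLC_F = 2.00 s (load 0, threshold 0.50 s, delay 0.00 s):
#>   mean 10.038%, 68.3% band [0.000, 20.056]%, 95.5% band [0.000, 86.133]%
p_exit(fit, tlc_f = 2, load = 1, seed = 1)$mean * 100
#> 16.4   # risk is higher under cognitive load

## Which uncertainty dominates predictions?
cv_decompose(fit, n_sim = 20000, seed = 2)
#> Predictive CV decomposition (within + between + estimation = total)
#>  load within between estimation total
#>     0  0.213   0.224      0.029 0.466
#>     1  0.233   0.259      0.033 0.525
```

Trial-to-trial (within) and driver-to-driver (between) variability dwarf
estimation uncertainty — predictions are limited by human variability, not
by sample size. (Absolute shares depend on the random-effect correlations,
which default to zero; see the methods vignette.)

```r
## Steering model: corrective aggression scales as a power law of margin
sfit <- fit_swa(ex$trials, control = mcmc_control(seed = 2))
coef(sfit)
#>  gamma0  gammaT  gammaL gammaTL
#>   3.507  -0.814  -0.152   0.013
```

`gammaT` ≈ −0.8: halving the margin at takeover multiplies the steering
correction by about 2^0.8 ≈ 1.8; `exp(gammaL)` ≈ 0.86 is a ~14% attenuation
of steering under load in this synthetic sample.

Other entry points: `failure_conditions()` / `sobol_conditions()` for
experimental design, `simulate_failure()` + `time_to_lane_crossing()` for
trajectory-level work, `predict()` / `plot()` on fits for predictive bands,
`exit_risk_curve()` for risk as a function of criticality, and
`takeover_cli()` (wrapped by `inst/exec/silentfail`) for shell use.

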