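# fovadapt

Analysis of whole-body motor adaptation in fish-operated-vehicle (FOV)
experiments. An FOV is a wheeled platform steered by a fish in an onboard
water tank: the fish's heading maps to the vehicle's motion direction, and
the experimenter can insert a fixed rotation (e.g. 45° to the right) between
the two. Across sessions the fish compensates; removing the rotation reveals
an aftereffect; re-introducing it probes savings. fovadapt is for
researchers running or re-analysing such adaptation protocols: it turns raw
vehicle trajectories into performance measures, fits Bayesian learning
curves, and quantifies stage differences.

## The model

Three per-trial measures describe performance: the session success count
(0–6), the signed angular error (the angle between the start→end and
start→target directions, clockwise positive), and the adjusted distance
*d* = *len* for successful trials and *len* + *EAL* otherwise, where
*EAL* = *eff* · *ET* penalises failed trials by the end-to-target distance
scaled by the session's efficiency *eff* = Σ*len* / Σ*SE*.

Session-level performance follows an exponential learning curve,

    μ̂(ses) = A_μ exp(−ses/τ_μ) + μ_∞,    σ̂(ses) = A_σ exp(−ses/τ_μ) + σ_∞,

with measure-specific likelihoods at trial level: Poisson(μ̂) for success
counts, Student-t(μ̂, σ̂, ν) for angular errors, Gamma(mode = μ̂, sd = σ̂)
for distances. Fish-level parameters sit in a population hierarchy (Gamma
priors for positive parameters, Normal for continuous ones, Exponential for
ν), sampled with JAGS (4 chains × 1000 warm-up + 1000 draws by default).
Fits are summarised by three derived parameters — initial value A_μ + μ_∞,
asymptotic performance μ_∞, and initial learning rate −A_μ/τ_μ — with 94%
highest-density intervals, and stages are compared through the posterior of
their differences against regions of practical equivalence (1
success/session, 5°, 2 m).

A two-tier simulator closes the loop: trial-level draws from the
likelihoods for parameter-recovery studies, and a kinematic agent that
drives the vehicle under rotational perturbation with an exponentially
relaxing heading bias, producing raw trajectories whose measured angular
error decays with the configured time constant by construction.

## Worked example

Simulate a small 45°-rotation cohort, compute metrics, and fit the angular
learning curve:

```r
library(fovadapt)

cfg <- simulation_config(n_fish = 4, stages = c(rotation = 15),
                         rotation = c(rotation = 45))
cohort  <- generate_cohort(cfg, seed = 7)
metrics <- compute_trial_metrics(cohort$samples)
sessions <- summarize_sessions(metrics)
head(sessions[, c("fish_id", "session", "success_count",
                  "median_angular_error_deg", "median_d_m")], 4)
#>   fish_id session success_count median_angular_error_deg median_d_m
#> 1  fish01       0             0                 48.80682   7.162207
#> 2  fish01       1             0                 34.81781   7.902245
#> 3  fish01       2             1                 27.67591   7.177629
#> 4  fish01       3             0                 22.12820   7.146776

model <- build_model(metrics, "angular", stage = "rotation")
fit <- sample_posterior(model, chains = 4, tune = 3000, draws = 1000, seed = 7)
fit
#> fov_fit: angular / rotation, 4 fish, 4000 draws (4 chains)
#>               parameter      median    hdi_low  hdi_high
#>           initial_value  42.0479147  27.308107 55.628744
#>  asymptotic_performance   0.3449514  -9.235149  7.688883
#>   initial_learning_rate -10.4775572 -16.622559 -5.477112
#> WARNING: max split-R-hat 1.235 exceeds 1.01
```

The fish start about 42° off target (the generator's agents initially miss
by the full 45° rotation), converge to an asymptote near 0°, and improve
by ~10°/session initially (the generator's time constant is 4 sessions:
45/4 ≈ 11). The convergence warning here is informative, not cosmetic: this
synthetic cohort has *constant* trial-to-trial spread, so the spread-curve
amplitude `A_sigma` sits at its zero boundary and mixes slowly; the curve
parameters above are well mixed (their split-R-hats are ≈ 1.00). Stage
comparisons then go through `compare_stages(fit_rotation, fit_savings,
"initial_learning_rate")` and `learning_rate_slope()`.

A thin command-line driver wraps the same functions
(`inst/cli/fovadapt.R`, subcommands `simulate`, `metrics`, `fit`,
`compare`).

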