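---
title: "Modelling motor adaptation in fish-operated-vehicle experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motor adaptation in fish-operated-vehicle experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovadapt)
```

## The experiment and the data

A fish-operated vehicle (FOV) is a wheeled platform carrying a water tank.
A camera tracks the fish in the tank, and whenever the fish swims near a
tank wall facing outward, the vehicle drives in the direction the fish is
facing. A trained goldfish can steer the vehicle from a start point to a
target about 2.5 m away to earn a food reward. The interesting manipulation
is a *rotational perturbation*: the control loop rotates the mapping from
fish heading to vehicle motion by a fixed angle (for example 45 degrees to
the right), and the fish must adapt. The schedule has five stages —
baseline, rotation, washout, savings (re-rotation), final — with sessions of
six trials each and a 3-minute limit per trial.

fovadapt analyses such experiments at three levels: per-trial performance
metrics, hierarchical Bayesian learning curves over sessions, and posterior
stage comparisons. A simulator generates fully synthetic cohorts so that
every stage of the pipeline can be exercised, and its calibration checked,
without animal data.

## Trial metrics

Each trial yields a timestamped vehicle trajectory. After cleaning
(untracked frames are dropped, gaps shorter than 1 s are bridged by linear
interpolation, and coordinates pass through a window-3 running median that
keeps the endpoints fixed), three measures are computed:

* **Success**: whether the final point of the trial lies in the target area;
  the per-session success count is the measure (0–6). When the input records
  an explicit trial outcome, that record wins; otherwise a closed disc of
  configurable radius (default 0.25 m) around the target centre is used. The
  physical target board is not dimensioned more precisely than this, which
  is why the disc is configurable and a recorded outcome takes precedence.
* **Angular error**: the signed angle at the start point between the
  start-to-end direction and the start-to-target direction, computed with
  the full-quadrant arctangent of the cross and dot products of the two
  vectors. Positive angles are clockwise, the direction a +45-degree
  rightward perturbation pushes an unadapted fish, so early rotation-stage
  errors are positive by convention. A literal `arctan(dy/dx)` of the end
  point would be quadrant-ambiguous and frame-bound, which is why the
  two-vector form is used.
* **Distance travelled**: the polyline length `len` of the trajectory. For
  failed trials this underestimates the work remaining, so the *estimated
  additional length* `EAL = eff * ET` is added, where `ET` is the
  end-to-target distance and `eff = sum(len) / sum(SE)` is the session's
  efficiency (total path length over total start-to-end displacement). The
  adjusted distance is `d = len` for successes and `len + EAL` otherwise.

Sessions are summarised by the success count and the medians of the other
two measures; even-length medians use the mean of the two middle values.
Zero-displacement trials have no defined direction: they are excluded from
angular-error medians and counted as failures. A session whose start-to-end
displacements all vanish has no defined efficiency; this raises an error by
default, with an explicit opt-in (`allow_degenerate_efficiency`) that
substitutes `eff = 1` with a warning.

The baseline advancement criterion mirrors the training protocol: a fish
leaves baseline when, over three consecutive sessions, the median session
success count is at least 4, the absolute median angular error over the
window's trials is below 15 degrees, and the median adjusted distance is
below 4.5 m, within a cap of 25 baseline sessions. The amplitude of the
criterion is evaluated per window by pooling the window's trials, which is
how `baseline_criterion()` is tested against an exhaustive window scan.

## The learning-curve model

Performance on session `ses` (0 = first session of a stage) is modelled as
an exponential relaxation,

    mu(ses) = A_mu * exp(-ses / tau_mu) + mu_inf,

and the dispersion of trial-level data around it as

    sigma(ses) = A_sigma * exp(-ses / tau_mu) + sigma_inf,

sharing the time constant `tau_mu` (an option to decouple the two constants
exists in the parameter bundle but the shared form is the default, as the
model is usually written). Three derived quantities characterise learning:
the initial value `A_mu + mu_inf`, the asymptotic performance `mu_inf`, and
the initial learning rate `-A_mu / tau_mu`, which is the slope of the mean
curve at `ses = 0`. Each stage is fitted with its own parameter set, so
"initial value" always refers to the start of the stage at hand.

Each measure gets a likelihood matched to its type:

* success counts: Poisson with rate `mu(ses)`, one count per session. The
  Poisson support is unbounded even though counts cannot exceed 6; the
  likelihood is kept as-is (the standard form for this analysis), and the
  simulator logs how often its clipped draws actually hit the bound so
  recovery studies quantify the mismatch. Because success *improves* upward,
  its amplitude is negative; the model parameterises the amplitude magnitude
  and fixes the sign from the measure's improvement direction.
* angular errors: Student-t with location `mu(ses)`, scale `sigma(ses)` and
  degrees of freedom `nu` shared across all fish. The "std" of this
  likelihood is interpreted as the scale parameter, not the standard
  deviation `sqrt(nu/(nu-2)) * scale`; the distinction only matters at small
  `nu` and is documented because the two readings are both plausible.
* distances: Gamma parameterised by mode `mu(ses)` and standard deviation
  `sigma(ses)`. The closed-form conversion to shape and rate
  (`rate = (mode + sqrt(mode^2 + 4 sd^2)) / (2 sd^2)`, `shape = 1 + mode *
  rate`) always yields `shape > 1`, i.e. a proper interior mode.

The Poisson mean must stay positive; inside the sampler it is guarded with
`max(mu, 0.001)` so that tail excursions of the amplitude do not crash the
chain. The guard is three orders of magnitude below any realistic rate.

## Hierarchy, priors, sampling

Fish share population-level structure: each fish-level parameter is drawn
around a population location with a population spread. Positive parameters
(time constants, spread parameters, and the amplitude magnitude and
asymptote of the positive-mean measures) are hierarchical on the log scale
(log-normal around the population location); the angular measure's amplitude
and asymptote are normal. Prior families follow the nature of each
parameter: Gamma for positive parameters, Normal for continuous ones,
Exponential (mean 30) for `nu`.

Two deliberate sampler-facing choices:

* **Parameterisation by identification strength.** With dozens of trials
  per fish the fish-level parameters are strongly identified by their own
  data; in that regime non-centred offsets create a ridge between the
  offsets and the population location that a Gibbs/slice sampler traverses
  very slowly (effective sample sizes of tens), so the trial-level models
  (angular, distance) use centred hierarchies — the opposite of the usual
  advice for sparse-data HMC fits, and deliberately so. The session-level
  Poisson model is the exception: its amplitude and time constant are
  weakly identified (one count per session), centring them invites a sticky
  spurious mode at amplitude zero, and those two parameters are therefore
  non-centred while the well-identified asymptote stays centred.
* **Spread hyperpriors bounded away from collapse.** With cohorts of ~8
  animals, a spread prior with substantial mass at zero lets the population
  interval collapse onto the realised cohort mean and undercover. Spread
  parameters get Gamma(3, 3/centre) priors (centre 0.3 on the log scale),
  broad on the right but with little mass near zero.

Prior centres are empirical-Bayes in spirit: the asymptote centre is the
median of the last third of sessions, the amplitude centre is the *first
session's* median minus the asymptote centre (the first-third median would
systematically underestimate amplitudes when the time constant is short,
because the curve has already decayed within the first third), and the time
constant centre is one third of the stage length. Amplitude centres of the
positive-mean measures are floored at the data's scale: the first-vs-last
contrast is a noisy guess estimated from the same data, and a Gamma prior
whose rate is tied to a collapsed contrast would actively exclude real
amplitudes — simulation shows exactly this overconfidence (intervals ~20%
too narrow) without the floor. Spread-curve centres come
from within-session residual MADs at trial level, since medians of session
medians hide trial-level dispersion. Widths are broad: Gamma shapes 1.2–1.5
for the weakly identified curve parameters, and Normal widths of twice the
data scale. Prior predictive simulation (`prior_predictive()`) is the tool
for checking that these choices generate all plausible data sets.

Sampling uses JAGS with 4 chains, 1000 warm-up iterations (split between
adaptation and burn-in) and 1000 retained draws per chain by default, i.e.
8000 retained samples. Every chain's RNG is seeded deterministically from
the call's single integer seed, so fits are exactly reproducible.
Diagnostics attached to each fit are split-R-hat (computed over half-chains)
and effective sample size for every monitored parameter; a fit is flagged
when any split-R-hat exceeds 1.01. Divergence counts, which the fit object
also carries for interface completeness, are a Hamiltonian-Monte-Carlo
concept and are reported as `NA` under the Gibbs backend — R-hat and ESS
carry the convergence contract here.

## Posterior summaries and stage comparisons

Results are reported as posterior medians with 94% highest-density
intervals. The HDI of a sample is the shortest contiguous window of sorted
draws containing 94% of them, with the leftmost window taken on ties; a
heuristic warns when the draws look multimodal (a deep interior trough in
the histogram), since a contiguous interval is then misleading.

Stage comparisons use a region of practical equivalence (ROPE) per measure:
differences of 1 success/session, 5 degrees, or 2 m are treated as
practically zero, and the reported quantity is the fraction of the
difference posterior inside the ROPE. Two independent stage fits are paired
draw-by-draw after a deterministic permutation derived from the seed and
each fit's identity; the pairing of independent posteriors is arbitrary, and
this scheme makes comparisons reproducible, exactly antisymmetric under
swapping the fits, and degenerate (all-zero differences) when a fit is
compared with itself.

The across-stage learning-rate relationship ("do fast first-exposure
learners relearn fast?") is computed as a Bayesian simple linear regression
of second-exposure initial learning rates on first-exposure rates across
fish. The default uses each fish's posterior median rate as a point; a
measurement-error variant that propagates each fish's posterior spread sits
behind a flag. Both are provided because the estimator behind the published
summary statistic is not fully specified; the regression's residual
variance carries a 0.5%-of-scale noise floor so exactly collinear inputs
(e.g. a stage compared with itself) keep a proper posterior.

## The simulator

The generator produces data at two tiers.

The **likelihood tier** (`draw_measures()`) draws trial-level measure values
directly from the three likelihoods along known fish-level curves, with
fish-level parameters drawn around population truths following the model's
own hierarchy. Its default truths describe a 45-degree rotation stage:
success rising from about 1.9 to 3.4 successes/session, angular error
decaying from about 11 degrees to 0, distance from 6 m toward 3.8 m, with
time constants implied by the corresponding initial learning rates. This
tier is the basis of the parameter-recovery study (`recovery_study()`):
20 cohorts of 8 fish x 15 sessions x 6 trials per measure, each fitted and
scored on whether the population 94% HDIs cover the generating truths.

The **trajectory tier** (`simulate_trial()`, `generate_cohort()`) produces
raw vehicle tracks. The simulated agent commits, at trial start, to a
heading equal to its bearing to the target plus a learned bias plus von
Mises aim noise (concentration 20 by default, about 13 degrees circular SD),
and the vehicle then integrates `speed * dt` steps of
`pose_to_motion(heading, rotation)` until it enters the target disc, leaves
the arena, or times out after 3 minutes. The bias relaxes exponentially
toward full compensation of the current stage's rotation with the fish's
time constant, and carries over between stages, so washout starts with a
leftward aftereffect for free. Defaults: 0.15 m/s vehicle speed (a straight
drive takes ~17 s), a 12 Hz control step, a 6 x 6 m arena.

The open-loop aim is a deliberate modelling decision, not an oversight: an
agent that continuously re-aims at the target under a constant bias follows
a pursuit spiral that still reaches the target, so its start-to-end angular
error would *not* equal the bias, and the session medians would not decay
exponentially. With per-trial aim, the measured angular error equals the
commanded offset exactly, which makes the simulator's learning curves
exponential by construction and lets a noiseless cohort recover the
configured time constant to numerical precision.

What the trajectory tier does **not** emulate: within-trial error
correction (real fish steer back), the wall-zone gating of vehicle motion
(the vehicle only moves when the fish is near a wall facing outward; a
stationary-dwell probability can reintroduce idle time), water and floor
dynamics, and any savings mechanism (relearning in the savings stage uses
the same time constant, so simulated cohorts show no savings unless
configured to). Passing recovery tests on synthetic data therefore
demonstrates that the inference machinery is calibrated for the stated
model, not that the model captures every feature of animal data.

## Problem sizes and numerical choices

The shipped tests exercise the pipeline at the cohort sizes above; the
recovery study runs reduced chains (success: 4 chains x 5000 draws after
5000 warm-up, which is cheap because the Poisson model sees only 120 counts,
but necessary because its amplitude/time-constant ridge mixes slowly; the
trial-level models mix well and run at 2 chains x 1000 after 1500 warm-up
for the angular measure and 2 x 500 after 800 for the distance measure). The
acceptance script simulates an 8-fish, 40-session trajectory cohort and
fits all three measures in a couple of minutes.

Other numerical conventions collected in one place: angles live in
(-180, 180] with clockwise positive; even-length medians average the two
middle values; the target disc is closed (boundary counts as success);
single-sample trajectories have length 0 with a warning; trials ending at
the boundary or by timeout are failures and enter the EAL correction; HDI
ties break leftmost; all stochastic functions take explicit integer seeds
and JAGS chain seeds derive from them.

## Known limitations

* The Poisson likelihood ignores the hard ceiling of 6 successes/session;
  near-ceiling cohorts will show slight asymptote attenuation (the
  simulator's clip log quantifies it). A binomial alternative would remove
  the mismatch at the cost of departing from the standard form.
* Population-level coverage with 8 animals depends on the spread
  hyperpriors; the shipped Gamma(3) choice is calibrated by simulation, but
  very small cohorts (3-4 fish) will undercover.
* The trajectory simulator's success probabilities are governed entirely by
  aim noise, so its success asymptote (~2/6 at the default concentration)
  is lower than a real, within-trial-correcting fish would achieve.
* `reproduce_deposited()` expects archival CSVs in (or convertible to) the
  package's trial dialect; column auto-detection covers raw samples and
  precomputed per-trial metrics, not arbitrary layouts.
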