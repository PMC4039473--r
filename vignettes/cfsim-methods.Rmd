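---
title: "Models and methods behind cfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cfsim is a simulation and analysis toolkit for interocular suppression
experiments in which a moving target must be detected under continuous flash
suppression (CFS). It covers four stages that normally live in separate
scripts: dynamic mask/target synthesis, a quantitative model of
retinotopically specific neural adaptation, adaptive staircase psychophysics
with simulated observers, and hierarchical Bayesian analysis of normalized
contrast thresholds. This vignette explains the models, the defaults, and
the design decisions a user should know before trusting (or changing) them.

## Stimuli

The mask is a field of 150 colored squares (0.46 deg side; red, green, blue
or yellow) inside a 7.32 deg bounding square on a mid-gray background. Two
mask families are generated:

* **Moving Mondrian mask (MMM).** Each element translates at a common speed
  along one of six canonical directions (left, right, up, down, and the two
  diagonals), with the six directions divided exactly evenly across the 150
  elements and colors divided as evenly as possible within each direction
  group (counts 7/6/6/6, rotating which color receives the extra element).
  Elements wrap toroidally at the display edge. Initial positions are
  randomized under a four-quadrant constraint — (38, 38, 37, 37) elements
  per quadrant, assignment randomized by seed — so no region starts empty.
* **Flashing (classic) CFS mask.** An independent random layout of the same
  150 squares appears every 100 ms (10 Hz by default) and is held for
  `round(frame_rate / refresh_rate)` display frames.

The target is a red circle of the same diameter as a mask element. It
enters at the right edge of a virtual 5.5 deg square, moves left on one of
six horizontal paths (three above and three below fixation, adjacent paths
separated by twice the target size), and fades in linearly over the first
20 frames. The trial durations printed for the different target speeds
(3.6 s at 3 deg/s; 5.5 s and 2.2 s at 2 and 5 deg/s) imply a traversal
slightly longer than the visible region; we treat duration as an explicit
per-condition parameter and simply stop drawing the target once it leaves
the display.

Every generator is a pure function of its parameters and a seed; frames are
row-major rasters with the origin at the frame center and y increasing
upward, rasterized by rounding to the nearest pixel. The default spatial
scale (17.5 px/deg, a 128 px frame) is the package's desk-scale resolution
for simulation work; any scale can be configured.

## Retinotopic adaptation model

Each grayscale stimulus update is filtered with two odd-symmetric
(sine-phase) Gabor kernels at 0 and 90 degrees whose carrier sits at the
Nyquist wavelength (2 px). The envelope follows the standard
wavelength/bandwidth relation

$$\sigma = \frac{\lambda}{\pi} \sqrt{\tfrac{\ln 2}{2}}
  \frac{2^b + 1}{2^b - 1},$$

with bandwidth b = 1 octave by default, and the kernel support is four
standard deviations. A Nyquist sine carrier is identically zero at integer
sample offsets, so the kernels are sampled at half-integer offsets; this
forces an even kernel side (the even integer nearest 4 sigma, at least 4),
where the carrier attains its extrema and odd symmetry — hence exact zero
mean — is preserved. Convolution is correlation with replicate padding; the
even support is anchored with tap offsets `a - side/2`, a half-pixel
asymmetry that is unavoidable on an integer grid and irrelevant to the
classification.

Each pixel is labeled with one of five responses: no response, or the
orientation of the larger absolute filter response signed by its polarity.
The "no response" threshold defaults to 5% of the bank's maximal response
to a full-contrast straight edge, computed numerically when the bank is
built and exposed in the configuration.

Adaptation is tracked per pixel and per response category (4 categories)
with an activation value starting at 1. The dynamics are multiplicative
per stimulus update and telescope exactly to the continuous exponentials:
constant stimulation for time $T$ leaves $e^{-T/\tau_d}$ ($\tau_d$ = 4 s),
and unstimulated recovery from $a_0$ reaches $1-(1-a_0)e^{-T/\tau_r}$
($\tau_r$ = 6 s).

Two modeling choices deserve emphasis, because they are what makes the
mask conditions separable at all:

* **Persistence gating.** Adaptation requires the same orientation *and*
  contrast polarity across successive stimulus updates: a label that just
  appeared or just changed at a pixel recovers rather than decays. Without
  this gate the instantaneous fraction of labeled pixels is nearly
  identical (~0.47) in every mask condition, total stimulation is equal,
  and all condition means collapse onto one another; with it, slow masks —
  whose edges linger over the same pixels — adapt most, and the measured
  separation is strong and monotone in speed.
* **Update time base.** The simulation steps once per *distinct stimulus
  update*: every display frame for the MMM (dt = 1/60 s), every refresh for
  the flashing mask (dt = 1/refresh). A 100 ms hold of an unchanged layout
  is a single presentation, not six frames of "the same feature across
  frames". Stepping the flashing mask at the display rate instead makes its
  static holds the most adaptation-prone stimulus of all and inverts the
  expected ranking; with the update time base the flashing mask is the
  least adapted condition, as intended by the continual-updating account it
  operationalizes.

A fresh adaptation field treats its first update as stimulus onset (no
persistence established, so no decay); fields can be initialized with a
response map to model an already-established stimulus, which is also how
the closed-form decay checks are phrased.

The per-trial summary is the sum of activation over all pixels and
categories, normalized by `n_pixels x 4` so a blank trial scores exactly 1,
and averaged over updates (time average) by default; an end-of-trial
variant is available (`variant = "final"`). Higher values mean less
adaptation. Trials are simulated independently (activation resets between
trials), 999 trials per condition by default; the packaged desk-scale runs
use 99 trials of 1 s at 128 px, which resolves the condition ordering with
standard errors around 2e-5.

A known desk-scale artifact: at 17.5 px/deg the 8 deg/s mask moves 2.33 px
per update, close to the 2 px carrier wavelength, so the filter-response
pattern re-aligns between updates and persistence is inflated relative to
5 deg/s; the 5 and 8 deg/s summaries can invert there. At finer scales the
displacement leaves the aliasing regime and the ordering is clean; this is
a property of Nyquist-wavelength filtering of pixel-locked motion, not of
the dynamics.

## Staircase psychophysics

Contrast thresholds are estimated with an accelerated transformed up-down
staircase, tracked in log10 contrast with a 0.05 log-unit step and clamped
to [1e-4, 1] (displayable contrast). The staircase starts one-up-one-down
(every correct response lowers the level) and switches permanently to
one-up-two-down at the first error; the main phase converges where
$p(\text{correct}) = \sqrt{1/2} \approx 70.71\%$. Sessions use two
staircases per condition with distinct starting contrasts (1.0 and 0.1 by
default), randomly interleaved; target paths are balanced within each
staircase; with 65 trials per staircase the single-target design yields 780
trials and the two-target (blocked, counterbalanced) design 1,560.

Thresholds are the mean of each staircase's final 20 trials, averaged over
the condition's staircases. Averaging is done in linear contrast by
default; a log-space switch is provided since the averaging space is a
genuine convention choice. Each participant's thresholds are normalized by
their mean threshold (so normalized values average exactly 1 per
participant) before group analysis. Condition-mean uncertainty for plots
uses Cousineau-centered data with Morey's correction.

Simulated observers use a cumulative Weibull psychometric with guess rate
0.5 (the above/below task), lapse 0.01 and slope beta = 3.5 — conventional
values for contrast detection. One calibration fact is worth knowing: with
a fixed 0.05 log-unit step, the *empirical* percent correct of the main
phase converges tightly to 70.71%, but evaluating the psychometric at the
mean reversal level underestimates it by one to two percentage points.
That bias is intrinsic to fixed-step up-down staircases (it grows with
step size times psychometric slope and does not shrink with more trials);
the package therefore treats empirical percent correct as the convergence
check and reports the reversal-level estimator where that exact recipe is
requested.

## Synthetic thresholds and ground truth

The generator emulates the structure the analysis assumes: log thresholds
are a baseline (0.02 contrast) plus a participant offset (SD 0.3), plus a
log-Gaussian speed-tuning bump peaked at the mask speed matching the target
speed (amplitude 0.35 log units, width 0.5 log-speed units), plus scaled
t-distributed noise (scale 0.1, 5 df) and occasional gross outliers (2% at
±1 log unit). The flashing-CFS condition is a separate categorical level at
0.8 times baseline, not a point on the speed axis. For the two-target
design the tuning center follows each target speed and the 5 deg/s block's
amplitude is scaled by 0.3, emulating the flattening of the threshold
profile for fast targets. Ground truth is returned on the analysis scale:
noise-free thresholds are normalized per participant and decomposed into
sum-to-zero deflections.

What passing tests on these data do and do not show: the generator matches
the analysis model's assumptions by construction (plus outliers), so
recovery results certify the inference machinery, not the realism of any
particular human dataset — real observers bring effect sizes, learning and
criterion drifts the generator does not model.

## Hierarchical Bayesian analysis

Normalized thresholds are modeled with a robust t likelihood: unknown
degrees of freedom with a uniform prior on [1, 100] (1 allows arbitrarily
heavy tails; by 100 the t is effectively normal), location built from a
grand mean, condition deflections and participant deflections (plus target
speed and interaction groups in the two-factor form), and a common scale.
Deflection groups get zero-centered hierarchical normal priors whose
spreads carry half-Cauchy(1) hyperpriors — weakly informative on the unit
scale of normalized thresholds; the grand mean gets a vague normal and the
residual scale a half-Cauchy(1). Sampling runs in JAGS with a non-centered
parameterization of all deflection groups, which keeps mixing healthy when
a group spread is near zero (after per-participant normalization the true
participant spread *is* essentially zero). Draws are post-hoc centered so
every deflection group sums to zero (interaction deflections over both
margins), which is also what makes them comparable across chains;
convergence requires split R-hat at or below 1.01 on all reported
parameters, with effective sample sizes reported. Defaults are 4 chains of
2,500 retained draws after 1,000 warm-up; the packaged simulation studies
use 2 chains of 700–1,500 draws per fit to keep replicate counts high.

Condition contrasts are per-draw weighted sums of deflections (weights
summing to zero), summarized by the narrowest interval containing 95% of
the draws (sorted-window scan); a contrast is declared credible exactly
when its HDI excludes zero, and because every contrast is a view of the
same joint posterior no multiplicity correction is applied. Posterior
predictive checks draw one replicate dataset per retained draw from the
fitted t likelihood at each cell and report per-cell predictive intervals
and their empirical coverage.

## Default-prior Bayes factors

Model selection uses the default scaled-g-prior ANOVA framework: each
effect group receives sum-to-zero-projected design columns (normalized
Helmert basis; Kronecker products for the interaction), effects are
N(0, g sigma^2) with g per group carrying an Inverse-Gamma(1/2, r^2/2)
prior (a scaled Cauchy on the effect scale), r = 0.5 for fixed effect
groups and r = 1 for the participant group, and Jeffreys priors on the
grand mean and error variance. Conditional on g the marginal likelihood is
closed-form; the package evaluates it via the Woodbury identity on the
k x k scale and integrates over g with adaptive Gauss-Hermite quadrature
in log g (mode located numerically, rule scaled by the local curvature) —
necessary because the g-likelihood concentrates far into the prior's tail
for strong effects, where any fixed rule under-resolves. A prior-sampling
Monte-Carlo fallback is provided. The five models (null, mask speed,
target speed, additive, full) all include the participant term, matching
the repeated-measures design; Bayes factors are ratios of marginal
likelihoods, so reflexivity and reciprocity hold by construction and the
quadrature is validated in the tests against a dense log-grid integration
with full N x N covariances.

## Numerical and scope notes

* Seeds: every stochastic stage takes an explicit seed; sub-seeds are
  derived by seeded sampling (all below 2^31). MCMC reproducibility is
  per-engine-version, as for any sampler.
* Ties in response classification (equal absolute responses) go to the
  0-degree kernel; rank ties in condition ordering break by label.
* Degenerate inputs error early with invalid-parameter messages
  (non-positive speeds, probabilities outside (0,1), incomplete designs,
  staircases shorter than the last-20 estimator, weights not summing to
  zero).
* The package deliberately models a single spatial-frequency channel, one
  adaptation timescale and one recovery timescale, and no dichoptic
  rendering (fusion borders, eye dominance, gamma) — those belong to the
  hardware side of an experiment, not to this simulation layer.
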