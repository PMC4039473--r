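# cfsim

Simulation and analysis tools for interocular suppression of **moving**
stimuli under continuous flash suppression (CFS). Classic CFS flashes a
fresh Mondrian layout in one eye every 100 ms; a *moving Mondrian mask*
(MMM) instead translates the same elements smoothly. Which mask suppresses
a moving target better — and whether the answer is predicted by how much
**retinotopically specific neural adaptation** each mask incurs — is the
scientific question this package makes computable:

* **Stimulus engine** — seeded, deterministic frame sequences for MMM
  masks (150 colored squares, six motion directions, quadrant-balanced
  placement, toroidal wrap), flashing CFS masks (10 Hz refresh), and a
  fading moving target on six balanced motion paths.
* **Adaptation simulation** — each stimulus update is filtered by two
  odd-symmetric Nyquist Gabor kernels (0° and 90°); each pixel is labeled
  with one of five responses (2 orientations × 2 contrast polarities, or
  none); per pixel and category an activation value decays as
  `exp(-dt/4 s)` while the feature persists across updates and recovers as
  `1-(1-a)exp(-dt/6 s)` otherwise. The trial summary (sum of activation,
  normalized to max 1, time-averaged) is an inverse index of adaptation:
  higher = less adapted.
* **Psychophysics** — accelerated 1-up/1-down → 1-up/2-down staircases
  (converging at 70.71 % correct), simulated Weibull observers, session
  plans with two interleaved staircases per condition (65 trials each:
  780 trials for the one-target design, 1,560 for the blocked two-target
  design), last-20-trials thresholds, per-participant normalization, and
  Cousineau–Morey within-subject CIs.
* **Bayesian inference** — the hierarchical robust-t repeated-measures
  model (`y ~ t(β₀ + β_cond + β_subj, σ, ν)`, hierarchical zero-centered
  priors, uniform prior on ν) fitted by MCMC via JAGS; sum-to-zero
  centered deflections; HDI contrasts with no multiplicity correction;
  posterior predictive checks; and default-prior (JZS) ANOVA Bayes factors
  computed from scratch by adaptive Gauss–Hermite quadrature over the
  scaled-g priors.
* **Synthetic data** — a ground-truthed generator (log-Gaussian speed
  tuning peaked at the mask speed matching the target, participant
  offsets, heavy-tailed noise, outliers) so the whole pipeline is testable
  end to end without human data.

## Worked example

Simulate adaptation for two mask conditions at desk scale, then run a
small simulated threshold experiment and fit the hierarchical model:

```r
library(cfsim)

geom <- display_geometry()              # 7.32 deg, 128 px, 60 Hz
bank <- build_gabor_bank(geom$side_px)  # sigma = 1.124 px, 4 px kernels

slow <- simulate_condition(mask_condition("mmm", speed = 1), geom,
                           n_trials = 12, duration = 1, seed = 99,
                           bank = bank)
cfs  <- simulate_condition(mask_condition("cfs"), geom,
                           n_trials = 12, duration = 1, seed = 99,
                           bank = bank)
slow
#> <cfs_adaptation_summary> MMM 1: mean 0.9893 (sd 0.0002, 12 trials)
cfs
#> <cfs_adaptation_summary> CFS: mean 0.9985 (sd 0.0001, 12 trials)
```

The slow moving mask (0.9893) sits well below the flashing mask (0.9985):
its edges linger on the same retinotopic locations, so simulated
adaptation is deeper (higher values mean *less* adaptation).

```r
gen <- generate_threshold_dataset(n_participants = 10,
                                  profile = effect_profile(),
                                  design = "exp1", seed = 4)
fit <- fit_one_way(gen$data, chains = 2, iter = 1000, warmup = 500,
                   seed = 5, on_nonconvergence = "warn")
round(colMeans(fit$draws[, paste0("bC[", fit$condition_levels, "]")]), 3)
#> bC[MMM 1] bC[MMM 2] bC[MMM 3] bC[MMM 5] bC[MMM 8]   bC[CFS]
#>     0.007     0.126     0.177     0.125    -0.140    -0.295

w <- setNames(c(-0.2, -0.2, 1, -0.2, -0.2, -0.2), fit$condition_levels)
contrast_hdi(fit, w)
#> <cfs_contrast> mean 0.2124, 95% HDI [0.1141, 0.3149] -> credibly different

jzs_anova_bf(gen$data, "mask_speed", "null")$bf
#> [1] 358893690
```

The matched mask speed (3 °/s, the generator's tuning peak) carries the
largest positive deflection; the matched-vs-rest contrast excludes zero;
and the Bayes factor overwhelmingly favors a mask-speed effect over the
null — exactly the qualitative pattern the generator encodes.

End-to-end runs (`run_experiment()`, `run_adaptation()`) write CSV/JSON
report bundles with every seed logged; `run_config()` round-trips through
JSON for full reproducibility.

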