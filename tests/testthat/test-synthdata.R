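test_that("effect profile validates its parameters", {
  expect_error(effect_profile(baseline_threshold = 0), "> 0")
  expect_error(effect_profile(tuning_amplitude = -1), ">= 0")
  expect_error(effect_profile(outlier_rate = 0.5), "0, 0.2")
})

test_that("a flat profile produces equal expected thresholds across speeds", {
  p <- effect_profile(tuning_amplitude = 0)
  gen <- generate_threshold_dataset(5, p, "exp1", seed = 1)
  cells <- gen$truth$normalized_cells
  mmm <- cells[setdiff(rownames(cells), "CFS"), 1]
  expect_equal(unname(diff(range(mmm))), 0, tolerance = 1e-12)
  # CFS remains a separate categorical level
  expect_equal(unname(cells["CFS", 1] / mmm[1]), p$cfs_level,
               tolerance = 1e-12)
})

test_that("sample moments match the generative model at n = 999", {
  p <- effect_profile(outlier_rate = 0, participant_sd = 0.3,
                      residual_scale = 0.1, residual_df = 5)
  gen <- generate_threshold_dataset(999, p, "exp1", seed = 77)
  d <- gen$data
  logt <- log(d$threshold)
  # between-participant spread of mean log thresholds
  pm <- tapply(logt, d$participant, mean)
  resid_var_of_mean <- 0.1^2 * (5 / 3) / 6 # residual part of participant means
  expect_equal(sd(pm), sqrt(0.3^2 + resid_var_of_mean), tolerance = 0.05)
  # residual spread around participant x condition structure:
  # t(5) scaled by 0.1 has sd 0.1 * sqrt(5/3); double centering over
  # J = 6 conditions removes a (1 - 1/J) share of the variance
  res <- logt - ave(logt, d$participant) -
    ave(logt, d$condition) + mean(logt)
  expect_equal(sd(res), 0.1 * sqrt(5 / 3) * sqrt(5 / 6), tolerance = 0.05)
  # participant offsets are returned as ground truth (factor levels are
  # alphabetical; restore generation order before comparing)
  pm_ord <- pm[sprintf("P%02d", seq_len(999))]
  # attenuated only by the residual share of the participant means:
  # rho = sd_u / sqrt(sd_u^2 + resvar/J) ~ 0.985
  expect_equal(cor(pm_ord, gen$truth$participant_offsets),
               0.3 / sqrt(0.3^2 + resid_var_of_mean), tolerance = 0.01)
})

test_that("the matched mask speed carries the largest mean threshold", {
  gen <- generate_threshold_dataset(400, effect_profile(), "exp1", seed = 31)
  m <- tapply(gen$data$value, gen$data$condition, mean)
  expect_equal(names(which.max(m)), "MMM 3")
  # ground-truth deflections identify the same peak
  defl <- gen$truth$condition_deflections
  expect_equal(names(which.max(defl)), "MMM 3")
  # the two-factor design shifts the peak with target speed
  gen2 <- generate_threshold_dataset(400, effect_profile(), "exp2", seed = 32)
  d2 <- gen2$data
  m2 <- tapply(d2$value[d2$target_speed == "2"],
               droplevels(d2$condition[d2$target_speed == "2"]), mean)
  expect_equal(names(which.max(m2)), "MMM 2")
  expect_error(generate_threshold_dataset(1, effect_profile(), "exp1", 1),
               "at least 2")
})

test_that("observer banks mirror the tuning profile", {
  flat <- generate_observer_bank(effect_profile(tuning_amplitude = 0,
                                                cfs_level = 1),
                                 n_participants = 3, seed = 2)
  for (obs in flat) {
    expect_equal(unname(diff(range(obs$alpha))), 0, tolerance = 1e-12)
  }
  bank <- generate_observer_bank(effect_profile(), n_participants = 3,
                                 seed = 2)
  for (obs in bank) {
    expect_equal(names(which.max(obs$alpha)), "MMM 3")
  }
  expect_error(generate_observer_bank(effect_profile(), conditions = NULL),
               "non-empty")
})

test_that("staircases against the observer bank recover its thresholds", {
  p <- effect_profile(participant_sd = 0)
  obs <- generate_observer_bank(p, n_participants = 1, seed = 6)[[1]]
  # long staircases on two contrasting conditions
  for (cond in c("MMM 3", "CFS")) {
    sim <- run_staircase_sim(obs, cond, n_main = 600, seed = 8)
    est <- estimate_threshold(sim$state, n_last = 20)
    target <- psychometric_inverse(obs, cond)
    expect_equal(est, target, tolerance = 0.25)
  }
})

test_that("the end-to-end recovery experiment is deterministic and coherent", {
  rep1 <- suppressWarnings(
    recovery_experiment(n_participants = 8, seed = 5, chains = 2,
                        iter = 500, warmup = 300))
  rep2 <- suppressWarnings(
    recovery_experiment(n_participants = 8, seed = 5, chains = 2,
                        iter = 500, warmup = 300))
  expect_identical(rep1$deflections, rep2$deflections)
  expect_identical(rep1$bf_mask_vs_null, rep2$bf_mask_vs_null)
  expect_s3_class(rep1, "cfs_recovery_report")
  expect_equal(nrow(rep1$deflections), 6L)
  expect_true(is.finite(rep1$bf_mask_vs_null))
  expect_true(is.logical(rep1$pass))
})
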