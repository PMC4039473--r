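test_that("rm_dataset validates completeness and positivity", {
  df <- expand.grid(participant = paste0("P", 1:4),
                    condition = c("a", "b", "c"))
  df$normalized <- 1
  d <- rm_dataset(df)
  expect_s3_class(d, "cfs_rm_dataset")
  expect_error(rm_dataset(df[-1, ]), "complete")
  df2 <- df; df2$normalized[1] <- -2
  expect_error(rm_dataset(df2), "positive")
})

test_that("hdi returns the narrowest interval with the stated mass", {
  set.seed(123)
  x <- rnorm(4000, 2, 1.3)
  for (p in c(0.5, 0.8, 0.95)) {
    h <- hdi(x, p)
    expect_equal(h, oracle_hdi(x, p))
    inside <- mean(x >= h[1] & x <= h[2])
    expect_gte(inside, p - 1e-9)
    expect_lt(inside, p + 2 / length(x) + 1e-9)
  }
  # skewed sample: hdi is narrower than the equal-tail interval
  y <- rlnorm(4000)
  h <- hdi(y, 0.9)
  q <- quantile(y, c(0.05, 0.95))
  expect_lt(h[2] - h[1], q[2] - q[1])
  expect_error(hdi(x, 1.2), "prob")
})

fit_small <- function(seed = 30, amplitude = 0.35, n = 8, ...) {
  gen <- generate_threshold_dataset(n, effect_profile(
    tuning_amplitude = amplitude, outlier_rate = 0), "exp1", seed = seed)
  list(gen = gen,
       fit = fit_one_way(gen$data, chains = 2, iter = 800, warmup = 500,
                         seed = seed + 1, on_nonconvergence = "warn", ...))
}

test_that("one-way robust fit recovers structure with sum-to-zero draws", {
  fs <- suppressWarnings(fit_small())
  fit <- fs$fit
  bC <- fit$draws[, grep("^bC\\[", colnames(fit$draws))]
  bS <- fit$draws[, grep("^bS\\[", colnames(fit$draws))]
  expect_lt(max(abs(rowSums(bC))), 1e-10)
  expect_lt(max(abs(rowSums(bS))), 1e-10)
  expect_true(all(c("b0", "sigma", "nu") %in% colnames(fit$draws)))
  expect_true(all(fit$draws[, "nu"] >= 1 & fit$draws[, "nu"] <= 100))
  # deflection estimates track the generator's ground truth
  truth <- fs$gen$truth$condition_deflections[fit$condition_levels]
  est <- colMeans(bC)
  expect_gt(cor(est, truth), 0.9)
  # reproducibility per seed
  fs2 <- suppressWarnings(fit_small())
  expect_identical(fit$draws, fs2$fit$draws)
})

test_that("contrasts follow the zero-sum rule and the HDI decision", {
  fit <- suppressWarnings(fit_small(seed = 44))$fit
  lv <- fit$condition_levels
  w <- setNames(c(1, -1, rep(0, 4)), lv)
  ct <- contrast_hdi(fit, w[w != 0])
  expect_equal(ct$hdi, oracle_hdi(ct$samples, 0.95), tolerance = 1e-12)
  expect_identical(ct$excludes_zero, ct$hdi[1] > 0 || ct$hdi[2] < 0)
  # contrasts computed jointly or one at a time are identical (no correction)
  w2 <- setNames(c(1, rep(-0.2, 5)), lv)
  ct_a <- contrast_hdi(fit, w2)
  ct_b <- contrast_hdi(fit, w2)
  expect_identical(ct_a$samples, ct_b$samples)
  # degenerate all-zero weights
  ct0 <- contrast_hdi(fit, setNames(rep(0, 6), lv))
  expect_equal(ct0$hdi, c(0, 0))
  expect_false(ct0$excludes_zero)
  expect_error(contrast_hdi(fit, setNames(c(1, 1), lv[1:2])), "sum to zero")
  expect_error(contrast_hdi(fit, c(bogus = 1, nope = -1)), "named")
})

test_that("posterior predictive replicates match draw count and cover the data", {
  fs <- suppressWarnings(fit_small(seed = 52, n = 10))
  ppc <- posterior_predictive(fs$fit, fs$gen$data, seed = 5)
  expect_equal(nrow(ppc$yrep), nrow(fs$fit$draws))
  expect_equal(ncol(ppc$yrep), nrow(fs$gen$data))
  expect_gt(ppc$coverage, 0.85)
  expect_lte(ppc$coverage, 1)
  # observed data lie in the range of the predictions
  z <- abs(fs$gen$data$value - ppc$cells$pred_mean) /
    apply(ppc$yrep, 2, sd)
  expect_lt(max(z), 6)
  other <- generate_threshold_dataset(4, effect_profile(), "exp1", 1)$data
  expect_error(posterior_predictive(fs$fit, other), "match")
})

test_that("the t likelihood resists outliers better than the normal", {
  gen <- generate_threshold_dataset(10, effect_profile(outlier_rate = 0),
                                    "exp1", seed = 60)
  clean <- gen$data
  dirty <- clean
  i <- which(dirty$condition == "MMM 1")[1]
  dirty$value[i] <- dirty$value[i] * 6 # one gross outlier
  fits <- lapply(list(t = "t", normal = "normal"), function(lik) {
    list(
      clean = suppressWarnings(fit_one_way(clean, chains = 2, iter = 600,
                                           warmup = 400, seed = 3,
                                           likelihood = lik,
                                           on_nonconvergence = "ignore")),
      dirty = suppressWarnings(fit_one_way(dirty, chains = 2, iter = 600,
                                           warmup = 400, seed = 3,
                                           likelihood = lik,
                                           on_nonconvergence = "ignore")))
  })
  shift <- vapply(fits, function(f) {
    cols <- grep("^bC\\[", colnames(f$clean$draws))
    max(abs(colMeans(f$dirty$draws[, cols]) - colMeans(f$clean$draws[, cols])))
  }, 0)
  expect_lt(shift[["t"]], shift[["normal"]])
  # and the t fit reads the contamination as a heavier tail (smaller nu)
  nu_clean <- median(fits$t$clean$draws[, "nu"])
  nu_dirty <- median(fits$t$dirty$draws[, "nu"])
  expect_lt(nu_dirty, nu_clean)
})

test_that("two-way fit centers all margins and nests the one-way model", {
  gen <- generate_threshold_dataset(8, effect_profile(outlier_rate = 0),
                                    "exp2", seed = 71)
  fit <- suppressWarnings(
    fit_two_way(gen$data, chains = 2, iter = 800, warmup = 500, seed = 72,
                on_nonconvergence = "warn"))
  d <- fit$draws
  bC <- d[, grep("^bC\\[", colnames(d))]
  bT <- d[, grep("^bT\\[", colnames(d))]
  bI <- d[, grep("^bI\\[", colnames(d))]
  expect_lt(max(abs(rowSums(bC))), 1e-10)
  expect_lt(max(abs(rowSums(bT))), 1e-10)
  # interaction deflections vanish over both margins
  for (l in fit$condition_levels) {
    cols <- grep(paste0("^bI\\[", l, ","), colnames(d), fixed = FALSE)
    expect_lt(max(abs(rowSums(d[, cols, drop = FALSE]))), 1e-10)
  }
  truth <- gen$truth$condition_deflections[fit$condition_levels]
  expect_gt(cor(colMeans(bC), truth), 0.8)
  expect_error(fit_two_way(generate_threshold_dataset(
    4, effect_profile(), "exp1", 1)$data, chains = 1, iter = 100,
    warmup = 100), "target_speed")
})
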