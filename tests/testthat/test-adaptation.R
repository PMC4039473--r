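test_that("activation starts at 1 and the closed forms are exact", {
  f <- adaptation_field(4)
  expect_true(all(f$activation == 1))
  # constant established stimulation for 4 s -> exactly 1/e
  lab <- matrix(1L, 4, 4)
  f <- adaptation_field(4, dt = 1 / 60, initial_labels = lab)
  for (i in 1:240) f <- update_adaptation(f, lab)
  expect_equal(f$activation[1, 1, 1], exp(-1), tolerance = 1e-12)
  # the other categories recovered (stayed at 1)
  expect_equal(f$activation[1, 1, 2], 1)
  # fully adapted, unstimulated for 6 s -> exactly 1 - 1/e
  f2 <- adaptation_field(4, dt = 1 / 60)
  f2$activation[] <- 0
  none <- matrix(0L, 4, 4)
  for (i in 1:360) f2 <- update_adaptation(f2, none)
  expect_equal(f2$activation[2, 2, 3], 1 - exp(-1), tolerance = 1e-12)
})

test_that("a label drives decay only after it persists across updates", {
  lab <- matrix(1L, 2, 2)
  f <- adaptation_field(2, dt = 1 / 60) # fresh field: first update is onset
  f <- update_adaptation(f, lab)
  expect_equal(f$activation[1, 1, 1], 1) # no decay yet
  f <- update_adaptation(f, lab)
  expect_equal(f$activation[1, 1, 1], exp(-(1 / 60) / 4), tolerance = 1e-14)
  # a changed label interrupts decay
  f <- update_adaptation(f, matrix(2L, 2, 2))
  a_after <- f$activation[1, 1, 1]
  expect_gt(a_after, exp(-2 * (1 / 60) / 4) - 1e-12)
  expect_equal(f$activation[1, 1, 2], 1) # the new label has not persisted
})

test_that("arbitrary label sequences match the scalar recursion oracle", {
  set.seed(91)
  for (rep in 1:5) {
    labels <- sample(0:4, 50, replace = TRUE)
    f <- adaptation_field(1, dt = 1 / 30)
    for (l in labels) f <- update_adaptation(f, matrix(as.integer(l), 1, 1))
    o <- oracle_adapt_pixel(labels, dt = 1 / 30)
    expect_equal(as.vector(f$activation), o$activation, tolerance = 1e-13)
  }
})

test_that("vectorized field updates equal per-pixel scalar recursion", {
  set.seed(14)
  side <- 16
  n_up <- 25
  seqs <- array(sample(0:4, side * side * n_up, replace = TRUE),
                dim = c(side, side, n_up))
  f <- adaptation_field(side, dt = 1 / 60)
  for (t in seq_len(n_up)) {
    f <- update_adaptation(f, matrix(as.integer(seqs[, , t]), side, side))
  }
  for (i in c(1, 7, 16)) for (j in c(2, 9, 16)) {
    o <- oracle_adapt_pixel(seqs[i, j, ], dt = 1 / 60)
    expect_equal(f$activation[i, j, ], o$activation, tolerance = 1e-13)
  }
})

test_that("activations stay within [0, 1] for any input sequence", {
  set.seed(5)
  f <- adaptation_field(8, dt = 0.1)
  for (t in 1:200) {
    f <- update_adaptation(f, matrix(sample(0:4, 64, TRUE), 8, 8))
    expect_true(all(f$activation >= 0 & f$activation <= 1))
  }
})

test_that("monotone dynamics: stimulated non-increasing, otherwise non-decreasing", {
  set.seed(8)
  f <- adaptation_field(4, dt = 0.05)
  prev_map <- NULL
  for (t in 1:60) {
    m <- matrix(sample(0:4, 16, TRUE), 4, 4)
    before <- f$activation
    eff <- cfsim:::effective_labels(m, f$prev_labels)
    f <- update_adaptation(f, m)
    for (c in 1:4) {
      stim <- eff == c
      expect_true(all(f$activation[, , c][stim] <= before[, , c][stim]))
      expect_true(all(f$activation[, , c][!stim] >= before[, , c][!stim]))
    }
  }
})

test_that("trial summaries are normalized, bounded and oracle-consistent", {
  expect_error(summarize_trial(numeric(0), 16), "empty")
  # blank trial: totals stay at the maximum -> summary exactly 1
  side <- 16
  f <- adaptation_field(side, dt = 1 / 60)
  totals <- numeric(3)
  none <- matrix(0L, side, side)
  for (t in 1:3) {
    f <- update_adaptation(f, none)
    totals[t] <- attr(f, "total")
  }
  expect_equal(summarize_trial(totals, side^2), 1)
  # toy moving square: compare against the per-pixel oracle
  seqs <- array(0L, dim = c(side, side, 3))
  seqs[4:6, 4:6, 1] <- 1L
  seqs[4:6, 5:7, 2] <- 1L
  seqs[4:6, 6:8, 3] <- 1L
  f <- adaptation_field(side, dt = 1 / 60)
  totals <- numeric(3)
  for (t in 1:3) {
    f <- update_adaptation(f, matrix(seqs[, , t], side, side))
    totals[t] <- attr(f, "total")
  }
  oracle_totals <- rowSums(sapply(seq_len(side^2), function(p) {
    i <- (p - 1) %% side + 1
    j <- (p - 1) %/% side + 1
    oracle_adapt_pixel(seqs[i, j, ], dt = 1 / 60)$totals
  }))
  expect_equal(totals, oracle_totals, tolerance = 1e-10)
  s <- summarize_trial(totals, side^2)
  expect_true(s > 0 && s <= 1)
  expect_equal(summarize_trial(totals, side^2, "final"),
               totals[3] / (side^2 * 4))
  expect_length(summarize_trial(totals, side^2, "per_frame"), 3L)
})

test_that("condition simulation is seeded and validates inputs", {
  geom <- tiny_geometry()
  bank <- build_gabor_bank(geom$side_px)
  s1 <- simulate_condition(mask_condition("mmm", 3), geom, n_trials = 2,
                           duration = 0.5, seed = 7, bank = bank)
  s2 <- simulate_condition(mask_condition("mmm", 3), geom, n_trials = 2,
                           duration = 0.5, seed = 7, bank = bank)
  expect_identical(s1$per_trial, s2$per_trial)
  expect_equal(s1$mean, mean(s1$per_trial))
  expect_true(all(s1$per_trial > 0 & s1$per_trial <= 1))
  # flashing mask runs and yields one bounded scalar per trial
  sc <- simulate_condition(mask_condition("cfs"), geom, n_trials = 1,
                           duration = 1, seed = 3, bank = bank)
  expect_length(sc$per_trial, 1L)
  expect_true(sc$per_trial > 0 && sc$per_trial <= 1)
  expect_error(simulate_condition(list(type = "bogus"), geom, 1, 0.5, 1),
               "unknown condition")
  expect_error(simulate_condition(mask_condition("mmm", 3), geom,
                                  n_trials = 0, 0.5, 1), "at least 1")
})

test_that("condition ranking is order-invariant with stable tie-breaks", {
  mk <- function(label, vals) {
    structure(list(condition = label, per_trial = vals, mean = mean(vals),
                   n_trials = length(vals)),
              class = "cfs_adaptation_summary")
  }
  a <- mk("A", c(0.5, 0.5))
  b <- mk("B", c(0.5, 0.5))
  c3 <- mk("C", c(0.9, 0.8))
  r1 <- rank_conditions(list(a, b, c3))
  r2 <- rank_conditions(list(c3, b, a))
  expect_identical(r1, r2)
  expect_equal(r1$condition, c("A", "B", "C")) # tie broken by label
  expect_equal(r1$rank, 1:3)
  expect_error(rank_conditions(list(a)), "two summaries")
})
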