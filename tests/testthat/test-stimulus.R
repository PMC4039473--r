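test_that("geometry validation enforces positive extents and frame size", {
  expect_error(display_geometry(mask_bound = -1), "positive")
  expect_error(display_geometry(target_region = 10), "mask_bound")
  expect_error(display_geometry(pixels_per_degree = 0.5), "8 px")
  geom <- display_geometry()
  expect_equal(geom$side_px, 128L)
})

test_that("MMM initialization balances directions, colors and quadrants", {
  geom <- display_geometry()
  el <- init_mmm_elements(geom, speed = 3, seed = 11)
  expect_equal(nrow(el), 150L)
  expect_equal(as.integer(table(el$direction)), rep(25L, 6L))
  # six distinct unit vectors
  dirs <- unique(el[, c("dx", "dy")])
  expect_equal(nrow(dirs), 6L)
  expect_equal(sqrt(dirs$dx^2 + dirs$dy^2), rep(1, 6))
  # colors near-even overall and within each direction group (7,6,6,6)
  expect_true(all(as.integer(table(el$color)) %in% 37:38))
  for (d in unique(el$direction)) {
    expect_equal(as.integer(sort(table(el$color[el$direction == d]),
                                 decreasing = TRUE)), c(7L, 6L, 6L, 6L))
  }
  # quadrant allocation (38,38,37,37) guarantees no empty quadrant at t = 0
  expect_equal(as.integer(sort(table(el$quadrant), decreasing = TRUE)),
               c(38L, 38L, 37L, 37L))
  for (s in 1:25) {
    q <- init_mmm_elements(geom, 3, seed = s)$quadrant
    expect_equal(sort(unique(q)), 1:4)
  }
  expect_identical(init_mmm_elements(geom, 3, seed = 11), el)
  expect_false(identical(init_mmm_elements(geom, 3, seed = 12), el))
  expect_error(init_mmm_elements(geom, 0, seed = 1), "positive")
})

test_that("stepping moves elements linearly and wraps at the bounds", {
  geom <- display_geometry()
  el <- init_mmm_elements(geom, speed = 3, seed = 2)
  # linear motion: center element moving right at 3 deg/s for 1 s
  el$x[1] <- 0; el$y[1] <- 0; el$dx[1] <- 1; el$dy[1] <- 0
  moved <- el
  for (i in 1:10) moved <- step_mmm(moved, 0.1, geom)
  expect_equal(moved$x[1], 3, tolerance = 1e-12)
  expect_equal(moved$y[1], 0)
  # wraparound: element at the right edge reappears on the left, same y
  el$x[2] <- 3.6; el$y[2] <- 1.2; el$dx[2] <- 1; el$dy[2] <- 0
  w <- step_mmm(el, 0.1, geom) # +0.3 deg crosses the 3.66 boundary
  expect_lt(w$x[2], 0)
  expect_equal(w$x[2], 3.9 - 7.32, tolerance = 1e-12)
  expect_equal(w$y[2], 1.2)
  # element count conserved and all positions inside the bounds
  many <- el
  for (i in 1:50) many <- step_mmm(many, 1 / 60, geom)
  expect_equal(nrow(many), 150L)
  expect_true(all(abs(many$x) <= 3.66 + 1e-9))
  # zero-speed elements do not move
  el$speed <- 0
  expect_equal(step_mmm(el, 1, geom)[, c("x", "y")], el[, c("x", "y")])
  expect_error(step_mmm(el, 0, geom), "positive")
})

test_that("rendering draws element-sized squares with draw-order occlusion", {
  geom <- display_geometry()
  el <- init_mmm_elements(geom, 3, seed = 1)[1:2, ]
  el$x <- 0; el$y <- 0
  el$color <- c("red", "blue")
  one <- render_mask_frame(el[1, ], geom)
  px <- sum(one[, , 1] != 0.5 | one[, , 2] != 0.5 | one[, , 3] != 0.5) # non-gray
  expect_equal(px, round(0.46 * geom$pixels_per_degree)^2)
  # full overlap: the later element (blue) wins
  both <- render_mask_frame(el, geom)
  colored <- both[, , 3] == 1
  expect_true(any(colored))
  expect_true(all(both[, , 1][colored] == 0))
  expect_false(any(both[, , 1] == 1)) # no red pixel survives
  expect_error(render_mask_frame(el[0, ], geom), "non-empty")
})

test_that("flashing CFS holds each independent layout for 1/refresh", {
  geom <- tiny_geometry()
  s <- generate_cfs_sequence(geom, duration = 1, refresh_rate = 10, seed = 5,
                             gray = TRUE)
  expect_length(s$frames, 60L)
  sums <- vapply(s$frames, sum, 0)
  expect_equal(length(rle(sums)$lengths), 10L)
  expect_true(all(rle(sums)$lengths == 6L))
  s2 <- generate_cfs_sequence(geom, 1, 10, seed = 5, gray = TRUE)
  expect_identical(s$frames, s2$frames)
  expect_error(generate_cfs_sequence(geom, 1, refresh_rate = 120, seed = 1),
               "frame rate")
})

test_that("consecutive CFS layouts are as independent as unrelated ones", {
  geom <- tiny_geometry()
  overlap <- function(a, b) mean(a != 0.5 & b != 0.5)
  # one long sequence: overlap of consecutive refreshes
  s <- generate_cfs_sequence(geom, duration = 100, refresh_rate = 10,
                             seed = 42, gray = TRUE)
  layouts <- s$frames[seq(1, 6000, by = 6)]
  cons <- vapply(seq_len(999), function(i) {
    overlap(layouts[[i]], layouts[[i + 1]])
  }, 0)
  # independent pairs from unrelated seeds
  indep <- vapply(seq_len(999), function(i) {
    overlap(layouts[[i]], layouts[[1000 - i + 1]])
  }, 0)
  expect_lt(abs(mean(cons) - mean(indep)),
            3 * sqrt(var(cons) / 999 + var(indep) / 999) + 1e-3)
})

test_that("target fades in linearly and follows the selected path", {
  geom <- display_geometry()
  spec <- target_spec(speed = 3, path_index = 2, contrast = 0.8,
                      duration = 3.6)
  s <- generate_target_sequence(spec, geom)
  expect_length(s$frames, 216L)
  # contrast proxy: max deviation from background in the red channel
  dev <- vapply(s$frames, function(f) max(abs(f[, , 1] - 0.5)), 0)
  ramp <- dev[1:20]
  expect_true(all(diff(ramp) > 0))
  expect_equal(dev[21], 0.8 * 0.5, tolerance = 1e-9)
  expect_equal(dev[20], dev[21])
  # adjacent paths differ by exactly twice the target size
  offs <- cfsim:::target_path_offsets(geom)
  expect_equal(diff(rev(offs)), rep(2 * 0.46, 5))
  expect_equal(offs, -rev(offs)) # symmetric about fixation
  expect_error(target_spec(3, 7, 0.5), "path_index")
})

test_that("frame counts follow round(duration x frame_rate) for all generators", {
  geom <- tiny_geometry()
  for (dur in c(0.5, 1.25, 3.6)) {
    n <- round(dur * geom$frame_rate)
    expect_length(generate_mmm_sequence(geom, dur, 3, seed = 1,
                                        gray = TRUE)$frames, n)
    expect_length(generate_cfs_sequence(geom, dur, 10, seed = 1,
                                        gray = TRUE)$frames, n)
    spec <- target_spec(3, 1, 0.5, duration = dur)
    expect_length(generate_target_sequence(spec, geom)$frames, n)
  }
})

test_that("mmm sequences are deterministic and reproducible per seed", {
  geom <- tiny_geometry()
  a <- generate_mmm_sequence(geom, 0.5, 5, seed = 9)
  b <- generate_mmm_sequence(geom, 0.5, 5, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_equal(luma(a$frames[[1]]),
               cfsim:::render_mask_gray(init_mmm_elements(geom, 5, 9), geom))
})
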