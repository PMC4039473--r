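#' Initialize moving-Mondrian mask elements
#'
#' Creates the element table for a moving Mondrian mask (MMM): `n_elements`
#' colored squares, each with one of six canonical motion directions. The six
#' directions are divided as evenly as possible across elements (exactly
#' evenly when `n_elements` is divisible by six), and within every direction
#' group the four colors are allocated as evenly as possible, rotating which
#' color receives the extra element from group to group. Initial positions
#' are randomized under a four-quadrant constraint: the elements are split
#' (as evenly as possible) over the four quadrants of the bounding square and
#' placed uniformly within their quadrant, so no region of the display starts
#' empty.
#'
#' @param geometry A [display_geometry()].
#' @param speed Common element speed (deg/s), strictly positive (0 is allowed
#'   only internally for static layouts).
#' @param seed Integer seed; the same seed yields an identical element table.
#' @return A data frame with one row per element and columns `x`, `y` (deg,
#'   origin at frame center, y increasing upward), `dx`, `dy` (unit direction),
#'   `speed`, `color`, `direction`, `quadrant`.
#' @export
#' @examples
#' el <- init_mmm_elements(display_geometry(), speed = 3, seed = 1)
#' table(el$direction)
init_mmm_elements <- function(geometry, speed, seed) {
  stopifnot(inherits(geometry, "cfs_geometry"))
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0) {
    stop_invalid("speed must be a single strictly positive number")
  }
  el <- mmm_layout(geometry, seed)
  el$speed <- speed
  el
}

# Shared layout generator: directions+colors (deterministic allocation),
# quadrant assignment and positions (seeded random). Used by both the MMM
# initializer and the flashing-CFS layout refresh.
mmm_layout <- function(geometry, seed) {
  n <- geometry$n_elements
  dirs <- mask_directions()
  cols <- mask_colors()
  ndir <- nrow(dirs)
  ncol_ <- length(cols)

  dir_counts <- balanced_counts(n, ndir)
  dir_idx <- rep.int(seq_len(ndir), dir_counts)

  # Within each direction group, allocate colors as evenly as possible and
  # rotate which colors get the extras so no color is globally favored.
  col_idx <- integer(n)
  pos <- 1L
  for (g in seq_len(ndir)) {
    m <- dir_counts[g]
    cc <- balanced_counts(m, ncol_)
    rot <- ((seq_len(ncol_) - 1L + (g - 1L)) %% ncol_) + 1L # rotated colors
    col_idx[pos:(pos + m - 1L)] <- rep.int(rot, cc)
    pos <- pos + m
  }

  B <- geometry$mask_bound
  half <- B / 2
  with_seed(seed, {
    quad_counts <- balanced_counts(n, 4L)
    quadrant <- sample(rep.int(1:4, quad_counts))
    # quadrants: 1 = upper right, 2 = upper left, 3 = lower left, 4 = lower right
    qx <- c(1, -1, -1, 1)[quadrant]
    qy <- c(1, 1, -1, -1)[quadrant]
    x <- qx * runif(n, 0, half)
    y <- qy * runif(n, 0, half)
    data.frame(x = x, y = y,
               dx = dirs[dir_idx, "dx"], dy = dirs[dir_idx, "dy"],
               speed = 0,
               color = cols[col_idx],
               direction = rownames(dirs)[dir_idx],
               quadrant = quadrant,
               row.names = NULL)
  })
}

#' Advance MMM elements by a time step
#'
#' Moves every element along its direction by `speed * dt` degrees.
#' Coordinates leaving the bounding square wrap to the opposite edge,
#' preserving the trajectory (toroidal topology), so an element that reaches
#' the edge of the display reappears on the other side.
#'
#' @param elements Element table from [init_mmm_elements()].
#' @param dt Time step in seconds (> 0).
#' @param geometry A [display_geometry()].
#' @return The element table with updated positions.
#' @export
step_mmm <- function(elements, dt, geometry) {
  stopifnot(inherits(geometry, "cfs_geometry"))
  if (dt <= 0) stop_invalid("dt must be positive")
  B <- geometry$mask_bound
  wrap <- function(v) ((v + B / 2) %% B) - B / 2
  elements$x <- wrap(elements$x + elements$dx * elements$speed * dt)
  elements$y <- wrap(elements$y + elements$dy * elements$speed * dt)
  elements
}

# Integer pixel block covered by a square element centered at (x, y) deg.
# Returns NULL when entirely off-frame.
element_block <- function(x, y, geometry) {
  ppd <- geometry$pixels_per_degree
  half <- geometry$mask_bound / 2
  s <- max(1L, as.integer(round(geometry$element_size * ppd)))
  left <- as.integer(round((x - geometry$element_size / 2 + half) * ppd)) + 1L
  top <- as.integer(round((half - (y + geometry$element_size / 2)) * ppd)) + 1L
  side <- geometry$side_px
  rows <- max(1L, top):min(side, top + s - 1L)
  cols <- max(1L, left):min(side, left + s - 1L)
  if (top + s - 1L < 1L || top > side || left + s - 1L < 1L || left > side) {
    return(NULL)
  }
  list(rows = rows, cols = cols)
}

#' Render one mask frame
#'
#' Draws each element as a filled square of `element_size` on a mid-gray
#' background. Overlapping elements are drawn on top of one another in list
#' order (later elements occlude earlier ones).
#'
#' @param elements Element table.
#' @param geometry A [display_geometry()].
#' @return A `side_px` x `side_px` x 3 array of RGB values in `[0, 1]`.
#' @export
render_mask_frame <- function(elements, geometry) {
  stopifnot(inherits(geometry, "cfs_geometry"))
  if (nrow(elements) == 0L) stop_invalid("elements must be non-empty")
  side <- geometry$side_px
  frame <- array(0.5, dim = c(side, side, 3))
  pal <- mask_palette()
  for (i in seq_len(nrow(elements))) {
    blk <- element_block(elements$x[i], elements$y[i], geometry)
    if (is.null(blk)) next
    rgb <- pal[elements$color[i], ]
    frame[blk$rows, blk$cols, 1] <- rgb[1]
    frame[blk$rows, blk$cols, 2] <- rgb[2]
    frame[blk$rows, blk$cols, 3] <- rgb[3]
  }
  frame
}

# Fast single-channel render: draws luma values directly (identical to
# luma(render_mask_frame(...))).
render_mask_gray <- function(elements, geometry) {
  side <- geometry$side_px
  frame <- matrix(0.5, side, side)
  lum <- mask_luma()
  for (i in seq_len(nrow(elements))) {
    blk <- element_block(elements$x[i], elements$y[i], geometry)
    if (is.null(blk)) next
    frame[blk$rows, blk$cols] <- lum[elements$color[i]]
  }
  frame
}

#' Convert an RGB frame to grayscale
#'
#' Standard Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param frame A H x W x 3 array, or a matrix (returned unchanged).
#' @return A H x W matrix of luminance values.
#' @export
luma <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] == 3L)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

new_frame_sequence <- function(frames, frame_rate, meta) {
  structure(
    list(frames = frames,
         timestamps = (seq_along(frames) - 1) / frame_rate,
         meta = meta),
    class = "cfs_frames")
}

#' @export
print.cfs_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cfs_frames> %d frames of %dx%d (%s)\n",
              length(x$frames), d[1], d[2],
              paste(deparse(x$meta$condition), collapse = "")))
  invisible(x)
}

#' Generate a flashing (classic CFS) mask sequence
#'
#' Classic continuous flash suppression: an independent random layout of
#' `n_elements` squares is generated every `1/refresh_rate` seconds and held
#' for `round(frame_rate / refresh_rate)` consecutive frames (exactly 6
#' frames for the canonical 60 fps / 10 Hz case).
#'
#' @param geometry A [display_geometry()].
#' @param duration Trial length in seconds.
#' @param refresh_rate Mask refresh rate in Hz (default 10); must not exceed
#'   the frame rate.
#' @param seed Integer seed.
#' @param gray If `TRUE`, frames are luminance matrices instead of RGB arrays.
#' @return A `cfs_frames` sequence of `round(duration * frame_rate)` frames.
#' @export
generate_cfs_sequence <- function(geometry, duration, refresh_rate = 10,
                                  seed = 1L, gray = FALSE) {
  stopifnot(inherits(geometry, "cfs_geometry"))
  if (refresh_rate > geometry$frame_rate) {
    stop_invalid("refresh_rate must not exceed the frame rate")
  }
  n_frames <- as.integer(round(duration * geometry$frame_rate))
  hold <- max(1L, as.integer(round(geometry$frame_rate / refresh_rate)))
  n_layouts <- ceiling(n_frames / hold)
  layout_seeds <- derive_seeds(seed, max(n_layouts, 1L))
  render <- if (gray) render_mask_gray else render_mask_frame
  frames <- vector("list", n_frames)
  for (l in seq_len(n_layouts)) {
    el <- mmm_layout(geometry, layout_seeds[l])
    img <- render(el, geometry)
    idx <- ((l - 1L) * hold + 1L):min(l * hold, n_frames)
    for (f in idx) frames[[f]] <- img
  }
  new_frame_sequence(frames, geometry$frame_rate,
                     list(condition = list(type = "cfs",
                                           refresh_rate = refresh_rate),
                          seed = seed, geometry = geometry))
}

#' Generate a moving-Mondrian mask sequence
#'
#' Elements translate smoothly frame to frame at a common speed, wrapping at
#' the display edges.
#'
#' @inheritParams generate_cfs_sequence
#' @param speed Element speed in deg/s.
#' @return A `cfs_frames` sequence.
#' @export
generate_mmm_sequence <- function(geometry, duration, speed, seed = 1L,
                                  gray = FALSE) {
  stopifnot(inherits(geometry, "cfs_geometry"))
  n_frames <- as.integer(round(duration * geometry$frame_rate))
  dt <- 1 / geometry$frame_rate
  el <- init_mmm_elements(geometry, speed, seed)
  render <- if (gray) render_mask_gray else render_mask_frame
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frames[[f]] <- render(el, geometry)
    if (f < n_frames) el <- step_mmm(el, dt, geometry)
  }
  new_frame_sequence(frames, geometry$frame_rate,
                     list(condition = list(type = "mmm", speed = speed),
                          seed = seed, geometry = geometry))
}

#' Target specification
#'
#' A circular target (diameter `element_size`) that traverses the display
#' right to left on one of six horizontal motion paths (three above, three
#' below fixation; adjacent paths separated by twice the target size) and
#' fades in linearly over the first `fade_in_frames` frames.
#'
#' @param speed Target speed (deg/s).
#' @param path_index Motion path, 1 (top) to 6 (bottom).
#' @param contrast Plateau contrast in `[0, 1]`.
#' @param fade_in_frames Frames of the linear contrast ramp (default 20).
#' @param duration Trial length (s).
#' @return An object of class `cfs_target_spec`.
#' @export
target_spec <- function(speed, path_index, contrast, fade_in_frames = 20L,
                        duration = 3.6) {
  if (!path_index %in% 1:6) stop_invalid("path_index must be in 1..6")
  if (contrast < 0 || contrast > 1) stop_invalid("contrast must be in [0, 1]")
  if (speed <= 0 || duration <= 0) stop_invalid("speed and duration must be positive")
  structure(list(speed = speed, path_index = as.integer(path_index),
                 contrast = contrast,
                 fade_in_frames = as.integer(fade_in_frames),
                 duration = duration),
            class = "cfs_target_spec")
}

# Vertical offsets (deg) of the six paths, symmetric about fixation,
# adjacent separation = 2 * element_size.
target_path_offsets <- function(geometry) {
  geometry$element_size * c(5, 3, 1, -1, -3, -5)
}

#' Generate a moving-target sequence
#'
#' The target is a red circle moving right to left at `spec$speed` on the
#' selected path. Its contrast ramps linearly from `contrast / fade_in_frames`
#' on the first frame to the full `spec$contrast` on frame `fade_in_frames`,
#' and stays constant thereafter. The target enters at the right edge of the
#' virtual target region (`x = target_region / 2`) and moves left; once it
#' leaves the display only the background is drawn, and the sequence ends at
#' `spec$duration`.
#'
#' @param spec A [target_spec()].
#' @param geometry A [display_geometry()].
#' @return A `cfs_frames` sequence of RGB frames.
#' @export
generate_target_sequence <- function(spec, geometry) {
  stopifnot(inherits(spec, "cfs_target_spec"), inherits(geometry, "cfs_geometry"))
  n_frames <- as.integer(round(spec$duration * geometry$frame_rate))
  dt <- 1 / geometry$frame_rate
  side <- geometry$side_px
  ppd <- geometry$pixels_per_degree
  half <- geometry$mask_bound / 2
  r <- geometry$element_size / 2
  y0 <- target_path_offsets(geometry)[spec$path_index]
  x_start <- geometry$target_region / 2

  # pixel-center coordinates in degrees
  px_x <- ((seq_len(side)) - 0.5) / ppd - half
  px_y <- half - ((seq_len(side)) - 0.5) / ppd
  target_rgb <- c(1, 0, 0) # red

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    cx <- x_start - spec$speed * (f - 1) * dt
    c_f <- spec$contrast * min(f / spec$fade_in_frames, 1)
    frame <- array(0.5, dim = c(side, side, 3))
    in_x <- which(abs(px_x - cx) <= r)
    in_y <- which(abs(px_y - y0) <= r)
    if (length(in_x) && length(in_y)) {
      dx2 <- (px_x[in_x] - cx)^2
      dy2 <- (px_y[in_y] - y0)^2
      disk <- outer(dy2, dx2, "+") <= r^2
      for (ch in 1:3) {
        sub <- frame[in_y, in_x, ch, drop = FALSE]
        sub[disk] <- 0.5 + c_f * (target_rgb[ch] - 0.5)
        frame[in_y, in_x, ch] <- sub
      }
    }
    frames[[f]] <- frame
  }
  new_frame_sequence(frames, geometry$frame_rate,
                     list(condition = list(type = "target", spec = spec),
                          seed = NA, geometry = geometry))
}

#' Write a frame sequence to disk
#'
#' Frames are written as 8-bit PNG files (requires the `png` package) plus a
#' JSON sidecar with condition, seed, frame rate and geometry.
#'
#' @param seq A `cfs_frames` sequence.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_frames <- function(seq, dir) {
  stopifnot(inherits(seq, "cfs_frames"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_invalid("writing PNG frames requires the 'png' package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(seq$frames))
  for (f in seq_along(seq$frames)) {
    paths[f] <- file.path(dir, sprintf("frame_%04d.png", f))
    png::writePNG(seq$frames[[f]], paths[f])
  }
  meta <- seq$meta
  meta$geometry <- unclass(meta$geometry)
  sidecar <- file.path(dir, "meta.json")
  jsonlite::write_json(
    list(condition = meta$condition, seed = meta$seed,
         frame_rate = seq$meta$geometry$frame_rate, geometry = meta$geometry),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
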