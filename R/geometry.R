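#' Display geometry for mask and target rendering
#'
#' Describes the spatial and temporal raster onto which masks and targets are
#' drawn. All spatial extents are in degrees of visual angle; the rendered
#' frame is a square of side `round(mask_bound * pixels_per_degree)` pixels.
#'
#' The defaults follow the stimulus configuration of the masking experiments
#' this package emulates: a 7.32 deg bounding square containing 150 mask
#' squares of 0.46 deg, a 5.5 deg virtual target region, and a 60 Hz frame
#' rate. `pixels_per_degree` trades spatial fidelity against compute; the
#' default of 17.5 px/deg gives a 128 px frame suitable for desk-scale
#' adaptation simulations.
#'
#' @param frame_rate Temporal sampling rate in Hz.
#' @param pixels_per_degree Spatial scale of the raster (px/deg).
#' @param mask_bound Side of the mask bounding square (deg).
#' @param target_region Side of the virtual square traversed by the target (deg).
#' @param element_size Side of each mask square and diameter of the target (deg).
#' @param n_elements Number of mask squares.
#' @return An object of class `cfs_geometry`.
#' @export
#' @examples
#' geom <- display_geometry()
#' geom$side_px
display_geometry <- function(frame_rate = 60, pixels_per_degree = 17.5,
                             mask_bound = 7.32, target_region = 5.5,
                             element_size = 0.46, n_elements = 150L) {
  if (frame_rate <= 0 || pixels_per_degree <= 0 || mask_bound <= 0 ||
      target_region <= 0 || element_size <= 0 || n_elements <= 0) {
    stop_invalid("all geometry extents must be strictly positive")
  }
  if (target_region > mask_bound) {
    stop_invalid("target_region must not exceed mask_bound")
  }
  side_px <- as.integer(round(mask_bound * pixels_per_degree))
  if (side_px < 8L) {
    stop_invalid("rendered frame side must be at least 8 px; ",
                 "increase pixels_per_degree")
  }
  structure(
    list(frame_rate = frame_rate,
         pixels_per_degree = pixels_per_degree,
         mask_bound = mask_bound,
         target_region = target_region,
         element_size = element_size,
         n_elements = as.integer(n_elements),
         side_px = side_px),
    class = "cfs_geometry")
}

#' @export
print.cfs_geometry <- function(x, ...) {
  cat(sprintf(
    "<cfs_geometry> %d px (%.2f deg at %.2f px/deg), %d elements of %.2f deg, %g Hz\n",
    x$side_px, x$mask_bound, x$pixels_per_degree, x$n_elements,
    x$element_size, x$frame_rate))
  invisible(x)
}

# Canonical unit direction vectors: right, left, up, down and the two
# diagonals (bottom-left to top-right, top-left to bottom-right).
mask_directions <- function() {
  s <- 1 / sqrt(2)
  matrix(c(1, 0,
           -1, 0,
           0, 1,
           0, -1,
           s, s,
           s, -s),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("right", "left", "up", "down",
                           "diag_up", "diag_down"), c("dx", "dy")))
}

mask_colors <- function() c("red", "green", "blue", "yellow")

# RGB palette for the four mask colors (unit cube, full saturation).
mask_palette <- function() {
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, 0, 1,
           1, 1, 0),
         ncol = 3, byrow = TRUE,
         dimnames = list(mask_colors(), c("r", "g", "b")))
}

# Luma (Rec. 601) of the palette entries, used for direct grayscale rendering.
mask_luma <- function() {
  pal <- mask_palette()
  drop(pal %*% c(0.299, 0.587, 0.114))
}
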