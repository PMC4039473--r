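#' Build the odd-symmetric Gabor filter bank
#'
#' Two sine-phase (odd-symmetric) Gabor kernels at 0 and 90 degrees with the
#' carrier at the Nyquist wavelength (2 px by default). The Gaussian envelope
#' follows the standard wavelength/bandwidth relation
#' \deqn{\sigma = \frac{\lambda}{\pi}\sqrt{\frac{\ln 2}{2}}\;
#'       \frac{2^b + 1}{2^b - 1}}
#' where \eqn{\lambda} is the wavelength in pixels and \eqn{b} the half-height
#' bandwidth in octaves. The kernel support is four standard deviations wide.
#'
#' Because a Nyquist sine carrier vanishes at every integer sample, the
#' kernels are sampled at half-integer offsets, which requires an even kernel
#' side (the even integer nearest to \eqn{4\sigma}, at least 4). There the
#' carrier attains its extrema (+1/-1), kernels are exactly odd-symmetric and
#' therefore zero-mean.
#'
#' The response threshold separating "no response" from a labeled response
#' defaults to `eps_frac` times the maximum absolute response of the bank to
#' a full-contrast straight luminance edge (computed numerically when the
#' bank is built).
#'
#' @param image_side Side of the images to be filtered (px, >= 8); recorded
#'   for reference and used for the edge-response calibration.
#' @param b Bandwidth in octaves (> 0), default 1.
#' @param wavelength Carrier wavelength in pixels, default 2 (Nyquist).
#' @param eps_frac Response threshold as a fraction of the maximal edge
#'   response, default 0.05.
#' @return An object of class `cfs_gabor_bank` with elements `k0`, `k90`
#'   (kernel matrices), `sigma`, `kernel_side`, `epsilon`, `max_edge_response`.
#' @export
#' @examples
#' bank <- build_gabor_bank(128)
#' bank$sigma
build_gabor_bank <- function(image_side, b = 1, wavelength = 2,
                             eps_frac = 0.05) {
  if (image_side < 8) stop_invalid("image_side must be at least 8")
  if (b <= 0) stop_invalid("bandwidth b must be strictly positive")
  sigma <- (wavelength / pi) * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
  side <- max(4L, 2L * as.integer(round(4 * sigma / 2)))
  off <- seq_len(side) - (side + 1) / 2 # half-integers for even side
  env <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  carrier_x <- sin(2 * pi * off / wavelength)
  # orientation 0: carrier varies along x (columns); orientation 90: along y
  k0 <- env * matrix(carrier_x, side, side, byrow = TRUE)
  k90 <- env * matrix(carrier_x, side, side, byrow = FALSE)

  # calibrate the response threshold on ideal unit-contrast step edges
  edge_v <- matrix(rep(c(0, 1), each = 16 * 16), 16, 32) # vertical edge
  ref <- max(abs(cpp_conv2_replicate(edge_v, k0)),
             abs(cpp_conv2_replicate(edge_v, k90)),
             abs(cpp_conv2_replicate(t(edge_v), k0)),
             abs(cpp_conv2_replicate(t(edge_v), k90)))
  structure(
    list(k0 = k0, k90 = k90, sigma = sigma, kernel_side = side,
         wavelength = wavelength, bandwidth = b, image_side = image_side,
         max_edge_response = ref, epsilon = eps_frac * ref),
    class = "cfs_gabor_bank")
}

#' @export
print.cfs_gabor_bank <- function(x, ...) {
  cat(sprintf(
    "<cfs_gabor_bank> lambda = %g px, b = %g oct, sigma = %.4f px, side = %d, eps = %.4g\n",
    x$wavelength, x$bandwidth, x$sigma, x$kernel_side, x$epsilon))
  invisible(x)
}

#' Classify per-pixel filter responses into five categories
#'
#' Convolves a grayscale frame with both bank kernels and assigns each pixel
#' one of five labels: no response (when the larger absolute response is
#' below the threshold), or the orientation of the larger absolute response
#' signed by its polarity. Convolution uses replicate (nearest-edge) padding
#' so a uniform frame produces zero response everywhere.
#'
#' @param gray_frame A single-channel matrix.
#' @param bank A [build_gabor_bank()] bank.
#' @param epsilon Response threshold; defaults to the bank's calibrated value.
#' @return An integer matrix of codes 0..4 with a `labels` attribute
#'   `c("none", "H+", "H-", "V+", "V-")` (H = 0-degree kernel, V = 90-degree).
#' @export
classify_responses <- function(gray_frame, bank, epsilon = bank$epsilon) {
  if (!is.matrix(gray_frame)) {
    stop_invalid("gray_frame must be a single-channel matrix")
  }
  if (epsilon < 0) stop_invalid("epsilon must be non-negative")
  lab <- cpp_gabor_classify(gray_frame, bank$k0, bank$k90, epsilon)
  attr(lab, "labels") <- c("none", "H+", "H-", "V+", "V-")
  lab
}
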