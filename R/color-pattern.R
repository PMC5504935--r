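#' Pixel-level color pattern primitives
#'
#' The extractor compares pixels not by their raw RGB distances but by the
#' angle between the two pixel vectors in RGB space: the length of a pixel
#' vector tracks illumination intensity while its direction tracks color, so
#' the angle is (up to quantization) invariant under global multiplicative
#' illumination change.  These functions implement the raw channel
#' differences, the vector-angle pattern, the squared RGB distance used as a
#' seed-proximity gate during subregion extraction, and the percentage
#' variation-rate metric used to report how strongly illumination shifted a
#' pixel's saturation or lightness between two acquisitions.
#'
#' @name color-pattern
NULL

as_pixel <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3 || anyNA(p))
    stop_spellerseg("a pixel must be 3 finite channel values", "bad_pixel")
  if (any(p < 0) || any(p > 255))
    stop_spellerseg("pixel channels must lie in [0, 255]", "bad_pixel")
  p
}

#' Channel-wise difference between two pixels
#'
#' @param p,q RGB pixels: numeric vectors of length 3 with channels in
#'   `[0, 255]`.
#' @return Integer vector `(dR, dG, dB)`, each component in `[-255, 255]`.
#' @examples
#' channel_differences(c(186, 69, 34), c(104, 140, 53))
#' @export
channel_differences <- function(p, q) {
  p <- as_pixel(p); q <- as_pixel(q)
  as.integer(round(p - q))
}

#' Angle between two pixel vectors in RGB space
#'
#' The color pattern at the heart of the extractor: each pixel is a vector
#' from the origin of RGB space, and the dissimilarity of two pixels is the
#' angle between their vectors.  Nonnegative channels confine the angle to
#' `[0, pi/2]`.  The all-zero pixel has no direction and is rejected.
#'
#' @inheritParams channel_differences
#' @return Angle in radians, in `[0, pi/2]` for 8-bit pixels.
#' @examples
#' vector_angle(c(100, 100, 100), c(200, 200, 200))  # collinear: 0
#' vector_angle(c(255, 0, 0), c(0, 255, 0))          # orthogonal: pi/2
#' @export
vector_angle <- function(p, q) {
  p <- as_pixel(p); q <- as_pixel(q)
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0)
    stop_spellerseg("degenerate all-zero pixel has no direction", "degenerate_pixel")
  acos(max(-1, min(1, sum(p * q) / (np * nq))))
}

# vectorized angle of every pixel of an image against one reference pixel;
# image is an M x N x 3 array, returns an M x N matrix.  Zero pixels get NA.
angle_map <- function(image, q) {
  q <- as_pixel(q)
  nq <- sqrt(sum(q^2))
  if (nq == 0)
    stop_spellerseg("degenerate all-zero pixel has no direction", "degenerate_pixel")
  dot <- image[, , 1] * q[1] + image[, , 2] * q[2] + image[, , 3] * q[3]
  np <- sqrt(image[, , 1]^2 + image[, , 2]^2 + image[, , 3]^2)
  a <- acos(pmin(pmax(dot / (np * nq), -1), 1))
  a[np == 0] <- NA_real_
  a
}

#' Squared RGB distance between two pixels
#'
#' The proximity gate used while iterating over subregions: the sum of
#' squared channel differences, deliberately without the square root, so the
#' configured gate threshold `r` carries squared-intensity units.
#'
#' @inheritParams channel_differences
#' @return Nonnegative scalar `sum((p - q)^2)`.
#' @export
rgb_distance_sq <- function(p, q) {
  p <- as_pixel(p); q <- as_pixel(q)
  sum((p - q)^2)
}

#' Percentage variation rate between a reference and an alternate value
#'
#' Reports how much a scalar pixel attribute (saturation, lightness)
#' changed between a reference acquisition and an alternate one:
#' `100 * |ref - alt| / ref`, rounded half-up to one decimal.  The reference
#' is always the first acquisition's value.
#'
#' @param v_ref Reference value(s), strictly positive.
#' @param v_alt Alternate value(s).
#' @return Variation rate(s) in percent, one decimal.
#' @examples
#' variation_rate(140, 163)  # 16.4
#' variation_rate(90, 120)   # 33.3
#' @export
variation_rate <- function(v_ref, v_alt) {
  v_ref <- as.numeric(v_ref); v_alt <- as.numeric(v_alt)
  if (any(!is.finite(v_ref)) || any(v_ref <= 0))
    stop_spellerseg("reference value must be positive", "nonpositive_reference")
  round_half_up(100 * abs(v_ref - v_alt) / v_ref, 1)
}
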