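#' Fuzzy decision core
#'
#' A Mamdani-style fuzzy inference system decides whether a candidate pixel
#' belongs to the seeded object.  The input variable is the vector angle
#' between the candidate and the seed; three piecewise-linear memberships
#' (negative / zero / positive, with breakpoints `alpha1 < alpha2`) fuzzify
#' it.  Two rules map these onto output sets "matched" (a triangle falling
#' from 1 at angle 0 to 0 at `rho_u`) and "unmatched" (a ramp rising from 0
#' at `rho_m` to 1 at pi/2), with `rho_m + rho_u = pi/2`.  The crisp output
#' is the centroid of the clipped output envelope; the pixel is extracted
#' when that centroid falls below the per-object threshold `sigma`.
#'
#' @name fuzzy-engine
NULL

#' Per-object fuzzy parameters
#'
#' @param alpha1,alpha2 Input membership breakpoints in radians,
#'   `0 < alpha1 < alpha2 <= pi/2`.  Angles below `alpha1` are fully
#'   "zero" (matched evidence); above `alpha2` fully "positive"
#'   (unmatched evidence).
#' @param rho_m Output breakpoint in radians, `0 < rho_m < pi/2`; the
#'   complementary breakpoint `rho_u = pi/2 - rho_m` is derived.
#' @param sigma Extraction threshold on the defuzzified output, radians.
#' @param r Seed-proximity gate threshold in squared-intensity units
#'   (see [rgb_distance_sq()]); `Inf` disables the gate.
#' @param gap_threshold Row/column gap-filling threshold in pixels.
#' @return An object of class `fuzzy_params`.
#' @examples
#' fuzzy_params(0.2, 0.3, 0.2, 0.5)  # a warm orange-red object
#' @export
fuzzy_params <- function(alpha1, alpha2, rho_m, sigma,
                         r = Inf, gap_threshold = 3) {
  stopifnot(is.numeric(alpha1), is.numeric(alpha2), is.numeric(rho_m),
            is.numeric(sigma), length(alpha1) == 1)
  if (!(alpha1 > 0 && alpha1 < alpha2 && alpha2 <= pi / 2))
    stop_spellerseg("need 0 < alpha1 < alpha2 <= pi/2", "bad_params")
  if (!(rho_m > 0 && rho_m < pi / 2))
    stop_spellerseg("need 0 < rho_m < pi/2", "bad_params")
  if (!(sigma > 0 && sigma < pi / 2))
    stop_spellerseg("need sigma in (0, pi/2)", "bad_params")
  if (!(r > 0)) stop_spellerseg("need r > 0", "bad_params")
  if (gap_threshold < 0) stop_spellerseg("need gap_threshold >= 0", "bad_params")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 rho_m = rho_m, rho_u = pi / 2 - rho_m,
                 sigma = sigma, r = r, gap_threshold = gap_threshold),
            class = "fuzzy_params")
}

#' @export
print.fuzzy_params <- function(x, ...) {
  cat(sprintf(
    "fuzzy parameters: alpha1=%.3g alpha2=%.3g rho_m=%.3g (rho_u=%.4g) sigma=%.3g r=%.4g gap=%d\n",
    x$alpha1, x$alpha2, x$rho_m, x$rho_u, x$sigma, x$r,
    as.integer(x$gap_threshold)))
  invisible(x)
}

#' Input membership degrees for an angle
#'
#' Piecewise-linear memberships of the input fuzzy variables negative,
#' zero and positive.  Intervals are left-closed; the positive membership
#' is 0 on `[-alpha1, alpha1)`, mirroring the negative one.  Angles from
#' [vector_angle()] are nonnegative so the negative set is retained only
#' for completeness of the input domain `[-pi/2, pi/2]`.
#'
#' @param x Angle(s) in radians, each in `[-pi/2, pi/2]`.
#' @param params A [fuzzy_params()] object.
#' @return For scalar `x`, a named vector `c(N=, Z=, P=)`; for vector `x`,
#'   a matrix with columns `N`, `Z`, `P`.
#' @export
input_memberships <- function(x, params) {
  stopifnot(inherits(params, "fuzzy_params"))
  if (any(x < -pi / 2 - 1e-12) || any(x > pi / 2 + 1e-12))
    stop_spellerseg("angle outside [-pi/2, pi/2]", "domain_error")
  a1 <- params$alpha1; a2 <- params$alpha2
  muN <- ifelse(x < -a2, 1, ifelse(x < -a1, (x + a1) / (a1 - a2), 0))
  muZ <- ifelse(x < -a2, 0,
         ifelse(x < -a1, (x + a2) / (a2 - a1),
         ifelse(x < a1, 1,
         ifelse(x < a2, (a2 - x) / (a2 - a1), 0))))
  muP <- ifelse(x < a1, 0, ifelse(x < a2, (x - a1) / (a2 - a1), 1))
  out <- cbind(N = muN, Z = muZ, P = muP)
  if (length(x) == 1) out[1, ] else out
}

#' Rule weights from input memberships
#'
#' Rule 1: zero angle difference means the pixels match (`w_m = mu_Z`).
#' Rule 2: a negative or positive difference means they do not
#' (`w_u = max(mu_N, mu_P)`).
#'
#' @param memberships Named vector `c(N=, Z=, P=)` from
#'   [input_memberships()].
#' @return Named vector `c(wm=, wu=)`, both in `[0, 1]`.
#' @export
rule_weights <- function(memberships) {
  m <- as.numeric(memberships)
  if (length(m) != 3 || any(m < 0) || any(m > 1))
    stop_spellerseg("memberships must be three degrees in [0,1]", "bad_params")
  c(wm = m[2], wu = max(m[1], m[3]))
}

# Exact centroid of the Mamdani output envelope
#   mu_out(x) = max(min(wm, muM(x)), min(wu, muU(x)))  on [0, pi/2]
# with muM a triangle falling 1 -> 0 over [0, rho_u] and muU a ramp rising
# 0 -> 1 over [rho_m, pi/2].  Uses max(f1,f2) = f1 + f2 - min(f1,f2); the
# overlap min(f1,f2) = min(wm, wu, tent(x)) is symmetric about
# (rho_m + rho_u)/2 so its moment is area * midpoint.  Vectorized in wm, wu.
defuzz_exact <- function(wm, wu, rho_m) {
  U <- pi / 2 - rho_m; m <- rho_m; P <- pi / 2
  t1 <- U * (1 - wm)
  A1 <- wm * U * (1 - wm / 2)
  M1 <- wm * t1^2 / 2 + U^2 / 6 - t1^2 / 2 + t1^3 / (3 * U)
  t2 <- m + wu * U
  A2 <- wu * U * (1 - wu / 2)
  M2 <- ((t2^3 / 3 - m * t2^2 / 2) - (m^3 / 3 - m^3 / 2)) / U +
    wu * (P^2 - t2^2) / 2
  if (m < U) {
    hm <- (U - m) / (2 * U)
    cc <- pmin(wm, wu)
    Amin <- ifelse(cc >= hm, (U - m)^2 / (4 * U), cc * (U - m) - cc^2 * U)
  } else Amin <- 0
  Mmin <- Amin * (U + m) / 2
  A <- A1 + A2 - Amin
  (M1 + M2 - Mmin) / A
}

# trapezoid-rule centroid of the same envelope on a uniform grid
defuzz_numeric <- function(wm, wu, rho_m, panels = 4096) {
  U <- pi / 2 - rho_m; m <- rho_m
  x <- seq(0, pi / 2, length.out = panels + 1)
  muM <- ifelse(x < U, (U - x) / U, 0)
  muU <- ifelse(x < m, 0, (x - m) / U)
  f <- pmax(pmin(wm, muM), pmin(wu, muU))
  h <- x[2] - x[1]
  trap <- function(v) sum((v[-1] + v[-length(v)]) / 2) * h
  trap(f * x) / trap(f)
}

#' Centroid defuzzification of the rule weights
#'
#' The crisp output is the center of mass of the envelope obtained by
#' clipping the matched output set at `wm` and the unmatched set at `wu`
#' and taking their pointwise maximum over `[0, pi/2]`.  The default
#' method integrates the piecewise-quadratic moment exactly in closed
#' form; `method = "numeric"` evaluates the same envelope with the
#' trapezoid rule on a uniform grid and exists as an independent check of
#' the algebra.
#'
#' @param weights Named vector `c(wm=, wu=)` from [rule_weights()].
#' @param params A [fuzzy_params()] object (only `rho_m` matters here).
#' @param method `"exact"` (closed form) or `"numeric"` (trapezoid rule).
#' @param panels Number of trapezoid panels for `method = "numeric"`.
#' @return Defuzzified output in radians, in `[0, pi/2]`.
#' @examples
#' p <- fuzzy_params(0.2, 0.3, 0.2, 0.5)
#' defuzzify(c(wm = 1, wu = 0), p)  # (pi/2 - 0.2) / 3
#' @export
defuzzify <- function(weights, params, method = c("exact", "numeric"),
                      panels = 4096) {
  stopifnot(inherits(params, "fuzzy_params"))
  method <- match.arg(method)
  wm <- as.numeric(weights[["wm"]]); wu <- as.numeric(weights[["wu"]])
  if (anyNA(c(wm, wu)) || wm < 0 || wu < 0 || wm > 1 || wu > 1)
    stop_spellerseg("rule weights must be in [0, 1]", "bad_params")
  if (wm + wu <= 0)
    stop_spellerseg("zero-area envelope: both rule weights are 0", "zero_area")
  if (method == "exact") defuzz_exact(wm, wu, params$rho_m)
  else defuzz_numeric(wm, wu, params$rho_m, panels)
}

# full inference chain on a vector of nonnegative angles -> defuzzified
# output.  On [0, pi/2] the zero/positive memberships are complementary so
# wm + wu = 1 and both weights follow from the zero membership alone.
defuzz_of_angle <- function(x, params) {
  a1 <- params$alpha1; a2 <- params$alpha2
  wm <- pmin(1, pmax(0, (a2 - x) / (a2 - a1)))
  wm[x < a1] <- 1
  wm[x >= a2] <- 0
  defuzz_exact(wm, 1 - wm, params$rho_m)
}

#' Fuzzy extraction decision for a candidate pixel
#'
#' Runs the full chain angle -> memberships -> rule weights -> centroid
#' and extracts the pixel when the defuzzified output falls below the
#' object's threshold `sigma`.  The decision inherits the scale invariance
#' of the angle pattern: multiplying the candidate's channels by any
#' positive scalar leaves it unchanged.
#'
#' @param p Candidate pixel (length-3 RGB vector).
#' @param seed The object's seed pixel.
#' @param params A [fuzzy_params()] object.
#' @return `TRUE` iff the candidate is extracted.
#' @export
match_decision <- function(p, seed, params) {
  stopifnot(inherits(params, "fuzzy_params"))
  defuzz_of_angle(vector_angle(p, seed), params) < params$sigma
}

# vectorized decision over a whole image: M x N logical matrix;
# degenerate (all-zero) pixels never match
match_mask <- function(image, seed, params) {
  a <- angle_map(image, seed)
  out <- matrix(FALSE, nrow(a), ncol(a))
  ok <- !is.na(a)
  out[ok] <- defuzz_of_angle(a[ok], params) < params$sigma
  out
}
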