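# Two-pathway catch-slip dissociation model shared by the bond-lifetime
# generator and the lifetime-curve analysis. The off-rate is the sum of a
# force-suppressed (catch) and a force-accelerated (slip) pathway:
#   k(F) = k_c0 * exp(-F / f_c) + k_s0 * exp(F / f_s)
# Mean bond lifetime at clamping force F is 1 / k(F). A pure slip bond is
# the k_c0 = 0 limit. Being a positive sum of convex exponentials, k(F) has
# at most one interior minimum, so this model produces flat, slip, or
# single-peak catch-slip lifetime curves (not triphasic ones).

#' Catch-slip bond kinetic parameters
#'
#' @param k_c0 Zero-force off-rate of the catch pathway (1/s); `0` encodes a
#'   pure slip bond.
#' @param f_c Force scale of catch-pathway suppression (pN).
#' @param k_s0 Zero-force off-rate of the slip pathway (1/s).
#' @param f_s Force scale of slip-pathway acceleration (pN).
#' @return An object of class `catch_slip_params`.
#' @export
catch_slip_params <- function(k_c0, f_c, k_s0, f_s) {
  stopifnot(k_c0 >= 0, f_c > 0, k_s0 > 0, f_s > 0)
  structure(list(k_c0 = k_c0, f_c = f_c, k_s0 = k_s0, f_s = f_s),
            class = "catch_slip_params")
}

#' Off-rate of a catch-slip bond at a clamping force
#'
#' @param force Clamping force(s), pN.
#' @param params A [catch_slip_params()].
#' @return Dissociation rate(s), 1/s; mean lifetime is `1 / catch_slip_rate()`.
#' @export
catch_slip_rate <- function(force, params) {
  stopifnot(inherits(params, "catch_slip_params"))
  params$k_c0 * exp(-force / params$f_c) + params$k_s0 * exp(force / params$f_s)
}

#' Analytic lifetime peak of a catch-slip bond
#'
#' Minimizes `k(F)` in closed form: the stationarity condition gives
#' `F* = log(k_c0 f_s / (k_s0 f_c)) / (1/f_c + 1/f_s)`. For a pure slip bond
#' (or when the stationary point falls at non-positive force) the lifetime is
#' maximal at `F = 0`.
#'
#' @param params A [catch_slip_params()].
#' @return List with `peak_force` (pN) and `peak_lifetime` (s).
#' @export
catch_slip_peak <- function(params) {
  stopifnot(inherits(params, "catch_slip_params"))
  f_star <- 0
  if (params$k_c0 > 0) {
    arg <- params$k_c0 * params$f_s / (params$k_s0 * params$f_c)
    if (arg > 1)
      f_star <- log(arg) / (1 / params$f_c + 1 / params$f_s)
  }
  list(peak_force = f_star,
       peak_lifetime = 1 / catch_slip_rate(f_star, params))
}

#' Catch-slip parameters calibrated to a target lifetime peak
#'
#' Given the force scales of the two pathways, solves for `k_c0` and `k_s0`
#' so that the mean-lifetime curve peaks exactly at `peak_force` with value
#' `peak_lifetime`. Used to encode phenotypes reported as "peak at ~15 pN,
#' ~5 s" without hand-tuning rate constants.
#'
#' @param peak_force Force at maximal lifetime (pN), > 0.
#' @param peak_lifetime Maximal mean lifetime (s), > 0.
#' @param f_c,f_s Pathway force scales (pN).
#' @return A [catch_slip_params()].
#' @export
catch_slip_from_peak <- function(peak_force, peak_lifetime, f_c, f_s) {
  stopifnot(peak_force > 0, peak_lifetime > 0, f_c > 0, f_s > 0)
  ratio <- (f_c / f_s) * exp(peak_force * (1 / f_c + 1 / f_s))  # k_c0 / k_s0
  k_star <- 1 / peak_lifetime
  k_s0 <- k_star / (ratio * exp(-peak_force / f_c) + exp(peak_force / f_s))
  catch_slip_params(k_c0 = ratio * k_s0, f_c = f_c, k_s0 = k_s0, f_s = f_s)
}

#' Default bond-kinetics phenotypes
#'
#' Calibrated parameter sets reproducing the qualitative phenotypes of
#' integrin alphaIIb-beta3--fibrinogen bonds: a healthy catch-slip bond
#' peaking near 15 pN / 5 s, and a hypertensive one shifted right and up to
#' ~35 pN / 10 s. Rate constants are derived from these peaks via
#' [catch_slip_from_peak()]; they are calibration, not measurement.
#'
#' @return Named list of [catch_slip_params()]: `integrin_healthy`,
#'   `integrin_hypertensive`, `gpib_slip`.
#' @export
default_bond_phenotypes <- function() {
  list(
    integrin_healthy = catch_slip_from_peak(15, 5, f_c = 7, f_s = 12),
    integrin_hypertensive = catch_slip_from_peak(35, 10, f_c = 15, f_s = 25),
    # hypertensive GPIb-alpha--VWFA1: plain slip bond, long-lived at low force
    gpib_slip = catch_slip_params(k_c0 = 0, f_c = 1, k_s0 = 0.12, f_s = 18)
  )
}
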