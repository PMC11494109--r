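# From per-channel fluorescence time courses to the 7-dimension thrombus
# profile, logistic growth fits, and residue sizes.

#' Subtract platelet autofluorescence from a 391-nm channel
#'
#' Platelet autofluorescence leaks into the 391-nm excitation channel as a
#' fixed fraction of the platelet signal; the corrected trace is
#' `max(raw - coeff * platelet, 0)` elementwise.
#'
#' @param raw_391 Raw intensity sequence of the 391-nm channel.
#' @param platelet_channel Platelet intensity sequence (same length).
#' @param coeff Leak coefficient (>= 0).
#' @return Corrected intensity sequence.
#' @export
correct_autofluorescence <- function(raw_391, platelet_channel, coeff) {
  if (length(raw_391) != length(platelet_channel))
    stop("channel lengths differ")
  stopifnot(coeff >= 0)
  pmax(raw_391 - coeff * platelet_channel, 0)
}

#' Detect the onset of thrombus formation
#'
#' Onset is the first time at which the platelet signal exceeds the baseline
#' mean + `k_sd` standard deviations for `run` consecutive frames, where the
#' baseline is the first `n_baseline` (pre-perfusion) frames.
#'
#' @param platelet_channel Platelet intensity sequence.
#' @param times Time grid (s), same length.
#' @param n_baseline Number of leading frames treated as baseline.
#' @param k_sd Threshold in baseline standard deviations (default 3).
#' @param run Required consecutive supra-threshold frames (default 3).
#' @return Onset time (s), or `NA_real_` if the signal never rises.
#' @export
detect_onset <- function(platelet_channel, times, n_baseline = 5L,
                         k_sd = 3, run = 3L) {
  stopifnot(length(platelet_channel) == length(times),
            n_baseline >= 2L, n_baseline < length(times), run >= 1L)
  base <- platelet_channel[seq_len(n_baseline)]
  thr <- mean(base) + k_sd * stats::sd(base)
  above <- platelet_channel > thr
  if (length(above) >= run) {
    runs <- stats::filter(as.numeric(above), rep(1, run), sides = 1)
    hit <- which(runs == run)
    if (length(hit)) return(times[hit[1L] - run + 1L])
  }
  NA_real_
}

#' Quantify the 7-dimension thrombus profile
#'
#' Reads every channel `read_offset` seconds after the detected onset, using
#' a 3-frame local average for robustness to single-frame noise. Thrombus
#' size is the platelet intensity at the readout; each biomarker dimension is
#' its (autofluorescence-corrected, where applicable) intensity divided by
#' the size. Channels listed in the time-course metadata `af_channels` are
#' corrected with the metadata coefficient unless `af_coeff` overrides it.
#'
#' @param tc A `timecourse_set` (see [simulate_timecourses()]), or any list
#'   with `times`, `channels` (must include `platelet` and the six biomarker
#'   channels) and optional `metadata`.
#' @param read_offset Readout time after onset (s), default 450.
#' @param af_coeff Optional override of the autofluorescence coefficient.
#' @return An object of class `thrombus_profile`: named numeric vector over
#'   [profile_dims()].
#' @export
quantify_profile <- function(tc, read_offset = 450, af_coeff = NULL) {
  ch <- tc$channels
  need <- c("platelet", .PROFILE_DIMS[-1])
  missing <- setdiff(need, names(ch))
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  onset <- detect_onset(ch$platelet, tc$times)
  if (is.na(onset)) stop("no onset detected in platelet channel")
  read_t <- onset + read_offset
  idx <- which.min(abs(tc$times - read_t))
  if (idx >= length(tc$times) || tc$times[length(tc$times)] < read_t)
    stop("readout time beyond end of trace")
  win <- max(1L, idx - 1L):min(length(tc$times), idx + 1L)

  coeff <- if (!is.null(af_coeff)) af_coeff
           else tc$metadata$autofluorescence_coeff
  if (is.null(coeff)) coeff <- 0
  af_channels <- tc$metadata$af_channels
  if (is.null(af_channels)) af_channels <- character(0)

  size <- mean(ch$platelet[win])
  if (size <= 0)
    stop("platelet signal is zero at readout: thrombus formation failed")
  prof <- c(size = size)
  for (d in .PROFILE_DIMS[-1]) {
    sig <- ch[[d]]
    if (d %in% af_channels)
      sig <- correct_autofluorescence(sig, ch$platelet, coeff)
    prof[[d]] <- mean(sig[win]) / size
  }
  structure(prof, class = "thrombus_profile")
}

#' @export
print.thrombus_profile <- function(x, digits = 4, ...) {
  cat("Thrombus profile [size, fg, vwf, psel, ps, eplus, act]:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Fit a logistic growth curve to the platelet channel
#'
#' Least-squares fit of `A / (1 + exp(-(t - t_half) / tau))` to the
#' post-onset platelet trace (time measured from onset). The
#' plateau-approach time is reported as `t_half + log(19) * tau`, the time at
#' which the curve reaches 95% of its plateau.
#'
#' @param platelet_channel Platelet intensity sequence.
#' @param times Time grid (s).
#' @param onset Onset time (s); detected with [detect_onset()] when `NULL`.
#' @return An object of class `growth_fit`: list with `plateau`, `t_half`,
#'   `slope_scale` (tau), `onset`, `plateau_time` (s after onset) and
#'   `goodness` (residual standard error).
#' @export
fit_growth <- function(platelet_channel, times, onset = NULL) {
  stopifnot(length(platelet_channel) == length(times))
  if (is.null(onset)) onset <- detect_onset(platelet_channel, times)
  if (is.na(onset)) stop("no onset detected; cannot fit growth curve")
  keep <- times >= onset
  t_rel <- times[keep] - onset
  y <- platelet_channel[keep]
  if (stats::sd(y) == 0 || length(y) < 5L)
    stop("degenerate (constant or too short) trace; growth fit rejected")
  a0 <- max(y)
  t0 <- t_rel[which.min(abs(y - a0 / 2))]
  fit <- tryCatch(
    stats::nls(y ~ A / (1 + exp(-(t_rel - th) / tau)),
               start = list(A = a0, th = max(t0, 1), tau = diff(range(t_rel)) / 6),
               lower = c(A = 0, th = 0, tau = 1e-6),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) stop("growth fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(plateau = unname(cf["A"]), t_half = unname(cf["th"]),
                 slope_scale = unname(cf["tau"]), onset = onset,
                 plateau_time = unname(cf["th"] + log(19) * cf["tau"]),
                 goodness = stats::sigma(fit)),
            class = "growth_fit")
}

#' Thrombus residue size under treatment
#'
#' @param treated_size Thrombus size with inhibitor (AFU).
#' @param control_size Untreated thrombus size (AFU), > 0.
#' @return Residue size in percent, `100 * treated / control`.
#' @export
residue_size <- function(treated_size, control_size) {
  if (any(control_size <= 0)) stop("control size must be positive")
  stopifnot(all(treated_size >= 0))
  100 * treated_size / control_size
}
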