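# Seeded synthetic-data generator. Emulates every input the analysis
# pipeline consumes: per-subject thrombus profiles across four cohorts,
# multi-channel fluorescence time courses, inhibitor dose effects, BFP touch
# sequences, force-clamped bond lifetimes, and ratiometric calcium traces.
# All generators are deterministic under (design, seed).

#' Cohort study design
#'
#' The default design mirrors the study population: healthy young (n = 33),
#' healthy older (n = 14), hypertensive young (n = 9) and hypertensive older
#' (n = 13) subjects; 69 in total. Disease and aging act as multiplicative
#' effects on selected profile dimensions, with log-normal between-subject
#' noise.
#'
#' Default effect multipliers `[1.8, 1.3, 1, 1, 1, 1.6, 1.5]` (for
#' `[size, fg, vwf, psel, ps, eplus, act]`) are used for both hypertension
#' and aging so that the derived effect barcode at the study's sample sizes
#' is `[+ + 0 0 0 + +]`; only directions and significance are reported for
#' the real cohorts, so the magnitudes are the generator's calibration.
#' In the `htn_older` cohort the two factors compose multiplicatively.
#'
#' @param cohort_sizes Named integer vector over
#'   `healthy_young`, `healthy_older`, `htn_young`, `htn_older`.
#' @param baseline_profile Seven positive means (healthy-young truth), in
#'   [profile_dims()] order; size in AFU, enrichments dimensionless.
#' @param baseline_cv Seven coefficients of variation of the log-normal
#'   between-subject noise.
#' @param hypertension_multipliers,aging_multipliers Seven positive
#'   multipliers applied to the affected cohorts.
#' @param growth Logistic growth parameters per condition: lists with
#'   `t_half` (s) and `tau` (s). Defaults put the 95%-of-plateau time at
#'   ~400 s for healthy and ~500 s for hypertensive thrombi.
#' @param mfi_baseline Flow-cytometry MFI means for total, extended (E+) and
#'   fully activated integrin alphaIIb-beta3 and P-selectin.
#' @param mfi_eplus_htn_factor Fold-elevation of the E+ integrin MFI in the
#'   hypertensive cohorts (the only MFI the disease shifts).
#' @return An object of class `study_design`.
#' @export
study_design <- function(cohort_sizes = c(healthy_young = 33L,
                                          healthy_older = 14L,
                                          htn_young = 9L,
                                          htn_older = 13L),
                         baseline_profile = c(size = 1000, fg = 0.5,
                                              vwf = 0.4, psel = 0.3,
                                              ps = 0.2, eplus = 0.6,
                                              act = 0.35),
                         baseline_cv = c(0.25, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
                         hypertension_multipliers = c(1.8, 1.3, 1, 1, 1, 1.6, 1.5),
                         aging_multipliers = c(1.8, 1.3, 1, 1, 1, 1.6, 1.5),
                         growth = list(healthy = list(t_half = 200, tau = 68),
                                       hypertensive = list(t_half = 250, tau = 85)),
                         mfi_baseline = c(total = 5000, eplus = 300,
                                          act = 150, psel = 200),
                         mfi_eplus_htn_factor = 3) {
  known <- c("healthy_young", "healthy_older", "htn_young", "htn_older")
  if (!all(names(cohort_sizes) %in% known))
    stop("unknown cohort keys: ",
         paste(setdiff(names(cohort_sizes), known), collapse = ", "))
  stopifnot(all(cohort_sizes >= 0), length(baseline_profile) == 7L,
            all(baseline_profile > 0), length(baseline_cv) == 7L,
            all(baseline_cv >= 0),
            length(hypertension_multipliers) == 7L,
            all(hypertension_multipliers > 0),
            length(aging_multipliers) == 7L, all(aging_multipliers > 0),
            mfi_eplus_htn_factor > 0)
  names(baseline_profile) <- .PROFILE_DIMS
  names(baseline_cv) <- .PROFILE_DIMS
  names(hypertension_multipliers) <- .PROFILE_DIMS
  names(aging_multipliers) <- .PROFILE_DIMS
  structure(list(cohort_sizes = cohort_sizes,
                 baseline_profile = baseline_profile,
                 baseline_cv = baseline_cv,
                 hypertension_multipliers = hypertension_multipliers,
                 aging_multipliers = aging_multipliers,
                 growth = growth,
                 mfi_baseline = mfi_baseline,
                 mfi_eplus_htn_factor = mfi_eplus_htn_factor),
            class = "study_design")
}

# mean-preserving log-normal draws: E[X] = mean for any cv
.rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.cohort_multipliers <- function(design, cohort) {
  m <- rep(1, 7)
  if (cohort %in% c("htn_young", "htn_older"))
    m <- m * design$hypertension_multipliers
  if (cohort %in% c("healthy_older", "htn_older"))
    m <- m * design$aging_multipliers
  m
}

#' Generate a synthetic subject table
#'
#' Draws, per subject: cohort label, an age from the cohort-appropriate range
#' (young 20-49, older 50-75), the seven true profile values
#' (baseline x cohort multipliers x log-normal subject noise) and
#' flow-cytometry MFIs for total / E+ / fully activated integrin
#' alphaIIb-beta3 and P-selectin, with only the E+ level elevated in the
#' hypertensive cohorts.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; a fixed seed yields bit-identical output.
#' @return A `data.frame` with columns `subject_id`, `cohort`, `age`, the
#'   seven [profile_dims()] and `mfi_total`, `mfi_eplus`, `mfi_act`,
#'   `mfi_psel`. The design is attached as attribute `"design"`.
#' @examples
#' study <- generate_study(study_design(), seed = 1)
#' nrow(study)  # 69
#' @export
generate_study <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(.sub_seed(seed, "study"))
  rows <- lapply(names(design$cohort_sizes), function(cohort) {
    n <- design$cohort_sizes[[cohort]]
    if (n == 0L) return(NULL)
    young <- cohort %in% c("healthy_young", "htn_young")
    age <- sample(if (young) 20:49 else 50:75, n, replace = TRUE)
    mult <- .cohort_multipliers(design, cohort)
    prof <- vapply(seq_len(7), function(d) {
      .rlnorm_cv(n, design$baseline_profile[d] * mult[d],
                 design$baseline_cv[d])
    }, numeric(n))
    if (n == 1L) prof <- matrix(prof, nrow = 1L)
    colnames(prof) <- .PROFILE_DIMS
    htn <- cohort %in% c("htn_young", "htn_older")
    mfi <- cbind(
      mfi_total = .rlnorm_cv(n, design$mfi_baseline[["total"]], 0.2),
      mfi_eplus = .rlnorm_cv(n, design$mfi_baseline[["eplus"]] *
                                  (if (htn) design$mfi_eplus_htn_factor else 1),
                             0.2),
      mfi_act = .rlnorm_cv(n, design$mfi_baseline[["act"]], 0.2),
      mfi_psel = .rlnorm_cv(n, design$mfi_baseline[["psel"]], 0.2))
    cbind(data.frame(cohort = cohort, age = age), prof, mfi)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Add measurement noise to true profiles
#'
#' Multiplies each true profile value by independent log-normal measurement
#' noise, emulating assay repeatability. Between-subject variability lives in
#' [generate_study()]; this is the within-subject technical component that a
#' paired design cancels.
#'
#' @param profiles Matrix or data.frame whose columns include
#'   [profile_dims()].
#' @param noise_cv Technical coefficient of variation (default 0.05).
#' @param seed Integer seed.
#' @return Numeric matrix of measured profiles (rows as input, 7 columns).
#' @export
measure_profiles <- function(profiles, noise_cv = 0.05, seed = 1L) {
  m <- as.matrix(profiles[, .PROFILE_DIMS, drop = FALSE])
  set.seed(.sub_seed(seed, "measure"))
  noise <- matrix(.rlnorm_cv(length(m), 1, noise_cv), nrow = nrow(m))
  m * noise
}

#' Acquisition settings for the stenosis assay
#'
#' @param frame_interval Seconds between frames.
#' @param duration Total recording length (s); must cover the 450-s readout
#'   after thrombus onset (plus one frame for the 3-frame readout window).
#' @param autofluorescence_coeff Fraction of the platelet signal leaking into
#'   the 391-nm channel(s).
#' @param noise_cv Multiplicative per-frame measurement noise CV.
#' @param onset_delay Time before thrombus formation starts (s).
#' @param af_channels Channels recorded at 391 nm that receive the platelet
#'   autofluorescence leak (default the fibrinogen channel).
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval = 5, duration = 600,
                             autofluorescence_coeff = 0.1, noise_cv = 0.05,
                             onset_delay = 30, af_channels = "fg") {
  stopifnot(frame_interval > 0, autofluorescence_coeff >= 0, noise_cv >= 0,
            onset_delay >= 0)
  if (duration < 450 + onset_delay + frame_interval)
    stop("duration too short for the 450-s readout after onset")
  structure(list(frame_interval = frame_interval, duration = duration,
                 autofluorescence_coeff = autofluorescence_coeff,
                 noise_cv = noise_cv, onset_delay = onset_delay,
                 af_channels = af_channels),
            class = "acquisition_spec")
}

#' Simulate multi-channel fluorescence time courses for one subject
#'
#' The platelet channel is zero before `onset_delay` and follows a logistic
#' growth curve `A / (1 + exp(-(t - t0 - t_half) / tau))` after it. The
#' amplitude `A` is calibrated so that the 3-frame readout at onset + 450 s
#' equals the subject's true thrombus size. Each biomarker channel is
#' enrichment x platelet channel x multiplicative log-normal noise; channels
#' listed in `acquisition$af_channels` additionally receive
#' `autofluorescence_coeff` x platelet signal.
#'
#' @param profile Named numeric vector over [profile_dims()] (a subject's
#'   true profile), or one row of a [generate_study()] table.
#' @param acquisition An [acquisition_spec()].
#' @param growth List with `t_half` and `tau` (s) of the logistic curve.
#' @param seed Integer seed.
#' @param read_offset Readout time after onset used for the amplitude
#'   calibration (s).
#' @return An object of class `timecourse_set`: list with `times`, `channels`
#'   (named list: `platelet` plus the six biomarker channels) and `metadata`
#'   (incl. the autofluorescence coefficient and channel list).
#' @export
simulate_timecourses <- function(profile, acquisition = acquisition_spec(),
                                 growth = list(t_half = 200, tau = 68),
                                 seed = 1L, read_offset = 450) {
  stopifnot(inherits(acquisition, "acquisition_spec"))
  profile <- .as_profile_vec(profile)
  dt <- acquisition$frame_interval
  times <- seq(0, acquisition$duration, by = dt)
  t0 <- acquisition$onset_delay
  frac <- ifelse(times < t0, 0,
                 1 / (1 + exp(-(times - t0 - growth$t_half) / growth$tau)))
  # calibrate amplitude so that the 3-frame mean at onset + read_offset
  # equals the nominal size
  read_t <- t0 + read_offset
  win <- read_t + c(-dt, 0, dt)
  win_frac <- mean(1 / (1 + exp(-(win - t0 - growth$t_half) / growth$tau)))
  amp <- profile[["size"]] / win_frac
  set.seed(.sub_seed(seed, "timecourse"))
  platelet <- amp * frac
  channels <- list(platelet = platelet)
  for (ch in .PROFILE_DIMS[-1]) {
    noise <- .rlnorm_cv(length(times), 1, acquisition$noise_cv)
    sig <- profile[[ch]] * platelet * noise
    if (ch %in% acquisition$af_channels)
      sig <- sig + acquisition$autofluorescence_coeff * platelet
    channels[[ch]] <- sig
  }
  structure(list(times = times, channels = channels,
                 metadata = list(
                   onset_delay = t0,
                   autofluorescence_coeff = acquisition$autofluorescence_coeff,
                   af_channels = acquisition$af_channels)),
            class = "timecourse_set")
}

#' Inhibitor specification
#'
#' Configuration of one inhibitor for the generator: its potency (Hill
#' parameters acting on thrombus size) and its effect barcode, i.e. which
#' non-size dimensions it suppresses or raises.
#'
#' @param name Inhibitor label.
#' @param ic50 Half-maximal inhibitory concentration (ug/mL).
#' @param hill_slope Hill slope (> 0).
#' @param floor_R Residue size (%) at saturating concentration.
#' @param barcode An [effect_barcode()] (7 trits), stored as
#'   `$effect_barcode`.
#' @return An object of class `inhibitor_spec`.
#' @export
inhibitor_spec <- function(name, ic50, hill_slope = 1, floor_R = 0,
                           barcode = "0000000") {
  stopifnot(ic50 > 0, hill_slope > 0, floor_R >= 0, floor_R <= 100)
  structure(list(name = name, ic50 = ic50, hill_slope = hill_slope,
                 floor_R = floor_R,
                 effect_barcode = as_effect_barcode(barcode)),
            class = "inhibitor_spec")
}

#' Default inhibitor panel
#'
#' Generator configurations mimicking the monoclonal-antibody panel:
#' GPIb-alpha--VWF blockade (NMC4-like, barcode `-0---` on VWF, P-selectin and
#' both integrin activation dimensions), integrin--VWF blockade (LJ-P5-like),
#' integrin--Fg blockade (7E9-like) and pan-integrin blockade (7E3-like).
#' IC50 values are plausible configuration, not reproduced measurements.
#'
#' @return Named list of [inhibitor_spec()] objects.
#' @export
default_inhibitors <- function() {
  list(
    nmc4 = inhibitor_spec("NMC4", ic50 = 0.5, hill_slope = 1.2, floor_R = 2,
                          barcode = "-0--0--"),
    ljp5 = inhibitor_spec("LJ-P5", ic50 = 5, hill_slope = 1, floor_R = 15,
                          barcode = "-0-0000"),
    e7e9 = inhibitor_spec("7E9", ic50 = 2, hill_slope = 1, floor_R = 5,
                          barcode = "--00000"),
    e7e3 = inhibitor_spec("7E3", ic50 = 1, hill_slope = 1.2, floor_R = 2,
                          barcode = "---0000")
  )
}

#' Apply an inhibitor to a true profile
#'
#' The size dimension is scaled by the Hill residue
#' ([predict_residue()] / 100). Each non-size dimension carrying a `-` (`+`)
#' trit in the inhibitor's effect barcode is scaled by
#' `factor ^ (2 * theta(C))`, where `theta(C) = 1 / (1 + (ic50/C)^slope)` is
#' the occupancy (0 at zero dose, 1/2 at the IC50), so the per-trit factor is
#' attained exactly at the IC50 and the effect deepens monotonically with
#' concentration. `0` trits are untouched.
#'
#' @param profile Named numeric vector over [profile_dims()].
#' @param spec An [inhibitor_spec()].
#' @param concentration Dose (same unit as `spec$ic50`), >= 0.
#' @param trit_factor_down Scaling of `-` dimensions at the IC50 (default 0.5).
#' @param trit_factor_up Scaling of `+` dimensions at the IC50 (default 1.5).
#' @return Modified profile (named numeric, 7 dimensions).
#' @export
apply_inhibitor <- function(profile, spec, concentration,
                            trit_factor_down = 0.5, trit_factor_up = 1.5) {
  stopifnot(inherits(spec, "inhibitor_spec"))
  if (concentration < 0) stop("concentration must be non-negative")
  profile <- .as_profile_vec(profile)
  out <- profile
  out[["size"]] <- profile[["size"]] *
    predict_residue(list(ic50 = spec$ic50, hill_slope = spec$hill_slope,
                         floor_R = spec$floor_R), concentration) / 100
  theta <- if (concentration == 0) 0 else
    1 / (1 + (spec$ic50 / concentration)^spec$hill_slope)
  trits <- unclass(spec$effect_barcode)
  for (d in 2:7) {
    if (trits[d] == -1L) out[d] <- out[d] * trit_factor_down^(2 * theta)
    if (trits[d] == 1L)  out[d] <- out[d] * trit_factor_up^(2 * theta)
  }
  out
}

#' BFP touch-cycle scenario
#'
#' @param p_a Steady-state adhesion probability per touch; if `NULL`, computed
#'   from the site densities and affinity via
#'   `p_a = 1 - exp(-m_r * m_l * affinity)`.
#' @param n_cycles Touch cycles per series (default 30).
#' @param m_r,m_l Receptor and ligand surface densities (sites/um^2).
#' @param affinity Effective 2D affinity `A_c K_a` (um^4/site); only needed
#'   when `p_a` is `NULL`.
#' @param forces Clamping forces (pN) at which lifetimes are collected.
#' @param lifetimes_per_force Lifetime draws per clamping force.
#' @param params A [catch_slip_params()] governing the lifetimes.
#' @return An object of class `bfp_scenario`.
#' @export
bfp_scenario <- function(p_a = NULL, n_cycles = 30L, m_r = 50, m_l = 100,
                         affinity = NULL,
                         forces = seq(5, 45, by = 10),
                         lifetimes_per_force = 100L,
                         params = default_bond_phenotypes()$integrin_healthy) {
  if (is.null(p_a)) {
    stopifnot(!is.null(affinity), affinity >= 0, m_r > 0, m_l > 0)
    p_a <- 1 - exp(-m_r * m_l * affinity)
  }
  stopifnot(p_a >= 0, p_a < 1, n_cycles >= 1, lifetimes_per_force >= 1,
            inherits(params, "catch_slip_params"))
  structure(list(p_a = p_a, n_cycles = as.integer(n_cycles), m_r = m_r,
                 m_l = m_l, forces = forces,
                 lifetimes_per_force = as.integer(lifetimes_per_force),
                 params = params),
            class = "bfp_scenario")
}

#' Simulate a touch-cycle outcome sequence
#'
#' Independent Bernoulli(`p_a`) adhesion outcomes over the scenario's touch
#' cycles.
#'
#' @param scenario A [bfp_scenario()].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 outcomes of length `n_cycles`.
#' @export
simulate_adhesion <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "bfp_scenario"))
  set.seed(.sub_seed(seed, "adhesion"))
  stats::rbinom(scenario$n_cycles, 1L, scenario$p_a)
}

#' Simulate force-clamped bond lifetimes
#'
#' At each clamping force `F`, lifetimes are exponential with rate
#' [catch_slip_rate()]`(F)`, so the mean lifetime is `1 / k(F)`.
#'
#' @param scenario A [bfp_scenario()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `force_pN`, `lifetime_s`.
#' @export
simulate_lifetimes <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "bfp_scenario"))
  set.seed(.sub_seed(seed, "lifetimes"))
  recs <- lapply(scenario$forces, function(f) {
    data.frame(force_pN = f,
               lifetime_s = stats::rexp(scenario$lifetimes_per_force,
                                        rate = catch_slip_rate(f, scenario$params)))
  })
  do.call(rbind, recs)
}

#' Simulate ratiometric calcium traces under repeated pulling
#'
#' Generates a normalized Fura-2 340/380 ratio trace per clamping force:
#' unity baseline for the first `n_baseline` frames, then a smooth pulse
#' whose amplitude is proportional to the mean bond lifetime at that force
#' (`amplitude_per_s / k(F)`), encoding the observation that the calcium
#' response mirrors the lifetime's catch-slip trend. The returned channels
#' carry the ratio in `i340` against a constant `i380`, so downstream
#' normalization ([normalize_calcium()]) recovers the injected amplitude
#' exactly at zero noise.
#'
#' @param forces Clamping forces (pN), one trace per force.
#' @param params A [catch_slip_params()] giving the lifetime model.
#' @param seed Integer seed.
#' @param amplitude_per_s Peak ratio increase per second of mean lifetime.
#' @param n_baseline Pre-stimulus baseline frames (default 10).
#' @param n_frames Total frames per trace.
#' @param frame_interval Seconds per frame.
#' @param noise_sd Additive Gaussian noise s.d. on the normalized ratio.
#' @return Named list (one element per force) of `data.frame`s with columns
#'   `time_s`, `i340`, `i380`.
#' @export
simulate_calcium <- function(forces, params = default_bond_phenotypes()$integrin_healthy,
                             seed = 1L, amplitude_per_s = 0.1,
                             n_baseline = 10L, n_frames = 61L,
                             frame_interval = 0.5, noise_sd = 0) {
  stopifnot(inherits(params, "catch_slip_params"), n_frames > n_baseline)
  set.seed(.sub_seed(seed, "calcium"))
  traces <- lapply(forces, function(f) {
    amp <- amplitude_per_s / catch_slip_rate(f, params)
    ratio <- rep(1, n_frames)
    stim <- seq(n_baseline + 1L, n_frames)
    s <- seq(0, 1, length.out = length(stim))
    ratio[stim] <- 1 + amp * sin(pi * s)^2
    if (noise_sd > 0) ratio <- ratio + stats::rnorm(n_frames, 0, noise_sd)
    i380 <- rep(1000, n_frames)
    data.frame(time_s = (seq_len(n_frames) - 1L) * frame_interval,
               i340 = ratio * i380, i380 = i380)
  })
  names(traces) <- paste0("F", forces)
  traces
}
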