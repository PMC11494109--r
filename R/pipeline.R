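# End-to-end orchestration: simulate a study, profile it, derive barcodes,
# discrimination statistics, hydrodynamics and BFP kinetics, and write a
# machine-readable run directory.

#' Default pipeline configuration
#'
#' A complete run configuration as a plain (YAML-serializable) list:
#' study design, acquisition settings, inhibitor panel, channel geometry and
#' perfusion state, statistics options and the base seed.
#'
#' @param seed Base seed for every random stage.
#' @return Named list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       design = study_design(),
       acquisition = acquisition_spec(),
       inhibitors = default_inhibitors(),
       geometry = channel_geometry(),
       flow = flow_condition(),
       bfp = list(healthy = bfp_scenario(p_a = 0.2,
                                         params = default_bond_phenotypes()$integrin_healthy),
                  hypertensive = bfp_scenario(p_a = 0.35,
                                              params = default_bond_phenotypes()$integrin_hypertensive)),
       stats = list(alpha = 0.05, correction = "holm-sidak",
                    marker = "eplus"),
       trit_factor_down = 0.5, trit_factor_up = 1.5)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file holding any subset of the [default_run_config()] fields
#' (given as plain argument lists) and merges it over the defaults, so the
#' serialized round trip is lossless for the fields provided.
#'
#' @param path YAML file path.
#' @return Configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(raw$seed)) raw$seed else 1L)
  if (!is.null(raw$design)) cfg$design <- do.call(study_design, raw$design)
  if (!is.null(raw$acquisition))
    cfg$acquisition <- do.call(acquisition_spec, raw$acquisition)
  if (!is.null(raw$inhibitors))
    cfg$inhibitors <- lapply(raw$inhibitors, function(sp)
      do.call(inhibitor_spec, sp))
  if (!is.null(raw$geometry)) cfg$geometry <- do.call(channel_geometry, raw$geometry)
  if (!is.null(raw$flow)) cfg$flow <- do.call(flow_condition, raw$flow)
  if (!is.null(raw$stats)) cfg$stats <- utils::modifyList(cfg$stats, raw$stats)
  for (f in c("trit_factor_down", "trit_factor_up"))
    if (!is.null(raw[[f]])) cfg[[f]] <- raw[[f]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Deterministic under (config, seed): simulates the cohort study, measures
#' profiles, derives the hypertension/aging effect barcodes and the paired
#' inhibitor barcodes, verifies the configured barcode additions, builds
#' healthy reference ranges, personal barcodes and their census, computes
#' correlation / separation / consistency statistics for the configured
#' marker, evaluates the stenosis shear field and the BFP kinetics, and
#' writes tidy CSV tables plus a `summary.json` (with the configuration
#' hash) into `out_dir`.
#'
#' @param config A [default_run_config()]-style list.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = seed, config_hash = rlang::hash(config))

  # hydrodynamics
  sf <- .stage("hydro", shear_field(config$geometry, config$flow))
  utils::write.csv(
    data.frame(x_um = sf$x_um, h_um = sf$h_um,
               shear_rate_per_s = sf$shear_rate_per_s,
               wss_dyn_cm2 = sf$wss_dyn_cm2),
    file.path(out_dir, "shear.csv"), row.names = FALSE)
  summary$hydro <- list(
    apex_wss_dyn_cm2 = apex_wss(sf),
    reynolds_inlet = reynolds_number(config$geometry, config$flow, "inlet"),
    reynolds_apex = reynolds_number(config$geometry, config$flow, "apex"),
    circular_equivalent = circular_equivalent(config$geometry, config$flow))

  # cohort study and measured profiles
  study <- .stage("study", generate_study(config$design, seed = seed))
  utils::write.csv(study, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  measured <- .stage("profiling",
                     measure_profiles(study, config$acquisition$noise_cv,
                                      seed = seed))
  prof_long <- data.frame(
    subject_id = rep(study$subject_id, times = 7),
    condition = "baseline",
    dim = rep(.PROFILE_DIMS, each = nrow(study)),
    value = as.vector(measured))
  utils::write.csv(prof_long, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)

  alpha <- config$stats$alpha
  corr <- config$stats$correction
  hy <- study$cohort == "healthy_young"
  htn <- study$cohort %in% c("htn_young", "htn_older")

  # factor effect barcodes
  summary$effect_barcodes <- .stage("barcode", {
    eb <- list(
      hypertension = barcode_string(derive_effect_barcode(
        measured[hy, ], measured[htn, ], paired = FALSE,
        alpha = alpha, correction = corr)),
      aging = barcode_string(derive_effect_barcode(
        measured[hy, ], measured[study$cohort == "healthy_older", ],
        paired = FALSE, alpha = alpha, correction = corr)))
    eb
  })

  # paired inhibitor barcodes at each inhibitor's IC50 (n = 5 healthy young)
  if (length(config$inhibitors)) {
    summary$inhibitors <- .stage("inhibitors", {
      donors <- study[which(hy)[1:5], ]
      lapply(config$inhibitors, function(spec) {
        true <- as.matrix(donors[, .PROFILE_DIMS])
        treated <- t(apply(true, 1, apply_inhibitor, spec = spec,
                           concentration = spec$ic50,
                           trit_factor_down = config$trit_factor_down,
                           trit_factor_up = config$trit_factor_up))
        colnames(treated) <- .PROFILE_DIMS
        mw <- measure_profiles(true, config$acquisition$noise_cv,
                               seed = .sub_seed(seed, paste0("wo_", spec$name)))
        mt <- measure_profiles(treated, config$acquisition$noise_cv,
                               seed = .sub_seed(seed, paste0("wi_", spec$name)))
        bc <- derive_effect_barcode(mw, mt, paired = TRUE,
                                    alpha = alpha, correction = corr)
        list(name = spec$name, ic50 = spec$ic50,
             configured_barcode = barcode_string(spec$effect_barcode),
             derived_barcode = barcode_string(bc))
      })
    })

    # barcode addition rule on the configured panel
    summary$barcode_additions <- .stage("additions", {
      specs <- config$inhibitors
      adds <- list()
      if (all(c("ljp5", "e7e9", "e7e3") %in% names(specs)))
        adds$integrin_blockade <- list(
          a = barcode_string(specs$ljp5$effect_barcode),
          b = barcode_string(specs$e7e9$effect_barcode),
          sum = barcode_string(add_barcodes(specs$ljp5$effect_barcode,
                                            specs$e7e9$effect_barcode)),
          expected = barcode_string(specs$e7e3$effect_barcode))
      if (all(c("nmc4", "ljp5") %in% names(specs)))
        adds$vwf_blockade <- list(
          a = barcode_string(specs$nmc4$effect_barcode),
          b = barcode_string(specs$ljp5$effect_barcode),
          sum = barcode_string(add_barcodes(specs$nmc4$effect_barcode,
                                            specs$ljp5$effect_barcode)))
      for (nm in names(specs))
        adds[[paste0("hypertension_plus_", nm)]] <- list(
          a = summary$effect_barcodes$hypertension,
          b = barcode_string(specs[[nm]]$effect_barcode),
          sum = barcode_string(add_barcodes(
            effect_barcode(summary$effect_barcodes$hypertension),
            specs[[nm]]$effect_barcode)))
      adds
    })
  }

  # reference ranges, personal barcodes, census
  summary$personal <- .stage("personal", {
    ranges <- build_reference_ranges(measured[hy, ])
    pbs <- apply(measured, 1, function(p)
      barcode_string(personal_barcode(p, ranges)))
    census <- barcode_census(pbs)
    utils::write.csv(
      data.frame(subject_id = study$subject_id, cohort = study$cohort,
                 barcode = pbs),
      file.path(out_dir, "personal_barcodes.csv"), row.names = FALSE)
    list(ranges = as.data.frame(ranges), n_distinct = census$n_distinct,
         dim_fractions = as.data.frame(census$dim_fractions))
  })

  # discrimination statistics on the configured marker
  summary$stats <- .stage("stats", {
    marker <- config$stats$marker
    x <- measured[, "size"]; y <- measured[, marker]
    co <- correlate(x, y)
    sep_marker <- best_threshold(y[hy], y[!hy])
    sep_size <- best_threshold(x[hy], x[!hy])
    cons <- classification_consistency(
      classify_by_threshold(y, sep_marker),
      classify_by_threshold(x, sep_size))
    list(marker = marker,
         correlation = unclass(co),
         separation_marker = unclass(sep_marker),
         separation_size = unclass(sep_size),
         consistency_pct = cons)
  })

  # BFP kinetics
  if (length(config$bfp)) {
    summary$bfp <- .stage("bfp", {
      lapply(config$bfp, function(sc) {
        touches <- simulate_adhesion(sc, seed = seed)
        freq <- adhesion_frequency(touches)
        kin <- avidity_affinity(sc$p_a, sc$m_r, sc$m_l)
        lt <- simulate_lifetimes(sc, seed = seed)
        curve <- bin_lifetimes(lt, min_count = 50L)
        cls <- classify_force_dependence(curve)
        list(p_a_true = sc$p_a, p_a_est = freq$p_a, p_a_se = freq$se,
             avidity = kin$avidity, affinity = kin$affinity,
             single_bond_prob = single_bond_probability(sc$p_a),
             phenotype = cls$phenotype, peak_force = cls$peak_force,
             peak_lifetime = cls$peak_lifetime)
      })
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
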