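test_that("zero noise and unit multipliers reproduce the baseline exactly", {
  d <- study_design(baseline_cv = rep(0, 7),
                    hypertension_multipliers = rep(1, 7),
                    aging_multipliers = rep(1, 7))
  st <- generate_study(d, seed = 3)
  for (dim in profile_dims())
    expect_equal(st[[dim]], rep(unname(d$baseline_profile[dim]), nrow(st)))
})

test_that("default design yields 69 subjects with the cohort split", {
  st <- generate_study(study_design(), seed = 1)
  expect_equal(nrow(st), 69)
  expect_equal(as.vector(table(st$cohort)[c("healthy_young", "healthy_older",
                                            "htn_young", "htn_older")]),
               c(33, 14, 9, 13))
  expect_true(all(st$age[st$cohort %in% c("healthy_young", "htn_young")] < 50))
  expect_true(all(st$age[st$cohort %in% c("healthy_older", "htn_older")] >= 50))
})

test_that("generation is bit-identical under a fixed seed and seed-sensitive", {
  a <- generate_study(seed = 7)
  b <- generate_study(seed = 7)
  attr(a, "design") <- attr(b, "design") <- NULL
  expect_identical(a, b)
  c_ <- generate_study(seed = 8)
  expect_false(isTRUE(all.equal(a$size, c_$size)))
})

test_that("unknown cohort keys are rejected", {
  expect_error(study_design(cohort_sizes = c(bogus = 5)), "unknown cohort")
})

test_that("healthy-young mean size is unbiased over repeated draws", {
  d <- study_design()
  means <- vapply(1:200, function(s) {
    st <- generate_study(d, seed = s)
    mean(st$size[st$cohort == "healthy_young"])
  }, numeric(1))
  mu <- mean(means)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mu - d$baseline_profile[["size"]]), 3 * se)
})

test_that("subject noise follows the configured log-normal family", {
  d <- study_design(cohort_sizes = c(healthy_young = 10000L))
  st <- generate_study(d, seed = 11)
  cv <- d$baseline_cv[["size"]]
  sdlog <- sqrt(log(1 + cv^2))
  ks <- stats::ks.test(st$size,
                       "plnorm",
                       meanlog = log(d$baseline_profile[["size"]]) - sdlog^2 / 2,
                       sdlog = sdlog)
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated time courses embed the true enrichments and are reproducible", {
  acq <- acquisition_spec(noise_cv = 0, autofluorescence_coeff = 0)
  tc <- simulate_timecourses(baseline_profile(), acq, seed = 1)
  post <- tc$times >= acq$onset_delay + 5
  expect_equal(tc$channels$fg[post] / tc$channels$platelet[post],
               rep(0.5, sum(post)))
  expect_equal(tc$channels$act[post] / tc$channels$platelet[post],
               rep(0.35, sum(post)))
  noisy1 <- simulate_timecourses(baseline_profile(), acquisition_spec(), seed = 5)
  noisy2 <- simulate_timecourses(baseline_profile(), acquisition_spec(), seed = 5)
  expect_identical(noisy1, noisy2)
})

test_that("acquisition rejects a duration too short for the 450-s readout", {
  expect_error(acquisition_spec(duration = 400), "450")
})

test_that("inhibitor application follows the Hill residue on size", {
  spec <- inhibitor_spec("test", ic50 = 2, hill_slope = 1, floor_R = 0,
                         barcode = "-0--0--")
  p <- baseline_profile()
  expect_equal(apply_inhibitor(p, spec, 0), p)               # no dose, no effect
  expect_equal(apply_inhibitor(p, spec, 2)[["size"]], 500)   # IC50 midpoint
  spec5 <- inhibitor_spec("sat", ic50 = 2, hill_slope = 1, floor_R = 5,
                          barcode = "0000000")
  expect_equal(apply_inhibitor(p, spec5, 1e9)[["size"]], 50, tolerance = 1e-6)
})

test_that("inhibited dimensions decrease monotonically with concentration", {
  spec <- inhibitor_spec("test", ic50 = 1, hill_slope = 1.3, floor_R = 5,
                         barcode = "-0--0--")
  doses <- c(0, 0.1, 0.5, 1, 2, 10, 100)
  prof <- t(vapply(doses, function(cc)
    apply_inhibitor(baseline_profile(), spec, cc), numeric(7)))
  for (d in c("size", "vwf", "psel", "eplus", "act"))
    expect_true(all(diff(prof[, d]) <= 1e-12))
  for (d in c("fg", "ps"))  # zero trits untouched
    expect_equal(prof[, d], rep(baseline_profile()[[d]], length(doses)))
})

test_that("touch-cycle outcomes are Bernoulli with the configured frequency", {
  sc0 <- bfp_scenario(p_a = 0)
  expect_equal(simulate_adhesion(sc0, seed = 1), rep(0L, 30))
  sc <- bfp_scenario(p_a = 0.2)
  freqs <- vapply(1:10000, function(s)
    mean(simulate_adhesion(sc, seed = s)), numeric(1))
  se <- sqrt(0.2 * 0.8 / 30) / sqrt(10000)
  expect_lt(abs(mean(freqs) - 0.2), 4 * se)
})

test_that("adhesion frequency derives from the site densities via the kinetics relation", {
  # m_r * m_l * A_c K_a = 0.2231 gives P_a = 1 - exp(-0.2231) ~ 0.2
  sc <- bfp_scenario(p_a = NULL, m_r = 50, m_l = 100, affinity = 0.2231 / 5000)
  expect_equal(sc$p_a, 1 - exp(-0.2231), tolerance = 1e-12)
  expect_equal(sc$p_a, 0.2, tolerance = 1e-3)
})

test_that("lifetimes are exponential with the analytic force-free mean in the slip limit", {
  # k_c0 = 0 and huge f_s: force-independent exponential with mean 1/k_s0
  params <- catch_slip_params(k_c0 = 0, f_c = 1, k_s0 = 0.5, f_s = 1e9)
  sc <- bfp_scenario(p_a = 0.2, forces = c(5, 25, 45),
                     lifetimes_per_force = 4000, params = params)
  lt <- simulate_lifetimes(sc, seed = 2)
  for (f in unique(lt$force_pN)) {
    m <- mean(lt$lifetime_s[lt$force_pN == f])
    expect_lt(abs(m - 2), 3 * 2 / sqrt(4000))
  }
  ks <- stats::ks.test(lt$lifetime_s[lt$force_pN == 5], "pexp", rate = 0.5)
  expect_gt(ks$p.value, 0.01)
  expect_identical(simulate_lifetimes(sc, seed = 2), lt)
})

test_that("calcium traces encode lifetime-proportional amplitudes", {
  # amplitude zero: flat unity trace
  tr0 <- simulate_calcium(20, amplitude_per_s = 0, noise_sd = 0)[[1]]
  nc0 <- normalize_calcium(tr0$time_s, tr0$i340, tr0$i380)
  expect_equal(nc0$normalized, rep(1, length(tr0$time_s)))
  expect_equal(nc0$delta_i_max, 0)
  # two forces whose mean lifetimes differ 2:1 give 2:1 peak increases
  params <- default_bond_phenotypes()$integrin_healthy
  pk <- catch_slip_peak(params)
  f_half <- uniroot(function(f) 1 / catch_slip_rate(f, params) -
                      pk$peak_lifetime / 2,
                    c(pk$peak_force, 100))$root
  trs <- simulate_calcium(c(pk$peak_force, f_half), params, noise_sd = 0)
  d1 <- normalize_calcium(trs[[1]]$time_s, trs[[1]]$i340, trs[[1]]$i380)$delta_i_max
  d2 <- normalize_calcium(trs[[2]]$time_s, trs[[2]]$i340, trs[[2]]$i380)$delta_i_max
  expect_equal(d1 / d2, 2, tolerance = 1e-6)  # uniroot locates f_half
  expect_identical(simulate_calcium(20, seed = 4, noise_sd = 0.02),
                   simulate_calcium(20, seed = 4, noise_sd = 0.02))
})
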