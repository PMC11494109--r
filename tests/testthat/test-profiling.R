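test_that("autofluorescence correction subtracts the platelet leak", {
  plt <- c(0, 10, 100, 200)
  expect_equal(correct_autofluorescence(0.2 * plt, plt, 0.2), rep(0, 4))
  raw <- c(5, 20, 30, 40)
  expect_equal(correct_autofluorescence(raw, plt, 0), raw)
  expect_equal(correct_autofluorescence(c(1, 1, 1, 1), plt, 0.2),
               pmax(c(1, 1, 1, 1) - 0.2 * plt, 0))
  expect_error(correct_autofluorescence(1:3, 1:4, 0.1), "length")
})

test_that("onset detection finds the generator's onset and handles flat traces", {
  acq <- acquisition_spec(noise_cv = 0, onset_delay = 30)
  tc <- simulate_timecourses(baseline_profile(), acq, seed = 1)
  onset <- detect_onset(tc$channels$platelet, tc$times)
  expect_lte(abs(onset - 30), acq$frame_interval)
  expect_true(is.na(detect_onset(rep(0, 100), seq(0, 495, by = 5))))
  # shifting the trace by k frames shifts the onset by k frames
  k <- 4L
  shifted <- c(rep(0, k), tc$channels$platelet)
  t_shifted <- seq(0, by = 5, length.out = length(shifted))
  expect_equal(detect_onset(shifted, t_shifted), onset + 5 * k)
})

test_that("profile quantification normalizes by platelet signal at the readout", {
  # hand-built trace: platelet 100 and Fg 50 after onset
  times <- seq(0, 500, by = 10)
  plt <- ifelse(times >= 50, 100, 0)
  ch <- list(platelet = plt, fg = 0.5 * plt, vwf = 0.4 * plt,
             psel = 0.3 * plt, ps = 0.2 * plt, eplus = 0.6 * plt,
             act = 0.35 * plt)
  p <- quantify_profile(list(times = times, channels = ch), read_offset = 400)
  expect_equal(p[["size"]], 100)
  expect_equal(p[["fg"]], 0.5)
})

test_that("zero-noise synthetic round trip recovers the true profile exactly", {
  truth <- baseline_profile()
  acq <- acquisition_spec(noise_cv = 0, autofluorescence_coeff = 0)
  p <- quantify_profile(simulate_timecourses(truth, acq, seed = 1))
  expect_equal(unclass(p), truth, tolerance = 1e-9)
  # with autofluorescence leaking into the Fg channel, correction recovers it
  acq_af <- acquisition_spec(noise_cv = 0, autofluorescence_coeff = 0.3)
  p_af <- quantify_profile(simulate_timecourses(truth, acq_af, seed = 1))
  expect_equal(unclass(p_af), truth, tolerance = 1e-9)
})

test_that("quantification is scale-equivariant", {
  acq <- acquisition_spec(noise_cv = 0.05)
  tc <- simulate_timecourses(baseline_profile(), acq, seed = 9)
  p1 <- quantify_profile(tc)
  tc$channels <- lapply(tc$channels, function(x) 3.5 * x)
  p2 <- quantify_profile(tc)
  expect_equal(p2[["size"]], 3.5 * p1[["size"]])
  expect_equal(unclass(p2)[-1], unclass(p1)[-1], tolerance = 1e-12)
})

test_that("failed thrombus formation and missing channels are rejected", {
  times <- seq(0, 500, by = 10)
  plt <- ifelse(times >= 50 & times < 200, 100, 0)  # collapses before readout
  ch <- lapply(c(platelet = 1, fg = .5, vwf = .4, psel = .3, ps = .2,
                 eplus = .6, act = .35), function(e) e * plt)
  expect_error(quantify_profile(list(times = times, channels = ch),
                                read_offset = 400), "failed")
  expect_error(quantify_profile(list(times = times,
                                     channels = ch[c("platelet", "fg")]),
                                read_offset = 400), "missing channels")
  # readout beyond the trace end
  acq <- acquisition_spec(noise_cv = 0)
  tc <- simulate_timecourses(baseline_profile(), acq, seed = 1)
  expect_error(quantify_profile(tc, read_offset = 1e4), "beyond")
})

test_that("profile recovery is unbiased at default noise", {
  truth <- baseline_profile()
  acq <- acquisition_spec()
  recovered <- t(vapply(1:200, function(s)
    unclass(quantify_profile(simulate_timecourses(truth, acq, seed = s))),
    numeric(7)))
  for (d in profile_dims()) {
    bias <- mean(recovered[, d]) - truth[[d]]
    se <- stats::sd(recovered[, d]) / sqrt(nrow(recovered))
    expect_lt(abs(bias), 3 * se + 1e-3 * truth[[d]])
  }
})

test_that("growth fit recovers logistic parameters and plateau times", {
  times <- seq(0, 600, by = 5)
  y <- 1000 / (1 + exp(-(times - 200) / 50))
  fit <- fit_growth(y, times, onset = 0)
  expect_equal(fit$plateau, 1000, tolerance = 1e-3)
  expect_equal(fit$t_half, 200, tolerance = 1e-3)
  expect_equal(fit$slope_scale, 50, tolerance = 1e-3)
  expect_equal(fit$plateau_time, 200 + log(19) * 50, tolerance = 1e-3)

  # generator configs: healthy plateaus near 400 s, hypertensive near 500 s
  acq <- acquisition_spec(noise_cv = 0)
  tc_h <- simulate_timecourses(baseline_profile(), acq,
                               growth = list(t_half = 200, tau = 68), seed = 1)
  fit_h <- fit_growth(tc_h$channels$platelet, tc_h$times)
  expect_lt(abs(fit_h$plateau_time - 400), 20)
  tc_htn <- simulate_timecourses(baseline_profile(),
                                 acquisition_spec(noise_cv = 0, duration = 700),
                                 growth = list(t_half = 250, tau = 85), seed = 1)
  fit_htn <- fit_growth(tc_htn$channels$platelet, tc_htn$times)
  expect_lt(abs(fit_htn$plateau_time - 500), 25)

  expect_error(fit_growth(rep(5, 100), seq(0, 495, 5), onset = 0),
               "degenerate")
})

test_that("residue size is the treated/control percentage", {
  expect_equal(residue_size(100, 100), 100)
  expect_equal(residue_size(0, 100), 0)
  expect_error(residue_size(50, 0), "positive")
  # inhibitor at its IC50 (floor 0, slope 1) halves the size
  spec <- inhibitor_spec("t", ic50 = 1, hill_slope = 1, floor_R = 0)
  treated <- apply_inhibitor(baseline_profile(), spec, 1)
  expect_equal(residue_size(treated[["size"]], baseline_profile()[["size"]]),
               50)
})
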