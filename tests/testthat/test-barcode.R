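test_that("barcode construction and canonical strings round trip", {
  b <- effect_barcode("++000++")
  expect_s3_class(b, "effect_barcode")
  expect_equal(unclass(b), stats::setNames(c(1L, 1L, 0L, 0L, 0L, 1L, 1L),
                                           profile_dims()))
  expect_equal(barcode_string(b), "++000++")
  expect_equal(barcode_string(effect_barcode(c(-1, 0, -1, -1, 0, -1, -1))),
               "-0--0--")
  expect_error(effect_barcode("+-0"), "7")
  expect_error(effect_barcode("++00x++"), "only")
  expect_error(effect_barcode(c(2, 0, 0, 0, 0, 0, 0)), "trits")
})

test_that("identical arms yield the all-neutral barcode", {
  set.seed(1)
  m <- matrix(rlnorm(10 * 7, 0, 0.2), ncol = 7,
              dimnames = list(NULL, profile_dims()))
  bc <- derive_effect_barcode(m, m + 0 * m, paired = FALSE)
  expect_equal(barcode_string(bc), "0000000")
  expect_error(derive_effect_barcode(m[1:2, ], m), "3 subjects")
  expect_error(derive_effect_barcode(m[1:5, ], m[1:4, ], paired = TRUE),
               "matched")
})

test_that("a paired inhibitor design recovers the configured effect barcode", {
  nmc4 <- default_inhibitors()$nmc4
  st <- generate_study(seed = 42)
  donors <- as.matrix(st[st$cohort == "healthy_young", ][1:5, profile_dims()])
  treated <- t(apply(donors, 1, apply_inhibitor, spec = nmc4,
                     concentration = nmc4$ic50))
  colnames(treated) <- profile_dims()
  mw <- measure_profiles(donors, 0.05, seed = 3)
  mt <- measure_profiles(treated, 0.05, seed = 4)
  bc <- derive_effect_barcode(mw, mt, paired = TRUE)
  expect_equal(barcode_string(bc), "-0--0--")
  prov <- attr(bc, "provenance")
  expect_equal(prov$dim, profile_dims())
  expect_true(all(prov$p_adj >= prov$p))
})

test_that("the addition rule is sign-saturating, commutative, not associative", {
  # sign saturation: -1 + -1 stays -1
  expect_equal(barcode_string(add_barcodes(effect_barcode("-000000"),
                                           effect_barcode("-000000"))),
               "-000000")
  # identity element
  zero <- effect_barcode("0000000")
  set.seed(2)
  for (i in 1:20) {
    x <- effect_barcode(sample(-1:1, 7, replace = TRUE))
    y <- effect_barcode(sample(-1:1, 7, replace = TRUE))
    expect_identical(add_barcodes(x, zero), x)
    expect_identical(add_barcodes(x, y), add_barcodes(y, x))
  }
  # counterexample to associativity: (+1 + +1) + -1 vs +1 + (+1 + -1)
  a <- effect_barcode("+000000"); c_ <- effect_barcode("-000000")
  left <- add_barcodes(add_barcodes(a, a), c_)
  right <- add_barcodes(a, add_barcodes(a, c_))
  expect_false(identical(left, right))
})

test_that("reference ranges are mean +/- 2 s.d. with Gaussian coverage", {
  expect_error(build_reference_ranges(
    matrix(1, 12, 7, dimnames = list(NULL, profile_dims()))), "zero standard")
  expect_error(build_reference_ranges(
    matrix(rnorm(7 * 5), 5, 7, dimnames = list(NULL, profile_dims()))), "10")

  set.seed(3)
  mu <- baseline_profile(); sigma <- 0.1 * mu
  m <- vapply(seq_len(7), function(d) rnorm(5000, mu[d], sigma[d]),
              numeric(5000))
  colnames(m) <- profile_dims()
  rr <- build_reference_ranges(m)
  for (d in seq_len(7)) {
    se_mean <- sigma[d] / sqrt(5000)
    se_sd <- sigma[d] / sqrt(2 * 5000)
    expect_lt(abs(rr$low[d] - (mu[d] - 2 * sigma[d])), 3 * (se_mean + 2 * se_sd))
    expect_lt(abs(rr$high[d] - (mu[d] + 2 * sigma[d])), 3 * (se_mean + 2 * se_sd))
  }
  # fresh draws from the same Gaussian fall inside ~95.45% of the time
  fresh <- vapply(seq_len(7), function(d) rnorm(20000, mu[d], sigma[d]),
                  numeric(20000))
  inside <- mean(fresh[, 1] >= rr$low[1] & fresh[, 1] <= rr$high[1])
  expect_lt(abs(100 * inside - 95.45), 1)
})

test_that("personal barcodes classify against closed reference intervals", {
  set.seed(4)
  m <- vapply(baseline_profile(), function(mu) rnorm(50, mu, 0.1 * mu),
              numeric(50))
  colnames(m) <- profile_dims()
  rr <- build_reference_ranges(m)
  expect_equal(barcode_string(personal_barcode(rr$mean, rr)), "0000000")
  expect_equal(barcode_string(personal_barcode(rr$mean + 3 * rr$sd, rr)),
               "+++++++")
  expect_equal(barcode_string(personal_barcode(rr$mean - 3 * rr$sd, rr)),
               "-------")
  # boundary values are normal (closed interval)
  expect_equal(barcode_string(personal_barcode(rr$high, rr)), "0000000")
  expect_equal(barcode_string(personal_barcode(rr$low, rr)), "0000000")
})

test_that("barcode census counts distinct codes and tail fractions", {
  same <- rep("0000000", 5)
  expect_equal(barcode_census(same)$n_distinct, 1)
  seven <- vapply(1:7, function(d) {
    tr <- integer(7); tr[d] <- 1L; barcode_string(effect_barcode(tr))
  }, character(1))
  cz <- barcode_census(seven)
  expect_equal(cz$n_distinct, 7)
  expect_equal(colSums(cz$dim_fractions), stats::setNames(rep(1, 7),
                                                          profile_dims()))
  # healthy-young self-application is dominated by normal values
  st <- generate_study(seed = 5)
  m <- measure_profiles(st, 0.05, seed = 5)
  hy <- st$cohort == "healthy_young"
  rr <- build_reference_ranges(m[hy, ])
  pbs <- apply(m[hy, ], 1, function(p) barcode_string(personal_barcode(p, rr)))
  cz_hy <- barcode_census(pbs)
  expect_true(all(cz_hy$dim_fractions["normal", ] > 0.85))
  # deterministic under the seed
  expect_identical(cz_hy, barcode_census(pbs))
})

test_that("with no true effect the per-dimension trit rate stays below alpha", {
  set.seed(6)
  false_pos <- matrix(0L, 1000, 7)
  for (s in 1:1000) {
    a <- matrix(rlnorm(10 * 7, 0, 0.2), ncol = 7,
                dimnames = list(NULL, profile_dims()))
    b <- matrix(rlnorm(10 * 7, 0, 0.2), ncol = 7,
                dimnames = list(NULL, profile_dims()))
    bc <- derive_effect_barcode(a, b, correction = "none")
    false_pos[s, ] <- unclass(bc) != 0L
  }
  rate <- colMeans(false_pos)
  bound <- 0.05 + 2 * sqrt(0.05 * 0.95 / 1000)
  expect_true(all(rate <= bound))
})
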