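# Independent oracles used across the suite.

# Exact wall shear rate at the centre of the wide wall of a rectangular duct
# (Fourier-series solution of fully developed laminar flow), per unit flow
# rate. Geometry in micrometres, flow in uL/min; returns 1/s.
duct_wall_shear_rate <- function(width_um, height_um, q_ul_min,
                                 n_terms = 200L) {
  w <- width_um * 1e-6; h <- height_um * 1e-6
  q <- q_ul_min * 1e-9 / 60
  i <- seq(1, 2 * n_terms - 1, by = 2)
  s1 <- sum((1 / i^2) * (1 - 1 / cosh(i * pi * w / (2 * h))))
  s2 <- sum((1 / i^4) * (w - (2 * h / (i * pi)) * tanh(i * pi * w / (2 * h))))
  q * pi^2 * s1 / (2 * h^2 * s2)
}

# O(n^2) pair-counting Kendall tau-b with tie correction.
kendall_tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) sum(vapply(table(v),
                                      function(m) m * (m - 1) / 2, numeric(1)))
  (conc - disc) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

# A baseline profile handy for many tests.
baseline_profile <- function() {
  c(size = 1000, fg = 0.5, vwf = 0.4, psel = 0.3, ps = 0.2,
    eplus = 0.6, act = 0.35)
}
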