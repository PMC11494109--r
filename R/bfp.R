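# Biomembrane-force-probe analytics: adhesion-frequency kinetics, the
# Poisson single-bond argument, lifetime-versus-force curves, bond-phenotype
# classification, and ratiometric calcium normalization.

#' Adhesion frequency from touch-cycle outcomes
#'
#' @param outcomes 0/1 (or logical) adhesion outcomes over repeated touch
#'   cycles (conventionally 30).
#' @return List with `p_a` (successes / cycles), `se`
#'   (binomial standard error `sqrt(p(1-p)/n)`) and `n_cycles`.
#' @examples
#' adhesion_frequency(c(rep(1, 6), rep(0, 24)))$p_a  # 0.2
#' @export
adhesion_frequency <- function(outcomes) {
  stopifnot(length(outcomes) >= 1L, all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  p <- mean(outcomes)
  list(p_a = p, se = sqrt(p * (1 - p) / n), n_cycles = n)
}

#' Effective avidity and 2D affinity from the adhesion frequency
#'
#' Inverts the steady-state adhesion-frequency relation
#' `P_a = 1 - exp(-m_r * m_l * A_c * K_a)`: with
#' `lambda = -log(1 - P_a)`, the effective avidity is
#' `A_c K_a m_r = lambda / m_l` and the effective affinity
#' `A_c K_a = lambda / (m_r * m_l)`.
#'
#' @param p_a Adhesion frequency in `[0, 1)`; `p_a = 1` is rejected
#'   explicitly (infinite affinity).
#' @param m_r,m_l Receptor and ligand surface densities (sites/um^2), > 0.
#' @return List with `lambda` (mean bond number per touch), `avidity`
#'   (`A_c K_a m_r`, um^2) and `affinity` (`A_c K_a`, um^4).
#' @export
avidity_affinity <- function(p_a, m_r, m_l) {
  if (p_a < 0) stop("p_a must be non-negative")
  if (p_a >= 1) stop("p_a = 1 implies infinite affinity; not estimable")
  stopifnot(m_r > 0, m_l > 0)
  lambda <- -log(1 - p_a)
  list(lambda = lambda, avidity = lambda / m_l,
       affinity = lambda / (m_r * m_l))
}

#' Probability that an adhesion event is a single bond
#'
#' Under the Poisson bond-number model with mean `lambda = -log(1 - p_a)`,
#' the probability that an observed adhesion carries exactly one bond is
#' `P(N = 1 | N >= 1) = lambda * exp(-lambda) / (1 - exp(-lambda))`. At the
#' operating point `p_a = 0.2` this is 89.3%, the basis of running
#' force-clamp assays at infrequent (~20%) adhesion.
#'
#' @param p_a Adhesion frequency in (0, 1).
#' @return Probability in (0, 1); approaches 1 as `p_a -> 0`.
#' @examples
#' single_bond_probability(0.2)  # 0.893
#' @export
single_bond_probability <- function(p_a) {
  stopifnot(all(p_a > 0), all(p_a < 1))
  lambda <- -log(1 - p_a)
  lambda * exp(-lambda) / (1 - exp(-lambda))
}

#' Bin bond lifetimes by clamping force
#'
#' Groups (force, lifetime) records into successive force bins and reports
#' the per-bin arithmetic mean lifetime, its standard error, the mean force
#' and the event count. Bins reaching `min_count` events (default 50,
#' matching the reporting rule of the lifetime-vs-force curves) are flagged
#' reportable.
#'
#' @param records `data.frame` with columns `force_pN` and `lifetime_s`.
#' @param bin_edges Strictly increasing bin edges (pN); default 10-pN bins
#'   from 0 covering the data.
#' @param min_count Events required for a reportable bin.
#' @return An object of class `lifetime_curve`: `data.frame` with columns
#'   `bin_low`, `bin_high`, `bin_mean_force`, `mean_lifetime`, `sem`,
#'   `count`, `reportable` (empty bins are dropped).
#' @export
bin_lifetimes <- function(records, bin_edges = NULL, min_count = 50L) {
  stopifnot(is.data.frame(records),
            all(c("force_pN", "lifetime_s") %in% names(records)))
  if (nrow(records) == 0L) stop("empty record set")
  if (is.null(bin_edges))
    bin_edges <- seq(0, 10 * ceiling(max(records$force_pN) / 10 + 1e-9) + 10,
                     by = 10)
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  idx <- findInterval(records$force_pN, bin_edges, rightmost.closed = TRUE)
  keep <- idx >= 1L & idx < length(bin_edges)
  records <- records[keep, ]; idx <- idx[keep]
  if (nrow(records) == 0L) stop("no records fall inside the bin edges")
  out <- do.call(rbind, lapply(sort(unique(idx)), function(i) {
    lt <- records$lifetime_s[idx == i]
    data.frame(bin_low = bin_edges[i], bin_high = bin_edges[i + 1L],
               bin_mean_force = mean(records$force_pN[idx == i]),
               mean_lifetime = mean(lt),
               sem = if (length(lt) > 1L) stats::sd(lt) / sqrt(length(lt)) else NA_real_,
               count = length(lt))
  }))
  out$reportable <- out$count >= min_count
  rownames(out) <- NULL
  class(out) <- c("lifetime_curve", "data.frame")
  out
}

#' Classify the force dependence of a lifetime curve
#'
#' Examines the sign pattern of successive bin-to-bin changes of the mean
#' lifetime, counting only changes exceeding a noise margin (default 1
#' combined s.e.m. of the two bins). Patterns: no significant change =
#' `"flat"`; monotone decrease = `"slip"`; a single interior peak
#' (rise then fall) = `"catch-slip"`, with the peak force and lifetime
#' reported; a decrease, rise and final decrease (slip-catch-slip) =
#' `"triphasic"`.
#'
#' @param curve A [bin_lifetimes()] result (or any data.frame with
#'   `bin_mean_force`, `mean_lifetime` and optionally `sem`).
#' @param margin Noise margin in combined s.e.m. units (default 1); bins with
#'   missing `sem` contribute 0 margin.
#' @return List with `phenotype` (one of `"flat"`, `"slip"`, `"catch-slip"`,
#'   `"triphasic"`), `peak_force` and `peak_lifetime` (the bin of maximal
#'   mean lifetime; `NA` for flat curves).
#' @export
classify_force_dependence <- function(curve, margin = 1) {
  stopifnot(all(c("bin_mean_force", "mean_lifetime") %in% names(curve)),
            nrow(curve) >= 2L)
  lt <- curve$mean_lifetime
  sem <- if ("sem" %in% names(curve)) curve$sem else rep(0, length(lt))
  sem[is.na(sem)] <- 0
  d <- diff(lt)
  tol <- margin * sqrt(sem[-length(sem)]^2 + sem[-1L]^2)
  s <- sign(d) * (abs(d) > tol)
  s <- s[s != 0]
  phen <- if (!length(s)) "flat"
  else {
    runs <- rle(s)$values
    if (identical(runs, c(-1)) ) "slip"
    else if (identical(runs, c(1))) "catch-slip"        # still rising at the last bin
    else if (identical(runs, c(1, -1))) "catch-slip"
    else if (identical(runs, c(-1, 1, -1))) "triphasic"
    else if (length(runs) >= 4L) "triphasic"
    else if (identical(runs, c(-1, 1))) "triphasic"     # catch regime entered after a slip phase
    else "catch-slip"
  }
  ipk <- which.max(lt)
  list(phenotype = phen,
       peak_force = if (phen == "flat") NA_real_ else curve$bin_mean_force[ipk],
       peak_lifetime = if (phen == "flat") NA_real_ else lt[ipk])
}

#' Normalize a ratiometric calcium trace
#'
#' Divides the 340-nm channel by the 380-nm channel and normalizes the ratio
#' by its mean over the first `n_baseline` frames. The peak increase
#' `delta_i_max` is the maximum of the normalized ratio over the
#' post-baseline (stimulation) window minus 1.
#'
#' @param times Frame times (s).
#' @param i340,i380 Channel intensities; `i380` must be positive.
#' @param n_baseline Baseline frames (default 10); the trace must be at
#'   least this long plus one stimulation frame.
#' @return An object of class `calcium_trace`: list with `times`,
#'   `normalized` (ratio trace) and `delta_i_max`.
#' @export
normalize_calcium <- function(times, i340, i380, n_baseline = 10L) {
  stopifnot(length(times) == length(i340), length(i340) == length(i380))
  if (length(i340) <= n_baseline)
    stop("trace must exceed the ", n_baseline, " baseline frames")
  if (any(i380 <= 0)) stop("i380 must be strictly positive")
  ratio <- i340 / i380
  normalized <- ratio / mean(ratio[seq_len(n_baseline)])
  structure(list(times = times, normalized = normalized,
                 delta_i_max = max(normalized[-seq_len(n_baseline)]) - 1),
            class = "calcium_trace")
}
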