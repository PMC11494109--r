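# Effect barcodes, the sign-saturating addition rule, reference ranges and
# personal thrombus barcodes.
#
# A barcode is an ordered 7-trit vector over {-1, 0, +1}, one trit per
# profile dimension, with canonical 7-character string form over "+0-"
# (e.g. "++000++").

#' Construct an effect barcode
#'
#' @param x A 7-character string over `+`, `0`, `-` (e.g. `"-0--0--"`), or an
#'   integer vector of length 7 over `{-1, 0, 1}`.
#' @return An object of class `effect_barcode` (integer trits named by
#'   [profile_dims()]).
#' @examples
#' effect_barcode("++000++")
#' @export
effect_barcode <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L, nchar(x) == 7L)
    chars <- strsplit(x, "")[[1L]]
    if (!all(chars %in% c("+", "0", "-")))
      stop("barcode string may contain only '+', '0', '-'")
    trits <- c("-" = -1L, "0" = 0L, "+" = 1L)[chars]
  } else {
    trits <- as.integer(x)
    if (length(trits) != 7L || !all(trits %in% -1:1))
      stop("barcode must be 7 trits over {-1, 0, +1}")
  }
  structure(stats::setNames(unname(trits), .PROFILE_DIMS),
            class = "effect_barcode")
}

#' @rdname effect_barcode
#' @export
as_effect_barcode <- function(x) {
  if (inherits(x, "effect_barcode")) x else effect_barcode(x)
}

#' Canonical string form of a barcode
#'
#' @param barcode An `effect_barcode` or trit vector.
#' @return 7-character string over `+0-`.
#' @export
barcode_string <- function(barcode) {
  trits <- unclass(as_effect_barcode(barcode))
  paste(c("-", "0", "+")[trits + 2L], collapse = "")
}

#' @export
format.effect_barcode <- function(x, ...) {
  paste0("[", paste(c("-", "0", "+")[unclass(x) + 2L], collapse = " "), "]")
}

#' @export
print.effect_barcode <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Holm's step-down version of the Sidak adjustment.
.p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(1 - (1 - p[o])^(m - seq_len(m) + 1))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Derive an effect barcode from paired or cohort profiles
#'
#' Per profile dimension, a two-sided t-test compares profiles with and
#' without the factor (paired t-test for within-subject drug designs, Welch
#' unpaired otherwise). The trit is the sign of the mean difference
#' (with minus without) when the multiplicity-adjusted p-value falls below
#' `alpha`, and 0 otherwise.
#'
#' @param profiles_without,profiles_with Matrices or data.frames whose
#'   columns include [profile_dims()]; rows are subjects. In paired mode the
#'   rows must be matched (same subjects, same order) and equal in number.
#' @param paired Logical: paired t-test (drug designs) or Welch unpaired
#'   (cohort comparisons).
#' @param alpha Significance level (default 0.05).
#' @param correction Multiplicity correction across the 7 dimensions:
#'   `"holm-sidak"` (default) or `"none"`.
#' @return An `effect_barcode` with attribute `provenance`: a `data.frame`
#'   of per-dimension mean differences, raw and adjusted p-values.
#' @export
derive_effect_barcode <- function(profiles_without, profiles_with,
                                  paired = FALSE, alpha = 0.05,
                                  correction = c("holm-sidak", "none")) {
  correction <- match.arg(correction)
  a <- as.matrix(as.data.frame(profiles_without)[, .PROFILE_DIMS, drop = FALSE])
  b <- as.matrix(as.data.frame(profiles_with)[, .PROFILE_DIMS, drop = FALSE])
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("need at least 3 subjects per arm")
  if (paired && nrow(a) != nrow(b))
    stop("paired mode requires equal, matched subject rows")
  res <- lapply(.PROFILE_DIMS, function(d) {
    tt <- stats::t.test(b[, d], a[, d], paired = paired,
                        var.equal = FALSE)
    c(diff = mean(b[, d]) - mean(a[, d]), p = tt$p.value)
  })
  diffs <- vapply(res, `[[`, numeric(1), "diff")
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- switch(correction,
                  "holm-sidak" = .p_adjust_holm_sidak(p),
                  none = p)
  trits <- ifelse(p_adj < alpha, sign(diffs), 0L)
  out <- effect_barcode(as.integer(trits))
  attr(out, "provenance") <- data.frame(dim = .PROFILE_DIMS,
                                        mean_diff = diffs, p = p,
                                        p_adj = p_adj)
  out
}

#' Add two effect barcodes
#'
#' Elementwise integer sum with sign saturation: each output trit is
#' `sign(a + b)`, so `-1 + -1` clamps to `-1`. The operation is commutative
#' but, because of the clamping, not associative in general.
#'
#' @param a,b `effect_barcode`s (or anything [effect_barcode()] accepts).
#' @return An `effect_barcode`.
#' @examples
#' # integrin-VWF blockade + integrin-Fg blockade = pan-integrin blockade
#' add_barcodes(effect_barcode("-0-0000"), effect_barcode("--00000"))
#' @export
add_barcodes <- function(a, b) {
  a <- as_effect_barcode(a); b <- as_effect_barcode(b)
  effect_barcode(as.integer(sign(unclass(a) + unclass(b))))
}

#' Build healthy reference ranges
#'
#' Per-dimension Gaussian reference intervals from healthy-young profiles:
#' sample mean and s.d., with bounds mean +/- 2 s.d. (covering ~95.45% of a
#' Gaussian dimension).
#'
#' @param healthy_profiles Matrix or data.frame with the [profile_dims()]
#'   columns; at least 10 rows.
#' @return An object of class `reference_ranges`: `data.frame` with columns
#'   `dim`, `mean`, `sd`, `low`, `high`.
#' @export
build_reference_ranges <- function(healthy_profiles) {
  m <- as.matrix(as.data.frame(healthy_profiles)[, .PROFILE_DIMS, drop = FALSE])
  if (nrow(m) < 10L) stop("need at least 10 healthy profiles")
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  if (any(s == 0)) stop("zero standard deviation in dimension(s): ",
                        paste(.PROFILE_DIMS[s == 0], collapse = ", "))
  out <- data.frame(dim = .PROFILE_DIMS, mean = unname(mu), sd = unname(s),
                    low = unname(mu - 2 * s), high = unname(mu + 2 * s))
  class(out) <- c("reference_ranges", "data.frame")
  out
}

#' Personal thrombus barcode
#'
#' Classifies each dimension of a subject's profile against the reference
#' ranges: `-1` below `low`, `+1` above `high`, `0` otherwise. Boundary
#' values classify as normal (closed reference interval).
#'
#' @param profile Named numeric vector over [profile_dims()].
#' @param ranges A [build_reference_ranges()] result.
#' @return An `effect_barcode`-classed 7-trit personal barcode.
#' @export
personal_barcode <- function(profile, ranges) {
  stopifnot(inherits(ranges, "reference_ranges"))
  v <- .as_profile_vec(profile)
  trits <- integer(7)
  trits[v < ranges$low] <- -1L
  trits[v > ranges$high] <- 1L
  effect_barcode(trits)
}

#' Census of personal barcodes
#'
#' @param barcodes A list of barcodes, a character vector of canonical
#'   strings, or a matrix of trits (subjects in rows).
#' @return List with `n_distinct`, `frequency` (named sorted table of
#'   canonical strings) and `dim_fractions` (3 x 7 matrix of low / normal /
#'   high fractions per dimension; columns sum to 1).
#' @export
barcode_census <- function(barcodes) {
  if (is.matrix(barcodes))
    barcodes <- lapply(seq_len(nrow(barcodes)),
                       function(i) effect_barcode(as.integer(barcodes[i, ])))
  if (is.character(barcodes)) barcodes <- lapply(barcodes, effect_barcode)
  trits <- t(vapply(barcodes, function(b) unclass(as_effect_barcode(b)),
                    integer(7)))
  strings <- apply(trits, 1, function(tr) barcode_string(as.integer(tr)))
  freq <- sort(table(strings), decreasing = TRUE)
  fr <- vapply(seq_len(7), function(d) {
    c(low = mean(trits[, d] == -1L),
      normal = mean(trits[, d] == 0L),
      high = mean(trits[, d] == 1L))
  }, numeric(3))
  colnames(fr) <- .PROFILE_DIMS
  list(n_distinct = length(freq), frequency = freq, dim_fractions = fr)
}
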