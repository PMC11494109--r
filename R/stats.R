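# Cohort-level correlation and discrimination statistics.

#' Correlation battery between two profile readouts
#'
#' Reports the ordinary least-squares slope with its two-sided t-test, the
#' Pearson coefficient, Spearman's rank correlation and Kendall's tau-b
#' (tie-corrected), as used to cross-check associations between thrombus
#' profile dimensions.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite.
#' @return An object of class `correlation_result`: list with `slope`,
#'   `slope_p`, `pearson_r`, `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  kd <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  structure(list(slope = unname(sm["x", "Estimate"]),
                 slope_p = unname(sm["x", "Pr(>|t|)"]),
                 pearson_r = stats::cor(x, y),
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 kendall_tau = unname(kd$estimate),
                 kendall_p = kd$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' Best separating threshold between two groups
#'
#' Scans all midpoints between consecutive sorted unique pooled values and
#' returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 100. Ties are broken toward higher specificity, then toward the lower
#' threshold. The criterion depends on the data only through ranks, so it is
#' invariant under strictly monotone transforms applied to both groups.
#'
#' @param negatives Marker values of the negative (e.g. healthy-young) group.
#' @param positives Marker values of the positive (e.g. at-risk) group.
#' @param direction `"auto"` picks the direction with the larger J;
#'   `"greater"` calls values above the threshold positive, `"less"` the
#'   reverse.
#' @return An object of class `separation_result`: list with `threshold`,
#'   `sensitivity` (%), `specificity` (%), `youden_j`, `direction`.
#' @export
best_threshold <- function(negatives, positives,
                           direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (!length(negatives) || !length(positives)) stop("empty group")
  pooled <- sort(unique(c(negatives, positives)))
  cand <- if (length(pooled) > 1L)
    (pooled[-1] + pooled[-length(pooled)]) / 2 else pooled
  eval_dir <- function(dir) {
    res <- vapply(cand, function(thr) {
      if (dir == "greater") {
        sens <- mean(positives > thr); spec <- mean(negatives <= thr)
      } else {
        sens <- mean(positives < thr); spec <- mean(negatives >= thr)
      }
      c(sens = 100 * sens, spec = 100 * spec)
    }, numeric(2))
    j <- res["sens", ] + res["spec", ] - 100
    best <- order(-j, -res["spec", ], cand)[1L]
    list(threshold = cand[best], sensitivity = unname(res["sens", best]),
         specificity = unname(res["spec", best]),
         youden_j = unname(j[best]), direction = dir)
  }
  out <- if (direction == "auto") {
    g <- eval_dir("greater"); l <- eval_dir("less")
    if (l$youden_j > g$youden_j) l else g
  } else eval_dir(direction)
  structure(out, class = "separation_result")
}

#' Classify values against a separation threshold
#'
#' @param values Marker values.
#' @param separation A [best_threshold()] result.
#' @return Logical vector: called positive?
#' @export
classify_by_threshold <- function(values, separation) {
  stopifnot(inherits(separation, "separation_result"))
  if (separation$direction == "greater") values > separation$threshold
  else values < separation$threshold
}

#' Consistency of two classifications
#'
#' @param labels_a,labels_b Classifications of the same subjects by two
#'   markers (logical or any comparable vectors of equal length).
#' @return Percent of subjects classified identically.
#' @export
classification_consistency <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0L)
  100 * mean(labels_a == labels_b)
}

#' One- or two-way group comparison
#'
#' Contract-level fixed-effects ANOVA with Tukey HSD multiple comparisons.
#' One-factor mode additionally reports the Welch (variance-heterogeneity
#' robust) p-value; two-factor mode fits the full interaction model and
#' reports the interaction p-value used to probe bi-directional cooperation
#' between risk factors.
#'
#' @param values Numeric response.
#' @param factor_a First grouping factor.
#' @param factor_b Optional second grouping factor.
#' @return List with `anova_table`, per-factor (and interaction) p-values,
#'   `tukey` (TukeyHSD result) and, for one-way designs, `welch_p`.
#' @export
group_compare <- function(values, factor_a, factor_b = NULL) {
  factor_a <- factor(factor_a)
  if (is.null(factor_b)) {
    if (nlevels(factor_a) < 2L || any(table(factor_a) == 0L))
      stop("empty group")
    fit <- stats::aov(values ~ factor_a)
    tab <- summary(fit)[[1L]]
    welch <- tryCatch(stats::oneway.test(values ~ factor_a)$p.value,
                      error = function(e) NA_real_)
    list(anova_table = tab, p = tab[["Pr(>F)"]][1L],
         f = tab[["F value"]][1L], df = tab[["Df"]],
         welch_p = welch, tukey = stats::TukeyHSD(fit))
  } else {
    factor_b <- factor(factor_b)
    if (nlevels(factor_a) < 2L || nlevels(factor_b) < 2L ||
        any(table(factor_a, factor_b) == 0L))
      stop("empty cell in the two-way design")
    fit <- stats::aov(values ~ factor_a * factor_b)
    tab <- summary(fit)[[1L]]
    list(anova_table = tab,
         p_a = tab[["Pr(>F)"]][1L], p_b = tab[["Pr(>F)"]][2L],
         p_interaction = tab[["Pr(>F)"]][3L],
         tukey = stats::TukeyHSD(fit))
  }
}
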