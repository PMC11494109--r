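# Hill dose-response fitting: residue size (%) versus inhibitor
# concentration, and IC50 extraction.
#
# The model is the inhibitor form of the Hill equation,
#   Residue(C) = R + (100 - R) / (1 + (C / IC50)^h),  h > 0,
# which is identical to the textbook form written with (IC50/C)^HillSlope
# under the sign convention HillSlope = -h (decreasing dose-response curves
# carry a negative Hill slope in that parameterization). Limits: 100% at
# C = 0, the saturating residue R as C -> Inf, and (100 + R)/2 at C = IC50.

#' Predict residue size from Hill parameters
#'
#' @param fit A `hill_fit` or any list with `ic50`, `hill_slope`, `floor_R`.
#' @param concentration Dose(s), >= 0 (same unit as `ic50`).
#' @return Residue size(s) in percent; `concentration = 0` returns 100.
#' @examples
#' predict_residue(list(ic50 = 1, hill_slope = 1, floor_R = 0), 1)  # 50
#' @export
predict_residue <- function(fit, concentration) {
  stopifnot(all(concentration >= 0), fit$ic50 > 0, fit$hill_slope > 0)
  r <- fit$floor_R
  ifelse(concentration == 0, 100,
         r + (100 - r) / (1 + (concentration / fit$ic50)^fit$hill_slope))
}

#' Fit the Hill equation to dose-response data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with multistart
#' initialization: IC50 starts log-spaced over three decades around the
#' geometric mid-dose, crossed with Hill slopes {0.5, 1, 2}. The saturating
#' residue is constrained to `[0, 100]`. Data showing no downward trend
#' (all residues near 100, or a non-negative rank correlation of residue
#' with dose) are flagged `"no_inhibition"` and no IC50 is reported.
#'
#' @param concentrations Doses (>= 0); at least 4 distinct values.
#' @param residues Residue sizes (%), same length, finite.
#' @return An object of class `hill_fit`: list with `ic50`, `hill_slope`,
#'   `floor_R`, `vcov` (parameter covariance, when available), `sse`,
#'   `converged` (logical) and `status` (`"ok"`, `"no_inhibition"` or
#'   `"not_converged"`).
#' @export
fit_hill <- function(concentrations, residues) {
  stopifnot(length(concentrations) == length(residues),
            all(is.finite(residues)), all(concentrations >= 0))
  if (length(unique(concentrations)) < 4L)
    stop("need at least 4 distinct concentrations")

  no_fit <- function(status)
    structure(list(ic50 = NA_real_, hill_slope = NA_real_,
                   floor_R = NA_real_, vcov = NULL, sse = NA_real_,
                   converged = FALSE, status = status),
              class = "hill_fit")

  # no-inhibition screen: flat-at-100 or rising dose-response
  if (max(residues) - min(residues) < 1) return(no_fit("no_inhibition"))
  rho <- suppressWarnings(
    stats::cor(concentrations, residues, method = "spearman"))
  if (!is.na(rho) && rho >= 0) return(no_fit("no_inhibition"))

  pos <- concentrations[concentrations > 0]
  mid <- exp(mean(log(range(pos))))
  starts <- expand.grid(ic50 = mid * 10^seq(-1.5, 1.5, length.out = 7),
                        h = c(0.5, 1, 2))
  r0 <- max(min(residues), 0)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        residues ~ R + (100 - R) / (1 + (concentrations / ic50)^h),
        start = list(R = min(r0, 99), ic50 = starts$ic50[i], h = starts$h[i]),
        lower = c(R = 0, ic50 = 1e-12, h = 0.05),
        upper = c(R = 100, ic50 = Inf, h = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(no_fit("not_converged"))
  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(list(ic50 = unname(cf["ic50"]), hill_slope = unname(cf["h"]),
                 floor_R = unname(cf["R"]), vcov = vc, sse = best$sse,
                 converged = TRUE, status = "ok"),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Hill fit: IC50 = %.4g, slope = %.3g, floor R = %.3g%%\n",
                x$ic50, x$hill_slope, x$floor_R))
  else cat("Hill fit: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Half-reduction concentration for biphasic dose-response data
#'
#' Some agents (e.g. negatively charged nanoparticles) show a biphasic
#' dose-dependency that the Hill equation cannot describe. This estimates
#' the concentration reducing the thrombus size by ~50% by monotone linear
#' interpolation (in log-concentration) along the descending branch, i.e.
#' from the first dose down to the dose of minimal residue.
#'
#' @param concentrations Doses in ascending order (> 0 on the branch used).
#' @param residues Residue sizes (%), same length.
#' @param target Residue level to cross (default 50%).
#' @return Interpolated concentration, or `NA` if the descending branch
#'   never crosses `target`.
#' @export
half_reduction_concentration <- function(concentrations, residues,
                                         target = 50) {
  stopifnot(length(concentrations) == length(residues), length(residues) >= 2L)
  o <- order(concentrations)
  concentrations <- concentrations[o]; residues <- residues[o]
  imin <- which.min(residues)
  branch <- seq_len(imin)
  cb <- concentrations[branch]; rb <- residues[branch]
  keep <- cb > 0
  cb <- cb[keep]; rb <- rb[keep]
  below <- which(rb <= target)
  if (!length(below)) return(NA_real_)
  j <- below[1L]
  if (j == 1L) return(cb[1L])
  w <- (rb[j - 1L] - target) / (rb[j - 1L] - rb[j])
  exp((1 - w) * log(cb[j - 1L]) + w * log(cb[j]))
}
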