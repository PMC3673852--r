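#' Variances of M- and A-values
#'
#' var(M) = 2 sigma^2 (1 - rho), var(A) = sigma^2 (1 + rho) / 2.  The ratio
#' identity log(4 var(A) / var(M)) / 2 = atanh(rho) is what lets the
#' intra-spot correlation be read off the two stratum variances.
#'
#' @param sigma2 marginal channel variance (> 0).
#' @param rho intra-spot correlation, |rho| < 1.
#' @return Named vector c(var_M, var_A).
#' @export
ma_variances <- function(sigma2, rho) {
  .check_eff(sigma2, rho)
  c(var_M = 2 * sigma2 * (1 - rho), var_A = sigma2 * (1 + rho) / 2)
}

#' Extra information in the A-values relative to the M-values
#'
#' For a common-reference contrast, the Fisher information carried by the
#' A-values relative to that carried by the M-values is (1 - rho)/(1 + rho):
#' the fractional efficiency gain of separate-channel over log-ratio
#' analysis.  It is 1 at rho = 0 (A doubles the information) and tends to 0
#' as rho tends to 1.
#'
#' @param rho intra-spot correlation, |rho| < 1.
#' @return The information gain fraction.
#' @export
info_gain_A_vs_M <- function(rho) {
  .check_eff(1, rho)
  (1 - rho) / (1 + rho)
}

#' Efficiency report for a common reference design
#'
#' n/2 arrays hybridize treatment B against a shared reference, n/2
#' treatment C.  For the contrast beta_B - beta_C:
#' var(gamma_M) = 8 sigma^2 (1 - rho)/n from the M-values,
#' var(gamma_A) = 8 sigma^2 (1 + rho)/n from the A-values, and a one-channel
#' experiment of the same size would achieve 4 sigma^2 / n.  The log-ratio
#' analysis beats the one-channel design iff rho > 0.5 (the break-even
#' correlation); the combined separate-channel estimator, an
#' inverse-variance combination of the two, always does.
#'
#' @param n total number of arrays (even).
#' @param sigma2 gene variance.
#' @param rho intra-spot correlation.
#' @return A list of class \code{"DesignEfficiencyReport"}.
#' @export
common_reference_eval <- function(n, sigma2 = 1, rho = 0) {
  .check_eff(sigma2, rho)
  .check_n_even(n)
  var_M <- 8 * sigma2 * (1 - rho) / n
  var_A <- 8 * sigma2 * (1 + rho) / n
  structure(list(design = "common_reference", n = n, sigma2 = sigma2,
                 rho = rho,
                 var_gamma_M = var_M,
                 var_gamma_A = var_A,
                 var_one_channel = 4 * sigma2 / n,
                 var_combined = 1 / (1 / var_M + 1 / var_A),
                 info_gain_A = info_gain_A_vs_M(rho),
                 break_even_rho = 0.5),
            class = "DesignEfficiencyReport")
}

#' Efficiency report for an unconnected design
#'
#' n/2 arrays co-hybridize B with C; n/2 co-hybridize D with E; no chain of
#' log-ratios links the two islands.  The within-island contrast gamma =
#' beta_B - beta_C has var 4 sigma^2 (1 - rho)/n and needs only M-values.
#' The cross-island contrast delta = beta_B - beta_D is estimable only by
#' the combined M/A analysis, with var 4 sigma^2 / n; its relative
#' efficiency versus the direct contrast is 1 - rho, the cost of comparing
#' across arrays instead of within spots.
#'
#' @inheritParams common_reference_eval
#' @return A list of class \code{"DesignEfficiencyReport"}.
#' @export
unconnected_eval <- function(n, sigma2 = 1, rho = 0) {
  .check_eff(sigma2, rho)
  .check_n_even(n)
  structure(list(design = "unconnected", n = n, sigma2 = sigma2, rho = rho,
                 var_gamma = 4 * sigma2 * (1 - rho) / n,
                 var_delta = 4 * sigma2 / n,
                 relative_efficiency = 1 - rho),
            class = "DesignEfficiencyReport")
}

#' Efficiency report for a paired (direct comparison) design
#'
#' Both treatments share every array, so the treatment contrast is a pure
#' within-spot comparison: the A-values carry no information about it and
#' the information gain from separate-channel analysis is exactly zero.
#'
#' @inheritParams common_reference_eval
#' @return A list of class \code{"DesignEfficiencyReport"}.
#' @export
paired_eval <- function(n, sigma2 = 1, rho = 0) {
  .check_eff(sigma2, rho)
  if (n < 1) stop("n must be positive")
  structure(list(design = "paired", n = n, sigma2 = sigma2, rho = rho,
                 var_gamma = 2 * sigma2 * (1 - rho) / n,
                 info_gain_A = 0),
            class = "DesignEfficiencyReport")
}

#' @export
print.DesignEfficiencyReport <- function(x, ...) {
  cat(sprintf("Design efficiency report: %s (n = %d, sigma2 = %g, rho = %g)\n",
              x$design, x$n, x$sigma2, x$rho))
  for (nm in setdiff(names(x), c("design", "n", "sigma2", "rho")))
    cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

.check_eff <- function(sigma2, rho) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (any(!is.finite(rho)) || any(abs(rho) >= 1))
    stop("rho must lie strictly in (-1, 1)")
  invisible(TRUE)
}

.check_n_even <- function(n) {
  if (n <= 0 || n %% 2 != 0) stop("n must be a positive even number of arrays")
  invisible(TRUE)
}
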