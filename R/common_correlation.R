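#' Per-gene correlation statistic on the atanh scale
#'
#' For one gene, tau = atanh(rho) is estimated by half the log of the
#' variance ratio 4*sigma2_A/sigma2_M, since
#' 4*var(A)/var(M) = (1+rho)/(1-rho).
#'
#' @param sigma2_M,sigma2_A stratum variance estimates (vectorized).
#' @return Numeric tau-hat value(s).
#' @export
tau_gene <- function(sigma2_M, sigma2_A) {
  if (any(sigma2_M <= 0) || any(sigma2_A <= 0))
    stop("stratum variances must be positive")
  0.5 * log(4 * sigma2_A / sigma2_M)
}

#' Bias of the per-gene tau statistic
#'
#' The stratum variance estimates follow approximate scaled chi-square
#' distributions on fractional df (d_M, d_A), so their log-ratio is biased.
#' Using E log(chisq_d / d) = digamma(d/2) - log(d/2), the bias of tau-hat is
#' (digamma(d_A/2) - log(d_A/2) - digamma(d_M/2) + log(d_M/2)) / 2,
#' and tau-hat minus this value is approximately unbiased for atanh(rho).
#'
#' @param d_M,d_A effective degrees of freedom (vectorized, positive).
#' @return Numeric bias value(s); zero when d_M equals d_A.
#' @export
tau_bias <- function(d_M, d_A) {
  if (any(d_M <= 0) || any(d_A <= 0))
    stop("degrees of freedom must be positive")
  (digamma(d_A / 2) - log(d_A / 2) - digamma(d_M / 2) + log(d_M / 2)) / 2
}

#' Pooled common intra-spot correlation
#'
#' Pools per-gene variance-ratio statistics into a single estimate of the
#' common intra-spot correlation.  Each usable gene contributes a
#' bias-corrected tau-hat; a trimmed mean (15 percent from each tail by
#' default) guards against outlier genes; the pooled correlation is
#' tanh of the trimmed mean.  Negative estimates are permitted, unlike the
#' variance-component formulation of the mixed model.
#'
#' @param fits a \code{GeneHetFitSet} from \code{\link{fit_all_genes}} (or a
#'   data frame with columns sigma2_M, sigma2_A, d_M, d_A, usable).
#' @param trim fraction trimmed from each tail (default 0.15).
#' @return A list of class \code{"CorrelationEstimate"}: \code{rho},
#'   \code{tau}, \code{tau_g} (named per-gene bias-corrected statistics,
#'   unusable genes absent), \code{trim}, \code{genes_used}.
#' @export
estimate_common_correlation <- function(fits, trim = 0.15) {
  use <- which(fits$usable)
  if (length(use) < 10L)
    stop("need at least 10 usable gene fits to pool a correlation (have ",
         length(use), ")")
  tau_g <- tau_gene(fits$sigma2_M[use], fits$sigma2_A[use]) -
    tau_bias(fits$d_M[use], fits$d_A[use])
  names(tau_g) <- fits$probe[use]
  tau <- mean(tau_g, trim = trim)
  structure(list(rho = tanh(tau), tau = tau, tau_g = tau_g,
                 trim = trim, genes_used = length(use)),
            class = "CorrelationEstimate")
}

#' @export
print.CorrelationEstimate <- function(x, ...) {
  cat(sprintf("Common intra-spot correlation: rho = %.4f (tau = %.4f)\n",
              x$rho, x$tau))
  cat(sprintf("pooled over %d genes, trim = %g per tail\n",
              x$genes_used, x$trim))
  invisible(x)
}

#' Non-robust pooled tau (diagnostic)
#'
#' The efficient-under-independence pooled estimator
#' tau = log(4 * sum(sigma2_A) / sum(sigma2_M)) / 2.  Exposed uncorrected and
#' untrimmed, for diagnostics only: it is not robust against outlier genes.
#'
#' @inheritParams estimate_common_correlation
#' @return Numeric tau value.
#' @export
pooled_tau <- function(fits) {
  use <- which(fits$usable)
  if (length(use) < 2L) stop("need at least 2 usable gene fits")
  0.5 * log(4 * sum(fits$sigma2_A[use]) / sum(fits$sigma2_M[use]))
}
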