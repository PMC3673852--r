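#' Construct a variance prior directly
#'
#' Mostly useful for fixing the prior rather than estimating it: d0 = 0
#' gives unmoderated gene-wise variances (ordinary t-statistics), d0 = Inf
#' forces every gene to the common variance s0_2.
#'
#' @param d0 prior degrees of freedom (> 0, may be Inf, or 0 for no
#'   moderation).
#' @param s0_2 prior variance (> 0; ignored when d0 = 0).
#' @return A \code{"VariancePrior"} object.
#' @export
variance_prior <- function(d0, s0_2 = 1) {
  if (d0 < 0) stop("d0 must be non-negative")
  if (s0_2 <= 0) stop("s0_2 must be positive")
  structure(list(d0 = d0, s0_2 = s0_2), class = "VariancePrior")
}

#' End-to-end differential expression analysis
#'
#' Runs the full separate-channel pipeline on a two-channel data set:
#' M/A transformation (with optional loess-M / quantile-A normalization),
#' per-gene two-stratum REML, pooling of the common intra-spot correlation,
#' rescaled gene-wise OLS, contrasts, and empirical Bayes moderated
#' t-statistics.  With \code{method = "log_ratio"} the classic M-value-only
#' analysis is run instead on the same pre-processed data, making the two
#' directly comparable.
#'
#' @param data a \code{\link{two_channel}} object or an \code{MAData}.
#' @param targets targets data frame describing the hybridizations.
#' @param contrasts character vector of contrast specifications for
#'   \code{\link{make_contrasts}}, or a ready contrast matrix; NULL fits
#'   coefficients only.
#' @param method \code{"separate_channel"} (default) or \code{"log_ratio"}.
#' @param normalize run the loess-M / quantile-A pipeline first.
#' @param dye_effect include a dye-effect column in the design.
#' @param trim trim fraction for correlation pooling.
#' @param rho fix the intra-spot correlation instead of estimating it
#'   (ignored for log-ratio fits).
#' @param moderate if FALSE, skip variance moderation (ordinary
#'   t-statistics).
#' @return A list of class \code{"ScAnalysis"} with components
#'   \code{correlation} (NULL for log-ratio fits), \code{het_fits},
#'   \code{fit}, \code{prior} and \code{ebayes}.
#' @export
sc_analysis <- function(data, targets, contrasts = NULL,
                        method = c("separate_channel", "log_ratio"),
                        normalize = FALSE, dye_effect = FALSE, trim = 0.15,
                        rho = NULL, moderate = TRUE) {
  method <- match.arg(method)
  ma <- if (inherits(data, "TwoChannelMatrix")) to_ma(data) else data
  stopifnot(inherits(ma, "MAData"))
  if (normalize) ma <- normalize_ma(ma)
  design <- build_channel_design(targets, dye_effect = dye_effect)
  correlation <- NULL
  het_fits <- NULL
  if (method == "separate_channel") {
    if (is.null(rho)) {
      Z <- transform_design(design)
      het_fits <- fit_all_genes(ma, Z)
      correlation <- estimate_common_correlation(het_fits, trim = trim)
      rho <- correlation$rho
    }
    fit <- fit_separate_channel(ma, design, rho)
  } else {
    fit <- fit_log_ratio(ma, design)
  }
  if (!is.null(contrasts)) {
    C <- if (is.character(contrasts)) make_contrasts(design, contrasts)
         else contrasts
    fit <- contrast_fit(fit, C)
  }
  prior <- if (moderate) fit_variance_prior(fit$sigma^2, fit$df_residual)
           else variance_prior(0)
  eb <- moderated_t(fit, prior)
  structure(list(correlation = correlation, het_fits = het_fits, fit = fit,
                 prior = prior, ebayes = eb, method = method),
            class = "ScAnalysis")
}

#' @export
print.ScAnalysis <- function(x, ...) {
  cat("Two-channel differential expression analysis (", x$method, ")\n", sep = "")
  if (!is.null(x$correlation)) print(x$correlation)
  cat(sprintf("prior: d0 = %g, s0^2 = %g; residual df = %g\n",
              x$prior$d0, x$prior$s0_2, x$fit$df_residual))
  invisible(x)
}
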