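#' Estimate the variance prior by log-scale moment matching
#'
#' The gene variances are modelled a priori as s0^2 * d0 / chisq_{d0}
#' (a scaled inverse chi-square).  Marginally each residual variance s_g^2
#' is then s0^2 times an F-like ratio, and on the log scale
#' e_g = log s_g^2 - digamma(d/2) + log(d/2) has mean
#' log s0^2 + digamma(d0/2) - log(d0/2) and variance
#' trigamma(d/2) + trigamma(d0/2).  Matching the first two moments gives d0
#' from the trigamma inverse and then s0^2.  Zero excess dispersion
#' (var(e) <= trigamma(d/2)) means the variances are exchangeable and d0 is
#' infinite.
#'
#' @param sigma2 length-G vector of gene residual variances.
#' @param d residual degrees of freedom of the gene-wise fits (scalar).
#' @return A list of class \code{"VariancePrior"}: \code{d0} (possibly
#'   \code{Inf}) and \code{s0_2}.
#' @export
fit_variance_prior <- function(sigma2, d) {
  if (length(sigma2) < 10L) stop("need at least 10 gene variances")
  if (d <= 0) stop("residual degrees of freedom must be positive")
  zero <- sigma2 <= 0
  if (all(zero)) stop("all gene variances are zero")
  if (any(zero)) {
    warning(sum(zero), " zero variance(s) excluded from prior estimation")
    sigma2 <- sigma2[!zero]
  }
  e <- log(sigma2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  excess <- stats::var(e) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 > 1e6) {
      d0 <- Inf
      s0_2 <- exp(emean)
    } else {
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  structure(list(d0 = d0, s0_2 = s0_2), class = "VariancePrior")
}

#' Inverse of the trigamma function
#'
#' Solves trigamma(x) = y for x > 0 by Newton iteration on the reciprocal
#' scale, where the function is nearly linear; monotonicity of trigamma
#' guarantees a unique root.
#'
#' @param y positive value(s).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @return x such that trigamma(x) = y.
#' @export
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  if (any(y <= 0)) stop("trigamma_inverse requires positive input")
  out <- y
  for (k in seq_along(y)) {
    yy <- y[k]
    if (yy > 1e7) { out[k] <- 1 / sqrt(yy); next }   # trigamma(x) ~ 1/x^2, x->0
    if (yy < 1e-6) { out[k] <- 1 / yy; next }        # trigamma(x) ~ 1/x, x->Inf
    x <- 0.5 + 1 / yy
    for (i in seq_len(max_iter)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < tol * x) break
    }
    out[k] <- x
  }
  out
}

#' Posterior (squeezed) gene variances
#'
#' The posterior mean of each gene variance given the prior:
#' s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d), a convex combination that pulls
#' noisy gene variances toward the prior value.
#'
#' @param sigma2 gene residual variances.
#' @param d residual degrees of freedom.
#' @param prior a \code{VariancePrior}.
#' @return Vector of posterior variances.
#' @export
squeeze_var <- function(sigma2, d, prior) {
  stopifnot(inherits(prior, "VariancePrior"))
  if (!is.finite(prior$d0)) return(rep(prior$s0_2, length(sigma2)))
  if (prior$d0 == 0) return(sigma2)
  (prior$d0 * prior$s0_2 + d * sigma2) / (prior$d0 + d)
}

#' Moderated t-statistics with exact null distributions
#'
#' Computes moderated t-statistics t~ = beta / (s~ sqrt(v_j)) using the
#' posterior standard deviations, with two-sided p-values from the t
#' distribution on d0 + d degrees of freedom (the normal distribution when
#' d0 is infinite).  BH-adjusted q-values and a fixed-lambda Storey pi0 are
#' attached per contrast.
#'
#' @param fit a \code{LinearFitSet} (usually after
#'   \code{\link{contrast_fit}}).
#' @param prior a \code{VariancePrior} from \code{\link{fit_variance_prior}}.
#' @param pi0_lambda lambda for the Storey pi0 estimate (default 0.5).
#' @return A list of class \code{"EBayesResult"}: \code{s_tilde_2},
#'   \code{t}, \code{p}, \code{q}, \code{df_total}, \code{pi0},
#'   \code{coefficients}, \code{probes}, \code{prior}.
#' @export
moderated_t <- function(fit, prior, pi0_lambda = 0.5) {
  stopifnot(inherits(fit, "LinearFitSet"), inherits(prior, "VariancePrior"))
  v <- fit$stdev_unscaled
  if (any(v <= 0)) stop("non-positive unscaled standard deviation in fit")
  s2 <- squeeze_var(fit$sigma^2, fit$df_residual, prior)
  df_total <- prior$d0 + fit$df_residual
  tt <- fit$coefficients / (sqrt(s2) %o% v)
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  q <- p
  pi0 <- numeric(ncol(p))
  for (j in seq_len(ncol(p))) {
    q[, j] <- bh_adjust(p[, j])
    pi0[j] <- suppressWarnings(storey_pi0(p[, j], lambda = pi0_lambda))
  }
  names(pi0) <- colnames(fit$coefficients)
  dimnames(tt) <- dimnames(p) <- dimnames(q) <-
    list(fit$probes, colnames(fit$coefficients))
  structure(list(s_tilde_2 = s2, t = tt, p = p, q = q,
                 df_total = df_total, pi0 = pi0,
                 coefficients = fit$coefficients, probes = fit$probes,
                 prior = prior),
            class = "EBayesResult")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (via \code{stats::p.adjust}).
#'
#' @param p vector of p-values in [0, 1].
#' @return Adjusted q-values, monotone in sorted p and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey estimate of the null proportion pi0
#'
#' pi0-hat = #\{p > lambda\} / (m (1 - lambda)) at a single fixed lambda,
#' clamped to (0, 1].
#'
#' @param p vector of p-values.
#' @param lambda threshold in (0, 1) (default 0.5).
#' @return Estimated proportion of true nulls.
#' @export
storey_pi0 <- function(p, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie strictly in (0, 1)")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  lower <- 1 / (m * (1 - lambda))
  if (pi0 <= 0) {
    warning("all p-values below lambda; pi0 clamped to its lower bound")
    pi0 <- lower
  }
  min(pi0, 1)
}

#' Ranked table of top genes for one contrast
#'
#' @param result an \code{EBayesResult}.
#' @param coef contrast name or index (default 1).
#' @param n number of genes to return (default 10; larger than G returns
#'   all).
#' @param sort_by one of \code{"p"}, \code{"t"}, \code{"logFC"},
#'   \code{"none"}.
#' @return Data frame with columns probe, logFC, t, p, q, sorted by the
#'   chosen key (ties broken by probe identifier).
#' @export
top_table <- function(result, coef = 1L, n = 10L, sort_by = c("p", "t", "logFC", "none")) {
  stopifnot(inherits(result, "EBayesResult"))
  sort_by <- match.arg(sort_by)
  if (is.character(coef) && !(coef %in% colnames(result$t)))
    stop("unknown coefficient: ", coef)
  tab <- data.frame(probe = result$probes,
                    logFC = result$coefficients[, coef],
                    t = result$t[, coef],
                    p = result$p[, coef],
                    q = result$q[, coef],
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- switch(sort_by,
                p = order(tab$p, tab$probe),
                t = order(-abs(tab$t), tab$probe),
                logFC = order(-abs(tab$logFC), tab$probe),
                none = seq_len(nrow(tab)))
  utils::head(tab[ord, , drop = FALSE], n)
}
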