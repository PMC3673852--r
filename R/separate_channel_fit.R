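#' Rescale M/A data and design to a homoscedastic model
#'
#' With a known common intra-spot correlation rho, dividing every M-value
#' (and M-row of the design) by sqrt(2*(1-rho)) and every A-value (and A-row)
#' by sqrt((1+rho)/2) gives all 2n observations the same variance sigma_g^2,
#' so per-gene inference reduces to ordinary least squares.  Estimates with
#' |rho| > 0.99 are clamped (with a warning) so both scale factors stay
#' finite.
#'
#' @param ma an \code{MAData} object.
#' @param Z a \code{TransformedDesign} for the same arrays.
#' @param rho common intra-spot correlation in (-1, 1), or a
#'   \code{CorrelationEstimate}.
#' @return A list with \code{z} (G x 2n matrix, scaled M columns then scaled
#'   A columns), \code{design} (scaled 2n x p matrix), \code{coefficients},
#'   \code{probes} and \code{rho} (after any clamping).
#' @export
rescale_ma <- function(ma, Z, rho) {
  stopifnot(inherits(ma, "MAData"), inherits(Z, "TransformedDesign"))
  if (inherits(rho, "CorrelationEstimate")) rho <- rho$rho
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("rho must lie strictly between -1 and 1")
  if (abs(rho) > 0.99) {
    warning("rho = ", signif(rho, 4), " clamped to +/-0.99 before rescaling")
    rho <- sign(rho) * 0.99
  }
  n <- Z$n
  sM <- sqrt(2 * (1 - rho))
  sA <- sqrt((1 + rho) / 2)
  z <- cbind(ma$M / sM, ma$A / sA)
  colnames(z) <- c(paste0(ma$arrays, ".M"), paste0(ma$arrays, ".A"))
  Zs <- Z$Z
  Zs[seq_len(n), ] <- Zs[seq_len(n), , drop = FALSE] / sM
  Zs[n + seq_len(n), ] <- Zs[n + seq_len(n), , drop = FALSE] / sA
  list(z = z, design = Zs, coefficients = Z$coefficients,
       probes = ma$probes, rho = rho)
}

#' Gene-wise ordinary least squares on rescaled data
#'
#' Fits every gene by OLS on the rescaled design.  Residual degrees of
#' freedom are 2n - rank(design): both the M- and the A-stratum contribute
#' residual information once the data are homoscedastic.
#'
#' @param scaled output of \code{\link{rescale_ma}} (or a list with a G x m
#'   data matrix \code{z} and m x p matrix \code{design}).
#' @return A list of class \code{"LinearFitSet"}: \code{coefficients}
#'   (G x p), \code{sigma} (length-G residual standard deviations),
#'   \code{df_residual}, \code{cov_unscaled} (p x p), \code{stdev_unscaled}
#'   (sqrt of its diagonal), \code{probes}, \code{method}.
#' @export
fit_gene_lm <- function(scaled) {
  z <- scaled$z
  D <- scaled$design
  qrD <- qr(D)
  p <- ncol(D)
  if (qrD$rank < p) stop("rescaled design is rank deficient")
  m <- nrow(D)
  if (m <= p) stop("need more observations than coefficients")
  beta <- t(qr.coef(qrD, t(z)))
  res <- z - beta %*% t(D)
  df <- m - p
  sigma <- sqrt(rowSums(res^2) / df)
  R <- qr.R(qrD)
  cov_unscaled <- chol2inv(R)
  dimnames(cov_unscaled) <- list(colnames(D), colnames(D))
  colnames(beta) <- colnames(D)
  structure(list(coefficients = beta, sigma = sigma, df_residual = df,
                 cov_unscaled = cov_unscaled,
                 stdev_unscaled = sqrt(diag(cov_unscaled)),
                 probes = scaled$probes, method = "separate_channel"),
            class = "LinearFitSet")
}

#' Fit the separate-channel linear model
#'
#' Convenience wrapper: transform the channel design to M/A form, rescale
#' data and design by the common correlation, and fit gene-wise OLS.
#'
#' @param ma an \code{MAData} object.
#' @param design a \code{ChannelDesign}.
#' @param rho common intra-spot correlation (or a
#'   \code{CorrelationEstimate}).
#' @return A \code{LinearFitSet} (see \code{\link{fit_gene_lm}}).
#' @export
fit_separate_channel <- function(ma, design, rho) {
  Z <- transform_design(design)
  fit_gene_lm(rescale_ma(ma, Z, rho))
}

#' Apply contrasts to a gene-wise linear fit
#'
#' Re-expresses a fit in terms of contrasts: coefficients become beta C and
#' the unscaled covariance becomes C' V C.  For log-ratio fits, contrasts are
#' first checked for estimability (a contrast is estimable only if it lies in
#' the row space of the difference design; cross-island comparisons of an
#' unconnected layout fail this check).
#'
#' @param fit a \code{LinearFitSet}.
#' @param contrasts a \code{ContrastMatrix} (p x k) or bare numeric matrix.
#' @return A \code{LinearFitSet} in contrast space.
#' @export
contrast_fit <- function(fit, contrasts) {
  stopifnot(inherits(fit, "LinearFitSet"))
  C <- unclass(contrasts)
  if (is.null(dim(C))) C <- matrix(C, ncol = 1L)
  if (nrow(C) != ncol(fit$coefficients))
    stop("contrast matrix rows must match fit coefficients")
  if (!is.null(fit$rowspace)) {
    Vr <- fit$rowspace
    resid <- C - Vr %*% crossprod(Vr, C)
    bad <- sqrt(colSums(resid^2)) > 1e-8 * pmax(sqrt(colSums(C^2)), 1)
    if (any(bad))
      stop("contrast(s) not estimable from log-ratios alone: ",
           paste(colnames(C)[bad], collapse = ", "),
           " (design unconnected for these comparisons)")
  }
  cov_new <- t(C) %*% fit$cov_unscaled %*% C
  fit$coefficients <- fit$coefficients %*% C
  fit$cov_unscaled <- cov_new
  fit$stdev_unscaled <- sqrt(diag(cov_new))
  fit
}

#' Classic log-ratio (M-value only) gene-wise fit
#'
#' The traditional analysis: gene-wise least squares of the M-values on the
#' difference design (red row minus green row of the channel design).  For
#' one-hot condition designs the difference design is rank deficient, so the
#' fit uses the minimum-norm (pseudoinverse) solution and records the design
#' row space; \code{\link{contrast_fit}} then refuses contrasts that are not
#' estimable from log-ratios, which is exactly the unconnected-design
#' failure mode the separate-channel analysis removes.
#'
#' @param ma an \code{MAData} object.
#' @param targets targets data frame (see \code{\link{read_targets}}), or a
#'   ready-made \code{ChannelDesign}.
#' @param dye_effect passed to \code{\link{build_channel_design}}.
#' @return A \code{LinearFitSet} with method tag \code{"log_ratio"}.
#' @export
fit_log_ratio <- function(ma, targets, dye_effect = FALSE) {
  stopifnot(inherits(ma, "MAData"))
  design <- if (inherits(targets, "ChannelDesign")) targets
            else build_channel_design(targets, dye_effect = dye_effect)
  n <- design$n
  X <- design$X
  D <- X[n + seq_len(n), , drop = FALSE] - X[seq_len(n), , drop = FALSE]
  sv <- svd(D)
  pos <- sv$d > max(dim(D)) * .Machine$double.eps * max(sv$d, 1)
  r <- sum(pos)
  if (r < 1L) stop("difference design has rank zero")
  if (n <= r) stop("no residual degrees of freedom for the log-ratio fit")
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  dinv <- 1 / sv$d[pos]
  Dplus <- V %*% (dinv * t(U))                  # p x n pseudoinverse
  beta <- ma$M %*% t(Dplus)
  res <- ma$M - beta %*% t(D)
  df <- n - r
  sigma <- sqrt(rowSums(res^2) / df)
  cov_unscaled <- V %*% (dinv^2 * t(V))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  colnames(beta) <- colnames(X)
  structure(list(coefficients = beta, sigma = sigma, df_residual = df,
                 cov_unscaled = cov_unscaled,
                 stdev_unscaled = sqrt(diag(cov_unscaled)),
                 probes = ma$probes, method = "log_ratio",
                 rowspace = V),
            class = "LinearFitSet")
}

#' @export
print.LinearFitSet <- function(x, ...) {
  cat(sprintf("LinearFitSet (%s): %d genes, %d coefficient(s), %g residual df\n",
              x$method, nrow(x$coefficients), ncol(x$coefficients),
              x$df_residual))
  invisible(x)
}
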