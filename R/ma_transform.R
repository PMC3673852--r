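#' Convert channel intensities to M- and A-values
#'
#' Reparameterizes the two correlated channel log-intensities of each spot
#' into two uncorrelated contrasts: the within-spot log-ratio
#' M = red - green and the spot mean log-intensity A = (red + green)/2.
#' Under the intra-spot correlation model var(M) = 2*sigma^2*(1-rho) and
#' var(A) = sigma^2*(1+rho)/2, and M and A are independent, which is what
#' makes the two-stratum analysis tractable.
#'
#' @param y a \code{\link{two_channel}} object.
#' @return An object of class \code{"MAData"}: list with \code{probes},
#'   \code{arrays}, \code{M} and \code{A} (both G x n).
#' @export
to_ma <- function(y) {
  stopifnot(inherits(y, "TwoChannelMatrix"))
  structure(list(probes = y$probes, arrays = y$arrays,
                 M = y$red - y$green, A = (y$red + y$green) / 2),
            class = "MAData")
}

#' Convert M- and A-values back to channel intensities
#'
#' Exact inverse of \code{\link{to_ma}}: green = A - M/2, red = A + M/2.
#'
#' @param ma an \code{MAData} object.
#' @return A \code{\link{two_channel}} object.
#' @export
from_ma <- function(ma) {
  stopifnot(inherits(ma, "MAData"))
  two_channel(green = ma$A - ma$M / 2, red = ma$A + ma$M / 2,
              probes = ma$probes, arrays = ma$arrays)
}

#' @export
print.MAData <- function(x, ...) {
  cat(sprintf("MAData: %d probes x %d arrays\n", length(x$probes), length(x$arrays)))
  invisible(x)
}

#' Transform a channel design matrix to the M/A parameterization
#'
#' Applies to the design matrix the same linear map that takes channel
#' intensities to (M, A): for each array the M-row of Z is the red row of X
#' minus the green row, and the A-row is their average.  In block form
#' Z = (C_M C_A)^T X with C_M^T = (-1,1) (x) I_n and C_A^T = (1/2,1/2) (x) I_n
#' acting on channel-stacked data.
#'
#' @param design a \code{ChannelDesign} following the green-then-red row
#'   convention.
#' @return An object of class \code{"TransformedDesign"}: list with \code{Z}
#'   (2n x p; rows 1..n are the M-block, n+1..2n the A-block),
#'   \code{coefficients} and \code{n}.
#' @export
transform_design <- function(design) {
  stopifnot(inherits(design, "ChannelDesign"))
  X <- design$X
  n <- design$n
  if (nrow(X) != 2L * n) stop("design matrix must have 2n rows")
  Xg <- X[seq_len(n), , drop = FALSE]
  Xr <- X[n + seq_len(n), , drop = FALSE]
  Z <- rbind(Xr - Xg, (Xr + Xg) / 2)
  rownames(Z) <- c(paste0(design$arrays, ".M"), paste0(design$arrays, ".A"))
  structure(list(Z = Z, coefficients = design$coefficients,
                 arrays = design$arrays, n = n),
            class = "TransformedDesign")
}

#' Loess-normalize M-values within each array
#'
#' Replaces each array's M-values by the residuals from a robust local
#' regression of M on A, removing intensity-dependent dye bias.  A-values are
#' left untouched.  Uses the weighted-lowess fit of \code{limma::loessFit},
#' the standard curve fitter for MA normalization.
#'
#' @param ma an \code{MAData} object.
#' @param span loess span as a fraction of the data (default 0.3).
#' @param iterations robustifying iterations (default 4).
#' @return The normalized \code{MAData}.
#' @export
normalize_m_loess <- function(ma, span = 0.3, iterations = 4L) {
  stopifnot(inherits(ma, "MAData"))
  if (nrow(ma$M) < 10L)
    stop("loess normalization needs at least 10 spots per array")
  M <- ma$M
  for (j in seq_len(ncol(M))) {
    fit <- limma::loessFit(y = M[, j], x = ma$A[, j], span = span,
                           iterations = iterations)
    M[, j] <- fit$residuals
  }
  ma$M <- M
  ma
}

#' Quantile-normalize A-values between arrays
#'
#' Forces the empirical distribution of A to be identical across arrays: each
#' array's sorted A-values are replaced by the mean of the sorted A-values
#' over all arrays.  Ties within an array receive the mean of the reference
#' values at their tied sorted positions, which keeps the map deterministic
#' and symmetric.  M-values are left untouched.
#'
#' @param ma an \code{MAData} object.
#' @return The normalized \code{MAData}.
#' @export
normalize_a_quantile <- function(ma) {
  stopifnot(inherits(ma, "MAData"))
  A <- ma$A
  G <- nrow(A)
  sorted <- apply(A, 2L, sort)
  mu <- rowMeans(sorted)
  for (j in seq_len(ncol(A))) {
    o <- order(A[, j])
    v <- A[o, j]
    out <- mu
    # runs of tied values share the mean of mu over their positions
    r <- rle(v)
    if (any(r$lengths > 1L)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$lengths > 1L))
        out[starts[k]:ends[k]] <- mean(mu[starts[k]:ends[k]])
    }
    A[o, j] <- out
  }
  ma$A <- A
  ma
}

#' Loess-M then quantile-A normalization pipeline
#'
#' The standard pre-processing for separate-channel analysis: within-array
#' loess normalization of the M-values followed by between-array quantile
#' normalization of the A-values.  The M-values after this pipeline equal the
#' M-values after loess alone, so results stay directly comparable with a
#' classic log-ratio analysis of the same data.
#'
#' @inheritParams normalize_m_loess
#' @param loess,aquantile logical switches for each step.
#' @return The normalized \code{MAData}.
#' @export
normalize_ma <- function(ma, span = 0.3, loess = TRUE, aquantile = TRUE) {
  if (loess) ma <- normalize_m_loess(ma, span = span)
  if (aquantile) ma <- normalize_a_quantile(ma)
  ma
}
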