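#' Two-stratum REML for one gene
#'
#' Fits the heteroscedastic regression of a gene's stacked (M, A) vector on
#' the transformed design Z, where the first n observations (M-block) share
#' variance sigma^2_M and the last n (A-block) share sigma^2_A.  The REML
#' estimates solve the score equations directly via a fixed point: weighted
#' least squares at the current variances, then each stratum variance is
#' updated to its residual sum of squares divided by the stratum's
#' leverage-corrected degrees of freedom sum(1 - h_i).  At convergence the
#' fractional effective degrees of freedom are d_M = sum over the M-block of
#' (1 - h_i) and likewise d_A, and the stratum estimates follow approximate
#' scaled chi-square distributions on those df.
#'
#' @param z numeric 2n-vector: the gene's M-values then A-values.
#' @param Z a \code{TransformedDesign} (or bare 2n x p matrix).
#' @param tol convergence tolerance on the maximum relative change of the two
#'   variances (default 1e-5).
#' @param max_iter iteration cap (default 40).
#' @return A list of class \code{"GeneHetFit"} with components
#'   \code{sigma2_M}, \code{sigma2_A}, \code{d_M}, \code{d_A}, \code{n_iter},
#'   \code{converged}, \code{usable}.
#' @export
reml_two_strata <- function(z, Z, tol = 1e-5, max_iter = 40L) {
  Zm <- if (inherits(Z, "TransformedDesign")) Z$Z else as.matrix(Z)
  n2 <- nrow(Zm)
  if (n2 %% 2L != 0L) stop("design must have an even number of rows (2n)")
  n <- n2 %/% 2L
  if (length(z) != n2) stop("data vector length must match design rows")
  p <- qr(Zm)$rank
  if (p < ncol(Zm)) stop("transformed design must be full rank")
  if (n2 <= p) stop("need more observations than coefficients")
  ctx <- .reml_context(Zm, n)
  fit <- .reml_fixed_point(z[seq_len(n)], z[n + seq_len(n)], ctx,
                           tol = tol, max_iter = max_iter)
  class(fit) <- "GeneHetFit"
  fit
}

# Precomputed pieces shared by every gene fitted on the same design.
.reml_context <- function(Zfull, n) {
  ZM <- Zfull[seq_len(n), , drop = FALSE]
  ZA <- Zfull[n + seq_len(n), , drop = FALSE]
  list(ZM = ZM, ZA = ZA,
       GM = crossprod(ZM), GA = crossprod(ZA),
       n = n, p = ncol(Zfull),
       rank_M = qr(ZM)$rank, rank_A = qr(ZA)$rank)
}

.reml_fixed_point <- function(zM, zA, ctx, tol = 1e-5, max_iter = 40L,
                              df_floor = 1e-2) {
  n <- ctx$n
  p <- ctx$p
  floor2 <- 1e-10 * max(mean(c(zM, zA)^2), .Machine$double.eps)
  bad <- function(reason) {
    list(sigma2_M = NA_real_, sigma2_A = NA_real_,
         d_M = NA_real_, d_A = NA_real_, n_iter = 0L,
         converged = FALSE, usable = FALSE, reason = reason)
  }
  # initialize both strata at the OLS residual mean square
  G0 <- ctx$GM + ctx$GA
  b0 <- tryCatch(solve(G0, crossprod(ctx$ZM, zM) + crossprod(ctx$ZA, zA)),
                 error = function(e) NULL)
  if (is.null(b0)) return(bad("singular design"))
  rss0 <- sum((zM - ctx$ZM %*% b0)^2) + sum((zA - ctx$ZA %*% b0)^2)
  s2 <- max(rss0 / (2 * n - p), floor2)
  sM2 <- sA2 <- s2
  converged <- FALSE
  clamped <- FALSE
  dM <- dA <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    aM <- 1 / sM2
    aA <- 1 / sA2
    Ainfo <- aM * ctx$GM + aA * ctx$GA
    V <- tryCatch(chol2inv(chol(Ainfo)), error = function(e) NULL)
    if (is.null(V)) return(bad("singular weighted information"))
    beta <- V %*% (aM * crossprod(ctx$ZM, zM) + aA * crossprod(ctx$ZA, zA))
    eM <- zM - ctx$ZM %*% beta
    eA <- zA - ctx$ZA %*% beta
    hM <- aM * rowSums((ctx$ZM %*% V) * ctx$ZM)
    hA <- aA * rowSums((ctx$ZA %*% V) * ctx$ZA)
    dM <- n - sum(hM)
    dA <- n - sum(hA)
    if (dM <= df_floor || dA <= df_floor) {
      return(bad("stratum degrees of freedom collapsed"))
    }
    sM2_new <- sum(eM^2) / dM
    sA2_new <- sum(eA^2) / dA
    if (sM2_new < floor2) { sM2_new <- floor2; clamped <- TRUE }
    if (sA2_new < floor2) { sA2_new <- floor2; clamped <- TRUE }
    delta <- max(abs(sM2_new - sM2) / sM2, abs(sA2_new - sA2) / sA2)
    sM2 <- sM2_new
    sA2 <- sA2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(sigma2_M = sM2, sigma2_A = sA2, d_M = dM, d_A = dA,
       n_iter = iter, converged = converged,
       usable = converged && !clamped, reason = if (clamped) "variance clamped" else NA_character_)
}

#' Two-stratum REML for every gene
#'
#' Runs \code{\link{reml_two_strata}} on each probe of an MA data set.
#' Per-gene failures (saturated strata, collapsed variances, non-convergence)
#' are flagged, never fatal, so downstream pooling can simply drop unusable
#' genes.
#'
#' @param ma an \code{MAData} object.
#' @param Z the matching \code{TransformedDesign}.
#' @param tol,max_iter passed to the per-gene fixed point.
#' @param verbose if TRUE, print a one-line summary of convergence counts.
#' @return A data frame of class \code{"GeneHetFitSet"} with one row per
#'   probe and columns \code{probe}, \code{sigma2_M}, \code{sigma2_A},
#'   \code{d_M}, \code{d_A}, \code{n_iter}, \code{converged}, \code{usable}.
#' @export
fit_all_genes <- function(ma, Z, tol = 1e-5, max_iter = 40L, verbose = FALSE) {
  stopifnot(inherits(ma, "MAData"), inherits(Z, "TransformedDesign"))
  n <- Z$n
  if (ncol(ma$M) != n) stop("number of arrays in data and design disagree")
  G <- nrow(ma$M)
  ctx <- .reml_context(Z$Z, n)
  out <- data.frame(probe = ma$probes,
                    sigma2_M = NA_real_, sigma2_A = NA_real_,
                    d_M = NA_real_, d_A = NA_real_, n_iter = 0L,
                    converged = FALSE, usable = FALSE,
                    stringsAsFactors = FALSE)
  for (g in seq_len(G)) {
    f <- .reml_fixed_point(ma$M[g, ], ma$A[g, ], ctx,
                           tol = tol, max_iter = max_iter)
    out$sigma2_M[g] <- f$sigma2_M
    out$sigma2_A[g] <- f$sigma2_A
    out$d_M[g] <- f$d_M
    out$d_A[g] <- f$d_A
    out$n_iter[g] <- f$n_iter
    out$converged[g] <- f$converged
    out$usable[g] <- f$usable
  }
  if (verbose)
    message(sprintf("REML: %d/%d genes converged, %d usable",
                    sum(out$converged), G, sum(out$usable)))
  class(out) <- c("GeneHetFitSet", class(out))
  out
}
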