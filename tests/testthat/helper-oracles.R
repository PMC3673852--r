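# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths.

# GLS on raw channel data with block correlation matrix: blocks [[1, rho],
# [rho, 1]] linking the green and red observation of each spot.
gls_channel_fit <- function(X, y, rho) {
  n <- nrow(X) / 2
  Cmat <- diag(2 * n)
  for (i in seq_len(n)) {
    Cmat[i, n + i] <- rho
    Cmat[n + i, i] <- rho
  }
  Ci <- solve(Cmat)
  A <- t(X) %*% Ci %*% X
  beta <- solve(A, t(X) %*% Ci %*% y)
  list(beta = drop(beta), cov = solve(A))
}

# Restricted log-likelihood of the two-stratum heteroscedastic model,
# evaluated at given stratum variances (beta profiled out by GLS).
reml_criterion <- function(zM, zA, ZM, ZA, sM2, sA2) {
  n <- length(zM)
  aM <- 1 / sM2
  aA <- 1 / sA2
  Ainfo <- aM * crossprod(ZM) + aA * crossprod(ZA)
  beta <- solve(Ainfo, aM * crossprod(ZM, zM) + aA * crossprod(ZA, zA))
  eM <- zM - ZM %*% beta
  eA <- zA - ZA %*% beta
  -0.5 * (n * log(sM2) + n * log(sA2)) -
    0.5 * determinant(Ainfo, logarithm = TRUE)$modulus -
    0.5 * (aM * sum(eM^2) + aA * sum(eA^2))
}

# Two-stage 2-D grid maximizer of the REML criterion on the log-variance
# scale; returns the maximizing (sigma2_M, sigma2_A).
reml_grid_oracle <- function(zM, zA, ZM, ZA, center, width = 3, steps = 41L,
                             refinements = 3L) {
  lM <- log(center[1])
  lA <- log(center[2])
  w <- width
  for (r in seq_len(refinements)) {
    gM <- seq(lM - w, lM + w, length.out = steps)
    gA <- seq(lA - w, lA + w, length.out = steps)
    val <- outer(gM, gA, Vectorize(function(a, b)
      reml_criterion(zM, zA, ZM, ZA, exp(a), exp(b))))
    idx <- which(val == max(val), arr.ind = TRUE)[1L, ]
    lM <- gM[idx[1L]]
    lA <- gA[idx[2L]]
    w <- 2 * w / (steps - 1)       # zoom around the best cell
  }
  c(sigma2_M = exp(lM), sigma2_A = exp(lA))
}

# O(m^2) step-up BH from the definition: q_(i) = min_{j >= i} m p_(j) / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(pmin(m * ps[i:m] / (i:m), 1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Digamma via recurrence to x > 10 plus the asymptotic series.
digamma_oracle <- function(x) {
  acc <- 0
  while (x < 10) {
    acc <- acc - 1 / x
    x <- x + 1
  }
  acc + log(x) - 1 / (2 * x) - 1 / (12 * x^2) + 1 / (120 * x^4) -
    1 / (252 * x^6) + 1 / (240 * x^8)
}

# Small simulated reference-design experiment reused by several files.
sim_reference <- function(G = 200, n = 8, rho = 0.85, seed = 1, ...) {
  simulate_two_channel(sim_config(G = G, layout = "reference", n = n,
                                  rho = rho, seed = seed, ...))
}

random_channel_design <- function(n, p) {
  repeat {
    X <- matrix(rnorm(2 * n * p), 2 * n, p)
    colnames(X) <- paste0("c", seq_len(p))
    if (qr(X)$rank == p) return(X)
  }
}
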