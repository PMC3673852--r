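#' Deterministic targets tables for standard two-colour layouts
#'
#' @param kind one of \code{"reference"} (every array pairs one treatment,
#'   red, against a shared reference, green), \code{"paired"} (the two
#'   conditions share every array), \code{"dye_swap_pairs"} (paired with
#'   alternating dye orientation), \code{"loop"} (conditions chained
#'   head-to-tail, one array per edge), \code{"unconnected"} (two islands:
#'   arrays 1..n/2 co-hybridize conditions 1 and 2, the rest conditions 3
#'   and 4).
#' @param n number of arrays.
#' @param conditions character vector of treatment condition labels;
#'   defaults per layout (\code{B, C} or \code{B, C, D, E}).
#' @param reference label of the reference sample for the reference layout.
#' @return A targets data frame with columns Array, Cy3, Cy5.
#' @export
make_layout <- function(kind = c("reference", "paired", "dye_swap_pairs",
                                 "loop", "unconnected"),
                        n, conditions = NULL, reference = "R") {
  kind <- match.arg(kind)
  arrays <- sprintf("A%02d", seq_len(n))
  tab <- switch(kind,
    reference = {
      if (is.null(conditions)) conditions <- c("B", "C")
      if (n %% length(conditions) != 0)
        stop("n must be a multiple of the number of conditions")
      data.frame(Array = arrays, Cy3 = reference,
                 Cy5 = rep(conditions, each = n / length(conditions)))
    },
    paired = {
      if (is.null(conditions)) conditions <- c("B", "C")
      if (length(conditions) != 2L) stop("paired layout needs exactly 2 conditions")
      data.frame(Array = arrays, Cy3 = conditions[1L], Cy5 = conditions[2L])
    },
    dye_swap_pairs = {
      if (is.null(conditions)) conditions <- c("B", "C")
      if (length(conditions) != 2L) stop("dye-swap layout needs exactly 2 conditions")
      if (n %% 2 != 0) stop("dye-swap layout needs an even n")
      swap <- seq_len(n) %% 2 == 0
      data.frame(Array = arrays,
                 Cy3 = ifelse(swap, conditions[2L], conditions[1L]),
                 Cy5 = ifelse(swap, conditions[1L], conditions[2L]))
    },
    loop = {
      if (is.null(conditions)) conditions <- LETTERS[1 + seq_len(n)]
      k <- length(conditions)
      if (n != k) stop("loop layout needs one array per condition (n = #conditions)")
      data.frame(Array = arrays, Cy3 = conditions,
                 Cy5 = conditions[c(seq_len(k)[-1L], 1L)])
    },
    unconnected = {
      if (is.null(conditions)) conditions <- c("B", "C", "D", "E")
      if (length(conditions) != 4L) stop("unconnected layout needs 4 conditions")
      if (n %% 2 != 0) stop("unconnected layout needs an even n")
      half <- n / 2
      data.frame(Array = arrays,
                 Cy3 = rep(conditions[c(1L, 3L)], c(half, half)),
                 Cy5 = rep(conditions[c(2L, 4L)], c(half, half)))
    })
  validate_targets(tab)
}

#' Simulation configuration
#'
#' Bundles the generative model for a synthetic two-channel experiment:
#' per-gene log2 intensities y_gic = x_ic' beta_g + b_gi + e_gic with spot
#' effects b_gi ~ N(0, rho sigma_g^2) and residuals
#' e_gic ~ N(0, (1 - rho) sigma_g^2); gene variances sigma_g^2 drawn from a
#' scaled inverse chi-square prior with hyperparameters (d0, s0_2); a
#' fraction prop_de of genes differentially expressed with log2 fold change
#' +/- lfc applied to one condition's coefficient.
#'
#' @param G number of genes.
#' @param layout a targets data frame, or a layout kind name for
#'   \code{\link{make_layout}}.
#' @param n number of arrays (used when \code{layout} is a kind name).
#' @param conditions condition labels for \code{\link{make_layout}}.
#' @param rho common intra-spot correlation, |rho| < 1.
#' @param d0,s0_2 variance-prior hyperparameters (d0 may be Inf).
#' @param prop_de fraction of differentially expressed genes in [0, 1].
#' @param lfc log2 fold-change magnitude for DE genes.
#' @param de_coef condition label receiving the DE offset; defaults to the
#'   first red-channel (treatment) condition of the layout.
#' @param baseline range of baseline mean log2 expression, drawn uniformly
#'   per gene (default c(6, 14), a typical microarray intensity range).
#' @param seed integer seed making the draw reproducible.
#' @return A list of class \code{"SimConfig"}.
#' @export
sim_config <- function(G = 1000L, layout = "reference", n = 8L,
                       conditions = NULL, rho = 0.85, d0 = 4, s0_2 = 0.25,
                       prop_de = 0, lfc = 1, de_coef = NULL,
                       baseline = c(6, 14), seed = NULL) {
  if (abs(rho) >= 1) stop("rho must lie strictly in (-1, 1)")
  if (prop_de < 0 || prop_de > 1) stop("prop_de must lie in [0, 1]")
  if (d0 <= 0) stop("d0 must be positive (or Inf)")
  if (s0_2 <= 0) stop("s0_2 must be positive")
  targets <- if (is.data.frame(layout)) validate_targets(layout)
             else make_layout(layout, n = n, conditions = conditions)
  if (is.null(de_coef)) de_coef <- targets$Cy5[1L]
  if (!(de_coef %in% c(targets$Cy3, targets$Cy5)))
    stop("de_coef must be a condition of the layout")
  structure(list(G = as.integer(G), targets = targets, rho = rho, d0 = d0,
                 s0_2 = s0_2, prop_de = prop_de, lfc = lfc,
                 de_coef = de_coef, baseline = baseline, seed = seed),
            class = "SimConfig")
}

#' Simulate a two-channel experiment under the mixed model
#'
#' Draws gene variances from the scaled inverse chi-square prior, assigns DE
#' genes a signed log-fold-change on the chosen coefficient, and generates
#' channel log2 intensities with the requested intra-spot correlation.  For
#' rho >= 0 the spot effect is generated explicitly as a variance component;
#' a negative rho has no variance-component representation, so in that case
#' the (M, A) pair is drawn directly from its implied bivariate normal and
#' mapped back to channels -- the two routes are distributionally identical
#' on the common support.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with \code{data} (a \code{\link{two_channel}} object),
#'   \code{targets}, \code{design} (the one-hot \code{ChannelDesign}) and
#'   \code{truth} (list: per-gene \code{sigma2}, coefficient matrix
#'   \code{beta}, logical \code{de}, signed \code{lfc}, plus the generating
#'   \code{rho}, \code{d0}, \code{s0_2}).
#' @export
simulate_two_channel <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  targets <- cfg$targets
  n <- nrow(targets)
  G <- cfg$G
  design <- build_channel_design(targets)
  X <- design$X
  p <- ncol(X)
  rho <- cfg$rho

  sigma2 <- if (is.finite(cfg$d0)) cfg$s0_2 * cfg$d0 / stats::rchisq(G, cfg$d0)
            else rep(cfg$s0_2, G)
  base <- stats::runif(G, cfg$baseline[1L], cfg$baseline[2L])
  beta <- matrix(base, G, p)
  colnames(beta) <- design$coefficients
  de <- rep(FALSE, G)
  lfc_signed <- numeric(G)
  n_de <- round(cfg$prop_de * G)
  if (n_de > 0L) {
    de[sample.int(G, n_de)] <- TRUE
    lfc_signed[de] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$lfc
    beta[, cfg$de_coef] <- beta[, cfg$de_coef] + lfc_signed
  }

  mu <- beta %*% t(X)                       # G x 2n, green cols then red
  sd_g <- sqrt(sigma2)
  if (rho >= 0) {
    b <- matrix(stats::rnorm(G * n), G, n) * (sqrt(rho) * sd_g)
    eps <- matrix(stats::rnorm(G * 2 * n), G, 2 * n) * (sqrt(1 - rho) * sd_g)
    y <- mu + cbind(b, b) + eps
    green <- y[, seq_len(n), drop = FALSE]
    red <- y[, n + seq_len(n), drop = FALSE]
  } else {
    muG <- mu[, seq_len(n), drop = FALSE]
    muR <- mu[, n + seq_len(n), drop = FALSE]
    M <- (muR - muG) + matrix(stats::rnorm(G * n), G, n) *
      (sqrt(2 * (1 - rho)) * sd_g)
    A <- (muR + muG) / 2 + matrix(stats::rnorm(G * n), G, n) *
      (sqrt((1 + rho) / 2) * sd_g)
    green <- A - M / 2
    red <- A + M / 2
  }
  probes <- sprintf("g%05d", seq_len(G))
  data <- two_channel(green, red, probes = probes, arrays = targets$Array)
  list(data = data, targets = targets, design = design,
       truth = list(sigma2 = sigma2, beta = beta, de = de,
                    lfc = lfc_signed, rho = rho, d0 = cfg$d0,
                    s0_2 = cfg$s0_2))
}
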