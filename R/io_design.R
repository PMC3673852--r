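#' Two-channel intensity container
#'
#' Bundles the green- and red-channel log2 intensity matrices of a two-colour
#' microarray experiment, aligned by probe and array identifiers.  All values
#' must be finite: the model assumes background-corrected, strictly positive
#' intensities, so missing or non-finite cells are a hard error rather than
#' something to impute.
#'
#' @param green,red numeric G x n matrices of log2 intensities (channel 1 =
#'   green, channel 2 = red).
#' @param probes character vector of G unique probe identifiers.
#' @param arrays character vector of n array identifiers.
#' @return An object of class \code{"TwoChannelMatrix"}: a list with
#'   components \code{probes}, \code{arrays}, \code{green}, \code{red}.
#' @export
two_channel <- function(green, red, probes = rownames(green),
                        arrays = colnames(green)) {
  green <- as.matrix(green)
  red <- as.matrix(red)
  if (!all(dim(green) == dim(red)))
    stop("green and red matrices must have identical dimensions")
  if (nrow(green) < 1L || ncol(green) < 2L)
    stop("need at least 1 probe and 2 arrays")
  if (is.null(probes)) probes <- as.character(seq_len(nrow(green)))
  if (is.null(arrays)) arrays <- as.character(seq_len(ncol(green)))
  probes <- as.character(probes)
  arrays <- as.character(arrays)
  if (length(probes) != nrow(green) || length(arrays) != ncol(green))
    stop("probe/array identifier lengths do not match matrix dimensions")
  if (anyDuplicated(probes))
    stop("probe identifiers must be unique")
  .check_finite(green, probes, arrays, "green")
  .check_finite(red, probes, arrays, "red")
  dimnames(green) <- dimnames(red) <- list(probes, arrays)
  structure(list(probes = probes, arrays = arrays, green = green, red = red),
            class = "TwoChannelMatrix")
}

.check_finite <- function(x, probes, arrays, channel) {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "non-finite %s intensity for probe '%s' on array '%s' (missing values are not allowed)",
      channel, probes[bad[1L, 1L]], arrays[bad[1L, 2L]]))
  invisible(TRUE)
}

#' @export
print.TwoChannelMatrix <- function(x, ...) {
  cat(sprintf("TwoChannelMatrix: %d probes x %d arrays\n",
              length(x$probes), length(x$arrays)))
  cat("arrays:", paste(utils::head(x$arrays, 8L), collapse = ", "),
      if (length(x$arrays) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Read two-channel intensities from tab-delimited files
#'
#' Each file holds one channel: a header row of array identifiers and a first
#' column of probe identifiers.  The two files are aligned by identifier, so
#' the column order may differ between them.
#'
#' @param path_green,path_red paths to the green- and red-channel TSV files.
#' @return A \code{\link{two_channel}} object.
#' @export
read_two_channel <- function(path_green, path_red) {
  g <- .read_channel_tsv(path_green)
  r <- .read_channel_tsv(path_red)
  if (nrow(g) != nrow(r) || ncol(g) != ncol(r))
    stop("green and red files have different dimensions")
  if (!setequal(rownames(g), rownames(r)) || !setequal(colnames(g), colnames(r)))
    stop("green and red files have different probe or array identifiers")
  r <- r[rownames(g), colnames(g), drop = FALSE]
  two_channel(g, r, probes = rownames(g), arrays = colnames(g))
}

.read_channel_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L) stop("expected a probe column plus at least 2 arrays in ", path)
  probes <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing value for probe '%s', array '%s' in %s",
                 probes[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path))
  rownames(num) <- probes
  num
}

#' Write a channel matrix in the TSV dialect read by read_two_channel
#' @param x numeric matrix with probe rownames and array colnames.
#' @param path output file path.
#' @export
write_channel <- function(x, path) {
  df <- data.frame(Probe = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a targets file
#'
#' The targets file has one row per array with columns \code{Array},
#' \code{Cy3} and \code{Cy5} giving the treatment condition hybridized to the
#' green (Cy3) and red (Cy5) channel of each array.
#'
#' @param path path to a TSV targets file.
#' @return A data frame with columns Array, Cy3, Cy5.
#' @export
read_targets <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  validate_targets(tab)
}

#' Validate a targets table
#' @param targets data frame with columns Array, Cy3, Cy5.
#' @return The validated data frame (invisibly identical to input).
#' @export
validate_targets <- function(targets) {
  need <- c("Array", "Cy3", "Cy5")
  if (!all(need %in% colnames(targets)))
    stop("targets must have columns ", paste(need, collapse = ", "))
  targets$Array <- as.character(targets$Array)
  if (anyDuplicated(targets$Array)) stop("duplicate array identifiers in targets")
  if (any(!nzchar(targets$Cy3)) || any(!nzchar(targets$Cy5)))
    stop("every condition label in targets must be non-empty")
  targets
}

#' Build the separate-channel design matrix
#'
#' Constructs the 2n x p design matrix whose rows correspond to the 2n channel
#' observations of an n-array experiment.  The row convention is fixed: rows
#' 1..n are the green channels of arrays 1..n and rows n+1..2n the red
#' channels, so that the M/A transformation matrices act as clean n-blocks.
#' Under the default parameterization each treatment condition gets one
#' indicator column (no intercept), so coefficients are population mean
#' log2 intensities per condition and comparisons are expressed as contrasts.
#'
#' @param targets targets data frame (see \code{\link{read_targets}}).
#' @param parameterization \code{"one_hot_conditions"} (default) or a
#'   user-supplied 2n x p numeric matrix following the same row convention.
#' @param dye_effect if TRUE, append an indicator column that is 0 for green
#'   rows and 1 for red rows, absorbing a common dye bias.
#' @return An object of class \code{"ChannelDesign"}: list with the design
#'   matrix \code{X} (2n x p), \code{coefficients} (column names),
#'   \code{arrays} and \code{n}.
#' @export
build_channel_design <- function(targets, parameterization = "one_hot_conditions",
                                 dye_effect = FALSE) {
  targets <- validate_targets(targets)
  n <- nrow(targets)
  if (is.matrix(parameterization)) {
    X <- parameterization
    if (nrow(X) != 2L * n) stop("custom design matrix must have 2n rows")
    if (is.null(colnames(X))) colnames(X) <- paste0("coef", seq_len(ncol(X)))
  } else if (identical(parameterization, "one_hot_conditions")) {
    # condition order: first appearance scanning each array's green then red
    conds <- unique(as.vector(rbind(targets$Cy3, targets$Cy5)))
    chan <- factor(c(targets$Cy3, targets$Cy5), levels = conds)
    X <- stats::model.matrix(~ 0 + chan)
    attr(X, "assign") <- NULL
    attr(X, "contrasts") <- NULL
    colnames(X) <- conds
  } else stop("unknown parameterization")
  if (isTRUE(dye_effect) || ("DyeEffect" %in% colnames(targets) &&
                             any(as.logical(targets$DyeEffect)))) {
    X <- cbind(X, Dye = rep(c(0, 1), each = n))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; aliased coefficients: ",
         paste(aliased, collapse = ", "))
  }
  rownames(X) <- c(paste0(targets$Array, ".G"), paste0(targets$Array, ".R"))
  structure(list(X = X, coefficients = colnames(X),
                 arrays = targets$Array, n = n,
                 row_convention = "green_then_red"),
            class = "ChannelDesign")
}

#' Build a contrast matrix from symbolic specifications
#'
#' Each contrast is given as a string \code{"name = expression"} where the
#' expression is a linear combination of design coefficient names, e.g.
#' \code{"BvsC = B - C"}.
#'
#' @param design a \code{ChannelDesign} (or anything with a
#'   \code{coefficients} character component).
#' @param spec character vector of contrast definitions.
#' @return p x k numeric matrix with one column per contrast, class
#'   \code{"ContrastMatrix"}.
#' @export
make_contrasts <- function(design, spec) {
  coefs <- design$coefficients
  p <- length(coefs)
  basis <- new.env(parent = baseenv())
  for (j in seq_len(p)) {
    v <- numeric(p)
    v[j] <- 1
    assign(coefs[j], v, envir = basis)
  }
  names_out <- character(0)
  cols <- list()
  for (s in spec) {
    parts <- strsplit(s, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("contrast spec must be 'name = expression': ", s)
    nm <- trimws(parts[1L])
    expr <- parse(text = parts[2L])[[1L]]
    used <- all.vars(expr)
    unknown <- setdiff(used, coefs)
    if (length(unknown) > 0L)
      stop("unknown coefficient name(s) in contrast '", nm, "': ",
           paste(unknown, collapse = ", "))
    col <- eval(expr, envir = basis)
    if (all(col == 0)) stop("contrast '", nm, "' is identically zero")
    if (nm %in% names_out) stop("duplicate contrast name: ", nm)
    names_out <- c(names_out, nm)
    cols[[nm]] <- col
  }
  C <- do.call(cbind, cols)
  rownames(C) <- coefs
  colnames(C) <- names_out
  class(C) <- c("ContrastMatrix", class(C))
  C
}
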