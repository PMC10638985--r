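#' Replace missing responses by zeros
#'
#' The zero-replacement policy treats a missing response like an incorrect
#' one: every NA becomes 0.  Marginal probabilities of a 1 are thereby
#' attenuated by the factor (1 - missing rate), which is the mechanism that
#' turns planned missingness into systematic variation of its own.
#'
#' @param data a [binary_dataset()].
#' @return a complete [binary_dataset()].
#' @export
replace_missing_with_zero <- function(data) {
  stopifnot(inherits(data, "mdcfa_binary"))
  v <- data$values
  v[is.na(v)] <- 0L
  binary_dataset(v, design = data$design, provenance = data$provenance)
}

#' Latent threshold from a marginal proportion
#'
#' The threshold tau for which P(V > tau) = p1 under the standard normal,
#' i.e. `qnorm(1 - p1)`.
#'
#' @param p1 marginal proportion of ones, strictly inside (0, 1).
#' @return the threshold (vectorized over `p1`).
#' @export
estimate_threshold <- function(p1) {
  if (any(p1 <= 0 | p1 >= 1))
    stop("degenerate margin: proportion of ones must be strictly in (0, 1)")
  qnorm(1 - p1)
}

#' Bivariate standard-normal rectangle probability
#'
#' P(X <= h, Y <= k) for correlation r, computed by a deterministic
#' Gauss-Legendre/Taylor series routine (absolute accuracy far below 1e-10).
#' Vectorized over its arguments.
#'
#' @param h,k upper limits.
#' @param r correlation(s) in (-1, 1).
#' @return vector of probabilities.
#' @export
pbvn <- function(h, k, r) {
  m <- max(length(h), length(k), length(r))
  pbvn_cpp(rep_len(as.double(h), m), rep_len(as.double(k), m),
           rep_len(as.double(r), m))
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum likelihood: thresholds are fixed at the normal quantiles
#' of the table margins, then the multinomial likelihood of the four cells
#' under the bivariate-normal model is maximized over the correlation.
#' Tables containing a zero cell receive a continuity correction
#' (`correct` added to every cell) before estimation, and the estimate is
#' box-constrained to `[-bound, bound]`.
#'
#' @param table 2x2 matrix of counts, rows = first item (1, 0), columns =
#'   second item (1, 0): `table[1,1]` counts (1,1) pairs.
#' @param correct continuity-correction constant for zero cells.
#' @param bound absolute bound on the estimate.
#' @return a list with `rho` and a `diagnostics` list (`corrected`,
#'   `degenerate`, cell counts).
#' @export
tetrachoric_pair <- function(table, correct = 0.5, bound = 0.999) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (sum(table) <= 0) stop("table must have a positive total count")
  res <- tetra_from_counts_cpp(table[1, 1], table[1, 2], table[2, 1],
                               table[2, 2], correct, bound)
  if (res$degenerate[1])
    stop("degenerate margin: a marginal count is zero")
  list(rho = res$rho[1],
       diagnostics = list(corrected = res$corrected[1],
                          degenerate = FALSE, counts = table))
}

#' Tetrachoric correlation matrix of a binary dataset
#'
#' Computes all p(p-1)/2 pairwise tetrachoric correlations.  Under the
#' default `"zero_replacement"` policy missing responses are first replaced
#' by zeros, so incomplete data yield a complete matrix whose distortions
#' carry the missing-data signal.  Items with degenerate margins (all 0 or
#' all 1) abort with an error naming the item.
#'
#' @param data a [binary_dataset()].
#' @param policy missing-data policy; only `"zero_replacement"` is
#'   implemented (`"pairwise"` is reserved).
#' @param correct,bound passed to the pairwise estimator, see
#'   [tetrachoric_pair()].
#' @return an object of class `mdcfa_corr`: list with `matrix` (p x p,
#'   unit diagonal), `thresholds`, `pd` flag, `ridge_applied` (0 until
#'   [ensure_pd()] smooths), and `pair_diagnostics`.
#' @export
tetrachoric_matrix <- function(data, policy = "zero_replacement",
                               correct = 0.5, bound = 0.999) {
  stopifnot(inherits(data, "mdcfa_binary"))
  policy <- match.arg(policy, c("zero_replacement", "pairwise"))
  if (policy == "pairwise")
    stop("pairwise-deletion policy is reserved but not implemented")
  data <- replace_missing_with_zero(data)
  X <- data$values
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop("need at least 2 items")
  p1 <- colMeans(X)
  bad <- which(p1 <= 0 | p1 >= 1)
  if (length(bad))
    stop("degenerate margin in item(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  tau <- estimate_threshold(p1)
  # all pairwise 2x2 tables at once via cross-products; pairs run in
  # column-major lower-triangle (vech) order throughout the package
  N11 <- crossprod(X)
  n1 <- diag(N11)
  il <- which(lower.tri(N11), arr.ind = TRUE)
  a <- N11[il]
  b <- n1[il[, 1]] - a           # item i = 1, item j = 0
  cc <- n1[il[, 2]] - a          # item i = 0, item j = 1
  d <- n - a - b - cc
  res <- tetra_from_counts_cpp(a, b, cc, d, correct, bound)
  R <- diag(p)
  R[lower.tri(R)] <- res$rho
  R <- R + t(R) - diag(p)
  dimnames(R) <- list(colnames(X), colnames(X))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(list(matrix = R, thresholds = stats::setNames(tau, colnames(X)),
                 pd = min(ev) > 0, ridge_applied = 0,
                 pair_diagnostics = list(corrected = sum(res$corrected),
                                         n_pairs = length(a),
                                         min_eigenvalue = min(ev))),
            class = "mdcfa_corr")
}

#' @export
print.mdcfa_corr <- function(x, ...) {
  p <- ncol(x$matrix)
  cat(sprintf(
    "Tetrachoric correlation input: %d items, mean off-diagonal %.4f\n",
    p, mean(x$matrix[upper.tri(x$matrix)])))
  cat(sprintf("  positive definite: %s (min eigenvalue %.2e, ridge %.3g)\n",
              x$pd, x$pair_diagnostics$min_eigenvalue, x$ridge_applied))
  invisible(x)
}

#' Positive-definiteness smoothing (ridge option)
#'
#' If the smallest eigenvalue of the matrix is below `floor`, a uniform
#' ridge is added to the diagonal and the matrix is rescaled back to unit
#' diagonal, mirroring the automatic ridge option of SEM software for
#' non-positive-definite tetrachoric input.  Applying it to an already
#' acceptable matrix changes nothing.
#'
#' @param x a correlation matrix or `mdcfa_corr` object.
#' @param floor required smallest eigenvalue.
#' @return same type as the input, with `ridge_applied` recorded (for plain
#'   matrices, as an attribute).
#' @export
ensure_pd <- function(x, floor = 1e-6) {
  obj <- NULL
  if (inherits(x, "mdcfa_corr")) { obj <- x; x <- x$matrix }
  stopifnot(isSymmetric(unname(x), tol = 1e-8))
  ev_min <- min(eigen(x, symmetric = TRUE, only.values = TRUE)$values)
  ridge <- 0
  if (ev_min < floor) {
    # after adding c to the diagonal and rescaling by 1/(1+c), the smallest
    # eigenvalue becomes (ev_min + c)/(1 + c) >= floor
    ridge <- (floor - ev_min) / (1 - floor)
    x <- (x + ridge * diag(ncol(x))) / (1 + ridge)
  }
  if (!is.null(obj)) {
    obj$matrix <- x
    obj$ridge_applied <- obj$ridge_applied + ridge
    obj$pd <- TRUE
    return(obj)
  }
  attr(x, "ridge_applied") <- ridge
  x
}

#' Probability-based covariance matrix of binary items
#'
#' cov(X_i, X_j) = P(X_i = 1 and X_j = 1) - P(X_i = 1) P(X_j = 1), with
#' missing entries counting as non-1 responses (they simply lower the
#' probabilities, which is how missingness enters this coefficient).
#'
#' @param data a [binary_dataset()].
#' @return a p x p covariance matrix with diagonal p1 * (1 - p1).
#' @export
probability_based_covariance <- function(data) {
  stopifnot(inherits(data, "mdcfa_binary"))
  X <- replace_missing_with_zero(data)$values
  n <- nrow(X)
  P11 <- crossprod(X) / n
  p1 <- diag(P11)
  V <- P11 - tcrossprod(p1)
  diag(V) <- p1 * (1 - p1)
  V
}

#' Write / read correlation input
#'
#' `write_corr_csv` writes the square matrix as CSV plus a thresholds
#' sidecar (`<path base>_thresholds.csv`); `write_corr_lower` writes the
#' lower triangle (including diagonal) as whitespace-separated text, one
#' matrix row per line.  `read_corr` reads either format back into a plain
#' symmetric matrix.
#'
#' @param x an `mdcfa_corr` object or plain correlation matrix.
#' @param path file path.
#' @export
write_corr_csv <- function(x, path) {
  m <- if (inherits(x, "mdcfa_corr")) x$matrix else x
  write.csv(as.data.frame(m), path, row.names = FALSE)
  if (inherits(x, "mdcfa_corr")) {
    side <- sub("([.][^.]+)?$", "_thresholds.csv", path)
    write.csv(data.frame(item = names(x$thresholds),
                         threshold = unname(x$thresholds)),
              side, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_corr_csv
#' @export
write_corr_lower <- function(x, path) {
  m <- if (inherits(x, "mdcfa_corr")) x$matrix else x
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(m[i, 1:i], digits = 8, format = "f"),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_corr_csv
#' @export
read_corr <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    m <- as.matrix(read.csv(path, check.names = FALSE))
  } else {
    rows <- strsplit(trimws(readLines(path)), "[[:space:]]+")
    rows <- rows[lengths(rows) > 0]
    p <- length(rows)
    m <- matrix(0, p, p)
    for (i in seq_len(p)) m[i, 1:i] <- as.numeric(rows[[i]])
    m <- m + t(m) - diag(diag(m))
  }
  dimnames(m) <- NULL
  m
}
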