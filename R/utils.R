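#' @useDynLib mdcfa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm pnorm rnorm optim cov quantile sd
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Derive a child seed from a master seed
#'
#' Counter-based derivation so that every replication, design cell and
#' bootstrap stream gets an independently reproducible seed from one master
#' seed.  A linear-congruential step (Park-Miller modulus) keeps all derived
#' seeds inside the 32-bit integer range R requires.
#'
#' @param master integer master seed.
#' @param ... further integer indices (stream, replication, ...) mixed in
#'   one after the other.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1 (prime)
  s <- as.double(master %% m)
  for (ix in c(...)) {
    s <- (s * 48271 + as.double(ix) * 16807 + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Half-vectorization (column-major lower triangle including diagonal).
vech <- function(x) x[lower.tri(x, diag = TRUE)]

# Indices of vech entries: returns 2-column matrix (row, col) per vech slot.
vech_index <- function(p) {
  ix <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  ix[order(ix[, "col"], ix[, "row"]), , drop = FALSE]
}

# Duplication matrix D_p: vec(X) = D %*% vech(X) for symmetric X.
duplication_matrix <- function(p) {
  ix <- vech_index(p)
  m <- nrow(ix)
  D <- matrix(0, p * p, m)
  for (j in seq_len(m)) {
    r <- ix[j, 1]; c <- ix[j, 2]
    D[(c - 1) * p + r, j] <- 1
    D[(r - 1) * p + c, j] <- 1
  }
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a
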