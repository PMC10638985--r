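#' One-factor (congeneric) model specification
#'
#' The customary CFA measurement model x = lambda * xi + delta.  In
#' `"fixed"` mode every loading is fixed to 1 and the factor variance is
#' free (t = p + 1 parameters); in `"free"` mode all loadings are free and
#' the factor variance is fixed to 1 (t = 2p).  Uniquenesses are always
#' free.
#'
#' @param p number of manifest variables (>= 3 for identification).
#' @param loadings_mode `"fixed"` or `"free"`.
#' @return an object of class `mdcfa_model`.
#' @examples
#' count_df(build_one_factor(20, "fixed"))  # 189
#' count_df(build_one_factor(20, "free"))   # 170
#' @export
build_one_factor <- function(p, loadings_mode = c("fixed", "free")) {
  loadings_mode <- match.arg(loadings_mode)
  if (p < 3) stop("under-identified: need at least 3 manifest variables")
  if (loadings_mode == "fixed") {
    lambda_a <- rep(1, p); phi_a <- NA_real_
  } else {
    lambda_a <- rep(NA_real_, p); phi_a <- 1
  }
  new_model_spec(p, lambda_a, phi_a, NULL, NULL, loadings_mode, integer(0))
}

#' Two-factor missing-data model specification
#'
#' The bifactor-type model x = lambda_a * xi_attribute +
#' lambda_m * xi_missing + delta, with orthogonal factors.  The missing
#' data latent variable loads only on the design columns.  In `"fixed"`
#' mode both loading vectors are fixed (attribute loadings 1 everywhere,
#' missing loadings 1 on design columns, 0 elsewhere) and both factor
#' variances are free.  In `"free"` mode the loadings are free and both
#' variances are fixed to 1; if every column is a design column, the first
#' missing loading is fixed to 0 to retain the bifactor identification
#' condition.
#'
#' @param p number of manifest variables.
#' @param missing_columns 1-based indices of columns carrying missing data.
#' @param loadings_mode `"fixed"` or `"free"`.
#' @return an object of class `mdcfa_model`.
#' @examples
#' count_df(build_missing_data_model(20, 11:20, "fixed"))  # 188
#' count_df(build_missing_data_model(20, 11:20, "free"))   # 160
#' @export
build_missing_data_model <- function(p, missing_columns,
                                     loadings_mode = c("fixed", "free")) {
  loadings_mode <- match.arg(loadings_mode)
  missing_columns <- as.integer(sort(unique(missing_columns)))
  if (p < 3) stop("under-identified: need at least 3 manifest variables")
  if (length(missing_columns) == 0)
    stop("'missing_columns' must be nonempty")
  if (max(missing_columns) > p) stop("design columns exceed p")
  lambda_m <- rep(0, p)
  if (loadings_mode == "fixed") {
    lambda_a <- rep(1, p); phi_a <- NA_real_
    lambda_m[missing_columns] <- 1
    phi_m <- NA_real_
  } else {
    lambda_a <- rep(NA_real_, p); phi_a <- 1
    lambda_m[missing_columns] <- NA_real_
    if (length(missing_columns) == p) {
      # bifactor condition: at least one variable on a single factor
      lambda_m[missing_columns[1]] <- 0
    }
    phi_m <- 1
  }
  new_model_spec(p, lambda_a, phi_a, lambda_m, phi_m, loadings_mode,
                 missing_columns)
}

new_model_spec <- function(p, lambda_a, phi_a, lambda_m, phi_m,
                           loadings_mode, missing_columns) {
  spec <- structure(
    list(p = as.integer(p), lambda_a = lambda_a, phi_a = phi_a,
         lambda_m = lambda_m, phi_m = phi_m, loadings_mode = loadings_mode,
         missing_columns = missing_columns),
    class = "mdcfa_model")
  if (count_df(spec) < 0) stop("negative degrees of freedom")
  spec
}

# Names of free parameters, in packing order: free attribute loadings,
# free missing loadings, phi_attribute, phi_missing, p uniquenesses.
free_names <- function(spec) {
  nm <- character(0)
  fa <- which(is.na(spec$lambda_a))
  if (length(fa)) nm <- c(nm, sprintf("lambda_a%02d", fa))
  if (!is.null(spec$lambda_m)) {
    fm <- which(is.na(spec$lambda_m))
    if (length(fm)) nm <- c(nm, sprintf("lambda_m%02d", fm))
  }
  if (is.na(spec$phi_a)) nm <- c(nm, "phi_attribute")
  if (!is.null(spec$phi_m) && is.na(spec$phi_m)) nm <- c(nm, "phi_missing")
  c(nm, sprintf("psi%02d", seq_len(spec$p)))
}

#' Number of free parameters of a model specification
#' @param spec an `mdcfa_model`.
#' @return integer t.
#' @export
n_free <- function(spec) length(free_names(spec))

#' Model degrees of freedom
#'
#' p(p+1)/2 distinct moments minus the number t of free parameters.
#'
#' @param spec an `mdcfa_model`.
#' @param p optional, defaults to the spec's p (kept as an argument for
#'   symmetry with the moment-counting rule).
#' @return integer df.
#' @export
count_df <- function(spec, p = spec$p) {
  as.integer(p * (p + 1) / 2 - n_free(spec))
}

#' @export
print.mdcfa_model <- function(x, ...) {
  kind <- if (is.null(x$lambda_m)) "one-factor" else "two-factor missing-data"
  cat(sprintf("%s model, %s loadings: p = %d, t = %d, df = %d\n",
              kind, x$loadings_mode, x$p, n_free(x), count_df(x)))
  invisible(x)
}

# Unpack a theta vector into full lambda/phi/psi structures.
unpack_theta <- function(spec, theta) {
  p <- spec$p
  i <- 0
  take <- function(k) { out <- theta[i + seq_len(k)]; i <<- i + k; out }
  lambda_a <- spec$lambda_a
  fa <- which(is.na(lambda_a))
  lambda_a[fa] <- take(length(fa))
  lambda_m <- spec$lambda_m
  fm <- integer(0)
  if (!is.null(lambda_m)) {
    fm <- which(is.na(lambda_m))
    lambda_m[fm] <- take(length(fm))
  }
  phi_a <- if (is.na(spec$phi_a)) take(1) else spec$phi_a
  phi_m <- spec$phi_m
  if (!is.null(phi_m) && is.na(phi_m)) phi_m <- take(1)
  psi <- take(p)
  list(lambda_a = lambda_a, lambda_m = lambda_m, phi_a = phi_a,
       phi_m = phi_m, psi = psi, free_a = fa, free_m = fm)
}

#' Model-implied covariance matrix
#'
#' Sigma(theta) = Lambda Phi Lambda' + Psi with orthogonal factors:
#' phi_a * lambda_a lambda_a' + phi_m * lambda_m lambda_m' + diag(psi).
#'
#' @param spec an `mdcfa_model`.
#' @param theta numeric vector of free parameters in packing order (free
#'   attribute loadings, free missing loadings, free factor variances,
#'   uniquenesses); see `free_names` via [n_free()].
#' @return the p x p symmetric implied matrix.
#' @export
implied_sigma <- function(spec, theta) {
  stopifnot(length(theta) == n_free(spec))
  u <- unpack_theta(spec, theta)
  S <- u$phi_a * tcrossprod(u$lambda_a)
  if (!is.null(u$lambda_m)) S <- S + u$phi_m * tcrossprod(u$lambda_m)
  S + diag(u$psi, spec$p)
}

# ML discrepancy and analytic gradient; returns +Inf outside the PD region.
ml_objective <- function(spec, S, ldS) {
  p <- spec$p
  function(theta) {
    Sig <- implied_sigma(spec, theta)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    ld + sum(Sinv * S) - ldS - p
  }
}

ml_gradient <- function(spec, S) {
  function(theta) {
    u <- unpack_theta(spec, theta)
    Sig <- implied_sigma(spec, theta)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    Sinv <- chol2inv(ch)
    Omega <- Sinv - Sinv %*% S %*% Sinv  # dF/dSigma (up to symmetry)
    g <- numeric(0)
    if (length(u$free_a))
      g <- c(g, 2 * u$phi_a * (Omega %*% u$lambda_a)[u$free_a])
    if (length(u$free_m))
      g <- c(g, 2 * u$phi_m * (Omega %*% u$lambda_m)[u$free_m])
    if (is.na(spec$phi_a))
      g <- c(g, drop(crossprod(u$lambda_a, Omega %*% u$lambda_a)))
    if (!is.null(spec$phi_m) && is.na(spec$phi_m))
      g <- c(g, drop(crossprod(u$lambda_m, Omega %*% u$lambda_m)))
    c(g, diag(Omega))
  }
}

# Starting values: fixed models start the factor variance at the mean
# off-diagonal of S; free models start loadings at sqrt of that mean.
start_values <- function(spec, S) {
  p <- spec$p
  rbar <- max(mean(S[upper.tri(S)]), 0.01)
  th <- numeric(0)
  if (any(is.na(spec$lambda_a)))
    th <- c(th, rep(sqrt(rbar), sum(is.na(spec$lambda_a))))
  if (!is.null(spec$lambda_m) && any(is.na(spec$lambda_m)))
    th <- c(th, rep(sqrt(rbar) / 2, sum(is.na(spec$lambda_m))))
  if (is.na(spec$phi_a)) th <- c(th, rbar)
  if (!is.null(spec$phi_m) && is.na(spec$phi_m)) th <- c(th, rbar / 4)
  c(th, pmax(mean(diag(S)) - rbar, 0.1) * rep(1, p))
}

theta_bounds <- function(spec) {
  nm <- free_names(spec)
  lower <- ifelse(grepl("^psi", nm), 1e-6,
                  ifelse(grepl("^phi", nm), 0, -10))
  upper <- ifelse(grepl("^lambda", nm), 10, 50)
  list(lower = lower, upper = upper, names = nm)
}

#' Fit a CFA model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' F(theta) = log det Sigma + tr(S Sigma^-1) - log det S - p
#' with an analytic-gradient quasi-Newton optimizer (L-BFGS-B; uniquenesses
#' bounded below at 1e-6, factor variances at 0).  On failure up to five
#' jittered restarts are attempted.  The correlation matrix is analyzed as
#' if it were a covariance matrix, following common SEM practice for
#' tetrachoric input.
#'
#' @param S a p x p positive-definite input matrix ([tetrachoric_matrix()]
#'   output, plain matrix, or [ensure_pd()] result).
#' @param spec an `mdcfa_model`.
#' @param N sample size; the chi-square uses the (N - 1) multiplier.
#' @param n_starts maximum number of jittered restarts after a failed fit.
#' @return an object of class `mdcfa_fit`: parameter estimates
#'   (`theta_hat`), `F_min`, `chisq_raw = (N-1) F_min`, `df`, convergence
#'   diagnostics (`converged`, `n_iter`, `gradient_norm`, `heywood`), the
#'   implied matrix `Sigma_hat`, and the inputs (`S`, `N`, `spec`).
#' @export
fit_ml <- function(S, spec, N, n_starts = 5) {
  if (inherits(S, "mdcfa_corr")) S <- S$matrix
  stopifnot(is.matrix(S), nrow(S) == spec$p, N > n_free(spec))
  chS <- tryCatch(chol(S), error = function(e)
    stop("input matrix is not positive definite; apply ensure_pd() first"))
  ldS <- 2 * sum(log(diag(chS)))
  fn <- ml_objective(spec, S, ldS)
  gr <- ml_gradient(spec, S)
  bd <- theta_bounds(spec)
  th0 <- start_values(spec, S)

  best <- NULL
  for (attempt in 0:n_starts) {
    th <- th0
    if (attempt > 0) {
      set.seed(1000 + attempt)
      th <- th0 * exp(rnorm(length(th0), 0, 0.2)) +
        rnorm(length(th0), 0, 0.02)
      th <- pmin(pmax(th, bd$lower), bd$upper)
    }
    opt <- tryCatch(
      optim(th, fn, gr, method = "L-BFGS-B", lower = bd$lower,
            upper = bd$upper,
            control = list(maxit = 500, factr = 1e4, pgtol = 1e-9)),
      error = function(e) NULL)
    if (is.null(opt)) next
    g <- gr(opt$par)
    # projected gradient: components pushing into an active bound are free
    at_lo <- opt$par <= bd$lower + 1e-10
    at_hi <- opt$par >= bd$upper - 1e-10
    g_proj <- g
    g_proj[at_lo & g > 0] <- 0
    g_proj[at_hi & g < 0] <- 0
    ok <- max(abs(g_proj)) < 1e-5 && opt$value < 1e9
    cand <- list(opt = opt, gnorm = max(abs(g_proj)), ok = ok)
    if (is.null(best) || opt$value < best$opt$value) best <- cand
    if (ok && attempt == 0) break
    if (ok && opt$value <= best$opt$value + 1e-10) { best <- cand; break }
  }
  if (is.null(best)) stop("optimization failed on all starts")
  opt <- best$opt
  theta <- stats::setNames(opt$par, bd$names)
  psi_ix <- grepl("^psi", bd$names)
  heywood <- which(psi_ix & opt$par <= 1e-6 + 1e-12)
  structure(list(
    theta_hat = theta,
    F_min = max(opt$value, 0),
    chisq_raw = max((N - 1) * opt$value, 0),
    df = count_df(spec),
    converged = best$ok,
    n_iter = opt$counts[["function"]],
    gradient_norm = best$gnorm,
    heywood = bd$names[heywood],
    Sigma_hat = implied_sigma(spec, opt$par),
    S = S, N = N, spec = spec), class = "mdcfa_fit")
}

#' @export
print.mdcfa_fit <- function(x, ...) {
  cat(sprintf(
    "CFA fit: F = %.6f, chi-square(raw) = %.2f, df = %d, converged: %s\n",
    x$F_min, x$chisq_raw, x$df, x$converged))
  if (length(x$heywood))
    cat("  Heywood-bounded uniquenesses:",
        paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

# Analytic Jacobian d vech(Sigma) / d theta' at theta (columns follow the
# packing order).  Used by the Satorra-Bentler scaling.
sigma_jacobian <- function(spec, theta) {
  p <- spec$p
  u <- unpack_theta(spec, theta)
  ix <- vech_index(p)
  m <- nrow(ix)
  cols <- list()
  vech_of <- function(M) M[cbind(ix[, 1], ix[, 2])]
  for (j in u$free_a) {
    dS <- matrix(0, p, p)
    dS[j, ] <- u$phi_a * u$lambda_a
    dS[, j] <- dS[, j] + u$phi_a * u$lambda_a
    cols[[length(cols) + 1]] <- vech_of(dS)
  }
  for (j in u$free_m) {
    dS <- matrix(0, p, p)
    dS[j, ] <- u$phi_m * u$lambda_m
    dS[, j] <- dS[, j] + u$phi_m * u$lambda_m
    cols[[length(cols) + 1]] <- vech_of(dS)
  }
  if (is.na(spec$phi_a))
    cols[[length(cols) + 1]] <- vech_of(tcrossprod(u$lambda_a))
  if (!is.null(spec$phi_m) && is.na(spec$phi_m))
    cols[[length(cols) + 1]] <- vech_of(tcrossprod(u$lambda_m))
  for (j in seq_len(p)) {
    dS <- matrix(0, p, p)
    dS[j, j] <- 1
    cols[[length(cols) + 1]] <- vech_of(dS)
  }
  matrix(unlist(cols), nrow = m)
}

#' Serialize a model specification to / from YAML
#'
#' Pattern vectors use the string `"free"` for free parameters and numbers
#' for fixed values.
#'
#' @param spec an `mdcfa_model`.
#' @param path file path.
#' @export
spec_to_yaml <- function(spec, path) {
  enc <- function(v) if (is.null(v)) NULL else
    lapply(seq_along(v), function(i) if (is.na(v[i])) "free" else v[i])
  yaml::write_yaml(list(p = spec$p, loadings_mode = spec$loadings_mode,
                        missing_columns = spec$missing_columns,
                        lambda_attribute = enc(spec$lambda_a),
                        lambda_missing = enc(spec$lambda_m),
                        phi_attribute = enc(spec$phi_a)[[1]],
                        phi_missing = if (is.null(spec$phi_m)) NULL else
                          enc(spec$phi_m)[[1]]),
                   path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  dec <- function(v) if (is.null(v)) NULL else
    vapply(v, function(e) if (identical(e, "free")) NA_real_
           else as.numeric(e), 0, USE.NAMES = FALSE)
  new_model_spec(y$p, dec(y$lambda_attribute), dec(list(y$phi_attribute)),
                 dec(y$lambda_missing),
                 if (is.null(y$phi_missing)) NULL else
                   dec(list(y$phi_missing)),
                 y$loadings_mode, as.integer(y$missing_columns %||%
                                               integer(0)))
}

#' Serialize a fit result to JSON
#' @param fit an `mdcfa_fit` or `mdcfa_scaled_fit`.
#' @param path file path.
#' @export
fit_to_json <- function(fit, path) {
  keep <- setdiff(names(fit), c("S", "Sigma_hat", "spec", "fit"))
  jsonlite::write_json(fit[keep], path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
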