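# internal: off-diagonal tetrachoric vector of a complete 0/1 matrix, in
# column-major lower-triangle order (matches vech of the off-diag moments).
tetra_offdiag <- function(X, correct = 0.5, bound = 0.999) {
  n <- nrow(X)
  N11 <- crossprod(X)
  n1 <- diag(N11)
  il <- which(lower.tri(N11), arr.ind = TRUE)
  a <- N11[il]
  b <- n1[il[, 1]] - a
  cc <- n1[il[, 2]] - a
  d <- n - a - b - cc
  tetra_from_counts_cpp(a, b, cc, d, correct, bound)$rho
}

#' Bootstrap estimate of the asymptotic covariance of the correlations
#'
#' Respondent-level nonparametric bootstrap of the full tetrachoric
#' pipeline (zero replacement included): rows of the binary data are
#' resampled with replacement, the complete tetrachoric matrix is
#' recomputed for every resample, and Gamma is (N - 1) times the bootstrap
#' covariance of the p(p-1)/2 unique correlations.  Resamples with a
#' degenerate margin (an all-0 or all-1 column) are redrawn and counted.
#'
#' @param data a [binary_dataset()] (may contain NAs; the zero-replacement
#'   policy is applied, exactly as in the estimation pipeline).
#' @param B number of bootstrap resamples (>= 50).
#' @param seed integer seed for the resampling.
#' @param correct,bound tetrachoric estimation settings, see
#'   [tetrachoric_pair()].
#' @return a p* x p* matrix (p* = p(p-1)/2) with attributes `B`, `n`,
#'   `redrawn` (number of redrawn degenerate resamples) and `method`.
#' @export
estimate_gamma <- function(data, B = 200, seed = 1L, correct = 0.5,
                           bound = 0.999) {
  stopifnot(inherits(data, "mdcfa_binary"), B >= 50)
  X <- replace_missing_with_zero(data)$values
  n <- nrow(X)
  pstar <- ncol(X) * (ncol(X) - 1) / 2
  set.seed(seed)
  draws <- matrix(NA_real_, B, pstar)
  redrawn <- 0L
  for (b in seq_len(B)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      m <- colMeans(Xb)
      if (all(m > 0 & m < 1)) break
      redrawn <- redrawn + 1L
      if (try == 100) stop("degenerate bootstrap margins in every redraw")
    }
    draws[b, ] <- tetra_offdiag(Xb, correct, bound)
  }
  G <- (n - 1) * cov(draws)
  attr(G, "B") <- B
  attr(G, "n") <- n
  attr(G, "redrawn") <- redrawn
  attr(G, "method") <- "respondent bootstrap"
  G
}

#' Normal-theory asymptotic covariance of correlations
#'
#' The covariance of the unique correlations implied by multivariate
#' normality at a given correlation matrix (the classic Pearson/ Girshick
#' expression), on the same (N - 1) scale as [estimate_gamma()].  Used for
#' checking that the Satorra-Bentler correction vanishes under normal
#' theory and available as a reference Gamma.
#'
#' @param R correlation matrix.
#' @return p* x p* covariance matrix in the same element order as
#'   [estimate_gamma()].
#' @export
normal_theory_gamma <- function(R) {
  p <- ncol(R)
  il <- which(lower.tri(R), arr.ind = TRUE)
  m <- nrow(il)
  G <- matrix(0, m, m)
  for (u in seq_len(m)) {
    i <- il[u, 1]; j <- il[u, 2]
    for (v in u:m) {
      k <- il[v, 1]; l <- il[v, 2]
      rij <- R[i, j]; rkl <- R[k, l]
      rik <- R[i, k]; ril <- R[i, l]; rjk <- R[j, k]; rjl <- R[j, l]
      cv <- 0.5 * rij * rkl * (rik^2 + ril^2 + rjk^2 + rjl^2) +
        rik * rjl + ril * rjk -
        rij * (rjk * rjl + rik * ril) -
        rkl * (rjk * rik + rjl * ril)
      G[u, v] <- G[v, u] <- cv
    }
  }
  G
}

# Embed a p* x p* off-diagonal Gamma into the full vech space (zero rows
# and columns for the diagonal moments, whose sampling variance is zero
# for correlation input).
embed_gamma <- function(gamma_off, p) {
  ix <- vech_index(p)
  off <- which(ix[, 1] != ix[, 2])
  # vech off-diagonal order equals column-major upper-triangle order
  G <- matrix(0, nrow(ix), nrow(ix))
  G[off, off] <- gamma_off
  G
}

# Normal-theory ML weight matrix on the vech scale at Sigma:
# W = 0.5 D' (Sigma^-1 kron Sigma^-1) D.
ml_weight <- function(Sigma) {
  p <- ncol(Sigma)
  Sinv <- solve(Sigma)
  D <- duplication_matrix(p)
  0.5 * crossprod(D, kronecker(Sinv, Sinv) %*% D)
}

# Residual-weight matrix U = W - W Delta (Delta' W Delta)^-1 Delta' W and
# the scaling factor tr(U Gamma) / df.
sb_factor <- function(Sigma_hat, Delta, gamma_full, df) {
  W <- ml_weight(Sigma_hat)
  WD <- W %*% Delta
  U <- W - WD %*% solve(crossprod(Delta, WD), t(WD))
  sum(U * t(gamma_full)) / df
}

#' Satorra-Bentler scaling of a fitted model
#'
#' Computes the scaling factor c = tr(U Gamma) / df, where U is the
#' standard residual-weight matrix of the ML discrepancy evaluated at the
#' parameter estimates, and divides the raw chi-square by it.  The
#' independence-baseline chi-square is computed from the same input matrix,
#' scaled by its own factor, and all fit indices are attached.
#'
#' @param fit an `mdcfa_fit` from [fit_ml()].
#' @param gamma asymptotic covariance of the unique correlations from
#'   [estimate_gamma()] (or [normal_theory_gamma()]).
#' @param spec the model specification; defaults to the one stored in
#'   `fit`.
#' @param baseline which baseline chi-square enters NNFI/CFI: `"raw"`
#'   (normal-theory baseline, the convention that reproduces published
#'   LISREL-style robust output) or `"scaled"` (baseline also
#'   Satorra-Bentler scaled).
#' @return an object of class `mdcfa_scaled_fit`: `chisq_scaled`, `c_sb`,
#'   `gamma_meta`, `indices` (rmsea, srmr, nnfi, cfi, aic), `baseline`
#'   (raw and scaled baseline chi-square, df, scaling factor, convention)
#'   plus the raw fit fields.
#' @export
sb_scale <- function(fit, gamma, spec = fit$spec,
                     baseline = c("raw", "scaled")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(fit, "mdcfa_fit"))
  if (!fit$converged)
    warning("scaling a non-converged fit")
  p <- spec$p
  df <- fit$df
  t <- n_free(spec)
  gamma_full <- embed_gamma(gamma, p)
  if (df == 0) {
    c_sb <- NA_real_
    chisq_scaled <- fit$chisq_raw
    flag <- "saturated model: scaling undefined, raw chi-square returned"
  } else {
    Delta <- sigma_jacobian(spec, fit$theta_hat)
    c_sb <- sb_factor(fit$Sigma_hat, Delta, gamma_full, df)
    if (is.na(c_sb) || c_sb <= 0)
      stop("nonpositive scaling factor: Gamma estimation failed")
    chisq_scaled <- fit$chisq_raw / c_sb
    flag <- NULL
  }
  # independence baseline: free diagonal, here identity for correlations
  S <- fit$S
  df_b <- p * (p - 1) / 2
  Sigma_b <- diag(diag(S), p)
  F_b <- determinant(Sigma_b, logarithm = TRUE)$modulus -
    determinant(S, logarithm = TRUE)$modulus +
    sum(diag(solve(Sigma_b, S))) - p
  chisq_b_raw <- as.numeric((fit$N - 1) * F_b)
  Delta_b <- sigma_jacobian(build_baseline_spec(p), rep(1, p))
  c_b <- sb_factor(Sigma_b, Delta_b, gamma_full, df_b)
  chisq_b_scaled <- chisq_b_raw / c_b
  chisq_b_used <- if (baseline == "raw") chisq_b_raw else chisq_b_scaled
  indices <- if (df > 0)
    fit_indices(chisq_scaled, df, chisq_b_used, df_b, fit$N,
                S = S, Sigma_hat = fit$Sigma_hat, t = t)
  else {
    d <- sqrt(diag(S))
    list(rmsea = NA_real_,
         srmr = sqrt(mean(vech((S - fit$Sigma_hat) / tcrossprod(d))^2)),
         nnfi = NA_real_, cfi = NA_real_, aic = chisq_scaled + 2 * t)
  }
  structure(list(
    chisq_scaled = chisq_scaled, c_sb = c_sb, chisq_raw = fit$chisq_raw,
    df = df,
    gamma_meta = list(method = attr(gamma, "method") %||% "supplied",
                      B = attr(gamma, "B"), redrawn = attr(gamma, "redrawn")),
    indices = indices,
    baseline = list(chisq_raw = chisq_b_raw, chisq_scaled = chisq_b_scaled,
                    c_sb = c_b, df = df_b, convention = baseline),
    flag = flag, converged = fit$converged, N = fit$N,
    fit = fit), class = "mdcfa_scaled_fit")
}

# degenerate spec used only to build the baseline Jacobian (p uniquenesses)
build_baseline_spec <- function(p) {
  structure(list(p = as.integer(p), lambda_a = rep(0, p), phi_a = 1,
                 lambda_m = NULL, phi_m = NULL, loadings_mode = "fixed",
                 missing_columns = integer(0)), class = "mdcfa_model")
}

#' @export
print.mdcfa_scaled_fit <- function(x, ...) {
  cat(sprintf(
    "Satorra-Bentler scaled fit: chi-square %.2f (raw %.2f, c = %.3f), df = %d\n",
    x$chisq_scaled, x$chisq_raw, x$c_sb, x$df))
  i <- x$indices
  cat(sprintf(
    "  RMSEA %.4f  SRMR %.4f  NNFI %.4f  CFI %.4f  AIC %.1f\n",
    i$rmsea, i$srmr, i$nnfi, i$cfi, i$aic))
  invisible(x)
}

#' Fit indices from chi-square statistics
#'
#' RMSEA = sqrt(max(chisq - df, 0) / (df (N - 1))); SRMR = root mean square
#' of the standardized residuals of S - Sigma_hat over the p(p+1)/2 unique
#' elements; NNFI and CFI from the independence baseline; AIC = chisq + 2t.
#' CFI is clamped to [0, 1].
#'
#' @param chisq,df model test statistic and degrees of freedom.
#' @param chisq_b,df_b baseline statistic and degrees of freedom.
#' @param N sample size.
#' @param S,Sigma_hat observed and implied matrices (needed for SRMR; if
#'   omitted SRMR is NA).
#' @param t number of free parameters (needed for AIC).
#' @return list with `rmsea`, `srmr`, `nnfi`, `cfi`, `aic`.
#' @export
fit_indices <- function(chisq, df, chisq_b, df_b, N, S = NULL,
                        Sigma_hat = NULL, t = NULL) {
  stopifnot(df > 0, df_b > 0)
  rmsea <- sqrt(max(chisq - df, 0) / (df * (N - 1)))
  srmr <- NA_real_
  if (!is.null(S) && !is.null(Sigma_hat)) {
    d <- sqrt(diag(S))
    res <- (S - Sigma_hat) / tcrossprod(d)
    srmr <- sqrt(mean(vech(res)^2))
  }
  rb <- chisq_b / df_b
  nnfi <- (rb - chisq / df) / (rb - 1)
  cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, 0)
  cfi <- min(max(cfi, 0), 1)
  aic <- if (is.null(t)) NA_real_ else chisq + 2 * t
  list(rmsea = rmsea, srmr = srmr, nnfi = nnfi, cfi = cfi, aic = aic)
}

#' Compare two fitted models by the delta-CFI / delta-RMSEA criteria
#'
#' Flags a substantial difference in fit when |delta CFI| >= 0.01 or
#' |delta RMSEA| >= 0.015 (the conventional model-comparison cut-offs).
#'
#' @param a,b `mdcfa_scaled_fit` objects (or any lists carrying an
#'   `indices` element), compared as a - b.
#' @param cfi_crit,rmsea_crit the difference criteria.
#' @return list with signed `delta_cfi`, `delta_rmsea` and logical flags
#'   `substantial_cfi`, `substantial_rmsea`.
#' @export
compare_models <- function(a, b, cfi_crit = 0.01, rmsea_crit = 0.015) {
  ia <- a$indices %||% a
  ib <- b$indices %||% b
  d_cfi <- ia$cfi - ib$cfi
  d_rmsea <- ia$rmsea - ib$rmsea
  list(delta_cfi = d_cfi, delta_rmsea = d_rmsea,
       substantial_cfi = abs(d_cfi) >= cfi_crit,
       substantial_rmsea = abs(d_rmsea) >= rmsea_crit)
}
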