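# Independent oracles used across test files.  These deliberately avoid the
# package's own computational paths (C++ bivariate normal, analytic-gradient
# optimizer) so that agreement is evidence, not tautology.

# Bivariate normal rectangle P(X <= h, Y <= k) by 1-D quadrature of
# Sheppard's theta-substitution formula, via stats::integrate.
pbvn_oracle <- function(h, k, r) {
  if (abs(r) < 1e-12) return(pnorm(h) * pnorm(k))
  if (r < 0) return(pnorm(h) - pbvn_oracle(h, -k, -r))
  f <- function(theta) {
    s <- sin(theta)
    exp(-(h^2 + k^2 - 2 * h * k * s) / (2 * cos(theta)^2))
  }
  v <- integrate(f, 0, asin(r), rel.tol = 1e-11, abs.tol = 1e-13)$value
  pnorm(h) * pnorm(k) + v / (2 * pi)
}

# Tetrachoric log-likelihood of a 2x2 table (thresholds from margins),
# written independently of the C++ path.
tetra_loglik_oracle <- function(rho, tab) {
  n <- sum(tab)
  p1 <- (tab[1, 1] + tab[1, 2]) / n
  p2 <- (tab[1, 1] + tab[2, 1]) / n
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  p11 <- 1 - pnorm(t1) - pnorm(t2) + pbvn_oracle(t1, t2, rho)
  p10 <- pmax((1 - pnorm(t1)) - p11, 1e-12)
  p01 <- pmax((1 - pnorm(t2)) - p11, 1e-12)
  p00 <- pmax(1 - (1 - pnorm(t1)) - (1 - pnorm(t2)) + p11, 1e-12)
  p11 <- pmax(p11, 1e-12)
  tab[1, 1] * log(p11) + tab[1, 2] * log(p10) +
    tab[2, 1] * log(p01) + tab[2, 2] * log(p00)
}

# Brute-force grid search for the tetrachoric MLE: coarse grid over
# (-0.999, 0.999) refined to step 1e-4 around the coarse maximum.
tetra_grid_oracle <- function(tab, correct = 0.5) {
  if (any(tab == 0)) tab <- tab + correct
  coarse <- seq(-0.999, 0.999, by = 0.01)
  ll <- vapply(coarse, tetra_loglik_oracle, 0, tab = tab)
  r0 <- coarse[which.max(ll)]
  fine <- seq(max(-0.999, r0 - 0.011), min(0.999, r0 + 0.011), by = 1e-4)
  llf <- vapply(fine, tetra_loglik_oracle, 0, tab = tab)
  fine[which.max(llf)]
}

# Random non-degenerate 2x2 count tables.
random_tables <- function(n_tables, n = 200, seed = 1) {
  set.seed(seed)
  out <- vector("list", n_tables)
  for (i in seq_len(n_tables)) {
    repeat {
      rho <- runif(1, -0.9, 0.9)
      t1 <- qnorm(runif(1, 0.15, 0.85))
      t2 <- qnorm(runif(1, 0.15, 0.85))
      p11 <- 1 - pnorm(t1) - pnorm(t2) + pbvn_oracle(t1, t2, rho)
      p <- c(p11, (1 - pnorm(t1)) - p11, (1 - pnorm(t2)) - p11,
             pnorm(t1) + pnorm(t2) - 1 + p11)
      cnt <- as.vector(stats::rmultinom(1, n, p))
      tab <- matrix(c(cnt[1], cnt[2], cnt[3], cnt[4]), 2, byrow = TRUE)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    out[[i]] <- tab
  }
  out
}

# Multistart reference minimizer of the ML discrepancy for small models,
# using Nelder-Mead (derivative-free) from many random starts.
fit_ml_oracle <- function(S, spec, n_starts = 12, seed = 1) {
  p <- spec$p
  t <- n_free(spec)
  ldS <- determinant(S, logarithm = TRUE)$modulus
  fn <- function(theta) {
    Sig <- implied_sigma(spec, theta)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e10)
    as.numeric(sum(log(ev)) + sum(solve(Sig) * S) - ldS - p)
  }
  set.seed(seed)
  best <- Inf
  nm <- free_names_oracle(spec)
  for (s in seq_len(n_starts)) {
    th0 <- ifelse(grepl("^psi", nm), runif(t, 0.3, 1),
                  ifelse(grepl("^phi", nm), runif(t, 0.05, 0.6),
                         runif(t, -0.2, 0.9)))
    o <- optim(th0, fn, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, fn, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

free_names_oracle <- function(spec) {
  nm <- character(0)
  if (any(is.na(spec$lambda_a)))
    nm <- c(nm, rep("lambda", sum(is.na(spec$lambda_a))))
  if (!is.null(spec$lambda_m) && any(is.na(spec$lambda_m)))
    nm <- c(nm, rep("lambda", sum(is.na(spec$lambda_m))))
  if (is.na(spec$phi_a)) nm <- c(nm, "phi")
  if (!is.null(spec$phi_m) && is.na(spec$phi_m)) nm <- c(nm, "phi")
  c(nm, rep("psi", spec$p))
}
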