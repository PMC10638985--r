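test_that("parameter counting reproduces the published model families", {
  expect_equal(count_df(build_one_factor(20, "fixed")), 189L)
  expect_equal(count_df(build_one_factor(20, "free")), 170L)
  expect_equal(count_df(build_missing_data_model(20, 17:20, "fixed")), 188L)
  expect_equal(count_df(build_missing_data_model(20, 11:20, "fixed")), 188L)
  expect_equal(n_free(build_missing_data_model(20, 11:20, "free")), 50L)
  expect_equal(count_df(build_missing_data_model(20, 11:20, "free")), 160L)
  expect_equal(count_df(build_missing_data_model(20, 17:20, "free")), 166L)
  # p = 3 fixed: t = phi + 3 uniquenesses = 4, so df = 6 - 4
  expect_equal(count_df(build_one_factor(3, "fixed")), 2L)

  # all columns in the design: first missing loading pinned to zero
  m <- build_missing_data_model(20, 1:20, "free")
  expect_identical(m$lambda_m[1], 0)
  expect_true(all(is.na(m$lambda_m[2:20])))

  expect_error(build_one_factor(2, "fixed"), "under-identified")
  expect_error(build_missing_data_model(20, integer(0), "fixed"), "nonempty")
})

test_that("AIC bookkeeping (chisq + 2t) reproduces every published pairing", {
  # (chisq, t, published AIC) from the four model families
  rows <- list(c(200.5, 21, 242.5), c(206.6, 22, 250.6),
               c(186.4, 40, 266.4), c(170.8, 50, 270.8))
  for (r in rows) {
    idx <- fit_indices(chisq = r[1], df = 189, chisq_b = 1000, df_b = 190,
                       N = 500, t = r[2])
    expect_equal(idx$aic, r[3], tolerance = 1e-12)
  }
})

test_that("implied covariance assembles loadings, variances, uniquenesses", {
  s <- build_one_factor(4, "free")
  # theta: 4 loadings, 4 uniquenesses (phi fixed at 1)
  expect_equal(implied_sigma(s, c(rep(0, 4), rep(1, 4))), diag(4))

  sf <- build_one_factor(20, "fixed")
  Sg <- implied_sigma(sf, c(0.1225, rep(0.8775, 20)))
  expect_equal(unique(Sg[upper.tri(Sg)]), 0.1225)
  expect_equal(diag(Sg), rep(1, 20))

  s2 <- build_missing_data_model(4, 3:4, "fixed")
  Sg2 <- implied_sigma(s2, c(0.2, 0.05, rep(0.5, 4)))
  expect_equal(Sg2[3, 4], 0.2 + 0.05)
  expect_equal(Sg2[1, 2], 0.2)
  expect_equal(Sg2[1, 3], 0.2)
  expect_equal(diag(Sg2)[3], 0.2 + 0.05 + 0.5)
})

test_that("saturated and equicorrelation inputs are recovered exactly", {
  spec <- build_one_factor(20, "fixed")
  # S equal to an implied matrix -> F = 0 and parameters recovered
  S0 <- implied_sigma(spec, c(0.1225, rep(0.8775, 20)))
  f0 <- fit_ml(S0, spec, 500)
  expect_lt(f0$F_min, 1e-9)
  expect_lt(f0$chisq_raw, 1e-5)
  expect_equal(unname(f0$theta_hat["phi_attribute"]), 0.1225,
               tolerance = 1e-4)

  # closed form for any equicorrelation matrix under the fixed model
  r <- 0.31
  S1 <- matrix(r, 12, 12); diag(S1) <- 1
  f1 <- fit_ml(S1, build_one_factor(12, "fixed"), 400)
  expect_lt(f1$F_min, 1e-9)
  expect_equal(unname(f1$theta_hat["phi_attribute"]), r, tolerance = 1e-4)
  expect_equal(unname(f1$theta_hat["psi01"]), 1 - r, tolerance = 1e-4)
})

test_that("the optimizer matches a dense multistart oracle on small models", {
  set.seed(314)
  n_cases <- 0
  for (p in c(3, 4, 5)) {
    for (case in 1:7) {
      lam <- runif(p, 0.3, 0.9)
      psi <- 1 - lam^2
      S <- tcrossprod(lam) + diag(psi)
      noise <- matrix(rnorm(p * p, 0, 0.03), p, p)
      S <- S + (noise + t(noise)) / 2
      diag(S) <- 1
      if (min(eigen(S, only.values = TRUE)$values) < 0.05) next
      spec <- if (case %% 2 == 0 && p >= 4) build_one_factor(p, "fixed")
              else build_one_factor(p, "free")
      if (count_df(spec) < 0) next
      fit <- fit_ml(S, spec, 500)
      oracle <- fit_ml_oracle(S, spec, n_starts = 12, seed = case)
      expect_lt(abs(fit$F_min - oracle), 1e-6)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 18)

  # 3-variable toy, parameter-level agreement with the oracle optimum
  S3 <- matrix(c(1, 0.2, 0.3, 0.2, 1, 0.25, 0.3, 0.25, 1), 3)
  spec3 <- build_one_factor(3, "free")
  f3 <- fit_ml(S3, spec3, 500)
  expect_lt(abs(f3$F_min - fit_ml_oracle(S3, spec3, seed = 2)), 1e-6)
  # df = 0: three free loadings reproduce S exactly
  expect_lt(f3$F_min, 1e-8)
  lam3 <- f3$theta_hat[1:3]
  expect_equal(unname(lam3[1] * lam3[2]), 0.2, tolerance = 1e-4)
})

test_that("adding the missing-data factor can only improve the discrepancy", {
  pm <- population_model(n = 500)
  for (seed in 1:5) {
    dat <- generate_binary(pm, seed = 700 + seed,
                           design = missing_design(11:20, 0.4))
    S <- ensure_pd(tetrachoric_matrix(dat))$matrix
    f1 <- fit_ml(S, build_one_factor(20, "fixed"), 500)
    f2 <- fit_ml(S, build_missing_data_model(20, 11:20, "fixed"), 500)
    expect_lte(f2$F_min, f1$F_min + 1e-8)
  }
})

test_that("free loadings recover the population loading from tetrachorics", {
  pm <- population_model(p = 20, loading = 0.35, n = 500)
  spec <- build_one_factor(20, "free")
  mean_loading <- vapply(1:100, function(r) {
    S <- ensure_pd(tetrachoric_matrix(generate_binary(pm, seed = 9000 + r)))
    fit <- fit_ml(S$matrix, spec, 500)
    mean(fit$theta_hat[1:20])
  }, 0)
  expect_lt(abs(mean(mean_loading) - 0.35), 0.03)
})

test_that("model specs and fit results serialize losslessly", {
  spec <- build_missing_data_model(20, 11:20, "free")
  f <- tempfile(fileext = ".yaml")
  spec_to_yaml(spec, f)
  back <- spec_from_yaml(f)
  expect_equal(back$lambda_a, spec$lambda_a)
  expect_equal(back$lambda_m, spec$lambda_m)
  expect_equal(back$phi_a, spec$phi_a)
  expect_equal(count_df(back), 160L)

  S <- implied_sigma(build_one_factor(5, "fixed"), c(0.2, rep(0.8, 5)))
  fit <- fit_ml(S, build_one_factor(5, "fixed"), 200)
  jf <- tempfile(fileext = ".json")
  fit_to_json(fit, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$df, 9)  # 15 moments - (phi + 5 uniquenesses)
  expect_true(parsed$converged)
  unlink(c(f, jf))
})
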