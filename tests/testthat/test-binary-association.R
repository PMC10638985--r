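test_that("bivariate normal rectangle probabilities match independent oracles", {
  hs <- c(-2, -0.8416, 0, 0.5, 1.5)
  rs <- c(-0.999, -0.9, -0.5, -0.1, 0, 0.1225, 0.5, 0.9, 0.95, 0.999)
  for (h in hs) for (k in hs) for (r in rs) {
    expect_equal(pbvn(h, k, r), pbvn_oracle(h, k, r), tolerance = 1e-9,
                 label = sprintf("pbvn(%g,%g,%g)", h, k, r))
  }
  # cross-check against the TVPACK implementation on a coarser grid
  for (r in c(-0.7, 0.3, 0.93)) {
    ref <- mvtnorm::pmvnorm(upper = c(0.3, -1.1),
                            corr = matrix(c(1, r, r, 1), 2),
                            algorithm = mvtnorm::TVPACK(1e-12))
    expect_equal(pbvn(0.3, -1.1, r), as.numeric(ref), tolerance = 1e-10)
  }
  # limiting identities
  expect_equal(pbvn(0.4, 1.2, 0), pnorm(0.4) * pnorm(1.2), tolerance = 1e-12)
})

test_that("pairwise tetrachoric estimation agrees with a grid-search oracle", {
  # canonical anchor cases
  expect_equal(tetrachoric_pair(matrix(c(25, 25, 25, 25), 2))$rho, 0,
               tolerance = 1e-5)
  perfect <- tetrachoric_pair(matrix(c(50, 0, 0, 50), 2))
  expect_gt(perfect$rho, 0.9)   # continuity-corrected, driven to the bound
  expect_true(perfect$diagnostics$corrected)

  anti <- tetrachoric_pair(matrix(c(0, 50, 50, 0), 2))
  expect_lt(anti$rho, -0.9)

  mid <- tetrachoric_pair(matrix(c(40, 10, 10, 40), 2))
  expect_lt(abs(mid$rho - tetra_grid_oracle(matrix(c(40, 10, 10, 40), 2))),
            1e-3)

  # 50 random tables against the brute-force oracle (absolute agreement)
  tabs <- random_tables(50, n = 200, seed = 99)
  for (tab in tabs) {
    expect_lt(abs(tetrachoric_pair(tab)$rho - tetra_grid_oracle(tab)), 1e-3,
              label = paste("table", paste(tab, collapse = ",")))
  }

  expect_error(tetrachoric_pair(matrix(c(10, 5, 0, 0), 2,
                                       byrow = TRUE)), "margin")
})

test_that("tetrachoric matrices recover the generating latent correlation", {
  pm <- population_model(p = 10, loading = 0.35, n = 4000)
  dat <- generate_binary(pm, seed = 7)
  ct <- tetrachoric_matrix(dat)
  expect_true(isSymmetric(ct$matrix))
  expect_equal(diag(ct$matrix), rep(1, 10), ignore_attr = TRUE)
  expect_lt(abs(mean(ct$matrix[upper.tri(ct$matrix)]) - 0.1225), 0.02)
  expect_equal(unname(ct$thresholds),
               unname(qnorm(1 - colMeans(dat$values))), tolerance = 1e-12)

  # identical columns sit at (or near) the positive bound
  X <- cbind(dat$values[, 1], dat$values[, 1], dat$values[, 2])
  ct2 <- tetrachoric_matrix(binary_dataset(X))
  expect_gt(ct2$matrix[1, 2], 0.9)

  # two items give a 2x2 matrix
  ct3 <- tetrachoric_matrix(binary_dataset(dat$values[, 1:2]))
  expect_equal(dim(ct3$matrix), c(2, 2))

  # degenerate margins are reported by item name
  Xd <- dat$values[1:50, 1:3]
  Xd[, 2] <- 1L
  expect_error(tetrachoric_matrix(binary_dataset(Xd)), "item02")
})

test_that("zero replacement shrinks design-column margins by 1 - rate", {
  pm <- population_model(n = 500)
  dat <- generate_binary(pm, seed = 55, design = missing_design(17:20, 0.6))
  complete <- dichotomize(simulate_continuous(pm, seed = 55), 0.5)
  zr <- replace_missing_with_zero(dat)
  expect_false(anyNA(zr$values))
  ratio <- colMeans(zr$values[, 17:20]) / colMeans(complete$values[, 17:20])
  expect_lt(max(abs(ratio - 0.4)), 0.06)
  # untouched cells keep their values
  expect_identical(zr$values[, 1:16], complete$values[, 1:16])
  # complete input is returned unchanged
  expect_identical(replace_missing_with_zero(complete)$values,
                   complete$values)
})

test_that("attenuation of between-column association is monotone in rate", {
  pm <- population_model(n = 500)
  mean_cross <- vapply(c(0, 0.2, 0.4, 0.6), function(rate) {
    vals <- vapply(1:8, function(r) {
      d <- if (rate > 0) missing_design(11:20, rate) else NULL
      dat <- generate_binary(pm, seed = 600 + r, design = d)
      R <- tetrachoric_matrix(dat)$matrix
      mean(R[1:10, 11:20])
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_cross) < 0))
})

test_that("positive-definiteness smoothing is minimal, recorded, idempotent", {
  expect_equal(ensure_pd(diag(3)), diag(3), ignore_attr = TRUE)
  expect_equal(attr(ensure_pd(diag(3)), "ridge_applied"), 0)

  A <- matrix(c(1, 0.9999, 0.9999, 1), 2)
  expect_equal(attr(ensure_pd(A), "ridge_applied"), 0)

  B <- diag(3)
  B[1, 2] <- B[2, 1] <- 0.9
  B[1, 3] <- B[3, 1] <- 0.9
  B[2, 3] <- B[3, 2] <- -0.9
  expect_lt(min(eigen(B, only.values = TRUE)$values), 0)
  Bs <- ensure_pd(B, floor = 1e-6)
  expect_gte(min(eigen(Bs, only.values = TRUE)$values), 1e-6 - 1e-12)
  expect_equal(diag(Bs), rep(1, 3), ignore_attr = TRUE)
  expect_gt(attr(Bs, "ridge_applied"), 0)

  # idempotence
  Bss <- ensure_pd(Bs, floor = 1e-6)
  expect_equal(unclass(Bss), unclass(Bs), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(attr(Bss, "ridge_applied"), 0)
})

test_that("probability-based covariances follow the joint-minus-product rule", {
  # deterministic toy: P(A=1)=0.6, P(B=1)=0.5, P(both)=0.4 -> cov 0.10
  A <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  B <- c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0)
  V <- probability_based_covariance(binary_dataset(cbind(A, B)))
  expect_equal(V[1, 2], 0.4 - 0.6 * 0.5, tolerance = 1e-12)
  expect_equal(diag(V), c(0.6 * 0.4, 0.5 * 0.5), ignore_attr = TRUE)

  # perfectly matched fair columns -> 0.25
  M <- cbind(rep(0:1, 20), rep(0:1, 20))
  expect_equal(probability_based_covariance(binary_dataset(M))[1, 2], 0.25)

  # independent fair items -> off-diagonals near zero
  set.seed(8)
  X <- matrix(rbinom(5000 * 4, 1, 0.5), 5000, 4)
  V2 <- probability_based_covariance(binary_dataset(X))
  expect_lt(max(abs(V2[upper.tri(V2)])), 0.02)
})

test_that("correlation input round-trips through CSV and lower-triangle text", {
  pm <- population_model(p = 5, n = 300)
  ct <- tetrachoric_matrix(generate_binary(pm, seed = 3))
  f1 <- tempfile(fileext = ".csv")
  write_corr_csv(ct, f1)
  expect_equal(read_corr(f1), unname(ct$matrix), tolerance = 1e-12)
  side <- sub("([.][^.]+)?$", "_thresholds.csv", f1)
  expect_true(file.exists(side))
  thr <- read.csv(side)
  expect_equal(thr$threshold, unname(ct$thresholds), tolerance = 1e-12)

  f2 <- tempfile(fileext = ".txt")
  write_corr_lower(ct, f2)
  expect_equal(read_corr(f2), unname(ct$matrix), tolerance = 1e-6)
  unlink(c(f1, f2, side))
})
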