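# VAR fitting, order selection, state-space conversion and partial
# variances via Riccati submodels.

test_that("least-squares VAR estimates are consistent and errors are typed", {
  sp <- benchmark_preset("chain3")
  X <- simulate_var(sp, 1e4, seed = 1)
  fit <- fit_var(X, 1)
  expect_lt(max(abs(fit$A[[1]] - sp$A[[1]])), 0.05)
  expect_equal(fit$n_used, 1e4 - 1)
  expect_true(fit$stable)

  # white noise: coefficients vanish at the root-N rate
  w <- simulate_var(var_spec(matrix(0, 3, 3)), 5000, seed = 2)
  fw <- fit_var(w, 1)
  expect_lt(max(abs(fw$A[[1]])), 3 / sqrt(5000))

  # too-short series
  expect_error(fit_var(X[, 1:7], 2), "too short")
  # collinear rows are named
  Xc <- rbind(X[1:2, 1:200], X[1, 1:200])
  expect_error(fit_var(Xc, 1), "collinear")
})

test_that("AIC selects the true order of a strongly coupled VAR(3)", {
  # 4 nodes: the AIC overshoot probability per extra candidate order is
  # roughly P(chi2_{M^2} > 2 M^2), ~1% here, so near-certain recovery
  M <- 4
  A1 <- diag(0.35, M); A1[2, 1] <- 0.25; A1[4, 3] <- 0.2
  A2 <- diag(-0.30, M)
  A3 <- diag(0.35, M); A3[3, 2] <- 0.2
  sp <- var_spec(list(A1, A2, A3))
  hits <- 0
  for (r in 1:40) {
    X <- simulate_var(sp, 5000, seed = 1000 + r)
    hits <- hits + (select_order_aic(X, 6) == 3)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("AIC prefers the smallest model on white noise and respects bounds", {
  hits <- 0
  for (r in 1:20) {
    X <- simulate_var(var_spec(matrix(0, 3, 3)), 1000, seed = 2000 + r)
    hits <- hits + (select_order_aic(X, 5) == 1)
  }
  expect_gt(hits / 20, 0.5)
  X <- simulate_var(benchmark_preset("chain3"), 500, seed = 3)
  expect_equal(as.integer(select_order_aic(X, 1)), 1L)
})

test_that("state-space conversion is exact", {
  A <- list(matrix(c(0.4, 0.2, 0.1, 0.3), 2, 2),
            matrix(c(0.2, 0, 0, 0.2), 2, 2))
  sp <- var_spec(A, matrix(c(1, 0.3, 0.3, 2), 2, 2))
  ss <- var_to_ss(sp)
  expect_equal(dim(ss$A_ss), c(4L, 4L))          # state dimension mM
  expect_identical(ss$V, sp$Sigma)               # V = Sigma by construction
  # impulse responses of the two forms agree
  M <- 2; m <- 2
  Psi_var <- list(diag(M))                       # VAR MA representation
  for (h in 1:10) {
    Ph <- matrix(0, M, M)
    for (l in seq_len(min(h, m)))
      Ph <- Ph + A[[l]] %*% Psi_var[[h - l + 1]]
    Psi_var[[h + 1]] <- Ph
  }
  Fk <- diag(m * M)
  for (h in 1:10) {
    Psi_ss <- ss$C %*% Fk %*% ss$K               # C A^{h-1} K
    expect_equal(Psi_ss, Psi_var[[h + 1]], tolerance = 1e-10)
    Fk <- ss$A_ss %*% Fk
  }
  expect_error(var_to_ss(var_spec(matrix(0.999, 1, 1)) |>
                           (\(s) { s$A[[1]][1, 1] <- 1.01
                                   s$spectral_radius <- 1.01; s })()),
               "unstable")
})

test_that("reduced submodels reproduce brute-force univariate regressions", {
  ss <- var_to_ss(benchmark_preset("chain3"))
  # keep everything: no reduction
  expect_identical(reduced_innovation_variance(ss, 1:3), ss$V)
  # independent processes: own innovation unchanged
  ssi <- var_to_ss(benchmark_preset("independent"))
  for (j in c(1, 4, 7))
    expect_equal(reduced_innovation_variance(ssi, j)[1, 1], 1, tolerance = 1e-8)
  # coupled bivariate: keep target only, against a long-lag OLS oracle
  sp <- var_spec(matrix(c(0.5, 0.4, 0, 0.5), 2, 2))
  v22 <- reduced_innovation_variance(var_to_ss(sp), 2)[1, 1]
  X <- simulate_var(sp, 1e6, seed = 11)
  mom <- netinfodyn:::lagged_moments(X[2, , drop = FALSE], 20)
  v_ols <- netinfodyn:::moment_resid_var(mom, 1, 1:20)
  expect_equal(v22, v_ols, tolerance = 0.01)
  expect_error(reduced_innovation_variance(ss, integer(0)), "subset")
})

test_that("partial variances match closed forms and respect nesting", {
  # AR(1) a = 0.9, unit innovation
  pv <- partial_variances(var_spec(matrix(0.9, 1, 1)), 1)
  expect_equal(pv$sigma2_j, 1 / 0.19, tolerance = 1e-8)
  expect_equal(pv$sigma2_j_self, 1.0, tolerance = 1e-8)
  # independent network: removing any source changes nothing
  sp <- benchmark_preset("independent")
  for (j in c(1, 5)) {
    pv <- partial_variances(sp, j)
    expect_equal(stats::na.omit(as.numeric(pv$sigma2_j_minus_i)),
                 rep(pv$sigma2_j_full, sp$M - 1), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # nesting inequalities across presets and random stable specs
  set.seed(33)
  specs <- c(lapply(c("independent", "chain3", "paperlike7"), benchmark_preset),
             replicate(30, random_stable_spec(M = 3, m = sample(1:2, 1)),
                       simplify = FALSE))
  for (sp in specs) {
    j <- sample.int(sp$M, 1)
    pv <- partial_variances(sp, j)
    tol <- 1e-10 * max(1, pv$sigma2_j)
    for (i in seq_len(sp$M)) {
      if (i == j) next
      expect_lte(pv$sigma2_j_full, pv$sigma2_j_minus_i[i] + tol)
      expect_lte(pv$sigma2_j_minus_i[i], pv$sigma2_j + tol)
    }
    expect_lte(pv$sigma2_j_self, pv$sigma2_j + tol)
    expect_gte(pv$sigma2_j_full, -tol)
  }
})

test_that("full-model partial variance equals the fit's residual variance", {
  X <- simulate_var(benchmark_preset("paperlike7"), 400, seed = 21)
  Xs <- standardize(X)
  fit <- fit_var(Xs, 2)
  mom <- netinfodyn:::lagged_moments(Xs, 2)
  for (j in c(1, 4)) {
    pv_reg <- netinfodyn:::regression_partial_variances(mom, j)
    expect_equal(pv_reg$sigma2_j_full, fit$Sigma[j, j], tolerance = 1e-10)
  }
})

test_that("VAR models serialize to JSON and back", {
  sp <- benchmark_preset("paperlike7")
  f <- withr::local_tempfile(fileext = ".json")
  write_var_json(sp, f)
  back <- read_var_json(f)
  expect_equal(back$A, lapply(sp$A, unname), tolerance = 1e-12)
  expect_equal(back$Sigma, unname(sp$Sigma), tolerance = 1e-12)
  expect_equal(back$labels, sp$labels)
  expect_equal(back$truth_adjacency, unname(sp$truth_adjacency))
})
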