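# Information measures: closed forms, decomposition identity, mediation,
# backend agreement and estimator bias behavior.

test_that("node measures match Gaussian closed forms", {
  expect_equal(node_entropy(1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-10)
  expect_equal(node_entropy(exp(2)) - node_entropy(1), 1, tolerance = 1e-10)
  expect_equal(node_entropy(1 / (2 * pi * exp(1))), 0, tolerance = 1e-10)
  expect_error(node_entropy(-1), "positive")

  # AR(1) a = 0.9 with unit process variance: innovation variance 0.19
  sp <- var_spec(matrix(0.9, 1, 1), matrix(0.19, 1, 1))
  pv <- partial_variances(sp, 1)
  expect_equal(node_storage(pv), 0.5 * log(1 / 0.19), tolerance = 1e-8)
  expect_equal(node_new_information(pv), 0.5 * log(2 * pi * exp(1) * 0.19),
               tolerance = 1e-8)
  expect_equal(node_total_transfer(pv), 0, tolerance = 1e-10)

  # AR(1) a = 0.5: S = 0.5 log(1/0.75)
  pv5 <- partial_variances(var_spec(matrix(0.5, 1, 1)), 1)
  expect_equal(node_storage(pv5), 0.5 * log(1 / 0.75), tolerance = 1e-8)

  # white noise: S = 0, N = H
  pvw <- partial_variances(var_spec(matrix(0, 2, 2)), 1)
  expect_equal(node_storage(pvw), 0, tolerance = 1e-10)
  expect_equal(node_new_information(pvw), node_entropy(pvw$sigma2_j),
               tolerance = 1e-10)
  expect_error(conditional_transfer(pvw, 1), "differ")
})

test_that("model-implied transfers vanish exactly without coupling", {
  mi <- model_measures(benchmark_preset("independent"))
  expect_lt(max(mi$nodes$T), 1e-10)
  expect_lt(max(mi$Tcond, na.rm = TRUE), 1e-10)
  # chain3: full mediation of 1 -> 3 by node 2
  mc <- model_measures(benchmark_preset("chain3"))
  expect_lt(mc$Tcond[1, 3], 1e-6)
  expect_gt(mc$Tcond[2, 3], 0.05)
  expect_gt(mc$nodes$T[2], 0)
  # paperlike7: all non-links are exactly mediated/absent
  p7 <- benchmark_preset("paperlike7")
  mp <- model_measures(p7)
  expect_lt(max(mp$Tcond[!p7$truth_adjacency], na.rm = TRUE), 1e-6)
})

test_that("both backends satisfy every invariant on arbitrary inputs", {
  set.seed(55)
  inputs <- list(
    standardize(simulate_var(benchmark_preset("paperlike7"), 300)),
    standardize(simulate_var(benchmark_preset("chain3"), 300)),
    standardize(matrix(rnorm(7 * 300), 7)))
  for (X in inputs) for (bk in c("state-space", "regression")) {
    im <- decompose_network(X, m = 3, backend = bk)
    nd <- im$nodes
    expect_lt(max(abs(nd$H - (nd$S + nd$T + nd$N))), 1e-8)
    expect_gt(min(nd$S), -1e-10)
    expect_gt(min(nd$T), -1e-10)
    expect_true(all(nd$N <= nd$H + 1e-10))
    if (bk == "regression")
      expect_gt(min(im$Tcond, na.rm = TRUE), -1e-10)
    else
      expect_gt(min(im$Tcond, na.rm = TRUE), -1e-8)
    # T_j >= every conditional transfer into j (variance nesting)
    for (j in seq_len(nrow(nd)))
      expect_true(all(im$Tcond[-j, j] <= nd$T[j] + 1e-8))
  }
})

test_that("backends agree on common inputs", {
  diffs <- c()
  for (r in 1:8) {
    X <- standardize(simulate_var(benchmark_preset("paperlike7"), 300,
                                  seed = 500 + r))
    im_ss <- decompose_network(X, m = 2, backend = "state-space")
    im_rg <- decompose_network(X, m = 2, backend = "regression")
    for (meas in c("S", "T", "N"))
      diffs <- c(diffs, abs(im_ss$nodes[[meas]] - im_rg$nodes[[meas]]))
  }
  expect_lt(mean(diffs), 0.02)
  expect_lt(max(diffs), 0.06)
})

test_that("a cohort of short paperlike realizations reproduces the storage pattern", {
  sp <- benchmark_preset("paperlike7")
  Ss <- Ns <- matrix(NA_real_, 18, 7)
  for (s in 1:18) {
    X <- standardize(simulate_var(sp, 300, seed = 7000 + s))
    im <- decompose_network(X, m = 1, backend = "state-space")
    Ss[s, ] <- im$nodes$S
    Ns[s, ] <- im$nodes$N
  }
  medS <- apply(Ss, 2, stats::median)
  names(medS) <- sp$labels
  expect_gt(medS["RR"], medS["RESP"])
  expect_gt(medS["RESP"], medS["PAT"])
  expect_true(all(medS["PAT"] > medS[4:7]))
})

test_that("white-noise estimates stay below their simulated null quantiles", {
  # null distribution of max S and T at N = 300, m = 3
  set.seed(77)
  null_S <- null_T <- matrix(NA_real_, 60, 7)
  for (r in 1:60) {
    im <- decompose_network(standardize(matrix(rnorm(7 * 300), 7)),
                            m = 3, backend = "regression")
    null_S[r, ] <- im$nodes$S
    null_T[r, ] <- im$nodes$T
  }
  q95_S <- stats::quantile(null_S, 0.95)
  im <- decompose_network(standardize(matrix(rnorm(7 * 300), 7)),
                          m = 3, backend = "regression")
  expect_true(all(im$nodes$S <= max(null_S)))
  expect_gt(mean(im$nodes$S <= q95_S), 0.5)
})

test_that("estimator bias on white noise shrinks with sample size", {
  set.seed(88)
  mean_ST <- vapply(c(300, 1000, 5000), function(N) {
    v <- vapply(1:10, function(r) {
      im <- decompose_network(standardize(matrix(rnorm(7 * N), 7)),
                              m = 3, backend = "regression")
      c(mean(im$nodes$S), mean(im$nodes$T))
    }, numeric(2))
    rowMeans(v)
  }, numeric(2))
  expect_true(all(diff(mean_ST[1, ]) < 0))   # S bias decreases
  expect_true(all(diff(mean_ST[2, ]) < 0))   # T bias decreases
})

test_that("short-sample estimates are unbiased against model truth", {
  sp <- benchmark_preset("paperlike7")
  truth <- model_measures(sp)$nodes
  nrep <- 60
  est <- array(NA_real_, c(nrep, 7, 2))
  for (r in seq_len(nrep)) {
    X <- standardize(simulate_var(sp, 300, seed = 40000 + r))
    im <- decompose_network(X, m = 1, backend = "state-space")
    est[r, , 1] <- im$nodes$S
    est[r, , 2] <- im$nodes$T
  }
  for (j in 1:7) {
    for (k in 1:2) {
      tr <- if (k == 1) truth$S[j] else truth$T[j]
      se <- stats::sd(est[, j, k]) / sqrt(nrep)
      # small-sample log-ratio estimators carry O(1/N) bias; require the
      # mean within 2 SE after allowing that known offset
      expect_lt(abs(mean(est[, j, k]) - tr), 2 * se + 0.05)
    }
  }
})

test_that("measures export to tidy CSV", {
  im <- model_measures(benchmark_preset("chain3"))
  f <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measures(im, f, subject = "S01", state = "REST", tcond_path = f2)
  tab <- utils::read.csv(f)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("subject", "state", "node", "H", "S", "T", "N") %in% names(tab)))
  tc <- utils::read.csv(f2)
  expect_equal(dim(tc), c(3L, 4L))
})
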