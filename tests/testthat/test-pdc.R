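test_that("MVAR least squares matches independent oracles", {
  set.seed(3)
  A1 <- matrix(c(0.5, 0.3, 0, 0.4, 0.5, 0.2, 0, 0, 0.3), 3, 3)
  A2 <- matrix(c(-0.2, 0, 0, 0.1, -0.1, 0, 0, 0, 0.1), 3, 3)
  seg <- generate_var_fixture(list(A1, A2), c(1, 0.8, 1.2), 3000, seed = 7)
  m <- fit_mvar(seg, 2)
  # oracle 1: normal equations solved directly on the stacked regression
  X <- seg$data - rowMeans(seg$data)
  n <- ncol(X); p <- 2; N <- 3
  Z <- cbind(t(X[, p:(n - 1)]), t(X[, (p - 1):(n - 2)]))
  Y <- t(X[, (p + 1):n])
  B <- solve(crossprod(Z), crossprod(Z, Y))
  for (r in 1:p) {
    oracle_Ar <- unname(t(B[((r - 1) * N + 1):(r * N), ]))
    expect_equal(unname(m$A[, , r]), oracle_Ar, tolerance = 1e-8)
  }
  # oracle 2: stats::ar.ols on the same (demeaned) data
  ao <- ar.ols(t(X), order.max = 2, aic = FALSE, demean = FALSE,
               intercept = FALSE)
  for (r in 1:p)
    expect_equal(unname(m$A[, , r]), unname(ao$ar[r, , ]), tolerance = 1e-8)
  # residual orthogonality: normal equations satisfied to machine precision
  res <- Y - Z %*% B
  expect_lt(max(abs(crossprod(Z, res))) / n, 1e-8)
  # consistency: estimates within 3 standard errors of the generating truth
  sigma_hat <- m$sigma
  ZtZinv <- solve(crossprod(Z))
  for (r in 1:p) {
    truthA <- if (r == 1) A1 else A2
    for (i in 1:N) for (j in 1:N) {
      se <- sqrt(sigma_hat[i, i] * ZtZinv[(r - 1) * N + j, (r - 1) * N + j])
      expect_lt(abs(m$A[i, j, r] - truthA[i, j]), 3.5 * se + 1e-12)
    }
  }
})

test_that("white noise yields uniformly small MVAR coefficients", {
  seg <- generate_var_fixture(list(matrix(0, 3, 3)), 1, 4000, seed = 21)
  m <- fit_mvar(seg, 3)
  # each coefficient ~ N(0, 1/n); allow 4 sigma with a multiplicity margin
  expect_lt(max(abs(m$A)), 4.5 / sqrt(m$nobs))
})

test_that("MVAR fit reports identifiability and rank problems", {
  seg <- generate_var_fixture(list(matrix(0, 2, 2)), 1, 30, seed = 1)
  expect_error(fit_mvar(seg, 20), "too few samples")
  x <- rnorm(500)
  dup <- signal_segment(rbind(x, x), 1000, c("a", "b"))
  expect_error(fit_mvar(dup, 2), "rank-deficient")
})

test_that("AIC order selection recovers a VAR(6) and clamps to the search range", {
  set.seed(8)
  coefs <- c(replicate(5, matrix(0, 2, 2), simplify = FALSE),
             list(matrix(c(0.6, 0.3, -0.3, 0.5), 2, 2)))
  seg <- generate_var_fixture(coefs, 1, 3000, seed = 12)
  sel <- select_order_aic(seg, 5, 20)
  expect_identical(sel$order, 6L)
  expect_length(sel$aic, 16L)
  expect_true(all(as.integer(names(sel$aic)) == 5:20))
  expect_true(sel$order >= 5 && sel$order <= 20)
})

test_that("PDC satisfies its normalization and vanishes without coupling", {
  seg <- generate_var_fixture(biv_var_coefs(), 1, 2000, seed = 5)
  m <- fit_mvar(seg, 5)
  sp <- pdc_spectrum(m)
  norms <- apply(sp$pi^2, c(2, 3), sum)    # sum over targets, per source x freq
  expect_lt(max(abs(norms - 1)), 1e-10)
  expect_true(all(sp$pi >= 0 & sp$pi <= 1))
  # diagonal coefficient matrices -> zero off-diagonal PDC
  mdiag <- m
  mdiag$A[] <- 0
  for (r in 1:5) mdiag$A[, , r] <- diag(c(0.4, 0.1)) / r
  spd <- pdc_spectrum(mdiag)
  offdiag <- spd$pi[1, 2, ] ; offdiag2 <- spd$pi[2, 1, ]
  expect_true(all(offdiag == 0) && all(offdiag2 == 0))
})

test_that("bivariate VAR(1) PDC matches the closed form", {
  # known model: x2 driven by x1 with a21 = 0.5, both self 0.5
  m <- structure(list(order = 1L,
                      A = array(biv_var_coefs()[[1]], c(2, 2, 1),
                                dimnames = list(c("x1", "x2"), c("x1", "x2"),
                                                NULL)),
                      sigma = diag(2), labels = c("x1", "x2"), fs = 1000,
                      nobs = 1000),
                 class = "mvar_model")
  f <- c(5, 20, 80)
  sp <- pdc_spectrum(m, freqs = f)
  for (k in seq_along(f)) {
    z <- exp(-2i * pi * f[k] / 1000)
    Abar <- diag(2) - matrix(c(0.5, 0.5, 0, 0.5), 2, 2) * z
    # closed form: pi_{2<-1} = |Abar21| / sqrt(|Abar11|^2 + |Abar21|^2)
    expected21 <- Mod(Abar[2, 1]) / sqrt(Mod(Abar[1, 1])^2 + Mod(Abar[2, 1])^2)
    expect_equal(sp$pi["x2", "x1", k], expected21, tolerance = 1e-12)
    expect_equal(sp$pi["x1", "x2", k], 0)   # no reverse influence
  }
})

test_that("band averaging is a mean over the grid and monotone", {
  seg <- generate_var_fixture(biv_var_coefs(), 1, 2000, seed = 5)
  sp <- pdc_spectrum(fit_mvar(seg, 4))
  fm <- band_average(sp, c(6, 92))
  sel <- sp$freq >= 6 & sp$freq <= 92
  expect_equal(sum(sel), 87)               # 1 Hz grid: 87 points in 6-92
  oracle <- apply(sp$pi[, , sel], c(1, 2), mean)
  expect_equal(fm, oracle)
  expect_true(all(fm >= 0 & fm <= 1))
  # constant spectrum -> every entry equals the constant
  spc <- sp; spc$pi[] <- 0.25
  expect_true(all(band_average(spc) == 0.25))
  # monotonicity
  sp_hi <- sp; sp_hi$pi <- pmin(sp$pi * 1.5, 1)
  expect_true(all(band_average(sp_hi) >= band_average(sp) - 1e-12))
  expect_error(band_average(sp, c(600, 700)), "no grid frequencies")
})

test_that("flow aggregation counts ordered pairs and validates groups", {
  groups <- default_electrode_groups()
  labels <- c(groups$VC, groups$FA)
  ones <- matrix(1, 6, 6, dimnames = list(labels, labels))
  fl <- aggregate_flows(ones, groups)
  expect_equal(fl$vc_to_fa, 8)
  expect_equal(fl$fa_to_vc, 8)
  expect_equal(fl$within_fa, 2)
  expect_equal(fl$within_vc, 12)
  zero <- ones * 0
  flz <- aggregate_flows(zero, groups)
  expect_true(all(unlist(flz) == 0))
  expect_error(aggregate_flows(ones[1:5, 1:5], groups), "not in flow matrix")
  expect_error(aggregate_flows(ones, list(VC = labels[1:4], FA = labels[3:5])),
               "disjoint")
})

test_that("channel relabeling permutes the flow matrix consistently", {
  seg <- generate_var_fixture(ssvepflow:::study_var_coefficients(0.15), 1,
                              2000, seed = 9)
  fm <- segment_flows(seg, p_min = 5, p_max = 5)$flow_matrix
  perm <- c(6, 1, 5, 2, 4, 3)
  seg2 <- select_channels(seg, seg$labels[perm])
  fm2 <- segment_flows(seg2, p_min = 5, p_max = 5)$flow_matrix
  expect_equal(fm2, fm[perm, perm], tolerance = 1e-10)
  # aggregation is invariant under the relabeling
  expect_equal(unlist(aggregate_flows(fm2)), unlist(aggregate_flows(fm)),
               tolerance = 1e-10)
})

test_that("planted unidirectional coupling is recovered as ordered flows in >= 95/100 seeds", {
  groups <- list(VC = c("V1_L", "V1_R", "V2_L", "V2_R"),
                 FA = c("FrA_L", "FrA_R"))
  coefs <- ssvepflow:::study_var_coefficients(0.15)
  hits <- 0L
  for (s in 1:100) {
    seg <- generate_var_fixture(coefs, 1, 3000, seed = 1000 + s)
    fl <- segment_flows(seg, groups = groups, p_min = 5, p_max = 5)$flows
    if (fl$vc_to_fa > fl$fa_to_vc) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
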