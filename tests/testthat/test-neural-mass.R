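test_that("sigmoid hits its midpoint, limits and an independently evaluated point", {
  cc <- column_constants()
  expect_equal(jr_sigmoid(cc$v0, cc), cc$e0)
  expect_equal(jr_sigmoid(1e6, cc), 2 * cc$e0)
  expect_equal(jr_sigmoid(-1e6, cc), 0)
  # direct evaluation of the closed form at v = 0 (e0 = 2.5, v0 = 6, r = 0.56)
  expect_equal(jr_sigmoid(0, cc), 2 * 2.5 / (1 + exp(0.56 * 6)))
  expect_equal(jr_sigmoid(0, cc), 0.1678461164, tolerance = 1e-8)
  # strictly increasing
  v <- seq(-20, 30, by = 0.5)
  expect_true(all(diff(jr_sigmoid(v, cc)) > 0))
})

test_that("column constants are validated", {
  expect_error(column_constants(A = -1), "positive")
  expect_error(column_constants(a = 40, b = 50), "a > b")
  expect_error(double_column_params(-5, 90, 2000, 300), "non-negative")
})

test_that("decoupled double column reproduces two independent single columns exactly", {
  sp <- stimulus_spec("control", duration = 2)
  p <- make_noise_input(sp, 5)
  pp <- make_noise_input(sp, 6)
  params <- double_column_params(80, 110, 0, 0)
  both <- simulate_double_column(params, p, pp)
  one <- simulate_single_column(80, p)
  expect_identical(both$data["u1", ], unname(one$data["u", ]))
  two <- simulate_single_column(110, pp)
  expect_identical(both$data["u2", ], unname(two$data["u", ]))
})

test_that("simulation is deterministic given (params, inputs)", {
  fix1 <- tiny_fixture(seed = 3, duration = 1)
  fix2 <- tiny_fixture(seed = 3, duration = 1)
  expect_identical(fix1$segment$data, fix2$segment$data)
  fix3 <- tiny_fixture(seed = 4, duration = 1)
  expect_false(identical(fix1$segment$data, fix3$segment$data))
})

test_that("constant input converges to the equilibrium of an independent root-finding oracle", {
  cc <- column_constants()
  C1 <- 90; C2 <- 100; K1 <- 2000; K2 <- 350; pconst <- 220
  # steady state reduced to (v1, v2): all derivatives zero implies
  #   y0 = (A/a) S(v), y1 = (A/a)(p + 0.8C S(C y0)),
  #   y2 = (B/b) 0.25C S(0.25C y0), y6 = (A/ad) K_in S(v_other)
  S <- function(v) 2 * cc$e0 / (1 + exp(cc$r * (cc$v0 - v)))
  resid <- function(v) {
    vres <- numeric(2)
    Cg <- c(C1, C2); Kin <- c(K2, K1)
    for (j in 1:2) {
      y0 <- (cc$A / cc$a) * S(v[j])
      y1 <- (cc$A / cc$a) * (pconst + 0.8 * Cg[j] * S(Cg[j] * y0))
      y2 <- (cc$B / cc$b) * 0.25 * Cg[j] * S(0.25 * Cg[j] * y0)
      y6 <- (cc$A / cc$ad) * Kin[j] * S(v[3 - j])
      vres[j] <- y1 + y6 - y2 - v[j]
    }
    sum(vres^2)
  }
  opt <- optim(c(100, 100), resid, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, resid, method = "BFGS",
               control = list(reltol = 1e-15))
  expect_lt(opt$value, 1e-12)
  n <- 6000
  seg <- simulate_double_column(double_column_params(C1, C2, K1, K2),
                                rep(pconst, n), rep(pconst, n), fs = 1000)
  expect_equal(unname(seg$data["u1", n]), opt$par[1], tolerance = 1e-5)
  expect_equal(unname(seg$data["u2", n]), opt$par[2], tolerance = 1e-5)
})

test_that("single column in the canonical regime is band-limited below 30 Hz", {
  sp <- stimulus_spec("control", duration = 4)
  seg <- simulate_single_column(135, make_noise_input(sp, 42), burn = 1)
  ps <- power_spectrum(seg, "u", spans = 11)
  expect_gt(sum(ps$power[ps$freq < 30]) / sum(ps$power), 0.9)
  expect_true(ps$freq[which.max(ps$power)] < 30)
})

test_that("8 Hz drive evokes a strong stimulus-frequency response, 44/84 Hz do not", {
  params <- double_column_params(85, 95, 2200, 300)
  band_power <- function(cond, f) {
    fix <- generate_inversion_fixture(params, stimulus_spec(cond), seed = 21)
    ps <- power_spectrum(fix$segment, "u1")
    list(band = mean(ps$power[ps$freq >= f - 1 & ps$freq <= f + 1]), ps = ps)
  }
  r8 <- band_power("8", 8)
  # local maximum at the stimulus frequency: the 8 Hz line dominates its
  # spectral neighbourhood
  near <- r8$ps$freq >= 5 & r8$ps$freq <= 11
  expect_equal(r8$ps$freq[near][which.max(r8$ps$power[near])], 8,
               tolerance = 0.51)
  # at 44/84 Hz the stimulus-frequency response is negligible in absolute
  # power (the PSP kernels low-pass the drive), the study's pattern of a
  # strong response only for the 8 Hz stimulus
  p44 <- band_power("44", 44)$band
  p84 <- band_power("84", 84)$band
  expect_gt(r8$band / p44, 10)
  expect_gt(r8$band / p84, 10)
})

test_that("power_spectrum satisfies Parseval and basic contracts", {
  set.seed(9)
  x <- rnorm(4000)
  seg <- signal_segment(matrix(x, 1), 1000, "w")
  ps <- power_spectrum(seg, "w")
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(sum(ps$power) * df, var(x), tolerance = 0.05)
  expect_true(all(ps$power >= 0))
  expect_true(max(ps$freq) <= 500 + 1e-9)
  # pure tone: argmax at the grid frequency nearest 8 Hz
  tone <- signal_segment(matrix(sin(2 * pi * 8 * (0:2999) / 1000), 1), 1000, "t")
  pst <- power_spectrum(tone, "t")
  expect_equal(pst$freq[which.max(pst$power)], 8, tolerance = 0.51)
  # zero signal: all-zero power
  z <- signal_segment(matrix(0, 1, 2000), 1000, "z")
  expect_true(all(power_spectrum(z, "z")$power == 0))
  expect_error(power_spectrum(tone, "nope"), "unknown channel")
  short <- signal_segment(matrix(rnorm(100), 1), 1000, "s")
  expect_error(power_spectrum(short, "s"), "at least 1 s")
})
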