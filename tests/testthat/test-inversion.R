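test_that("relative error matches its closed forms", {
  x <- rnorm(100)
  expect_equal(relative_error(x, x), 0)
  expect_equal(relative_error(c(3, 4), c(0, 0)), 1)
  expect_equal(relative_error(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(relative_error(c(0, 0), c(1, 1)), "zero norm")
  expect_error(relative_error(1:3, 1:4), "equal length")
})

test_that("fitness is zero at the generating truth and decomposes into channel REs", {
  fix <- tiny_fixture(seed = 11, duration = 1)
  U1 <- fix$segment$data["u1", ]; U2 <- fix$segment$data["u2", ]
  truth <- c(fix$true_params$C1, fix$true_params$C2,
             fix$true_params$K1, fix$true_params$K2)
  f0 <- dc_fitness(truth, U1, U2, fix$p, fix$p_prime)
  expect_lt(f0, 1e-10)
  # default rule = sum of independently computed channel REs
  cand <- truth + c(5, -5, 100, 50)
  seg <- simulate_double_column(double_column_params(cand[1], cand[2],
                                                     cand[3], cand[4]),
                                fix$p, fix$p_prime, burn = fix$burn)
  expect_equal(dc_fitness(cand, U1, U2, fix$p, fix$p_prime),
               relative_error(U1, seg$data["u1", ]) +
                 relative_error(U2, seg$data["u2", ]))
  # perturbing K1 from truth strictly increases fitness
  expect_gt(dc_fitness(truth + c(0, 0, 500, 0), U1, U2, fix$p, fix$p_prime), f0)
  expect_gt(dc_fitness(truth - c(0, 0, 500, 0), U1, U2, fix$p, fix$p_prime), f0)
})

test_that("PSO recovers the optimum of a convex objective within 1e-3", {
  target <- c(C1 = 77, C2 = 101, K1 = 2345.5, K2 = 432)
  obj <- function(x) sum(((x - target) / c(60, 60, 1500, 500))^2)
  res <- pso_optimize(obj, pso_config(Q = 40, G_max = 200, delta = 1e-18,
                                      D = 200), seed = 4)
  expect_lt(max(abs(res$par - target)), 1e-3)
  expect_lt(res$fitness, 1e-10)
})

test_that("PSO contracts are honoured: monotone trace, bounds, stagnation, determinism", {
  cfg <- pso_config(Q = 12, G_max = 40, D = 5)
  res <- pso_optimize(function(x) sum(x^2), cfg, seed = 1)
  expect_true(all(diff(res$trace) <= 0))
  b <- default_param_bounds()
  expect_true(all(res$par >= b$lower - 1e-12) && all(res$par <= b$upper + 1e-12))
  # constant objective: stagnation stops the run exactly D generations
  # beyond the initialization
  resc <- pso_optimize(function(x) 1, cfg, seed = 2)
  expect_identical(resc$generations, 5L)
  expect_length(resc$trace, 6L)
  # same seed -> identical trajectory; objective errors are penalized
  r1 <- pso_optimize(function(x) sum(x^2), cfg, seed = 9)
  r2 <- pso_optimize(function(x) sum(x^2), cfg, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$par, r2$par)
  rp <- pso_optimize(function(x) stop("boom"), pso_config(Q = 4, G_max = 2),
                     seed = 1)
  expect_equal(rp$fitness, pso_config()$penalty)
})

test_that("segment inversion recovers the generating parameters on a shared-noise fixture", {
  fix <- tiny_fixture(seed = 11)
  res <- invert_segment(fixture = fix,
                        config = pso_config(Q = 30, G_max = 40), seed = 99)
  expect_true(all(res$relative_error < 0.01))
  # K1 recovered within a pre-registered tolerance (pilot recovery study:
  # 10 seeds at these settings gave max |K1 error| < 60)
  expect_lt(abs(res$params$K1 - fix$true_params$K1), 100)
  b <- default_param_bounds()
  est <- c(res$params$C1, res$params$C2, res$params$K1, res$params$K2)
  expect_true(all(est >= b$lower & est <= b$upper))
  expect_equal(res$fitness, min(res$trace))
})

test_that("a mismatched stimulus model degrades the attainable fit", {
  fix <- tiny_fixture(condition = "control", seed = 17)
  U1 <- fix$segment$data["u1", ]; U2 <- fix$segment$data["u2", ]
  truth <- c(fix$true_params$C1, fix$true_params$C2,
             fix$true_params$K1, fix$true_params$K2)
  matched <- dc_fitness(truth, U1, U2, fix$p, fix$p_prime)
  sp8 <- stimulus_spec("8", duration = 4)
  p8 <- make_stimulus_input(sp8, fix$seed)      # same noise, wrong pulse model
  mismatched <- dc_fitness(truth, U1, U2, p8, fix$p_prime)
  expect_lt(matched, 1e-10)
  expect_gt(mismatched, 10 * (matched + 1e-12))
  expect_gt(mismatched, 0)
})

test_that("segment averaging is the per-parameter arithmetic mean", {
  mk <- function(K1) structure(list(params = double_column_params(80, 90, K1, 300),
                                    fitness = 0,
                                    relative_error = c(u1 = 0, u2 = 0),
                                    trace = 0, generations = 1,
                                    seeds = c(swarm = 1)),
                               class = "inversion_result")
  one <- average_segment_results(list(mk(1600)))
  expect_equal(one$K1, 1600)
  two <- average_segment_results(list(mk(1600), mk(2000)))
  expect_equal(two$K1, 1800)
  expect_equal(two$C1, 80)
  expect_error(average_segment_results(list()), "at least one")
})
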