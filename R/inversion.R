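#' Relative error between two series
#'
#' `RE = ||X - Y|| / ||X||` with the Euclidean norm; the fit-quality measure
#' used throughout the inversion.
#'
#' @param X reference series (non-zero norm).
#' @param Y candidate series, same length.
#' @return Non-negative scalar; zero iff `X == Y`.
#' @export
relative_error <- function(X, Y) {
  if (length(X) != length(Y))
    stop("X and Y must have equal length (", length(X), " vs ", length(Y), ")")
  nx <- sqrt(sum(X^2))
  if (nx == 0) stop("relative error undefined: reference series has zero norm")
  sqrt(sum((X - Y)^2)) / nx
}

#' PSO configuration
#'
#' Defaults follow the standard swarm settings used for the double-column
#' inversion: swarm size `Q = 60`, `G_max = 100` generations, attraction
#' constants `t1 = t2 = 2`, inertia decaying linearly from `w_start = 0.9`
#' to `w_end = 0.4` over the run, termination when the global best has
#' improved by less than `delta = 1e-6` for `D = 20` consecutive
#' generations.
#'
#' @param Q swarm size (>= 2).
#' @param G_max maximum number of generations (>= 1).
#' @param t1,t2 cognitive and social velocity constants.
#' @param w_start,w_end endpoints of the linear inertia schedule.
#' @param delta termination (stagnation) error.
#' @param D stagnation window in generations.
#' @param bounds list with numeric `lower` and `upper` vectors (equal
#'   length, `lower < upper`); defaults to [default_param_bounds()].
#' @param penalty fitness value assigned when the objective fails (e.g.
#'   a diverged simulation), so the swarm can continue.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(Q = 60, G_max = 100, t1 = 2, t2 = 2,
                       w_start = 0.9, w_end = 0.4,
                       delta = 1e-6, D = 20,
                       bounds = default_param_bounds(),
                       penalty = 1e6) {
  stopifnot(Q >= 2, G_max >= 1, delta > 0, D >= 1,
            length(bounds$lower) == length(bounds$upper),
            all(bounds$lower < bounds$upper))
  structure(list(Q = as.integer(Q), G_max = as.integer(G_max),
                 t1 = t1, t2 = t2, w_start = w_start, w_end = w_end,
                 delta = delta, D = as.integer(D), bounds = bounds,
                 penalty = penalty),
            class = "pso_config")
}

#' Particle swarm optimization over a box
#'
#' Standard global-best PSO. Velocities update as
#' `v <- w(u) v + t1 r1 (P_i - E_i) + t2 r2 (P_g - E_i)` with fresh uniform
#' `r1`, `r2` per component, positions as `E <- E + v`; components leaving
#' the box are clamped to the boundary and their velocity zeroed. Personal
#' and global bests keep the incumbent on ties. The run stops after `G_max`
#' generations or when the global best has improved by less than `delta`
#' for `D` consecutive generations.
#'
#' @param objective function of a numeric vector (length = number of
#'   bounded dimensions) returning a scalar; non-finite values are replaced
#'   by `config$penalty`.
#' @param config a [pso_config()].
#' @param seed integer seed; the whole trajectory is determined by
#'   (objective, config, seed).
#' @return A list of class `pso_result`: `par` (best position), `fitness`,
#'   `trace` (best fitness after initialization and after each generation),
#'   `generations`, `seed`.
#' @export
pso_optimize <- function(objective, config = pso_config(), seed) {
  stopifnot(inherits(config, "pso_config"))
  lo <- as.numeric(config$bounds$lower)
  hi <- as.numeric(config$bounds$upper)
  d <- length(lo)
  span <- hi - lo
  evalf <- function(x) {
    v <- tryCatch(objective(x), error = function(e) NA_real_)
    if (!is.finite(v)) config$penalty else v
  }
  with_seed(seed, {
    Q <- config$Q
    E <- matrix(stats::runif(Q * d, rep(lo, each = Q), rep(hi, each = Q)),
                nrow = Q)
    V <- matrix(stats::runif(Q * d, rep(-span, each = Q), rep(span, each = Q)),
                nrow = Q)
    fit <- apply(E, 1, evalf)
    P <- E
    Pfit <- fit
    gbest_i <- which.min(Pfit)
    Pg <- P[gbest_i, ]
    Pgfit <- Pfit[gbest_i]
    trace <- Pgfit
    stagnation <- 0L
    u <- 0L
    while (u < config$G_max) {
      u <- u + 1L
      w <- if (config$G_max > 1)
        config$w_start - (config$w_start - config$w_end) * (u - 1) / (config$G_max - 1)
      else config$w_start
      r1 <- matrix(stats::runif(Q * d), Q, d)
      r2 <- matrix(stats::runif(Q * d), Q, d)
      V <- w * V + config$t1 * r1 * (P - E) +
        config$t2 * r2 * (matrix(Pg, Q, d, byrow = TRUE) - E)
      E <- E + V
      for (j in seq_len(d)) {
        below <- E[, j] < lo[j]; above <- E[, j] > hi[j]
        E[below, j] <- lo[j]; E[above, j] <- hi[j]
        V[below | above, j] <- 0
      }
      fit <- apply(E, 1, evalf)
      improved <- fit < Pfit          # strict: incumbent kept on ties
      P[improved, ] <- E[improved, , drop = FALSE]
      Pfit[improved] <- fit[improved]
      prev <- Pgfit
      gbest_i <- which.min(Pfit)
      if (Pfit[gbest_i] < Pgfit) {    # strict: incumbent kept on ties
        Pg <- P[gbest_i, ]
        Pgfit <- Pfit[gbest_i]
      }
      trace <- c(trace, Pgfit)
      stagnation <- if ((prev - Pgfit) < config$delta) stagnation + 1L else 0L
      if (stagnation >= config$D) break
    }
    structure(list(par = stats::setNames(Pg, names(config$bounds$lower)),
                   fitness = Pgfit, trace = trace, generations = u,
                   seed = seed),
              class = "pso_result")
  })
}

#' Model-fit objective for a candidate coupling vector
#'
#' Simulates the double-column model at the candidate `(C1, C2, K1, K2)`
#' under the fixed drive `(p, p_prime)` (the shared-noise protocol: the
#' identical realization used for every candidate) and scores it against the
#' target channels. The default rule is the sum of the per-channel relative
#' errors; `"sse"` (sum of squared errors) and `"spectral"` (relative error
#' between raw periodograms) are available.
#'
#' @param candidate numeric vector `(C1, C2, K1, K2)`.
#' @param U1,U2 target channels (occipital, frontal), equal length.
#' @param p,p_prime fixed input realizations ([input_series()]), covering
#'   `burn + length(U1)/fs` seconds.
#' @param burn burn-in seconds discarded before comparison.
#' @param rule one of `"re_sum"`, `"sse"`, `"spectral"`.
#' @param constants1,constants2 fixed [column_constants()].
#' @param penalty value returned when the simulation diverges.
#' @return Non-negative scalar fitness; zero iff both channels fit exactly.
#' @export
dc_fitness <- function(candidate, U1, U2, p, p_prime, burn = 1,
                       rule = c("re_sum", "sse", "spectral"),
                       constants1 = column_constants(),
                       constants2 = column_constants(),
                       penalty = 1e6) {
  rule <- match.arg(rule)
  params <- double_column_params(candidate[[1]], candidate[[2]],
                                 candidate[[3]], candidate[[4]],
                                 constants1, constants2)
  seg <- tryCatch(simulate_double_column(params, p, p_prime, burn = burn),
                  error = function(e) NULL)
  if (is.null(seg)) return(penalty)
  u1 <- seg$data["u1", ]; u2 <- seg$data["u2", ]
  if (length(u1) != length(U1))
    stop("target length ", length(U1), " does not match simulated length ",
         length(u1), " (check burn and input duration)")
  switch(rule,
         re_sum = relative_error(U1, u1) + relative_error(U2, u2),
         sse = sum((U1 - u1)^2) + sum((U2 - u2)^2),
         spectral = {
           fs <- seg$fs
           ps <- function(x) stats::spec.pgram(stats::ts(x, frequency = fs),
                                               taper = 0, detrend = FALSE,
                                               plot = FALSE)$spec
           relative_error(ps(U1), ps(u1)) + relative_error(ps(U2), ps(u2))
         })
}

#' Invert one two-channel segment by PSO
#'
#' Estimates `(C1, C2, K1, K2)` from the occipital/frontal pair by particle
#' swarm optimization of [dc_fitness()] within the search box. Candidate
#' simulations are driven by a fixed noise realization: either the stored
#' inputs of a synthetic fixture or a seeded realization for real
#' recordings.
#'
#' @param U1,U2 target channels (numeric vectors) or pass `fixture`.
#' @param condition stimulus condition label (used to build the drive when
#'   no explicit inputs are given).
#' @param fixture optionally an `inversion_fixture`; its segment, stored
#'   noise and burn-in are used and `U1`/`U2`/`condition` may be omitted.
#' @param p,p_prime explicit fixed input realizations (override both).
#' @param noise_seed seed used to draw the fixed realization when none is
#'   supplied.
#' @param config a [pso_config()].
#' @param seed integer seed for the swarm.
#' @param fs sampling rate of `U1`/`U2` (default 1000).
#' @param burn burn-in seconds (default 1).
#' @param rule fitness combination rule, see [dc_fitness()].
#' @return A list of class `inversion_result`: `params`
#'   ([double_column_params()]), `fitness`, `relative_error` (named per
#'   channel), `trace`, `generations`, `seeds`.
#' @export
invert_segment <- function(U1 = NULL, U2 = NULL, condition = NULL,
                           fixture = NULL, p = NULL, p_prime = NULL,
                           noise_seed = 1L, config = pso_config(), seed,
                           fs = 1000, burn = 1, rule = "re_sum") {
  if (!is.null(fixture)) {
    stopifnot(inherits(fixture, "inversion_fixture"))
    U1 <- fixture$segment$data["u1", ]
    U2 <- fixture$segment$data["u2", ]
    p <- fixture$p; p_prime <- fixture$p_prime
    burn <- fixture$burn
    fs <- fixture$segment$fs
  }
  stopifnot(is.numeric(U1), is.numeric(U2), length(U1) == length(U2))
  if (is.null(p) || is.null(p_prime)) {
    if (is.null(condition)) stop("need a condition label to build the drive")
    sspec <- stimulus_spec(condition, duration = length(U1) / fs + burn,
                           fs = fs)
    p <- make_stimulus_input(sspec, noise_seed)
    p_prime <- make_noise_input(sspec, noise_seed + 1L)
  }
  obj <- function(x) dc_fitness(x, U1, U2, p, p_prime, burn = burn,
                                rule = rule, penalty = config$penalty)
  res <- pso_optimize(obj, config, seed)
  params <- double_column_params(res$par[[1]], res$par[[2]],
                                 res$par[[3]], res$par[[4]])
  seg <- simulate_double_column(params, p, p_prime, burn = burn)
  re <- c(u1 = relative_error(U1, seg$data["u1", ]),
          u2 = relative_error(U2, seg$data["u2", ]))
  structure(list(params = params, fitness = res$fitness,
                 relative_error = re, trace = res$trace,
                 generations = res$generations,
                 seeds = c(swarm = seed)),
            class = "inversion_result")
}

#' Average inversion results across segments
#'
#' The per-subject estimate: the arithmetic mean of each coupling across
#' the segment-level inversions.
#'
#' @param results non-empty list of `inversion_result` objects.
#' @return A [double_column_params()] with the averaged couplings (constants
#'   taken from the first result).
#' @export
average_segment_results <- function(results) {
  if (length(results) == 0) stop("need at least one inversion result")
  for (r in results) stopifnot(inherits(r, "inversion_result"))
  m <- rowMeans(vapply(results, function(r)
    c(r$params$C1, r$params$C2, r$params$K1, r$params$K2), numeric(4)))
  first <- results[[1]]$params
  double_column_params(m[1], m[2], m[3], m[4],
                       first$constants1, first$constants2)
}
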