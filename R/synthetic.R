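#' Stimulus specification
#'
#' Describes the external drive fed to the occipital column: uniform white
#' noise (pulse density, default range 120-320 per second) with, for the
#' flicker conditions, a periodic pulse train at the stimulus frequency
#' added on top. The resting control condition is pure noise.
#'
#' @param condition one of `"control"`, `"8"`, `"44"`, `"84"` (Hz).
#' @param pulse_amplitude drive increment of the pulse train (default 7.0).
#' @param noise_range two-element range of the uniform noise floor.
#' @param duration seconds (default 3).
#' @param fs sampling rate in Hz (default 1000).
#' @param duty pulse duty cycle in (0, 1); default 0.5 (square wave at half
#'   the stimulus period).
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(condition = c("control", "8", "44", "84"),
                          pulse_amplitude = 7.0, noise_range = c(120, 320),
                          duration = 3, fs = 1000, duty = 0.5) {
  condition <- as.character(condition)
  condition <- match.arg(condition)
  stopifnot(length(noise_range) == 2, noise_range[1] < noise_range[2],
            duration > 0, fs > 0, duty > 0, duty < 1, pulse_amplitude >= 0)
  structure(list(condition = condition, pulse_amplitude = pulse_amplitude,
                 noise_range = noise_range, duration = duration, fs = fs,
                 duty = duty),
            class = "stimulus_spec")
}

#' Frequency in Hz of a condition label (0 for control)
#' @param condition condition label.
#' @return numeric frequency, Hz.
#' @export
condition_frequency <- function(condition) {
  condition <- as.character(condition)
  if (!condition %in% c("control", "8", "44", "84"))
    stop("unsupported condition '", condition,
         "'; expected control, 8, 44 or 84")
  if (condition == "control") 0 else as.numeric(condition)
}

#' Generate the pulse-density input for a condition
#'
#' Control: one uniform draw in `noise_range` per sample. Flicker
#' conditions: the same noise plus a square pulse train at the condition
#' frequency (amplitude `pulse_amplitude`, duty cycle `duty`, first onset at
#' t = 0).
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed; the series is fully determined by (spec, seed).
#' @return An [input_series()].
#' @export
make_stimulus_input <- function(spec, seed) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  f <- condition_frequency(spec$condition)
  vals <- with_seed(seed, stats::runif(n, spec$noise_range[1], spec$noise_range[2]))
  if (f > 0) {
    t <- (seq_len(n) - 1) / spec$fs
    phase <- (t * f) %% 1
    vals <- vals + spec$pulse_amplitude * (phase < spec$duty)
  }
  input_series(vals, spec$fs)
}

#' Pure white-noise drive (frontal input p')
#'
#' @param spec a [stimulus_spec()] (noise range, duration, fs are used).
#' @param seed integer seed.
#' @return An [input_series()] of uniform noise in `noise_range`.
#' @export
make_noise_input <- function(spec, seed) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  vals <- with_seed(seed, stats::runif(n, spec$noise_range[1], spec$noise_range[2]))
  input_series(vals, spec$fs)
}

# evaluate expr under a local RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a two-channel inversion fixture with known parameters
#'
#' Simulates the double-column model under a stimulus condition and stores
#' the exact noise realizations used, so that inversion can re-simulate
#' candidates under the identical drive (shared-noise protocol). A 1 s
#' burn-in is prepended and discarded, so the returned segment covers
#' `spec$duration` seconds of steady-state activity.
#'
#' @param true_params a [double_column_params()] (the generating truth).
#' @param spec a [stimulus_spec()].
#' @param seed integer seed.
#' @param burn burn-in seconds discarded before the analysis window.
#' @return A list of class `inversion_fixture` with elements `segment`
#'   (2-channel [signal_segment()]), `p`, `p_prime` (the stored
#'   [input_series()] including burn-in), `true_params`, `burn`, `spec`,
#'   `seed`.
#' @export
generate_inversion_fixture <- function(true_params, spec, seed, burn = 1) {
  stopifnot(inherits(true_params, "double_column_params"),
            inherits(spec, "stimulus_spec"))
  full_spec <- spec
  full_spec$duration <- spec$duration + burn
  p <- make_stimulus_input(full_spec, seed)
  p_prime <- make_noise_input(full_spec, seed + 1L)
  segment <- simulate_double_column(true_params, p, p_prime, burn = burn)
  structure(list(segment = segment, p = p, p_prime = p_prime,
                 true_params = true_params, burn = burn, spec = spec,
                 seed = seed),
            class = "inversion_fixture")
}

#' Generate a stationary VAR realization with known structure
#'
#' Simulates `x(n) = sum_r A_r x(n - r) + w(n)` with independent Gaussian
#' innovations, after checking stationarity via the companion-form spectral
#' radius. 500 burn-in samples are discarded.
#'
#' @param coefficients list of N x N lag matrices `A_r`, r = 1..p;
#'   `A_r[i, j]` maps source channel j at lag r onto target channel i.
#' @param innovation_sd per-channel innovation standard deviations
#'   (recycled to N).
#' @param n_samples samples to return.
#' @param seed integer seed.
#' @param fs nominal sampling rate attached to the segment (default 1000).
#' @param labels channel labels.
#' @return A [signal_segment()] with N channels.
#' @export
generate_var_fixture <- function(coefficients, innovation_sd = 1,
                                 n_samples, seed, fs = 1000,
                                 labels = NULL) {
  stopifnot(is.list(coefficients), length(coefficients) >= 1)
  N <- nrow(coefficients[[1]])
  for (A in coefficients)
    stopifnot(is.matrix(A), nrow(A) == N, ncol(A) == N)
  p <- length(coefficients)
  rho <- var_spectral_radius(coefficients)
  if (rho >= 1)
    stop(sprintf("unstable VAR coefficients: companion spectral radius %.4f >= 1",
                 rho))
  innovation_sd <- rep_len(innovation_sd, N)
  if (is.null(labels)) labels <- rownames(coefficients[[1]])
  if (is.null(labels)) labels <- paste0("ch", seq_len(N))
  burn <- 500L
  ntot <- n_samples + burn + p
  x <- with_seed(seed, {
    w <- matrix(stats::rnorm(N * ntot, sd = innovation_sd), nrow = N)
    x <- matrix(0, N, ntot)
    for (t in (p + 1):ntot) {
      acc <- w[, t]
      for (r in seq_len(p)) acc <- acc + coefficients[[r]] %*% x[, t - r]
      x[, t] <- acc
    }
    x
  })
  signal_segment(x[, (burn + p + 1):ntot, drop = FALSE], fs, labels)
}

#' Companion-form spectral radius of a VAR coefficient set
#' @param coefficients list of N x N lag matrices.
#' @return largest eigenvalue modulus of the companion matrix.
#' @export
var_spectral_radius <- function(coefficients) {
  N <- nrow(coefficients[[1]])
  p <- length(coefficients)
  comp <- matrix(0, N * p, N * p)
  for (r in seq_len(p))
    comp[1:N, ((r - 1) * N + 1):(r * N)] <- coefficients[[r]]
  if (p > 1)
    comp[(N + 1):(N * p), 1:(N * (p - 1))] <- diag(N * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Study fixture specification
#'
#' The emulated multi-subject SSVEP study: `subjects` animals, the four
#' stimulus conditions, `segments` 3 s segments per condition at 1000 Hz.
#' Per subject and condition a true double-column parameter set is drawn
#' (mid-box values plus per-subject and per-cell jitter) with K1 elevated by
#' `k1_effect` in the 8 Hz condition; per subject and condition a 6-channel
#' VAR generator over the visual-cortex/frontal montage is built with the
#' VC -> FA coupling elevated by `flow_effect` in the 8 Hz condition.
#'
#' @param subjects number of subjects (default 10).
#' @param conditions condition labels (default the four study conditions).
#' @param segments segments per subject x condition (default 5).
#' @param duration,fs segment duration (s) and sampling rate (Hz).
#' @param k1_effect added to the K1 baseline in the 8 Hz condition
#'   (default 500).
#' @param flow_effect added to the VC -> FA VAR coupling in the 8 Hz
#'   condition (default 0.12).
#' @param subject_sd standard deviations of the per-subject parameter
#'   jitter, named (C1, C2, K1, K2).
#' @param cell_sd standard deviations of the per-cell (subject x condition)
#'   jitter, same names.
#' @param seed integer master seed; every segment is reproducible from it.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(subjects = 10,
                       conditions = c("control", "8", "44", "84"),
                       segments = 5, duration = 3, fs = 1000,
                       k1_effect = 500, flow_effect = 0.12,
                       subject_sd = c(C1 = 5, C2 = 5, K1 = 120, K2 = 40),
                       cell_sd = c(C1 = 3, C2 = 3, K1 = 60, K2 = 20),
                       seed = 1L) {
  stopifnot(subjects >= 2, segments >= 1, duration > 0, fs > 0)
  structure(list(subjects = subjects, conditions = as.character(conditions),
                 segments = segments, duration = duration, fs = fs,
                 k1_effect = k1_effect, flow_effect = flow_effect,
                 subject_sd = subject_sd, cell_sd = cell_sd,
                 seed = as.integer(seed)),
            class = "study_spec")
}

# baseline (mid-box) truth used by the study generator
study_baseline <- function() c(C1 = 90, C2 = 90, K1 = 2000, K2 = 350)

# 6-channel montage of the flow analysis
#' Default electrode-group map: visual cortex and frontal area
#' @return list with elements `VC` (V1_L, V1_R, V2_L, V2_R) and `FA`
#'   (FrA_L, FrA_R).
#' @export
default_electrode_groups <- function() {
  list(VC = c("V1_L", "V1_R", "V2_L", "V2_R"), FA = c("FrA_L", "FrA_R"))
}

# VAR(1) generator over the 6-channel montage with a planted VC -> FA
# coupling strength `vcfa`
study_var_coefficients <- function(vcfa) {
  groups <- default_electrode_groups()
  labels <- c(groups$VC, groups$FA)
  N <- length(labels)
  A1 <- matrix(0, N, N, dimnames = list(labels, labels))
  diag(A1) <- 0.4
  # weak within-group lagged interactions
  for (g in groups) for (i in g) for (j in g) if (i != j) A1[i, j] <- 0.05
  # directed VC -> FA coupling (target rows FA, source columns VC)
  A1[groups$FA, groups$VC] <- A1[groups$FA, groups$VC] + vcfa
  # weak constant feedback FA -> VC
  A1[groups$VC, groups$FA] <- A1[groups$VC, groups$FA] + 0.03
  list(A1)
}

#' Generate the emulated study
#'
#' Produces, for every subject x condition x segment, a two-channel
#' double-column recording (for model inversion) and a 6-channel VAR
#' recording over the VC/FA montage (for the PDC analysis), together with a
#' manifest of every true parameter and seed. When `dir` is given the
#' segments are written as delimited text with JSON sidecars plus a
#' `manifest.json`; the fixture is always returned in memory as well.
#'
#' @param spec a [study_spec()].
#' @param dir optional output directory; must not already contain files
#'   unless `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return A list of class `study_fixture` with `spec`, `manifest`
#'   (data.frame: subject, condition, segment, seeds, true parameters,
#'   planted VC->FA coupling) and `segments` (nested list
#'   `[[subject]][[condition]][[segment]]`, each with elements `model`
#'   and `var`).
#' @export
generate_study_fixture <- function(spec = study_spec(), dir = NULL,
                                   overwrite = FALSE) {
  stopifnot(inherits(spec, "study_spec"))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
      stop("output directory ", dir,
           " is not empty; pass overwrite = TRUE to reuse it")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  base <- study_baseline()
  bounds <- default_param_bounds()
  nsub <- spec$subjects
  conds <- spec$conditions
  nseg <- spec$segments

  # deterministic sub-seed table drawn once from the master seed
  nneed <- nsub * (4 + length(conds) * (4 + nseg * 2 + 1))
  subseeds <- with_seed(spec$seed,
                         sample.int(.Machine$integer.max, nneed))
  k <- 0L
  nxt <- function() { k <<- k + 1L; subseeds[k] }

  manifest <- list()
  segments <- vector("list", nsub)
  for (s in seq_len(nsub)) {
    subj_jit <- vapply(names(base), function(nm)
      with_seed(nxt(), stats::rnorm(1, 0, spec$subject_sd[[nm]])),
      numeric(1))
    segments[[s]] <- stats::setNames(vector("list", length(conds)), conds)
    for (cond in conds) {
      cell_jit <- vapply(names(base), function(nm)
        with_seed(nxt(), stats::rnorm(1, 0, spec$cell_sd[[nm]])),
        numeric(1))
      truth <- base + subj_jit + cell_jit
      if (cond == "8") truth["K1"] <- truth["K1"] + spec$k1_effect
      truth <- pmin(pmax(truth, bounds$lower), bounds$upper)
      params <- double_column_params(truth[["C1"]], truth[["C2"]],
                                     truth[["K1"]], truth[["K2"]])
      vcfa <- 0.03 + if (cond == "8") spec$flow_effect else 0
      vcfa_jit <- with_seed(nxt(), stats::rnorm(1, 0, 0.01))
      vcfa <- max(0, vcfa + vcfa_jit)
      coefs <- study_var_coefficients(vcfa)
      sspec <- stimulus_spec(cond, duration = spec$duration, fs = spec$fs)
      seglist <- vector("list", nseg)
      for (g in seq_len(nseg)) {
        seed_model <- nxt(); seed_var <- nxt()
        fix <- generate_inversion_fixture(params, sspec, seed_model)
        varseg <- generate_var_fixture(coefs, innovation_sd = 1,
                                       n_samples = spec$duration * spec$fs,
                                       seed = seed_var, fs = spec$fs,
                                       labels = rownames(coefs[[1]]))
        seglist[[g]] <- list(model = fix, var = varseg)
        manifest[[length(manifest) + 1L]] <- data.frame(
          subject = s, condition = cond, segment = g,
          seed_model = seed_model, seed_var = seed_var,
          C1 = truth[["C1"]], C2 = truth[["C2"]],
          K1 = truth[["K1"]], K2 = truth[["K2"]], vcfa = vcfa)
      }
      segments[[s]][[cond]] <- seglist
    }
  }
  manifest <- do.call(rbind, manifest)
  fixture <- structure(list(spec = spec, manifest = manifest,
                            segments = segments),
                       class = "study_fixture")
  if (!is.null(dir)) {
    for (i in seq_len(nrow(manifest))) {
      row <- manifest[i, ]
      stem <- sprintf("s%02d_%s_seg%d", row$subject, row$condition,
                      row$segment)
      seg <- segments[[row$subject]][[row$condition]][[row$segment]]
      write_segment(seg$model$segment, file.path(dir, paste0(stem, "_model.tsv")))
      write_segment(seg$var, file.path(dir, paste0(stem, "_var.tsv")))
    }
    spec_out <- unclass(spec)
    spec_out$subject_sd <- as.list(spec_out$subject_sd)
    spec_out$cell_sd <- as.list(spec_out$cell_sd)
    jsonlite::write_json(
      list(spec = spec_out, manifest = manifest),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  fixture
}

#' Read back a study manifest written by [generate_study_fixture()]
#' @param dir fixture directory containing `manifest.json`.
#' @return list with `spec` and `manifest` (data.frame).
#' @export
read_study_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- m$spec
  sp$subject_sd <- unlist(sp$subject_sd)
  sp$cell_sd <- unlist(sp$cell_sd)
  sp$conditions <- as.character(unlist(sp$conditions))
  m$spec <- do.call(study_spec, sp)
  m
}
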