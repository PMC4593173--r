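#' Physiological constants of one cortical column
#'
#' Fixed constants of a Jansen-Rit cortical column. Defaults are the
#' literature values of the original model: EPSP/IPSP gains `A`/`B` (mV) set
#' the maximum amplitudes of the excitatory and inhibitory postsynaptic
#' potentials; `a`/`b` (1/s) their rate constants; `e0` (1/s), `v0` (mV) and
#' `r` (1/mV) parameterize the potential-to-rate sigmoid (maximum firing
#' rate 2*e0, threshold v0, steepness r); `ad` (1/s) is the rate constant of
#' the delay kernel carrying information between the two columns.
#'
#' @param A EPSP gain in mV.
#' @param B IPSP gain in mV.
#' @param a excitatory rate constant, 1/s.
#' @param b inhibitory rate constant, 1/s.
#' @param e0 half of the maximum firing rate, 1/s.
#' @param v0 sigmoid threshold potential, mV.
#' @param r sigmoid steepness, 1/mV.
#' @param ad inter-column delay rate constant, 1/s.
#' @return A named list of class `column_constants`.
#' @export
column_constants <- function(A = 3.25, B = 22, a = 100, b = 50,
                             e0 = 2.5, v0 = 6, r = 0.56, ad = 33) {
  vals <- list(A = A, B = B, a = a, b = b, e0 = e0, v0 = v0, r = r, ad = ad)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constant '", nm, "' must be a single positive finite number")
  }
  if (a <= b)
    stop("excitatory kinetics must be faster than inhibitory (a > b); got a = ",
         a, ", b = ", b)
  structure(vals, class = "column_constants")
}

#' Free parameters of the coupled double-column model
#'
#' `C1` and `C2` are the global intra-column connectivity constants of
#' column 1 (occipital) and column 2 (frontal): the total number of synapses
#' the interneurons establish within the column, from which the four
#' sub-connectivities are derived as (C, 0.8C, 0.25C, 0.25C). `K1` scales
#' the pyramidal output of column 1 entering column 2 (occipital -> frontal
#' information flow), `K2` the reverse.
#'
#' @param C1,C2 intra-column connectivity, dimensionless.
#' @param K1 coupling gain column 1 -> column 2, dimensionless.
#' @param K2 coupling gain column 2 -> column 1, dimensionless.
#' @param constants1,constants2 fixed [column_constants()] of each column.
#' @return An object of class `double_column_params`.
#' @export
double_column_params <- function(C1, C2, K1, K2,
                                 constants1 = column_constants(),
                                 constants2 = column_constants()) {
  for (nm in c("C1", "C2", "K1", "K2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative finite number")
  }
  stopifnot(inherits(constants1, "column_constants"),
            inherits(constants2, "column_constants"))
  structure(list(C1 = C1, C2 = C2, K1 = K1, K2 = K2,
                 constants1 = constants1, constants2 = constants2),
            class = "double_column_params")
}

#' @export
print.double_column_params <- function(x, ...) {
  cat(sprintf("<double_column_params> C1 = %.3f, C2 = %.3f, K1 = %.3f, K2 = %.3f\n",
              x$C1, x$C2, x$K1, x$K2))
  invisible(x)
}

#' Default inversion search box for (C1, C2, K1, K2)
#'
#' The boundaries within which the couplings are estimated:
#' C1, C2 in \[60, 120\], K1 in \[1500, 3000\], K2 in \[100, 600\].
#'
#' @return A list with numeric `lower` and `upper` vectors named
#'   C1, C2, K1, K2.
#' @export
default_param_bounds <- function() {
  list(lower = c(C1 = 60, C2 = 60, K1 = 1500, K2 = 100),
       upper = c(C1 = 120, C2 = 120, K1 = 3000, K2 = 600))
}

#' Potential-to-rate sigmoid
#'
#' Converts mean membrane potential to population firing rate:
#' `Sigm(v) = 2*e0 / (1 + exp(r*(v0 - v)))`. Strictly increasing, bounded in
#' (0, 2*e0), equal to `e0` at `v = v0`.
#'
#' @param v membrane potential, mV (vectorized).
#' @param constants a [column_constants()].
#' @return Firing rate(s), 1/s.
#' @export
jr_sigmoid <- function(v, constants = column_constants()) {
  stopifnot(inherits(constants, "column_constants"))
  2 * constants$e0 / (1 + exp(constants$r * (constants$v0 - v)))
}

#' Pulse-density input series
#'
#' @param values numeric vector, pulse-density drive per sample (1/s).
#' @param fs sampling rate, Hz.
#' @return An object of class `input_series` with fields `values`, `fs`,
#'   `duration` (seconds).
#' @export
input_series <- function(values, fs) {
  stopifnot(is.numeric(values), length(values) > 0, fs > 0)
  structure(list(values = as.numeric(values), fs = fs,
                 duration = length(values) / fs),
            class = "input_series")
}

#' Simulate the coupled double-column model
#'
#' Integrates the coupled two-column Jansen-Rit system with fixed-step
#' 4th-order Runge-Kutta, starting from the all-zero state, with inputs held
#' constant within each sample. The recorded outputs are the pyramidal-cell
#' membrane potentials u1 (column 1, occipital) and u2 (column 2, frontal):
#' the sum of the excitatory feedback and inter-column PSPs minus the
#' inhibitory PSP.
#'
#' @param params a [double_column_params()].
#' @param p input drive of column 1, an [input_series()] (or numeric vector).
#' @param p_prime input drive of column 2, same length and rate as `p`.
#' @param dt integration step in seconds; must divide the sample interval
#'   `1/fs` into an integer number of substeps (default `1/fs`).
#' @param burn seconds to discard from the start of the output (transient
#'   removal; the integration still starts from the zero state).
#' @param fs sampling rate; taken from `p` when it is an [input_series()].
#' @return A two-channel [signal_segment()] with labels `u1`, `u2`.
#' @export
simulate_double_column <- function(params, p, p_prime, dt = NULL, burn = 0,
                                   fs = NULL) {
  stopifnot(inherits(params, "double_column_params"))
  if (inherits(p, "input_series")) { fs <- p$fs; p <- p$values }
  if (inherits(p_prime, "input_series")) {
    if (!is.null(fs) && p_prime$fs != fs) stop("p and p_prime must share fs")
    p_prime <- p_prime$values
  }
  if (is.null(fs)) stop("fs must be given when inputs are plain vectors")
  if (length(p) != length(p_prime))
    stop("p and p_prime must have equal length")
  if (is.null(dt)) dt <- 1 / fs
  substeps <- (1 / fs) / dt
  if (abs(substeps - round(substeps)) > 1e-8)
    stop("dt must divide the sample interval 1/fs evenly")
  substeps <- as.integer(round(substeps))
  burn_samples <- as.integer(round(burn * fs))
  out <- dc_simulate_cpp(params$C1, params$C2, params$K1, params$K2,
                         unclass(params$constants1), unclass(params$constants2),
                         p, p_prime, fs, substeps, burn_samples)
  if (isTRUE(attr(out, "diverged")))
    stop(sprintf(paste0("double-column integration diverged for parameter set ",
                        "C1 = %.4g, C2 = %.4g, K1 = %.4g, K2 = %.4g"),
                 params$C1, params$C2, params$K1, params$K2))
  signal_segment(out, fs, c("u1", "u2"))
}

#' Simulate a single uncoupled column
#'
#' Convenience wrapper: one Jansen-Rit column driven by `p`, i.e. the
#' double-column system with both coupling gains zero, returning only its
#' output channel.
#'
#' @param C global connectivity constant (canonical literature value 135).
#' @param p input drive, an [input_series()] or numeric vector.
#' @param constants fixed [column_constants()].
#' @inheritParams simulate_double_column
#' @return A one-channel [signal_segment()] with label `u`.
#' @export
simulate_single_column <- function(C, p, constants = column_constants(),
                                   dt = NULL, burn = 0, fs = NULL) {
  params <- double_column_params(C1 = C, C2 = C, K1 = 0, K2 = 0,
                                 constants1 = constants,
                                 constants2 = constants)
  if (inherits(p, "input_series")) { fs <- p$fs; p <- p$values }
  seg <- simulate_double_column(params, p, rep(0, length(p)), dt = dt,
                                burn = burn, fs = fs)
  signal_segment(seg$data["u1", , drop = FALSE], seg$fs, "u")
}

#' Raw periodogram of one channel
#'
#' Power spectrum via the raw periodogram (no taper, no smoothing unless
#' requested), scaled so that the sum of the returned power values times the
#' frequency step approximates the time-domain variance of the channel
#' (one-sided convention).
#'
#' @param segment a [signal_segment()] with at least one second of data.
#' @param channel channel label.
#' @param spans optional smoothing spans passed to [stats::spec.pgram()].
#' @return A list with `freq` (Hz, from ~0 to fs/2) and `power`
#'   (non-negative).
#' @export
power_spectrum <- function(segment, channel, spans = NULL) {
  stopifnot(inherits(segment, "signal_segment"))
  x <- segment_channel(segment, channel)
  if (length(x) < segment$fs)
    stop("need at least 1 s of data (", segment$fs, " samples at fs = ",
         segment$fs, " Hz)")
  if (stats::var(x) == 0) {
    # spec.pgram rejects constant series; a constant signal has no power at
    # any non-zero frequency
    n <- length(x)
    freq <- seq_len(floor(n / 2)) / n * segment$fs
    return(list(freq = freq, power = rep(0, length(freq))))
  }
  sp <- stats::spec.pgram(stats::ts(x, frequency = segment$fs), taper = 0,
                          detrend = FALSE, plot = FALSE, spans = spans)
  # spec.pgram returns a two-sided density in cycles per time unit; fold to
  # a one-sided convention so that sum(power) * df ~ var(x)
  list(freq = sp$freq, power = 2 * sp$spec)
}
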