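#' Fit a multivariate autoregressive model by least squares
#'
#' Ordinary least squares on the stacked regression
#' `x(n) = sum_r A_r x(n - r) + w(n)`, per segment, after removing each
#' channel's mean. `A_r[i, j]` is the linear effect of channel j at lag r
#' onto channel i at lag 0.
#'
#' @param segment a [signal_segment()] with N channels.
#' @param p model order (number of lags).
#' @return A list of class `mvar_model`: `order`, `A` (array N x N x p),
#'   `sigma` (innovation covariance, maximum-likelihood scaling), `labels`,
#'   `fs`, `nobs` (effective observations used).
#' @export
fit_mvar <- function(segment, p) {
  stopifnot(inherits(segment, "signal_segment"), p >= 1)
  X <- segment$data
  N <- nrow(X); n <- ncol(X)
  if (n <= N * p + p)
    stop("too few samples (", n, ") for N = ", N, ", p = ", p,
         " (need more than N*p + p)")
  X <- X - rowMeans(X)
  Teff <- n - p
  # design: rows = time points p+1..n, cols = N*p lagged values
  Z <- matrix(0, Teff, N * p)
  for (r in seq_len(p))
    Z[, ((r - 1) * N + 1):(r * N)] <- t(X[, (p + 1 - r):(n - r), drop = FALSE])
  Y <- t(X[, (p + 1):n, drop = FALSE])
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    # identify channels implicated in the deficiency for the error message
    bad <- unique(((qrz$pivot[(qrz$rank + 1):ncol(Z)] - 1) %% N) + 1)
    stop("rank-deficient regressor matrix; linearly dependent channel(s): ",
         paste(segment$labels[bad], collapse = ", "))
  }
  B <- qr.coef(qrz, Y)                     # (N*p) x N, column = target channel
  res <- Y - Z %*% B
  sigma <- crossprod(res) / Teff
  A <- array(0, c(N, N, p),
             dimnames = list(segment$labels, segment$labels, NULL))
  for (r in seq_len(p))
    A[, , r] <- t(B[((r - 1) * N + 1):(r * N), , drop = FALSE])
  dimnames(sigma) <- list(segment$labels, segment$labels)
  structure(list(order = p, A = A, sigma = sigma, labels = segment$labels,
                 fs = segment$fs, nobs = Teff),
            class = "mvar_model")
}

#' Select the MVAR order by AIC
#'
#' Fits every order in `p_min:p_max` and returns the order minimizing the
#' multivariate AIC `log det(Sigma) + 2 p N^2 / T`, where `Sigma` is the
#' ML innovation covariance and `T` the effective sample size of that fit.
#' Ties resolve to the smallest order.
#'
#' @param segment a [signal_segment()].
#' @param p_min,p_max search range (defaults 5 and 20).
#' @return A list with `order` (the argmin) and `aic` (named numeric vector
#'   over the whole range).
#' @export
select_order_aic <- function(segment, p_min = 5, p_max = 20) {
  stopifnot(p_min >= 1, p_max >= p_min)
  orders <- p_min:p_max
  aic <- vapply(orders, function(p) {
    m <- fit_mvar(segment, p)
    N <- length(m$labels)
    determinant(m$sigma, logarithm = TRUE)$modulus[1] + 2 * p * N^2 / m$nobs
  }, numeric(1))
  names(aic) <- orders
  list(order = orders[which.min(aic)], aic = aic)
}

#' Partial directed coherence spectrum of a fitted MVAR model
#'
#' Computes `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)` and the
#' column-normalized PDC magnitudes
#' `pi_ij(f) = |Abar_ij(f)| / sqrt(sum_k |Abar_kj(f)|^2)`, so that
#' `pi_ij(f)` quantifies the directed influence of source channel j onto
#' target channel i and `sum_i pi_ij(f)^2 = 1` for every source j and
#' frequency f.
#'
#' @param model an `mvar_model` from [fit_mvar()].
#' @param freqs frequency grid in Hz, within (0, fs/2); default 1 Hz steps
#'   from 1 to fs/2.
#' @param fs sampling rate (default the model's).
#' @return A list of class `pdc_spectrum`: `freq`, `pi` (array
#'   N x N x F of magnitudes in \[0, 1\], target x source x frequency),
#'   `labels`.
#' @export
pdc_spectrum <- function(model, freqs = NULL, fs = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  if (is.null(fs)) fs <- model$fs
  if (is.null(freqs)) freqs <- seq(1, fs / 2, by = 1)
  stopifnot(all(freqs > 0), all(freqs <= fs / 2))
  N <- length(model$labels)
  p <- model$order
  out <- array(NA_real_, c(N, N, length(freqs)),
               dimnames = list(model$labels, model$labels, NULL))
  for (k in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[k] * seq_len(p) / fs)
    Abar <- diag(N) + 0i
    for (r in seq_len(p)) Abar <- Abar - model$A[, , r] * z[r]
    denom <- sqrt(colSums(Mod(Abar)^2))
    if (any(denom == 0))
      stop("degenerate model: zero PDC denominator at f = ", freqs[k], " Hz")
    out[, , k] <- sweep(Mod(Abar), 2, denom, "/")
  }
  structure(list(freq = freqs, pi = out, labels = model$labels),
            class = "pdc_spectrum")
}

#' Band-averaged directed-flow matrix
#'
#' Averages the PDC magnitude over the grid frequencies inside `band`
#' (inclusive), yielding the N x N directed flow-strength matrix
#' (target x source, entries in \[0, 1\]).
#'
#' @param spectrum a `pdc_spectrum`.
#' @param band two-element frequency band in Hz (default `c(6, 92)`).
#' @return N x N numeric matrix, entry (i, j) = mean PDC strength of the
#'   flow j -> i over the band.
#' @export
band_average <- function(spectrum, band = c(6, 92)) {
  stopifnot(inherits(spectrum, "pdc_spectrum"), length(band) == 2)
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel))
    stop("band [", band[1], ", ", band[2],
         "] Hz contains no grid frequencies")
  apply(spectrum$pi[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Aggregate a flow matrix into the four area-level strengths
#'
#' Sums the band-averaged directed strengths over the ordered electrode
#' pairs between and within the visual-cortex (VC) and frontal-area (FA)
#' groups. With 4 VC and 2 FA electrodes: VC -> FA and FA -> VC each sum 8
#' ordered pairs, within-FA sums 2, within-VC sums 12; self-loops are
#' excluded.
#'
#' @param flow_matrix N x N matrix, target x source, with channel labels as
#'   dimnames (as returned by [band_average()]).
#' @param groups list with character vectors `VC` and `FA`; defaults to
#'   [default_electrode_groups()]. Groups must be disjoint and present in
#'   the matrix labels.
#' @return A list of class `flow_summary` with `vc_to_fa`, `fa_to_vc`,
#'   `within_vc`, `within_fa`.
#' @export
aggregate_flows <- function(flow_matrix, groups = default_electrode_groups()) {
  labels <- rownames(flow_matrix)
  if (is.null(labels) || !identical(labels, colnames(flow_matrix)))
    stop("flow_matrix needs identical row/column channel labels")
  missing <- setdiff(c(groups$VC, groups$FA), labels)
  if (length(missing))
    stop("group label(s) not in flow matrix: ", paste(missing, collapse = ", "))
  if (length(intersect(groups$VC, groups$FA)))
    stop("electrode groups VC and FA must be disjoint")
  within <- function(g) {
    sub <- flow_matrix[g, g, drop = FALSE]
    sum(sub) - sum(diag(sub))
  }
  structure(list(
    vc_to_fa = sum(flow_matrix[groups$FA, groups$VC]),  # targets FA, sources VC
    fa_to_vc = sum(flow_matrix[groups$VC, groups$FA]),
    within_vc = within(groups$VC),
    within_fa = within(groups$FA)),
    class = "flow_summary")
}

#' Full segment-level PDC flow analysis
#'
#' Convenience chain: order selection by AIC (range `p_min:p_max`), MVAR
#' fit, PDC spectrum on a 1 Hz grid, band average, and area aggregation.
#'
#' @param segment a [signal_segment()] restricted to the analysis montage.
#' @param band averaging band in Hz (default `c(6, 92)`).
#' @param groups electrode-group map, see [aggregate_flows()].
#' @param p_min,p_max AIC search range; set `p_min == p_max` to fix the
#'   order.
#' @return A list with `order`, `flow_matrix` and `flows`
#'   (a `flow_summary`).
#' @export
segment_flows <- function(segment, band = c(6, 92),
                          groups = default_electrode_groups(),
                          p_min = 5, p_max = 20) {
  ord <- if (p_min == p_max) list(order = p_min)
         else select_order_aic(segment, p_min, p_max)
  model <- fit_mvar(segment, ord$order)
  spec <- pdc_spectrum(model)
  fm <- band_average(spec, band)
  list(order = ord$order, flow_matrix = fm,
       flows = aggregate_flows(fm, groups))
}
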