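#' Subjects x conditions measurement table
#'
#' A complete repeated-measures layout: one value (a coupling estimate or a
#' flow strength) per subject and condition.
#'
#' @param values numeric matrix, subjects x conditions, no missing cells.
#' @param subjects subject ids (default from rownames or `s1..sn`).
#' @param conditions condition labels (default from colnames).
#' @return An object of class `condition_table`.
#' @export
condition_table <- function(values, subjects = rownames(values),
                            conditions = colnames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("repeated-measures table must be complete (no NA)")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 subjects and 2 conditions")
  if (is.null(subjects)) subjects <- paste0("s", seq_len(nrow(values)))
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(values)))
  stopifnot(length(subjects) == nrow(values),
            length(conditions) == ncol(values))
  dimnames(values) <- list(subjects, conditions)
  structure(list(values = values, subjects = as.character(subjects),
                 conditions = as.character(conditions)),
            class = "condition_table")
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor computed from the double-centered sample
#' covariance of the condition columns:
#' `eps = tr(C)^2 / ((k - 1) * sum(C^2))`. Always in
#' `[1/(k - 1), 1]`; equal to 1 under compound symmetry, and equal to 1 by
#' construction when k = 2.
#'
#' @param table a [condition_table()].
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(table) {
  stopifnot(inherits(table, "condition_table"))
  k <- ncol(table$values)
  S <- stats::cov(table$values)
  Cc <- sweep(S, 1, rowMeans(S))
  Cc <- sweep(Cc, 2, colMeans(S))
  Cc <- Cc + mean(S)
  denom <- (k - 1) * sum(Cc^2)
  if (denom <= .Machine$double.eps * sum(diag(S))^2 || denom == 0) {
    warning("singular condition covariance; returning the epsilon lower bound")
    return(1 / (k - 1))
  }
  eps <- sum(diag(Cc))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject decomposition of the subjects x conditions table:
#' `F = MS_condition / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom, with the Greenhouse-Geisser p value obtained by scaling both
#' degrees of freedom by [gg_epsilon()].
#'
#' @param table a [condition_table()].
#' @return A list of class `anova_result`: `F`, `df_num`, `df_den`,
#'   `epsilon`, `p_uncorrected`, `p_gg`, `ss` (named sums of squares).
#' @export
rm_anova_gg <- function(table) {
  stopifnot(inherits(table, "condition_table"))
  X <- table$values
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  subj_means <- rowMeans(X)
  cond_means <- colMeans(X)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_err <- sum((X - outer(subj_means, cond_means, "+") + grand)^2)
  df_num <- k - 1
  df_den <- (k - 1) * (n - 1)
  ms_err <- ss_err / df_den
  # guard against exact and numerically-zero residual variance
  degenerate <- ss_err <= 1e-18 * max(ss_subj, ss_cond, 1)
  if (degenerate) {
    if (ss_cond <= 1e-18 * max(ss_subj, 1))
      stop("degenerate data: zero within-cell variance everywhere")
    Fv <- Inf
  } else Fv <- (ss_cond / df_num) / ms_err
  eps <- gg_epsilon(table)
  p_unc <- stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
  p_gg <- stats::pf(Fv, eps * df_num, eps * df_den, lower.tail = FALSE)
  structure(list(F = Fv, df_num = df_num, df_den = df_den, epsilon = eps,
                 p_uncorrected = p_unc, p_gg = p_gg,
                 ss = c(condition = ss_cond, subject = ss_subj,
                        error = ss_err)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%g, %g) = %.3f, p = %.4f (GG eps = %.3f, p_GG = %.4f)\n",
              x$df_num, x$df_den, x$F, x$p_uncorrected, x$epsilon, x$p_gg))
  invisible(x)
}

#' Paired t post-hoc tests with Bonferroni correction
#'
#' Tests the reference condition against every other condition with
#' two-sided paired t tests; corrected p values are `min(1, m * p_raw)`
#' with `m` the number of tested pairs. A pair with a zero-variance,
#' all-zero difference vector is reported as `t = 0`, `p = 1`; a constant
#' non-zero difference leaves t undefined and is flagged.
#'
#' @param table a [condition_table()].
#' @param reference reference condition label (each other condition is
#'   compared against it).
#' @return A data.frame with columns `pair`, `t`, `df`, `p_raw`,
#'   `p_corrected`, `undefined`.
#' @export
posthoc_paired_bonferroni <- function(table, reference) {
  stopifnot(inherits(table, "condition_table"))
  if (!reference %in% table$conditions)
    stop("reference condition '", reference, "' not in table")
  others <- setdiff(table$conditions, reference)
  m <- length(others)
  rows <- lapply(others, function(cond) {
    x <- table$values[, reference]
    y <- table$values[, cond]
    d <- x - y
    if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      if (all(abs(d) <= 1e-12 * max(1, abs(mean(d)))) && mean(d) == 0)
        data.frame(pair = paste(reference, "vs", cond), t = 0,
                   df = length(d) - 1, p_raw = 1, p_corrected = 1,
                   undefined = FALSE)
      else
        data.frame(pair = paste(reference, "vs", cond), t = NA_real_,
                   df = length(d) - 1, p_raw = NA_real_,
                   p_corrected = NA_real_, undefined = TRUE)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(pair = paste(reference, "vs", cond),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_corrected = min(1, m * tt$p.value), undefined = FALSE)
    }
  })
  do.call(rbind, rows)
}
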