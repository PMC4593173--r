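# Shared helpers: small fixtures built in code at test time.

# a short double-column fixture with known parameters
tiny_fixture <- function(condition = "8", seed = 11,
                         params = double_column_params(85, 95, 2200, 300),
                         duration = 3) {
  generate_inversion_fixture(params,
                             stimulus_spec(condition, duration = duration),
                             seed = seed)
}

# bivariate VAR(1) with x1 -> x2 coupling only
biv_var_coefs <- function(self = 0.5, cross = 0.5) {
  list(matrix(c(self, cross, 0, self), 2, 2))
}

# subjects x conditions table of iid normals
random_table <- function(n = 10, k = 4, seed = 1, mean = 0, sd = 1) {
  set.seed(seed)
  condition_table(matrix(rnorm(n * k, mean, sd), n, k),
                  conditions = if (k == 4) c("control", "8", "44", "84")
                               else paste0("c", seq_len(k)))
}

# independent textbook oracle for the within-subject ANOVA, via stats::aov
aov_oracle <- function(tab) {
  df <- data.frame(
    y = as.vector(tab$values),
    subject = factor(rep(tab$subjects, times = ncol(tab$values))),
    condition = factor(rep(tab$conditions, each = nrow(tab$values)),
                       levels = tab$conditions))
  fit <- stats::aov(y ~ condition + Error(subject / condition), data = df)
  s <- summary(fit)[["Error: subject:condition"]][[1]]
  list(F = s["condition", "F value"], p = s["condition", "Pr(>F)"],
       df = unname(s[, "Df"]))
}
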