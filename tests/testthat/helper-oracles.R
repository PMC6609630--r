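# Independent oracles used across test files.

# Expand each study into n_j pseudo-individuals whose sample mean is exactly
# X_j and whose population-style SD (divisor n) is exactly SD_j, then compute
# the pooled %CV from the raw pseudo-individuals. Brute-force reference for
# the method II formula.
pooled_cv_bruteforce <- function(x, sd, n) {
  y <- unlist(lapply(seq_along(x), function(j) {
    base <- scale(seq_len(n[j]))[, 1]          # mean 0, sample sd 1
    base <- base * sqrt(n[j] / (n[j] - 1))     # population sd 1
    x[j] + sd[j] * base
  }))
  grand <- mean(y)
  100 * sqrt(mean((y - grand)^2)) / grand
}

# Upper-tail chi-squared probability by numerical integration of the density
# written out explicitly (independent of pchisq).
chisq_upper_tail_integrate <- function(q, df) {
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, q, Inf, rel.tol = 1e-12)$value
}

# Tolerance for comparisons against printed table values: one unit in the
# last printed decimal place or 0.5% relative, whichever is larger (printed
# values chain rounded intermediates).
printed_tol <- function(printed, decimals) {
  pmax(10^(-decimals), abs(printed) * 0.005)
}

expect_close_printed <- function(actual, printed, decimals) {
  expect_lt(abs(actual - printed), printed_tol(printed, decimals) + 1e-12)
}

# Small deterministic multi-study fixture used by several files.
fixture_study_set <- function() {
  study_set("UGT1A1", "liver",
            label = c("a, 2012", "b, 2014", "c, 2016", "d, 2018"),
            x = c(28, 44, 31, 39), sd = c(9, 21, 12, 16),
            n = c(24, 17, 9, 12))
}
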