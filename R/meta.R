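## Meta-analysis engine: fixed- and random-effects summaries with Cochran's Q,
## the method-of-moments between-study variance, H2/I2 heterogeneity indices,
## the sample-size weighted mean, three pooled %CV estimators, and geometric
## (lognormal) confidence intervals.
##
## Weighting follows the source convention for abundance data: fixed-effect
## weights are the inverse of the reported study variance, w_j = 1/SD_j^2
## (total inter-individual variance, not the variance of the study mean).

.as_study_set <- function(x) {
  if (inherits(x, "study_set")) return(x)
  if (is.data.frame(x)) {
    need <- c("x", "n")
    if (!all(need %in% names(x)))
      stop("data.frame input needs at least columns 'x' and 'n'",
           call. = FALSE)
    return(study_set(protein = attr(x, "protein") %||% "unnamed",
                     tissue = attr(x, "tissue") %||% "liver",
                     label = x$label %||% paste0("study ", seq_len(nrow(x))),
                     x = x$x, sd = x$sd %||% NA_real_, n = x$n,
                     cv = x$cv %||% NA_real_))
  }
  stop("expected a study_set or a data.frame", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed-effect summary estimate
#'
#' Inverse-variance weighted summary over the studies that report a positive
#' SD: weights \eqn{w_j = 1/SD_j^2}, estimate
#' \eqn{\mu_F = \sum w_j X_j / \sum w_j}, and Cochran's heterogeneity
#' statistic \eqn{Q_F = \sum w_j (X_j - \mu_F)^2} with \eqn{df = k_{used}-1}.
#' Studies with missing or zero SD are excluded here (and counted in
#' `k_used`) but still contribute to [weighted_mean()].
#'
#' @param studies A [study_set()] or a data.frame with columns `x`, `sd`, `n`.
#' @return List of class `dmet_fe`: `mu`, `w` (named weights), `Q`, `df`,
#'   `k_used`, `used` (logical index into the study set).
#' @export
fixed_effect <- function(studies) {
  ss <- .as_study_set(studies)
  d <- ss$data
  used <- !is.na(d$sd) & d$sd > 0
  if (!any(used))
    stop("insufficient variance data: no study with positive SD for ",
         ss$protein, call. = FALSE)
  w <- 1 / d$sd[used]^2
  names(w) <- d$label[used]
  mu <- sum(w * d$x[used]) / sum(w)
  Q <- sum(w * (d$x[used] - mu)^2)
  structure(list(mu = mu, w = w, Q = Q, df = sum(used) - 1L,
                 k_used = sum(used), used = used),
            class = "dmet_fe")
}

#' Random-effects summary estimate
#'
#' DerSimonian–Laird style method-of-moments random-effects model on the same
#' study subset as [fixed_effect()]. When \eqn{Q_F > df},
#' \eqn{\hat\tau^2 = (Q_F - df) / (\sum w_j - \sum w_j^2/\sum w_j)} and the
#' random-effects weights are \eqn{w^*_j = 1/(w_j^{-1} + \hat\tau^2)};
#' otherwise \eqn{\hat\tau^2 = 0} and the random-effects results equal the
#' fixed-effect ones (the tie \eqn{Q_F = df} is treated the same way).
#'
#' @param studies A [study_set()] (or data.frame).
#' @param fe Optional [fixed_effect()] result computed on the same subset.
#' @return List of class `dmet_re`: `mu`, `w_star`, `tau2`, `Q`.
#' @export
random_effect <- function(studies, fe = NULL) {
  ss <- .as_study_set(studies)
  if (is.null(fe)) fe <- fixed_effect(ss)
  w <- fe$w
  if (fe$Q <= fe$df) {
    return(structure(list(mu = fe$mu, w_star = w, tau2 = 0, Q = fe$Q),
                     class = "dmet_re"))
  }
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0)
    stop("insufficient studies to estimate between-study variance",
         call. = FALSE)
  tau2 <- (fe$Q - fe$df) / denom
  w_star <- 1 / (1 / w + tau2)
  x <- ss$data$x[fe$used]
  mu <- sum(w_star * x) / sum(w_star)
  Q <- sum(w_star * (x - mu)^2)
  structure(list(mu = mu, w_star = w_star, tau2 = tau2, Q = Q),
            class = "dmet_re")
}

#' Heterogeneity indices from Q and df
#'
#' \eqn{H^2 = Q/df} and \eqn{I^2(\%) = (H^2-1)/H^2 \cdot 100}, floored at
#' zero. The P-value is the upper-tail probability of a chi-squared variate
#' with `df` degrees of freedom at `Q`. Classes: `none` when the floored
#' \eqn{I^2} is 0, `low` below 37.5%, `medium` below 62.5%, `high` at or
#' above 62.5% (midpoints of the conventional 0/25/50/75 anchors). The
#' \eqn{H^2} concern label is `considerable` above 1.5, `little` below 1.2,
#' `intermediate` between.
#'
#' @param Q Non-negative heterogeneity statistic.
#' @param df Degrees of freedom (k - 1), at least 1.
#' @return List of class `dmet_het`: `H2`, `I2_pct`, `P_value`, `het_class`,
#'   `H2_concern`.
#' @export
heterogeneity_indices <- function(Q, df) {
  if (length(df) != 1 || df < 1)
    stop("heterogeneity indices are undefined for a single study (df = 0)",
         call. = FALSE)
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  H2 <- Q / df
  I2 <- max(0, (H2 - 1) / H2 * 100)
  if (!is.finite(I2)) I2 <- 0               # Q = 0 edge
  P <- stats::pchisq(Q, df, lower.tail = FALSE)
  het_class <- if (I2 == 0) "none" else if (I2 < 37.5) "low" else
    if (I2 < 62.5) "medium" else "high"
  concern <- if (H2 > 1.5) "considerable" else if (H2 < 1.2) "little" else
    "intermediate"
  structure(list(H2 = H2, I2_pct = I2, P_value = P,
                 het_class = het_class, H2_concern = concern),
            class = "dmet_het")
}

#' Sample-size weighted mean abundance
#'
#' \eqn{WM = \sum n_j X_j / N}; uses every study (SD not required).
#'
#' @param studies A [study_set()] (or data.frame).
#' @return The weighted mean (same unit as the study means).
#' @export
weighted_mean <- function(studies) {
  d <- .as_study_set(studies)$data
  sum(d$n * d$x) / sum(d$n)
}

#' Pooled %CV, method I (between-study variance only)
#'
#' \eqn{\nu = \sum n_j (X_j - WM)^2 / N} and
#' \eqn{\%CV = 100\sqrt{\nu}/WM}. Uses only study means and sizes.
#'
#' @param studies A [study_set()] (or data.frame).
#' @param WM Weighted mean; defaults to [weighted_mean()] of `studies`.
#' @return Percent coefficient of variation, with attribute `nu`.
#' @export
cv_method_I <- function(studies, WM = weighted_mean(studies)) {
  d <- .as_study_set(studies)$data
  if (WM <= 0) stop("%CV is undefined for non-positive weighted mean",
                    call. = FALSE)
  N <- sum(d$n)
  nu <- sum(d$n * (d$x - WM)^2) / N
  structure(100 * sqrt(nu) / WM, nu = nu)
}

#' Pooled %CV, method II (within- plus between-study variance)
#'
#' Overall sum of squares
#' \eqn{SS = \sum[(SD_j^2 + X_j^2) n_j] - N \cdot WM^2} and
#' \eqn{\%CV = 100\sqrt{SS/N}/WM}. Equivalent to pooling the per-study
#' (population-style) variances with the between-study spread, so method II
#' is never smaller than method I and equals it when all SDs are zero.
#'
#' @param studies A [study_set()] (or data.frame); every study must have an
#'   SD — callers wanting to drop SD-less studies must subset first (the
#'   error lists the offenders).
#' @param WM Weighted mean of the same studies.
#' @return Percent coefficient of variation, with attribute `overall_SS`.
#' @export
cv_method_II <- function(studies, WM = weighted_mean(studies)) {
  d <- .as_study_set(studies)$data
  if (WM <= 0) stop("%CV is undefined for non-positive weighted mean",
                    call. = FALSE)
  if (any(is.na(d$sd)))
    stop("method II requires an SD for every study; missing for: ",
         paste(d$label[is.na(d$sd)], collapse = ", "), call. = FALSE)
  N <- sum(d$n)
  SS <- sum((d$sd^2 + d$x^2) * d$n) - N * WM^2
  SS <- max(SS, 0)                          # guard rounding at zero variance
  structure(100 * sqrt(SS / N) / WM, overall_SS = SS)
}

#' Pooled %CV, method III (weighted mean of study CVs)
#'
#' \eqn{\%CV = 100 \sum n_j CV_j / N}, with \eqn{CV_j} the within-study
#' coefficient of variation (fraction), taken as reported or derived as
#' \eqn{SD_j/X_j}.
#'
#' @param studies A [study_set()] (or data.frame).
#' @return Percent coefficient of variation.
#' @export
cv_method_III <- function(studies) {
  d <- .as_study_set(studies)$data
  cv <- ifelse(is.na(d$cv) & !is.na(d$sd), d$sd / d$x, d$cv)
  if (any(is.na(cv)))
    stop("method III requires a CV (or SD) for every study; missing for: ",
         paste(d$label[is.na(cv)], collapse = ", "), call. = FALSE)
  100 * sum(d$n * cv) / sum(d$n)
}

#' Geometric (lognormal) confidence interval around a weighted mean
#'
#' \eqn{CI = \exp[\ln(WM) \pm z\,\sigma/\sqrt{k}]} with
#' \eqn{\sigma = \sqrt{\ln[(\%CV/100)^2 + 1]}}, the SD of the data on the
#' natural-log scale. `z = 1.96` gives the 95% interval; `z = 4.26` the
#' 99.998% interval used for model-acceptance ranges.
#'
#' @param WM Positive weighted mean.
#' @param cv_pct Percent coefficient of variation (non-negative).
#' @param k Number of studies (positive integer).
#' @param z Standard-normal quantile; default 1.96.
#' @return Named numeric vector `c(low, high)`.
#' @export
geometric_ci <- function(WM, cv_pct, k, z = 1.96) {
  if (!is.finite(WM) || WM <= 0) stop("WM must be positive", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (is.na(cv_pct)) return(c(low = NA_real_, high = NA_real_))
  if (cv_pct < 0) stop("cv_pct must be non-negative", call. = FALSE)
  sigma <- sqrt(log((cv_pct / 100)^2 + 1))
  half <- z * sigma / sqrt(k)
  c(low = WM * exp(-half), high = WM * exp(half))
}
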