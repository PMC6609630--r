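## dmet_meta(): the one-stop fit combining heterogeneity analysis (FE/RE,
## Q, H2, I2, P) with sample-size-weighted pooling (WM, %CV methods I-III,
## geometric CIs) and forest-plot rows, plus its S3 methods and the flat
## table exporters.

#' Meta-analysis of one protein's study-level abundance data
#'
#' Fits the full two-track meta-analysis to a study set: an inverse-variance
#' track (fixed- and random-effects summaries with Cochran's Q and the
#' H\eqn{^2}/I\eqn{^2} heterogeneity indices) and a sample-size track (the
#' weighted mean with pooled %CV by three methods and geometric confidence
#' intervals). Studies lacking an SD take part only in the estimators that do
#' not need one (WM, method I, method III via a reported CV); the per-method
#' study counts are reported in `k_used`.
#'
#' The headline confidence intervals are computed around the all-study
#' weighted mean with each method's %CV and the full study count `k`, so
#' printed (WM, %CV, k) triples reconstruct them exactly.
#'
#' @param studies A [study_set()] or a data.frame with columns `x`, `sd`,
#'   `n` (and optionally `label`, `cv`).
#' @param z Standard-normal quantile for the confidence intervals
#'   (default 1.96, the 95% level).
#' @return An object of class `dmet_meta`; see Details. Methods:
#'   [print.dmet_meta()], [summary.dmet_meta()], [coef.dmet_meta()],
#'   [confint.dmet_meta()], [plot.dmet_meta()].
#' @details The object carries `protein`, `tissue`, `k`, `N`, `studies`
#'   (the per-study table), `fe`, `re`, `het_fe`, `het_re` (NULL where
#'   unavailable, see `flags`), `pooled` (WM, `nu`, `overall_SS`, per-method
#'   `cv_pct`, `sigma`, `ci_low`, `ci_high`, `k_used`, `z`) and `forest`
#'   (one row per study plus one summary row per %CV method).
#' @examples
#' ss <- study_set("UGT1A1", "liver",
#'                 label = c("a, 2014", "b, 2016", "c, 2018"),
#'                 x = c(30, 42, 35), sd = c(12, 20, 14), n = c(24, 17, 9))
#' fit <- dmet_meta(ss)
#' coef(fit)
#' confint(fit)
#' @export
dmet_meta <- function(studies, z = 1.96) {
  ss <- .as_study_set(studies)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  d <- ss$data
  flags <- list(fe = TRUE, re = TRUE, het = TRUE,
                method_II = TRUE, method_III = TRUE)

  fe <- tryCatch(fixed_effect(ss), error = function(e) e)
  if (inherits(fe, "error")) { flags$fe <- flags$re <- flags$het <- FALSE
    fe <- NULL }
  re <- if (!is.null(fe)) random_effect(ss, fe) else NULL
  het_fe <- het_re <- NULL
  if (!is.null(fe) && fe$df >= 1) {
    het_fe <- heterogeneity_indices(fe$Q, fe$df)
    het_re <- heterogeneity_indices(re$Q, fe$df)
  } else flags$het <- FALSE

  WM <- weighted_mean(ss)
  cv <- c(I = NA_real_, II = NA_real_, III = NA_real_)
  k_used <- c(I = ss$k, II = 0L, III = 0L)
  cv_I <- cv_method_I(ss, WM)
  cv["I"] <- as.numeric(cv_I)
  has_sd <- !is.na(d$sd)
  overall_SS <- NA_real_
  if (any(has_sd)) {
    sub <- ss
    sub$data <- d[has_sd, , drop = FALSE]
    sub$k <- sum(has_sd); sub$N <- sum(d$n[has_sd])
    cv_II <- cv_method_II(sub, weighted_mean(sub))
    cv["II"] <- as.numeric(cv_II)
    overall_SS <- attr(cv_II, "overall_SS")
    k_used["II"] <- sub$k
  } else flags$method_II <- FALSE
  has_cv <- !is.na(ifelse(is.na(d$cv) & !is.na(d$sd), d$sd / d$x, d$cv))
  if (any(has_cv)) {
    sub <- ss
    sub$data <- d[has_cv, , drop = FALSE]
    sub$k <- sum(has_cv); sub$N <- sum(d$n[has_cv])
    cv["III"] <- cv_method_III(sub)
    k_used["III"] <- sub$k
  } else flags$method_III <- FALSE

  sigma <- sqrt(log((cv / 100)^2 + 1))
  ci <- vapply(cv, function(c_) geometric_ci(WM, c_, ss$k, z), numeric(2))
  pooled <- list(WM = WM, nu = attr(cv_I, "nu"), overall_SS = overall_SS,
                 cv_pct = cv, sigma = sigma,
                 ci_low = ci["low", ], ci_high = ci["high", ],
                 k_used = k_used, z = z, k = ss$k, N = ss$N)

  study_half <- z * d$sd / sqrt(d$n)
  forest <- data.frame(
    label = c(d$label, paste("Method", names(cv))),
    mean = c(d$x, rep(WM, 3)),
    ci_low = c(d$x - study_half, ci["low", ]),
    ci_high = c(d$x + study_half, ci["high", ]),
    row_kind = c(rep("study", ss$k), rep("method_summary", 3)),
    stringsAsFactors = FALSE)

  structure(list(protein = ss$protein, tissue = ss$tissue,
                 k = ss$k, N = ss$N, studies = d,
                 fe = fe, re = re, het_fe = het_fe, het_re = het_re,
                 pooled = pooled, forest = forest, z = z, flags = flags),
            class = "dmet_meta")
}

#' @export
print.dmet_meta <- function(x, digits = 2, ...) {
  cat(sprintf("Meta-analysis: %s (%s), k = %d studies, N = %d donors\n",
              x$protein, x$tissue, x$k, x$N))
  if (!is.null(x$fe)) {
    cat(sprintf("  FE: mu = %.*f, Q = %.*f, df = %d (k_used = %d)\n",
                digits, x$fe$mu, digits, x$fe$Q, x$fe$df, x$fe$k_used))
    cat(sprintf("  RE: mu = %.*f, tau2 = %.*f, Q = %.*f\n",
                digits, x$re$mu, digits, x$re$tau2, digits, x$re$Q))
    if (!is.null(x$het_fe))
      cat(sprintf("  Heterogeneity (FE): H2 = %.*f, I2 = %.*f%%, P = %.2g (%s)\n",
                  digits, x$het_fe$H2, digits, x$het_fe$I2_pct,
                  x$het_fe$P_value, x$het_fe$het_class))
  } else cat("  FE/RE unavailable (no study with positive SD)\n")
  p <- x$pooled
  cat(sprintf("  WM = %.*f pmol/mg\n", digits, p$WM))
  for (m in c("I", "II", "III"))
    if (!is.na(p$cv_pct[m]))
      cat(sprintf("  method %-3s %%CV = %6.2f  %2.0f%% CI [%.*f, %.*f] (k_used = %d)\n",
                  m, p$cv_pct[m],
                  100 * (2 * stats::pnorm(p$z) - 1),
                  digits, p$ci_low[m], digits, p$ci_high[m], p$k_used[m]))
  invisible(x)
}

#' @export
coef.dmet_meta <- function(object, ...) {
  c(mu_F = if (is.null(object$fe)) NA_real_ else object$fe$mu,
    mu_R = if (is.null(object$re)) NA_real_ else object$re$mu,
    WM = object$pooled$WM)
}

#' @export
confint.dmet_meta <- function(object, parm = c("I", "II", "III"),
                              level = NULL, ...) {
  p <- object$pooled
  parm <- match.arg(parm, several.ok = TRUE)
  cbind(low = p$ci_low[parm], high = p$ci_high[parm])
}

#' @export
summary.dmet_meta <- function(object, ...) {
  structure(list(fit = object,
                 heterogeneity = heterogeneity_table(list(object)),
                 pooling = pooling_table(list(object))),
            class = "summary.dmet_meta")
}

#' @export
print.summary.dmet_meta <- function(x, ...) {
  print(x$fit)
  cat("\nHeterogeneity table:\n")
  print(x$heterogeneity, row.names = FALSE, digits = 4)
  cat("\nPooling table:\n")
  print(x$pooling, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Forest plot of a meta-analysis fit
#'
#' Per-study means with presentation intervals (mean \eqn{\pm z\,SD_j/\sqrt{n_j}};
#' never used in pooling) and the three pooled summaries with their geometric
#' confidence intervals.
#'
#' @param x A [dmet_meta()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dmet_meta <- function(x, ...) {
  f <- x$forest[rev(seq_len(nrow(x$forest))), ]
  n <- nrow(f)
  xlim <- range(c(f$mean, f$ci_low, f$ci_high), na.rm = TRUE)
  graphics::plot(f$mean, seq_len(n), yaxt = "n", xlim = xlim,
                 xlab = "abundance (pmol/mg microsomal protein)", ylab = "",
                 pch = ifelse(f$row_kind == "study", 15, 18),
                 main = sprintf("%s (%s)", x$protein, x$tissue), ...)
  graphics::axis(2, at = seq_len(n), labels = f$label, las = 1, cex.axis = 0.7)
  graphics::segments(f$ci_low, seq_len(n), f$ci_high, seq_len(n))
  graphics::abline(v = x$pooled$WM, lty = 2)
  invisible(x)
}

#' Heterogeneity table across fits
#'
#' One row per protein: df, then Q, H2, I2, P-value and heterogeneity class
#' for the fixed- and random-effects models.
#'
#' @param fits List of [dmet_meta()] fits.
#' @return A `data.frame`.
#' @export
heterogeneity_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (is.null(f$het_fe))
      return(data.frame(protein = f$protein, tissue = f$tissue,
                        k = f$k, k_used = if (is.null(f$fe)) 0L else f$fe$k_used,
                        df = NA_integer_, Q_F = NA_real_, H2_F = NA_real_,
                        I2_F_pct = NA_real_, P_F = NA_real_,
                        class_F = NA_character_, Q_R = NA_real_,
                        H2_R = NA_real_, I2_R_pct = NA_real_, P_R = NA_real_,
                        class_R = NA_character_, tau2 = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(protein = f$protein, tissue = f$tissue, k = f$k,
               k_used = f$fe$k_used, df = f$fe$df,
               Q_F = f$fe$Q, H2_F = f$het_fe$H2, I2_F_pct = f$het_fe$I2_pct,
               P_F = f$het_fe$P_value, class_F = f$het_fe$het_class,
               Q_R = f$re$Q, H2_R = f$het_re$H2, I2_R_pct = f$het_re$I2_pct,
               P_R = f$het_re$P_value, class_R = f$het_re$het_class,
               tau2 = f$re$tau2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooling table across fits
#'
#' Three rows per protein (one per %CV method): weighted mean, weighted %CV,
#' and the geometric confidence bounds, mirroring a summary-table layout with
#' explicit column names.
#'
#' @param fits List of [dmet_meta()] fits.
#' @return A `data.frame`.
#' @export
pooling_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    p <- f$pooled
    data.frame(protein = f$protein, tissue = f$tissue,
               method = c("I", "II", "III"),
               weighted_mean = p$WM, weighted_cv_pct = unname(p$cv_pct),
               ci_low = unname(p$ci_low), ci_high = unname(p$ci_high),
               k = f$k, k_used = unname(p$k_used), N = f$N,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize a fit to a JSON-ready list
#'
#' @param fit A [dmet_meta()] fit.
#' @return A nested list mirroring the fit, suitable for
#'   [jsonlite::write_json()].
#' @export
meta_as_list <- function(fit) {
  list(protein = fit$protein, tissue = fit$tissue, k = fit$k, N = fit$N,
       fe = if (is.null(fit$fe)) NULL else
         list(mu = fit$fe$mu, Q = fit$fe$Q, df = fit$fe$df,
              k_used = fit$fe$k_used, w = as.list(fit$fe$w)),
       re = if (is.null(fit$re)) NULL else
         list(mu = fit$re$mu, tau2 = fit$re$tau2, Q = fit$re$Q),
       heterogeneity = if (is.null(fit$het_fe)) NULL else
         list(FE = unclass(fit$het_fe), RE = unclass(fit$het_re)),
       pooled = lapply(fit$pooled, function(v)
         if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
       flags = fit$flags)
}
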