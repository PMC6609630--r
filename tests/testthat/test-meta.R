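# Meta-analysis engine: hand-arithmetic oracles, printed-table
# reconstructions, an independent meta-analysis library as cross-check, and
# the structural invariants of the estimators.

two_study <- function() study_set("P", label = c("a", "b"), x = c(10, 20),
                                  sd = c(1, 2), n = c(5, 5))

test_that("fixed-effect summary matches the hand-arithmetic oracle", {
  fe <- fixed_effect(two_study())
  expect_equal(unname(fe$w), c(1, 0.25))
  expect_equal(fe$mu, 12)
  expect_equal(fe$Q, 1 * (10 - 12)^2 + 0.25 * (20 - 12)^2)  # = 20
  expect_equal(fe$df, 1L)
  # single usable study: mu = X1, Q = 0, df = 0
  one <- study_set("P", label = "a", x = 10, sd = 2, n = 5)
  fe1 <- fixed_effect(one)
  expect_equal(fe1$mu, 10)
  expect_equal(fe1$Q, 0)
  expect_equal(fe1$df, 0L)
  # studies without SD are dropped and counted
  mix <- study_set("P", label = c("a", "b", "c"), x = c(10, 20, 15),
                   sd = c(1, 2, NA), n = c(5, 5, 5))
  expect_equal(fixed_effect(mix)$k_used, 2L)
  nosd <- study_set("P", label = "a", x = 10, sd = NA_real_, n = 5)
  expect_error(fixed_effect(nosd), "insufficient variance")
})

test_that("random-effects summary matches the hand-arithmetic oracle", {
  fe <- fixed_effect(two_study())
  re <- random_effect(two_study(), fe)
  expect_equal(re$tau2, (20 - 1) / (1.25 - 1.0625 / 1.25))  # = 47.5
  expect_equal(unname(re$w_star), c(1 / 48.5, 1 / 51.5))
  expect_equal(re$mu, 14.85, tolerance = 1e-4)
  expect_equal(re$Q, 1, tolerance = 1e-4)
})

test_that("Q <= df collapses the RE model onto the FE model", {
  ss <- study_set("P", label = c("a", "b", "c"), x = c(10, 10.1, 9.9),
                  sd = c(2, 2, 2), n = c(5, 5, 5))
  fe <- fixed_effect(ss)
  expect_lte(fe$Q, fe$df)
  re <- random_effect(ss, fe)
  expect_equal(re$tau2, 0)
  expect_equal(re$mu, fe$mu)
  expect_equal(re$Q, fe$Q)
  # exact tie behaves the same way
  fe_tie <- fe; fe_tie$Q <- fe$df
  re_tie <- random_effect(ss, fe_tie)
  expect_equal(re_tie$tau2, 0)
})

test_that("large tau2 drives the RE estimate toward the unweighted mean", {
  ss <- study_set("P", label = letters[1:4], x = c(5, 50, 500, 5000),
                  sd = c(0.1, 0.1, 0.1, 0.1), n = rep(5, 4))
  re <- random_effect(ss)
  expect_gt(re$tau2, 1e4)
  expect_equal(re$mu, mean(c(5, 50, 500, 5000)), tolerance = 0.01)
})

test_that("FE and RE cross-check against an independent meta-analysis library", {
  skip_if_not_installed("metafor")
  set.seed(11)
  for (rep in 1:5) {
    k <- sample(4:9, 1)
    x <- rlnorm(k, log(40), 0.4)
    sd <- x * runif(k, 0.2, 0.6)
    ss <- study_set("P", label = paste0("s", 1:k), x = x, sd = sd,
                    n = rep(10, k))
    fe <- fixed_effect(ss)
    re <- random_effect(ss, fe)
    m_fe <- metafor::rma(yi = x, vi = sd^2, method = "FE")
    m_dl <- metafor::rma(yi = x, vi = sd^2, method = "DL")
    expect_equal(fe$mu, as.numeric(m_fe$beta), tolerance = 1e-10)
    expect_equal(fe$Q, m_fe$QE, tolerance = 1e-10)
    expect_equal(re$tau2, m_dl$tau2, tolerance = 1e-8)
    expect_equal(re$mu, as.numeric(m_dl$beta), tolerance = 1e-8)
  }
})

test_that("heterogeneity indices reproduce printed reference rows", {
  # high-heterogeneity row: Q = 31.24, df = 6
  h <- heterogeneity_indices(31.24, 6)
  expect_close_printed(h$H2, 5.21, 2)
  expect_close_printed(h$I2_pct, 80.79, 2)
  expect_close_printed(h$P_value, 0.000023, 6)
  expect_identical(h$het_class, "high")
  expect_identical(h$H2_concern, "considerable")
  # Q below df floors I2 at zero: Q = 0.18, df = 1
  h2 <- heterogeneity_indices(0.18, 1)
  expect_equal(h2$H2, 0.18)
  expect_equal(h2$I2_pct, 0)
  expect_close_printed(h2$P_value, 0.67, 2)
  expect_identical(h2$het_class, "none")
  # Q = df boundary
  h3 <- heterogeneity_indices(4, 4)
  expect_equal(h3$H2, 1)
  expect_equal(h3$I2_pct, 0)
  expect_error(heterogeneity_indices(1, 0), "single study")
})

test_that("heterogeneity classes split at the 37.5/62.5 midpoints", {
  cls <- function(i2) {
    # invert I2 -> H2 to drive the classifier through Q/df
    H2 <- 1 / (1 - i2 / 100)
    heterogeneity_indices(H2 * 10, 10)$het_class
  }
  expect_identical(cls(21.74), "low")
  expect_identical(cls(29.67), "low")
  expect_identical(cls(42.77), "medium")
  expect_identical(cls(48.65), "medium")
  expect_identical(cls(58.45), "medium")
  expect_identical(cls(63), "high")
  expect_identical(cls(79.73), "high")
})

test_that("chi-squared upper tail matches a numerical-integration oracle", {
  for (df in c(1, 3, 6, 10))
    for (q in c(0.18, 2, 8.5, 31.24, 50)) {
      h <- heterogeneity_indices(q, df)
      expect_lt(abs(h$P_value - chisq_upper_tail_integrate(q, df)), 1e-10)
    }
})

test_that("weighted mean and %CV method I match hand arithmetic", {
  ss <- study_set("P", label = c("a", "b"), x = c(10, 20), n = c(3, 1),
                  sd = c(1, 1))
  expect_equal(weighted_mean(ss), 12.5)
  cv <- cv_method_I(ss)
  expect_equal(attr(cv, "nu"), 18.75)
  expect_equal(as.numeric(cv), 100 * sqrt(18.75) / 12.5)   # 34.64
  # constant studies -> WM = c, cv = 0
  cc <- study_set("P", label = c("a", "b"), x = c(7, 7), sd = c(0, 0),
                  n = c(4, 9))
  expect_equal(weighted_mean(cc), 7)
  expect_equal(as.numeric(cv_method_I(cc)), 0)
})

test_that("%CV method II: hand value, zero-SD identity and SD requirement", {
  ss <- study_set("P", label = c("a", "b"), x = c(10, 20), sd = c(0, 0),
                  n = c(3, 1))
  cv2 <- cv_method_II(ss)
  expect_equal(attr(cv2, "overall_SS"), 700 - 625)         # = 75
  expect_equal(as.numeric(cv2), as.numeric(cv_method_I(ss)))  # 34.64
  miss <- study_set("P", label = c("a", "b"), x = c(10, 20),
                    sd = c(1, NA), n = c(3, 1))
  expect_error(cv_method_II(miss), "\\bb\\b")
})

test_that("%CV method II >= method I, verified against the pseudo-individual oracle", {
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    x <- rlnorm(k, log(30), 0.5)
    sd <- x * runif(k, 0, 0.7)
    n <- sample(5:40, k, replace = TRUE)
    ss <- study_set("P", label = paste0("s", 1:k), x = x, sd = sd, n = n)
    WM <- weighted_mean(ss)
    cv1 <- as.numeric(cv_method_I(ss, WM))
    cv2 <- as.numeric(cv_method_II(ss, WM))
    expect_gte(cv2, cv1)
    expect_equal(cv2, pooled_cv_bruteforce(x, sd, n), tolerance = 1e-9)
    # decomposition: SS = N*nu + sum(n*sd^2)
    expect_equal(attr(cv_method_II(ss, WM), "overall_SS"),
                 sum(n) * attr(cv_method_I(ss, WM), "nu") + sum(n * sd^2),
                 tolerance = 1e-9)
  }
})

test_that("%CV method III is the sample-size-weighted mean of study CVs", {
  ss <- study_set("P", label = c("a", "b"), x = c(10, 20),
                  sd = c(1, 4), n = c(3, 1))       # cv = 0.1, 0.2
  expect_equal(cv_method_III(ss), 12.5)
  cc <- study_set("P", label = c("a", "b"), x = c(10, 20),
                  sd = c(3, 6), n = c(5, 9))       # all cv = 0.3
  expect_equal(cv_method_III(cc), 30)
  none <- study_set("P", label = "a", x = 10, sd = NA_real_, n = 5)
  expect_error(cv_method_III(none), "method III")
})

test_that("geometric CI reproduces printed reference intervals", {
  # WM = 35.97, cv = 102.97, k = 9 -> (20.64, 62.69)
  ci <- geometric_ci(35.97, 102.97, 9)
  expect_close_printed(ci[["low"]], 20.64, 2)
  expect_close_printed(ci[["high"]], 62.69, 2)
  # WM = 24.63, cv = 54.98, k = 2 -> (12.08, 50.21)
  ci2 <- geometric_ci(24.63, 54.98, 2)
  expect_close_printed(ci2[["low"]], 12.08, 2)
  expect_close_printed(ci2[["high"]], 50.21, 2)
})

test_that("geometric CI degenerates and widens correctly", {
  expect_equal(unname(geometric_ci(10, 0, 5)), c(10, 10))
  expect_equal(unname(geometric_ci(10, 30, 5, z = 0)), c(10, 10))
  w1 <- diff(geometric_ci(10, 30, 5, z = 1))
  w2 <- diff(geometric_ci(10, 30, 5, z = 2))
  expect_gt(w2, w1)
  # symmetric on the log scale and contains WM
  ci <- geometric_ci(35.97, 102.97, 9)
  expect_equal(log(35.97) - log(ci[["low"]]), log(ci[["high"]]) - log(35.97))
  expect_true(ci[["low"]] <= 35.97 && 35.97 <= ci[["high"]])
  expect_error(geometric_ci(-1, 30, 5), "positive")
  expect_error(geometric_ci(10, 30, 0), "k")
})

test_that("estimators stay inside the span of the study means", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    x <- rlnorm(k, log(50), 0.6)
    sd <- x * runif(k, 0.1, 0.5)
    n <- sample(3:30, k, replace = TRUE)
    ss <- study_set("P", label = paste0("s", 1:k), x = x, sd = sd, n = n)
    fe <- fixed_effect(ss)
    re <- random_effect(ss, fe)
    for (m in c(fe$mu, re$mu, weighted_mean(ss))) {
      expect_gte(m, min(x))
      expect_lte(m, max(x))
    }
    # RE weights never exceed FE weights; equality iff tau2 = 0
    expect_true(all(re$w_star <= fe$w + 1e-12))
    if (re$tau2 > 0) expect_true(all(re$w_star < fe$w))
  }
})

test_that("dmet_meta composes the tracks and reports availability", {
  ss <- fixture_study_set()
  fit <- dmet_meta(ss)
  expect_s3_class(fit, "dmet_meta")
  expect_equal(fit$pooled$WM, weighted_mean(ss))
  expect_equal(unname(fit$pooled$cv_pct["I"]),
               as.numeric(cv_method_I(ss)))
  expect_equal(unname(fit$pooled$ci_low["II"]),
               geometric_ci(fit$pooled$WM, fit$pooled$cv_pct[["II"]],
                            fit$k)[["low"]])
  expect_named(coef(fit), c("mu_F", "mu_R", "WM"))
  expect_equal(dim(confint(fit)), c(3L, 2L))
  # forest rows: one per study + three summaries, bounds ordered
  expect_equal(nrow(fit$forest), fit$k + 3)
  ok <- stats::complete.cases(fit$forest[c("ci_low", "ci_high")])
  expect_true(all(fit$forest$ci_low[ok] <= fit$forest$mean[ok] + 1e-12))
  expect_true(all(fit$forest$mean[ok] <= fit$forest$ci_high[ok] + 1e-12))
  expect_output(print(fit), "WM")
  expect_output(print(summary(fit)), "Pooling table")
})

test_that("dmet_meta handles SD-less studies via per-method subsets", {
  ss <- study_set("P", label = c("a", "b", "c"), x = c(10, 20, 30),
                  sd = c(1, 2, NA), n = c(5, 5, 5))
  fit <- dmet_meta(ss)
  expect_equal(fit$fe$k_used, 2L)
  expect_equal(unname(fit$pooled$k_used), c(3L, 2L, 2L))
  expect_false(is.na(fit$pooled$cv_pct[["II"]]))
  # no usable SD at all: FE/RE unavailable but pooling still works
  none <- study_set("P", label = c("a", "b"), x = c(10, 20),
                    sd = NA_real_, n = c(5, 5))
  fit2 <- dmet_meta(none)
  expect_null(fit2$fe)
  expect_false(fit2$flags$fe)
  expect_equal(fit2$pooled$WM, 15)
  expect_true(is.na(fit2$pooled$cv_pct[["II"]]))
})

test_that("tables and JSON serialization cover every fit", {
  fits <- list(dmet_meta(fixture_study_set()),
               dmet_meta(two_study()))
  ht <- heterogeneity_table(fits)
  expect_equal(nrow(ht), 2)
  expect_true(all(c("Q_F", "H2_F", "I2_F_pct", "P_F", "class_F",
                    "tau2") %in% names(ht)))
  pt <- pooling_table(fits)
  expect_equal(nrow(pt), 6)
  expect_equal(unique(pt$method), c("I", "II", "III"))
  lst <- meta_as_list(fits[[1]])
  expect_equal(lst$fe$Q, fits[[1]]$fe$Q)
  expect_no_error(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA))
})
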