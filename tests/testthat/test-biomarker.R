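test_that("roc_auc: rank statistic, identities, and edge cases", {
  # brute-force pair count: positives {3,5,7}, negatives {1,2,6} -> 7/9
  r <- roc_auc(c(3, 5, 7, 1, 2, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 7 / 9, tolerance = 1e-12)

  # perfect separation and pure ties
  expect_equal(roc_auc(c(10, 9, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(4, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)

  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both label classes")

  set.seed(6)
  for (i in 1:10) {
    x <- sample(round(rnorm(30, 0, 2), 1))   # rounded -> ties happen
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_auc(x, y)
    # trapezoidal area equals the rank formulation exactly
    expect_equal(roc_trapezoid(r), r$auc, tolerance = 1e-12)
    # AUC(-x) = 1 - AUC(x)
    expect_equal(roc_auc(-x, y)$auc, 1 - r$auc, tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(x / 2), y)$auc, r$auc, tolerance = 1e-12)
    # curve is monotone
    expect_true(all(diff(r$points$sens) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))
  }
})

test_that("combined_roc: redundant and informative second markers", {
  set.seed(19)
  y <- rep(c(0, 1), each = 25)
  a <- rnorm(50, mean = y)
  # B identical to A adds nothing
  expect_equal(combined_roc(a, a, y)$auc, roc_auc(a, y)$auc,
               tolerance = 1e-9)

  # planted additive signal in both markers: combined beats the best single
  # in most replicates
  wins <- 0L
  for (i in 1:30) {
    b <- rnorm(50, mean = y)
    a2 <- rnorm(50, mean = y)
    best_single <- max(roc_auc(a2, y)$auc, roc_auc(b, y)$auc)
    if (combined_roc(a2, b, y)$auc >= best_single) wins <- wins + 1L
  }
  expect_gte(wins / 30, 0.9)

  # pure-noise B leaves the combined AUC near AUC(A) at large n
  set.seed(20)
  y2 <- rep(c(0, 1), each = 300)
  a3 <- rnorm(600, mean = 1.5 * y2)
  noise <- rnorm(600)
  expect_lt(abs(combined_roc(a3, noise, y2)$auc - roc_auc(a3, y2)$auc), 0.03)
})

test_that("univariate_fits: closed-form slope, constants, null calibration", {
  d <- data.frame(y = c(1, 3, 5), x = c(0, 1, 2), k = c(2, 2, 2))
  # exactly linear outcome: R^2 = 1, SE -> 0; summary() warns about it
  fits <- suppressWarnings(univariate_fits(d, "y", c("x", "k")))
  expect_equal(fits$beta[fits$predictor == "x"], 2, tolerance = 1e-12)
  expect_equal(fits$r2[fits$predictor == "x"], 1, tolerance = 1e-12)
  expect_true(fits$constant[fits$predictor == "k"])
  expect_true(is.na(fits$beta[fits$predictor == "k"]))

  # under the null, |beta| < 3 SE nearly always
  set.seed(42)
  hits <- 0L
  for (i in 1:40) {
    dn <- data.frame(y = rnorm(200), x = rnorm(200))
    f <- univariate_fits(dn, "y", "x")
    if (abs(f$beta) < 3 * f$se) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("multivariable_fit gates on univariate p < 0.10", {
  set.seed(7)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), junk = rnorm(n))
  d$y <- 1 + 0.8 * d$x1 + 0.8 * d$x2 + rnorm(n)

  fit <- multivariable_fit(d, "y", c("x1", "x2", "junk"))
  expect_true(all(c("x1", "x2") %in% fit$included))
  expect_false("junk" %in% fit$included)
  expect_lt(fit$model_p, 0.001)
  expect_true(fit$r2 > 0 && fit$r2 <= 1)

  # no qualifying predictor -> intercept-only with note
  dnull <- data.frame(y = rnorm(40), x = rnorm(40))
  # force the gate shut regardless of the draw
  fit0 <- multivariable_fit(dnull, "y", "x", entry_p = 1e-12)
  expect_identical(fit0$included, character(0))
  expect_match(fit0$note, "intercept-only")

  # exactly one qualifying predictor: multivariable equals univariate
  uni <- univariate_fits(d, "y", "x1")
  fit1 <- multivariable_fit(d, "y", "x1", univariate = uni)
  expect_equal(fit1$coefficients$beta[2], uni$beta, tolerance = 1e-12)
  expect_equal(fit1$coefficients$p[2], uni$p, tolerance = 1e-12)
})

test_that("planted interference slope and opioid effect are recovered", {
  set.seed(123)
  cfg <- cohort_sim_config(n_per_group = c(no_sci = 20L, acute_sci = 20L,
                                           chronic_sci = 20L),
                           pain_prevalence = c(no_sci = 0, acute_sci = 0.5,
                                               chronic_sci = 0.6),
                           interference_slope = 4e-4, opioid_beta = 3,
                           noise_sd = 1, seed = 77)
  markers <- matrix(exp(rnorm(60, log(3000), 1)), ncol = 1,
                    dimnames = list(sprintf("S%03d", 1:60), "mir19b"))
  cohort <- simulate_cohort(cfg, marker_levels = markers)
  fit <- multivariable_fit(cohort, "interference_mood",
                           c("mir19b", "opioid", "age", "sex_male"))
  expect_true(all(c("mir19b", "opioid") %in% fit$included))
  co <- fit$coefficients
  b <- co$beta[co$term == "mir19b"]
  se <- co$se[co$term == "mir19b"]
  expect_lt(abs(b - 4e-4), 3 * se)
})

test_that("covariate derivation uses the printed conversion constants", {
  # 2 glasses of wine + 1 beer = 2 x 10.8 + 13.2 = 34.8 g
  expect_equal(alcohol_grams(wine = 2, beer = 1), 34.8)
  expect_equal(alcohol_grams(liquor = 2), 30.2)
  expect_equal(alcohol_grams(), 0)
  expect_error(alcohol_grams(wine = -1))

  expect_equal(pack_years(packs_per_day = 1, years = 10), 10)
  expect_equal(pack_years(cigarettes_per_day = 10, years = 4), 2)
  expect_equal(pack_years(packs_per_day = 0, years = 10), 0)
  expect_error(pack_years(packs_per_day = -1, years = 2))

  expect_true(is_smoker(lifetime_packs = 20))
  expect_false(is_smoker(lifetime_packs = 19))
  expect_true(is_smoker(cigarettes_per_day = 1, years = 1))
  expect_false(is_smoker(cigarettes_per_day = 2, years = 0.5))
  expect_true(is_smoker(tobacco_grams = 336))
})

test_that("cohort_summary reproduces printed table statistics from counts", {
  # sex split 24/38 male vs 24/28 male: chi-square (no correction) p ~ 0.04
  d <- data.frame(
    pain = rep(c(0, 1), c(38, 28)),
    male = c(rep(c(1, 0), c(24, 14)), rep(c(1, 0), c(24, 4))))
  s <- cohort_summary(d, "pain", dichotomous = "male")
  expect_equal(round(s$p, 2), 0.04)

  # pooled mean column: groups with means 36.62 and 40.11 pool to 38.10
  age <- c(rep(36.62, 38), rep(40.11, 28)) + rep(c(-0.5, 0.5), 33)
  d$age <- age
  s2 <- cohort_summary(d, "pain", continuous = "age")
  expect_match(s2$total, "^38\\.10")

  # identical dichotomous groups give p = 1
  d3 <- data.frame(g = rep(c("a", "b"), each = 10),
                   flag = rep(c(0, 1), 10))
  s3 <- cohort_summary(d3, "g", dichotomous = "flag")
  expect_equal(s3$p, 1)

  expect_error(cohort_summary(data.frame(g = factor("a", levels = c("a", "b")),
                                         x = 1), "g", continuous = "x"),
               "empty group")
})
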