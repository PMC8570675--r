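# Biomarker statistics: ROC/AUC (single markers and a joint logistic
# score), univariate OLS screening of pain-interference predictors, the
# p < 0.10 entry-gated multivariable model, covariate derivation
# (grams of alcohol, pack-years, smoker status), and Table-1-style group
# summaries with tests.

#' ROC curve and AUC for a single marker
#'
#' The AUC is the Mann-Whitney probability that a random positive outranks
#' a random negative, with ties counted one half; the curve is traced over
#' every distinct threshold and its trapezoidal area equals the rank
#' statistic exactly.
#'
#' @param values numeric marker levels.
#' @param labels binary labels (logical, 0/1, or two-level factor); the
#'   higher level / `TRUE` / 1 is the positive class.
#' @return a `roc_curve`: list with `points` (data.frame `threshold`,
#'   `sens`, `fpr`) and `auc`.
#' @export
roc_auc <- function(values, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(values)                       # midranks: ties count 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(values), decreasing = TRUE))
  pts <- do.call(rbind, lapply(th, function(t) {
    data.frame(threshold = t,
               sens = sum(values >= t & labels == 1L) / n1,
               fpr = sum(values >= t & labels == 0L) / n0)
  }))
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =", format(x$auc), "\n")
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc a `roc_curve`.
#' @return the trapezoidal AUC (equals `roc$auc` up to floating point).
#' @export
roc_trapezoid <- function(roc) {
  p <- roc$points[order(roc$points$fpr, roc$points$sens), ]
  sum(diff(p$fpr) * (head(p$sens, -1) + p$sens[-1]) / 2)
}

#' ROC of two markers combined by a logistic score
#'
#' Fits `label ~ A + B` by maximum-likelihood logistic regression and runs
#' [roc_auc()] on the fitted linear predictor. Complete separation is
#' tolerated: the iteration cap is reached with a warning and the fitted
#' score still ranks samples.
#'
#' @param a,b numeric marker levels on the same samples.
#' @param labels binary labels as in [roc_auc()].
#' @return a `roc_curve`.
#' @export
combined_roc <- function(a, b, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  fit <- suppressWarnings(glm(labels ~ a + b, family = binomial()))
  roc_auc(fit$linear.predictors, labels)
}

#' Univariate linear-model screen of pain-interference predictors
#'
#' One ordinary-least-squares fit of `outcome ~ predictor` per candidate,
#' on complete cases for that pair (so n varies by predictor, mirroring
#' per-variable data availability). Constant predictors are flagged and
#' excluded from fitting.
#'
#' @param data data.frame holding outcome and predictors.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names;
#'   dichotomous predictors must be coded 0/1.
#' @return data.frame: `predictor`, `beta`, `se`, `p`, `r2`, `n`,
#'   `constant` (flag for excluded predictors, beta/se/p `NA`).
#' @export
univariate_fits <- function(data, outcome, predictors) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  out <- lapply(predictors, function(px) {
    d <- data[complete.cases(data[, c(outcome, px)]), c(outcome, px)]
    n <- nrow(d)
    if (n < 3 || length(unique(d[[px]])) < 2) {
      return(data.frame(predictor = px, beta = NA_real_, se = NA_real_,
                        p = NA_real_, r2 = NA_real_, n = n, constant = TRUE,
                        stringsAsFactors = FALSE))
    }
    # backticks: marker ids (e.g. "mir-001-5p") are not syntactic names
    fit <- lm(stats::as.formula(paste0("`", outcome, "` ~ `", px, "`")),
              data = d)
    sm <- summary(fit)
    co <- sm$coefficients
    data.frame(predictor = px, beta = co[2, 1], se = co[2, 2], p = co[2, 4],
               r2 = sm$r.squared, n = n, constant = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Multivariable model with a univariate entry gate
#'
#' Includes exactly the predictors whose univariate p-value is below
#' `entry_p` (0.10 by default) in one joint OLS fit on complete cases.
#' When no predictor qualifies an intercept-only fit is returned with a
#' note.
#'
#' @inheritParams univariate_fits
#' @param entry_p univariate p-value entry threshold.
#' @param univariate optional precomputed result of [univariate_fits()];
#'   computed if missing.
#' @return list with `included` (predictor names), `coefficients`
#'   (data.frame `term`, `beta`, `se`, `p`), `model_p` (overall F),
#'   `r2`, `n`, `note`.
#' @export
multivariable_fit <- function(data, outcome, predictors, entry_p = 0.10,
                              univariate = NULL) {
  if (is.null(univariate)) univariate <- univariate_fits(data, outcome, predictors)
  keep <- univariate$predictor[!univariate$constant &
                                 !is.na(univariate$p) &
                                 univariate$p < entry_p]
  if (!length(keep)) {
    d <- data[!is.na(data[[outcome]]), , drop = FALSE]
    return(list(included = character(0),
                coefficients = data.frame(term = "(Intercept)",
                                          beta = mean(d[[outcome]]),
                                          se = sd(d[[outcome]]) / sqrt(nrow(d)),
                                          p = NA_real_),
                model_p = NA_real_, r2 = 0, n = nrow(d),
                note = "no predictor passed the entry gate; intercept-only fit"))
  }
  d <- data[complete.cases(data[, c(outcome, keep)]), c(outcome, keep)]
  fit <- lm(stats::as.formula(paste0("`", outcome, "` ~ ",
                                     paste0("`", keep, "`", collapse = " + "))),
            data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(included = keep,
       coefficients = data.frame(term = rownames(co), beta = co[, 1],
                                 se = co[, 2], p = co[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
       model_p = model_p, r2 = sm$r.squared, n = nrow(d), note = NA_character_)
}

# covariate derivation -------------------------------------------------------

#' Lifetime alcohol in grams from drink counts
#'
#' Per-drink conversions: a 4 oz glass of wine = 10.8 g, a 12 oz beer =
#' 13.2 g, a 1.5 oz shot of liquor = 15.1 g of alcohol.
#'
#' @param wine,beer,liquor drink counts (non-negative, vectorized).
#' @return grams of alcohol.
#' @export
alcohol_grams <- function(wine = 0, beer = 0, liquor = 0) {
  stopifnot(all(wine >= 0), all(beer >= 0), all(liquor >= 0))
  10.8 * wine + 13.2 * beer + 15.1 * liquor
}

#' Pack-years of cigarette exposure
#'
#' Packs per day times years smoked; a pack is 20 cigarettes, so
#' `cigarettes_per_day` may be given instead of `packs_per_day`.
#'
#' @param packs_per_day packs smoked per day.
#' @param years years of smoking.
#' @param cigarettes_per_day alternative to `packs_per_day`.
#' @return pack-years.
#' @export
pack_years <- function(packs_per_day = NULL, years, cigarettes_per_day = NULL) {
  if (is.null(packs_per_day)) {
    stopifnot(!is.null(cigarettes_per_day))
    packs_per_day <- cigarettes_per_day / 20
  }
  stopifnot(all(packs_per_day >= 0), all(years >= 0))
  packs_per_day * years
}

#' Smoker status dichotomy
#'
#' A smoker is anyone with a lifetime total of 20 or more packs (or 336 g
#' of tobacco) or who smoked at least one cigarette a day for at least one
#' year.
#'
#' @param lifetime_packs total packs ever smoked.
#' @param cigarettes_per_day,years daily habit and its duration.
#' @param tobacco_grams lifetime loose-tobacco grams.
#' @return logical.
#' @export
is_smoker <- function(lifetime_packs = 0, cigarettes_per_day = 0, years = 0,
                      tobacco_grams = 0) {
  stopifnot(all(lifetime_packs >= 0), all(cigarettes_per_day >= 0),
            all(years >= 0), all(tobacco_grams >= 0))
  lifetime_packs >= 20 | tobacco_grams >= 336 |
    (cigarettes_per_day >= 1 & years >= 1)
}

#' Group summary table with per-variable tests
#'
#' Continuous variables are summarized as mean +/- SD per group and tested
#' by Welch's t-test (two groups) or one-way ANOVA (three or more);
#' dichotomous variables as n (%) with a Pearson chi-square test without
#' continuity correction (`fisher = TRUE` switches to Fisher's exact
#' test). A pooled "total" column is included.
#'
#' @param data cohort data.frame.
#' @param group name of the grouping column.
#' @param continuous,dichotomous character vectors of column names.
#' @param fisher use Fisher's exact test for the dichotomous rows.
#' @return data.frame, one row per variable: per-group summary strings, a
#'   total column and the test p-value.
#' @export
cohort_summary <- function(data, group, continuous = character(0),
                           dichotomous = character(0), fisher = FALSE) {
  g <- as.factor(data[[group]])   # as.factor: keep declared (unused) levels
  if (any(table(g) == 0)) stop("empty group in summary")
  lev <- levels(g)
  fmt_row <- function(name, cells, total, p) {
    row <- data.frame(variable = name, stringsAsFactors = FALSE)
    for (i in seq_along(lev)) row[[lev[i]]] <- cells[i]
    row$total <- total
    row$p <- p
    row
  }
  rows <- list()
  for (v in continuous) {
    x <- data[[v]]
    ok <- !is.na(x)
    cells <- vapply(lev, function(l) {
      xi <- x[ok & g == l]
      sprintf("%.2f ± %.2f", mean(xi), sd(xi))
    }, character(1))
    total <- sprintf("%.2f ± %.2f", mean(x[ok]), sd(x[ok]))
    p <- if (length(lev) == 2) {
      t.test(x[ok] ~ g[ok])$p.value
    } else {
      d <- data.frame(x = x[ok], g = g[ok])
      anova(lm(x ~ g, data = d))[["Pr(>F)"]][1]
    }
    rows[[length(rows) + 1L]] <- fmt_row(v, cells, total, p)
  }
  for (v in dichotomous) {
    x <- as.integer(data[[v]] > 0)
    ok <- !is.na(x)
    tab <- table(x[ok], g[ok])
    cells <- vapply(lev, function(l) {
      n1 <- sum(x[ok] == 1 & g[ok] == l); nl <- sum(g[ok] == l)
      sprintf("%d (%.1f)", n1, 100 * n1 / nl)
    }, character(1))
    total <- sprintf("%d (%.1f)", sum(x[ok]), 100 * mean(x[ok]))
    p <- if (length(unique(x[ok])) < 2) 1 else if (fisher) {
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    rows[[length(rows) + 1L]] <- fmt_row(v, cells, total, p)
  }
  do.call(rbind, rows)
}
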