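# Differential-expression screening. The study design deliberately screens
# on the raw p-value (no FDR adjustment) combined with a two-fold change
# gate; the test menu is Welch's t-test / one-way ANOVA on normalized
# values and chi-square (no continuity correction) or Fisher's exact test
# on aggregated raw counts.

#' Two-group differential screening per row
#'
#' For `test = "t"` a two-sided Welch t-test is run on the normalized
#' values of each row. For `test = "chi2"` / `"fisher"` the raw counts are
#' summed per group and tested against the remaining library counts in a
#' 2x2 table (chi-square without continuity correction; Fisher's exact
#' when any expected cell is below 5 and `test = "auto_count"`).
#' The log2 fold change is `log2((mean2 + eps) / (mean1 + eps))`, second
#' group over first.
#'
#' @param values numeric matrix of normalized values (rows = miRNAs).
#' @param groups factor/character vector over columns; exactly two levels.
#' @param test `"t"`, `"chi2"`, `"fisher"`, or `"auto_count"` (chi-square
#'   unless an expected cell < 5, then Fisher).
#' @param counts raw count matrix, required for the count-based tests.
#' @param eps pseudocount on group means for the fold change (default 0.5).
#' @return data.frame: `id`, `mean1`, `mean2`, `log2fc`, `test`, `p`,
#'   `degenerate` (zero variance in both groups for the t-test).
#' @export
compare_two_groups <- function(values, groups, test = c("t", "chi2", "fisher",
                                                        "auto_count"),
                               counts = NULL, eps = 0.5) {
  test <- match.arg(test)
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else unique(as.character(groups))
  groups <- as.character(groups)
  stopifnot(length(lev) == 2, length(groups) == ncol(values))
  g1 <- groups == lev[1]; g2 <- groups == lev[2]
  if (test == "t" && (sum(g1) < 2 || sum(g2) < 2)) {
    stop("each group needs at least 2 samples for the t-test")
  }
  if (test != "t" && is.null(counts)) {
    stop("count-based tests need the raw count matrix")
  }
  if (test != "t") {
    lib1 <- sum(counts[, g1]); lib2 <- sum(counts[, g2])
  }
  ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  out <- lapply(seq_len(nrow(values)), function(i) {
    v1 <- values[i, g1]; v2 <- values[i, g2]
    m1 <- mean(v1); m2 <- mean(v2)
    degenerate <- FALSE
    if (test == "t") {
      if (var(v1) == 0 && var(v2) == 0) {
        p <- 1; degenerate <- TRUE; used <- "t"
      } else {
        p <- t.test(v2, v1)$p.value; used <- "t"
      }
    } else {
      k1 <- sum(counts[i, g1]); k2 <- sum(counts[i, g2])
      tab <- matrix(c(k1, lib1 - k1, k2, lib2 - k2), nrow = 2)
      expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      used <- test
      if (test == "auto_count") used <- if (any(expct < 5)) "fisher" else "chi2"
      p <- if (used == "fisher") fisher.test(tab)$p.value
           else suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(id = ids[i], mean1 = m1, mean2 = m2,
               log2fc = log2((m2 + eps) / (m1 + eps)),
               test = used, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- lev
  res
}

#' k-group differential screening per row (one-way ANOVA)
#'
#' One-way fixed-effects ANOVA per row; pairwise log2 fold changes between
#' group means are attached. With exactly two groups the call is delegated
#' to [compare_two_groups()] (note the pooled-variance F of a two-group
#' ANOVA differs from Welch's t used there).
#'
#' @inheritParams compare_two_groups
#' @param groups grouping vector; every group needs n >= 2.
#' @return data.frame with `id`, per-group means, `p` (ANOVA F-test) and
#'   pairwise `log2fc_<a>_vs_<b>` columns.
#' @export
compare_k_groups <- function(values, groups, eps = 0.5) {
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else unique(as.character(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group '", names(sizes)[which(sizes < 2)[1]], "' has fewer than 2 samples")
  }
  if (length(lev) == 2) return(compare_two_groups(values, groups, "t", eps = eps))
  ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  gf <- factor(groups, levels = lev)
  out <- lapply(seq_len(nrow(values)), function(i) {
    y <- values[i, ]
    means <- tapply(y, gf, mean)
    grand <- mean(y)
    ssb <- sum(tabulate(gf) * (means - grand)^2)
    ssw <- sum((y - means[gf])^2)
    df1 <- length(lev) - 1; df2 <- length(y) - length(lev)
    if (ssw == 0 && ssb == 0) {
      fstat <- 0; p <- 1
    } else if (ssw == 0) {
      fstat <- Inf; p <- 0
    } else {
      fstat <- (ssb / df1) / (ssw / df2)
      p <- pf(fstat, df1, df2, lower.tail = FALSE)
    }
    row <- data.frame(id = ids[i], stringsAsFactors = FALSE)
    for (l in lev) row[[paste0("mean_", l)]] <- unname(means[l])
    row$F <- fstat
    row$p <- p
    for (a in seq_along(lev)) for (b in seq_along(lev)) {
      if (a < b) {
        row[[paste0("log2fc_", lev[b], "_vs_", lev[a])]] <-
          log2((means[[b]] + eps) / (means[[a]] + eps))
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Call differential expression and build volcano records
#'
#' No multiple-testing adjustment is applied: rows are flagged when the
#' raw p-value is below `alpha` and |log2 fold change| reaches `lfc_min`
#' (two-fold by default).
#'
#' @param results data.frame from [compare_two_groups()] with `log2fc` and
#'   `p` columns.
#' @param alpha raw p-value cutoff (default 0.05).
#' @param lfc_min minimum |log2 fold change| (default 1).
#' @return `results` with `de` (logical), `direction` (`"up"`, `"down"`,
#'   `"ns"`) and `neg_log10_p` columns appended.
#' @export
call_de <- function(results, alpha = 0.05, lfc_min = 1) {
  stopifnot(all(c("log2fc", "p") %in% names(results)))
  de <- results$p < alpha & abs(results$log2fc) >= lfc_min
  results$de <- de
  results$direction <- ifelse(!de, "ns", ifelse(results$log2fc > 0, "up", "down"))
  results$neg_log10_p <- -log10(results$p)
  results
}
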