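#' Kolmogorov-Smirnov normality screen with test routing
#'
#' One-sample KS test of the sample against a Normal with the sample's own
#' mean and SD (the uncorrected estimated-parameter reference used by common
#' statistics packages; the Lilliefors-corrected variant is available). The
#' routing rule sends p > 0.05 to the two-sample t branch and everything
#' else to the Mann-Whitney branch.
#'
#' @param sample numeric vector, n >= 5, non-constant.
#' @param lilliefors use the Lilliefors correction (requires the nortest
#'   package).
#' @param alpha routing threshold (0.05).
#' @return list with `statistic`, `p`, `branch` (`"t-test"` or
#'   `"mann-whitney"`).
#' @export
ks_normality <- function(sample, lilliefors = FALSE, alpha = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 5L) stopf("need n >= 5")
  if (stats::sd(sample) == 0) stopf("constant sample")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stopf("the Lilliefors variant requires the 'nortest' package")
    ks <- nortest::lillie.test(sample)
  } else {
    ks <- suppressWarnings(
      stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample)))
  }
  list(statistic = unname(ks$statistic), p = ks$p.value,
       branch = if (ks$p.value > alpha) "t-test" else "mann-whitney")
}

#' Two-sample t-test from printed group summaries
#'
#' Closed-form two-sample t from per-group (n, mean, SD) — exactly what a
#' published "mean +/- SD" table provides. The pooled (Student) variant uses
#' `s^2 = [(n1-1)s1^2 + (n2-1)s2^2] / (n1+n2-2)` with `df = n1+n2-2`; the
#' Welch variant uses the Satterthwaite degrees of freedom.
#'
#' @param g1,g2 lists (or named vectors) with `n`, `mean`, `sd` per group.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @examples
#' ttest_from_summary(list(n = 51, mean = 41.17, sd = 3.24),
#'                    list(n = 48, mean = 39.95, sd = 2.77))$p  # ~0.047
#' @export
ttest_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  g1 <- as.list(g1); g2 <- as.list(g2)
  for (g in list(g1, g2))
    if (g$n < 2 || g$sd <= 0) stopf("each group needs n >= 2 and sd > 0")
  if (variant == "pooled") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
    t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Two-sided; exact for small tie-free samples, normal approximation with
#' tie correction otherwise (the behavior of [stats::wilcox.test()], which
#' performs the computation). The returned `U` is the statistic for
#' `sample1`; `U1 + U2 = n1 * n2`.
#'
#' @param sample1,sample2 numeric vectors.
#' @return list with `U`, `p`.
#' @export
mannwhitney <- function(sample1, sample2) {
  wt <- suppressWarnings(stats::wilcox.test(sample1, sample2,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Continuity-corrected chi-square with df = 1; the correction is capped so
#' the statistic cannot go negative. Uncorrected and Fisher-exact variants
#' are available.
#'
#' @param table 2x2 matrix of nonnegative counts (rows = group,
#'   columns = category), or a length-4 vector `(a, b, c, d)` filled by row.
#' @param variant `"yates"` (default), `"uncorrected"` or `"fisher"`.
#' @return list with `statistic` (NA for the Fisher variant), `p`, `df`.
#' @examples
#' chi2_yates(matrix(c(48, 3, 47, 1), 2, 2, byrow = TRUE))$p  # ~0.654
#' @export
chi2_yates <- function(table, variant = c("yates", "uncorrected", "fisher")) {
  variant <- match.arg(variant)
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0))
    stopf("need a 2x2 table of nonnegative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("a table margin is zero")
  if (variant == "fisher") {
    ft <- stats::fisher.test(table)
    return(list(statistic = NA_real_, p = ft$p.value, df = NA_integer_))
  }
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = variant == "yates"))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Group-comparison table for cohort demographics
#'
#' For each requested continuous variable: per-group mean +/- SD, a
#' normality screen on each group ([ks_normality()]), then a pooled
#' two-sample t-test if both groups pass (p > 0.05) or a Mann-Whitney U test
#' otherwise. Dichotomous variables (exactly 2 distinct values) get a
#' Yates-corrected chi-square. The test used is recorded per row.
#'
#' @param participants data.frame with a `group` column (values 1/2 or
#'   `"MCI"`/`"nMCI"`) and the requested variables.
#' @param variables character vector of column names to compare.
#' @param dichotomous subset of `variables` to treat as dichotomous;
#'   non-numeric two-level columns are treated as dichotomous automatically.
#' @param out_dir optional directory; writes `demographics.tsv` and
#'   `demographics.md`.
#' @return data.frame with columns `variable`, `mci_summary`,
#'   `nmci_summary`, `test`, `statistic`, `p`.
#' @export
demographics_table <- function(participants, variables,
                               dichotomous = character(), out_dir = NULL) {
  stopifnot("group" %in% names(participants))
  missing_v <- setdiff(variables, names(participants))
  if (length(missing_v))
    stopf("missing column(s): %s", paste(missing_v, collapse = ", "))
  grp <- participants$group
  if (!all(grp %in% c(1, 2, "MCI", "nMCI")))
    stopf("`group` must be 1/2 or MCI/nMCI")
  is1 <- grp %in% c(1, "MCI")

  rows <- lapply(variables, function(v) {
    x <- participants[[v]]
    if (v %in% dichotomous || (!is.numeric(x) && length(unique(x)) == 2L)) {
      tab <- table(factor(is1, c(TRUE, FALSE)), factor(x))
      res <- chi2_yates(matrix(as.integer(tab), 2, 2))
      data.frame(variable = v,
                 mci_summary = paste(tab[1, ], collapse = "/"),
                 nmci_summary = paste(tab[2, ], collapse = "/"),
                 test = "chi-square (Yates)", statistic = res$statistic,
                 p = res$p, stringsAsFactors = FALSE)
    } else {
      x1 <- x[is1]; x2 <- x[!is1]
      ## samples too small to screen for normality default to the t branch
      branch <- if (length(x1) < 5L || length(x2) < 5L) "t-test"
        else if (stats::sd(x1) == 0 || stats::sd(x2) == 0) "t-test"
        else if (ks_normality(x1)$branch == "t-test" &&
                 ks_normality(x2)$branch == "t-test") "t-test"
        else "mann-whitney"
      if (branch == "t-test") {
        if (stats::sd(x1) == 0 && stats::sd(x2) == 0 &&
            mean(x1) == mean(x2)) {
          res <- list(t = 0, p = 1)
        } else {
          res <- ttest_from_summary(
            list(n = length(x1), mean = mean(x1), sd = max(stats::sd(x1), 1e-12)),
            list(n = length(x2), mean = mean(x2), sd = max(stats::sd(x2), 1e-12)))
        }
        stat <- res$t; p <- res$p; test <- "t-test (pooled)"
      } else {
        res <- mannwhitney(x1, x2)
        stat <- res$U; p <- res$p; test <- "Mann-Whitney U"
      }
      data.frame(variable = v,
                 mci_summary = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
                 nmci_summary = sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2)),
                 test = test, statistic = stat, p = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "demographics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    md <- c("| Variable | MCI | nMCI | Test | p |",
            "|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %s | %.3f |", out$variable,
                    out$mci_summary, out$nmci_summary, out$test, out$p))
    writeLines(md, file.path(out_dir, "demographics.md"))
  }
  out
}

#' Printed cohort summary statistics
#'
#' Loads the shipped per-group (n, mean, SD) summaries of the study cohort's
#' demographic and polysomnography variables, plus the printed p-values, for
#' recomputation from summaries alone.
#'
#' @return data.frame with columns `variable`, `unit`, `mci_n`, `mci_mean`,
#'   `mci_sd`, `nmci_n`, `nmci_mean`, `nmci_sd`, `printed_p`.
#' @export
table1_summaries <- function() {
  path <- system.file("extdata", "table1_demographics.tsv",
                      package = "neurodc", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname table1_summaries
#' @return for `table1_sex_counts()`: a 2x2 integer matrix (rows MCI/nMCI,
#'   columns male/female).
#' @export
table1_sex_counts <- function() {
  path <- system.file("extdata", "table1_sex_counts.tsv",
                      package = "neurodc", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("male", "female")])
  rownames(m) <- df$group
  m
}
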