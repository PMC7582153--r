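#' Group comparison tests over a lesion feature table
#'
#' Thin layer over base R's established test routines, recording the test
#' name, group sizes, statistic and p-value in a tidy one-row data frame.
#' All tests are two-sided and no multiplicity correction is applied.
#'
#' * `mann_whitney`: `feature` numeric vs a two-level `grouping`
#'   (`wilcox.test`, rank-sum form).
#' * `kruskal_wallis`: `feature` numeric vs a multi-level `grouping`.
#' * `wilcoxon_signed_rank`: paired within-lesion values in `feature` and
#'   `feature2` (e.g. viable vs necrotic coverage). When all paired
#'   differences are zero the conventional degenerate result (statistic 0,
#'   p = 1) is returned, since the test statistic has no distribution there.
#' * `fisher_exact`: `feature` and `grouping` are categorical columns whose
#'   cross-table is tested (`fisher.test`).
#'
#' @param table lesion feature data.frame.
#' @param feature column name of the outcome (numeric, or categorical for
#'   Fisher).
#' @param grouping column name of the grouping factor (`NULL` for the signed
#'   rank test).
#' @param test which test to run.
#' @param feature2 second paired column, signed-rank test only.
#' @return One-row data.frame: `comparison`, `test`, `n1`, `n2`,
#'   `statistic`, `p`.
#' @export
compare_groups <- function(table, feature, grouping = NULL,
                           test = c("mann_whitney", "kruskal_wallis",
                                    "wilcoxon_signed_rank", "fisher_exact"),
                           feature2 = NULL) {
  test <- match.arg(test)
  row <- function(comparison, n1, n2, statistic, p)
    data.frame(comparison = comparison, test = test, n1 = n1, n2 = n2,
               statistic = statistic, p = p, stringsAsFactors = FALSE)

  if (test == "wilcoxon_signed_rank") {
    if (is.null(feature2))
      stop("signed-rank test needs paired columns `feature` and `feature2`")
    x <- table[[feature]]; y <- table[[feature2]]
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) == 0) stop("no paired observations")
    if (all(x == y))
      return(row(paste(feature, "vs", feature2), length(x), length(x), 0, 1))
    ht <- wilcox.test(x, y, paired = TRUE)
    return(row(paste(feature, "vs", feature2), length(x), length(x),
               unname(ht$statistic), ht$p.value))
  }

  g <- table[[grouping]]
  v <- table[[feature]]
  keep <- complete.cases(v, g)
  v <- v[keep]; g <- factor(g[keep])
  if (any(tabulate(g) == 0) || nlevels(g) < 2)
    stop("each group must have at least one observation")

  if (test == "mann_whitney") {
    if (nlevels(g) != 2) stop("Mann-Whitney needs exactly 2 groups")
    ht <- wilcox.test(v ~ g)
    row(paste(feature, "by", grouping), sum(g == levels(g)[1]),
        sum(g == levels(g)[2]), unname(ht$statistic), ht$p.value)
  } else if (test == "kruskal_wallis") {
    ht <- kruskal.test(v ~ g)
    row(paste(feature, "by", grouping), length(v), nlevels(g),
        unname(ht$statistic), ht$p.value)
  } else {
    tab <- table(v, g)
    ht <- fisher.test(tab)
    row(paste(feature, "by", grouping), sum(tab[, 1]), sum(tab[, 2]),
        NA_real_, ht$p.value)
  }
}

#' Exact Fisher test on a prebuilt contingency table
#'
#' Convenience wrapper used when the 2x2 counts (e.g. responder by pattern)
#' are already tabulated.
#'
#' @param counts a contingency matrix.
#' @return One-row data.frame as in [compare_groups()].
#' @export
fisher_from_counts <- function(counts) {
  ht <- fisher.test(counts)
  data.frame(comparison = "contingency table", test = "fisher_exact",
             n1 = sum(counts[, 1]), n2 = sum(counts[, 2]),
             statistic = NA_real_, p = ht$p.value, stringsAsFactors = FALSE)
}

#' Peripheral coverage vs ETV change regression
#'
#' Ordinary least squares of the percent ETV change on peripheral Lipiodol
#' coverage, plus Spearman's rank correlation — the association the source
#' study summarizes as percent response per percentage point of peripheral
#' coverage.
#'
#' @param table data.frame with columns `peripheral_pct` and `pct_change`.
#' @return List: `slope`, `intercept`, `slope_se`, `spearman_rho`, `p`
#'   (Spearman), `n`.
#' @export
peripheral_regression <- function(table) {
  keep <- complete.cases(table$peripheral_pct, table$pct_change)
  x <- table$peripheral_pct[keep]
  y <- table$pct_change[keep]
  if (length(x) < 3) stop("need at least 3 lesions with defined values")
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       slope_se = summary(fit)$coefficients[2, 2],
       spearman_rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
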