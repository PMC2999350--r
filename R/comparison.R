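# Between-set statistics: two-sample rank-sum tests on per-node measures,
# two-proportion chi-square tests for hub fractions, Pearson correlations
# among measures, and the table-builder comparing topology profiles.

comparison_row <- function(measure, set_a, set_b, test, statistic, p_value,
                           n_a, n_b) {
  data.frame(measure = measure, set_a = set_a, set_b = set_b, test = test,
             statistic = as.numeric(statistic), p_value = as.numeric(p_value),
             n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location difference between two independent samples.
#' The p-value is exact (full enumeration of rank assignments) for small
#' tie-free samples and uses the normal approximation with tie correction
#' otherwise, the standard behavior for rank-sum tests on large samples.
#'
#' @param x,y Numeric samples (each non-empty); `NA`s are dropped.
#' @param set_a,set_b Optional labels carried into the result.
#' @param measure Optional measure label.
#' @return One-row comparison data frame (`measure`, `set_a`, `set_b`,
#'   `test`, `statistic` = Mann-Whitney W, `p_value`, `n_a`, `n_b`).
#' @export
wilcoxon_rank_sum <- function(x, y, set_a = "a", set_b = "b", measure = "") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty sample in rank-sum test")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                            correct = TRUE))
  comparison_row(measure, set_a, set_b, "wilcoxon", wt$statistic,
                 wt$p.value, length(x), length(y))
}

#' Two-proportion chi-square test
#'
#' 2x2 chi-square test (1 d.f.) of equal proportions, used for comparing hub
#' fractions between protein sets. Yates continuity correction is applied by
#' default; a warning is emitted when an expected cell count drops below 1.
#'
#' @param count_a,n_a Successes and trials in group a.
#' @param count_b,n_b Successes and trials in group b.
#' @param continuity Apply Yates correction (default `TRUE`).
#' @param set_a,set_b,measure Optional labels.
#' @return One-row comparison data frame; `statistic` is the chi-square value.
#' @export
chi_square_two_proportions <- function(count_a, n_a, count_b, n_b,
                                       continuity = TRUE,
                                       set_a = "a", set_b = "b",
                                       measure = "") {
  if (n_a < 1L || n_b < 1L) stop("group sizes must be at least 1")
  if (count_a < 0 || count_a > n_a || count_b < 0 || count_b > n_b) {
    stop("counts must satisfy 0 <= count <= n")
  }
  p_pool <- (count_a + count_b) / (n_a + n_b)
  expected <- c(n_a * p_pool, n_a * (1 - p_pool),
                n_b * p_pool, n_b * (1 - p_pool))
  if (any(expected < 1)) warning("expected cell count below 1")
  if (count_a / n_a == count_b / n_b) {
    # identical proportions (including the all-or-none boundary, where the
    # chi-square statistic is 0/0): no evidence of a difference
    return(comparison_row(measure, set_a, set_b, "chi_square", 0, 1, n_a, n_b))
  }
  ht <- suppressWarnings(stats::prop.test(c(count_a, count_b), c(n_a, n_b),
                                          correct = continuity))
  comparison_row(measure, set_a, set_b, "chi_square", ht$statistic,
                 ht$p.value, n_a, n_b)
}

#' Pearson product-moment correlation test
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance;
#'   pairs with an `NA` are dropped.
#' @param set_a,set_b,measure Optional labels.
#' @return One-row comparison data frame; `statistic` is r, `p_value` the
#'   two-sided p from the t transform.
#' @export
pearson_correlation <- function(x, y, set_a = "x", set_b = "y",
                                measure = "") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  comparison_row(measure, set_a, set_b, "pearson", ct$estimate, ct$p.value,
                 length(x), length(y))
}

#' Compare topology profiles across protein sets
#'
#' For each requested pair of sets and each measure, runs a two-sided
#' rank-sum test on the per-node defined values. For degree (`"k"`) a
#' two-sample Kolmogorov-Smirnov row (test `"ks"`) is additionally emitted:
#' an average-degree comparison and a degree-*distribution* comparison are
#' different questions and both are reported, labeled distinctly. Hub
#' fractions are compared with the two-proportion chi-square test at each
#' cutoff (measure `"hub>cutoff"`).
#'
#' @param profiles Named list of `topology_profile` objects (names are set
#'   labels).
#' @param pairs List of length-2 character vectors of set labels.
#' @param measures Measures to compare; subset of `k`, `B`, `C`, `gSPD`,
#'   `cSPD`.
#' @param hub_cutoffs Degree cutoffs for the hub-fraction rows.
#' @return Data frame, one row per (pair, measure/test).
#' @export
compare_profiles <- function(profiles, pairs,
                             measures = c("k", "B", "C", "gSPD", "cSPD"),
                             hub_cutoffs = c(5L, 12L)) {
  stopifnot(is.list(profiles), length(names(profiles)) == length(profiles))
  measures <- match.arg(measures, several.ok = TRUE)
  rows <- list()
  for (pr in pairs) {
    a <- pr[[1L]]; b <- pr[[2L]]
    if (!a %in% names(profiles)) stop("unknown set label: ", a)
    if (!b %in% names(profiles)) stop("unknown set label: ", b)
    na <- profiles[[a]]$nodes; nb <- profiles[[b]]$nodes
    for (m in measures) {
      xa <- na[[m]]; xb <- nb[[m]]
      rows[[length(rows) + 1L]] <-
        wilcoxon_rank_sum(xa, xb, set_a = a, set_b = b, measure = m)
      if (m == "k") {
        ks <- suppressWarnings(stats::ks.test(xa[!is.na(xa)], xb[!is.na(xb)]))
        rows[[length(rows) + 1L]] <-
          comparison_row("k", a, b, "ks", ks$statistic, ks$p.value,
                         sum(!is.na(xa)), sum(!is.na(xb)))
      }
    }
    for (co in hub_cutoffs) {
      ha <- classify_hubs(na$k, co); hb <- classify_hubs(nb$k, co)
      rows[[length(rows) + 1L]] <-
        chi_square_two_proportions(ha$count, nrow(na), hb$count, nrow(nb),
                                   set_a = a, set_b = b,
                                   measure = paste0("hub>", co))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
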