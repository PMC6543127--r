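#' Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 20 and the data
#' are tie-free; otherwise the normal approximation with tie and continuity
#' corrections. Two-sided.
#'
#' @param x,y numeric vectors (non-empty).
#' @param exact_max pooled size up to which the exact null distribution is
#'   used (in the absence of ties).
#' @return list(statistic = W, p).
#' @export
wilcoxonRankSum <- function(x, y, exact_max = 20) {
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up q-values: q_(i) = min over j >= i of p_(j) * m / j, capped at 1,
#' returned in the original order. Controls the false discovery rate for
#' independent or positively dependent tests.
#'
#' @param pvals vector of p-values in [0, 1] (no NA).
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  if (anyNA(pvals)) stop("NA p-values")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Group-wise differential abundance
#'
#' The standard case-control screen: abundance/prevalence filter
#' ([filterFeatures()]), per-feature two-sided Wilcoxon rank-sum test, and
#' Benjamini-Hochberg adjustment across the tested features. Direction is
#' the group with the higher mean abundance.
#'
#' @param m relative [AbundanceMatrix-class].
#' @param meta sample metadata with columns sample_id, group (two groups,
#'   case/control).
#' @param alpha q-value significance threshold.
#' @param min_mean,min_prevalence filter thresholds (see
#'   [filterFeatures()]); set both to 0 to test every feature.
#' @return data.frame (one row per tested feature): feature_id, mean_case,
#'   mean_control, direction, statistic, p, q, significant.
#' @export
differentialFeatures <- function(m, meta, alpha = 0.05,
                                 min_mean = 1e-4, min_prevalence = 6) {
  stopifnot(is(m, "AbundanceMatrix"))
  filtered <- filterFeatures(
    if (m@kind == "relative") m else relativeAbundance(m),
    min_mean, min_prevalence)
  v <- abundances(filtered)
  grp <- meta$group[match(colnames(v), meta$sample_id)]
  if (length(unique(grp)) != 2) stop("exactly two groups required")
  if (any(table(grp) < 2)) stop("need at least 2 samples per group")
  case <- grp == "case"
  if (!any(case)) { # generic two-group fallback: first level is "case"
    case <- grp == sort(unique(grp))[1]
  }
  if (!nrow(v))
    return(data.frame(feature_id = character(), mean_case = numeric(),
                      mean_control = numeric(), direction = character(),
                      statistic = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  tests <- apply(v, 1L, function(row)
    unlist(wilcoxonRankSum(row[case], row[!case])))
  mean_case <- rowMeans(v[, case, drop = FALSE])
  mean_control <- rowMeans(v[, !case, drop = FALSE])
  q <- bhAdjust(tests["p", ])
  data.frame(
    feature_id = rownames(v),
    mean_case = mean_case, mean_control = mean_control,
    direction = ifelse(mean_case >= mean_control, "case_enriched",
                       "control_enriched"),
    statistic = tests["statistic", ], p = tests["p", ], q = q,
    significant = q < alpha, row.names = NULL)
}

#' Row-wise z-scores
#'
#' Standardises each feature across samples: subtract the row mean, divide
#' by the row standard deviation. The SD convention is the population SD
#' (divide by n) by default; constant rows map to all zeros.
#'
#' @param m matrix or [AbundanceMatrix-class].
#' @param population use the population SD (TRUE) or the sample SD.
#' @return matrix of z-scores, same dimnames.
#' @export
zscoreRows <- function(m, population = TRUE) {
  v <- if (is(m, "AbundanceMatrix")) abundances(m) else as.matrix(m)
  n <- ncol(v)
  mu <- rowMeans(v)
  centred <- v - mu
  sd <- sqrt(rowSums(centred^2) / if (population) n else (n - 1))
  z <- centred / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t with df = n1 + n2 - 2, computed from group
#' means, SDs and sizes (as printed in a baseline-characteristics table).
#' Set \code{welch = TRUE} for the Welch-Satterthwaite variant.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @param welch use unequal-variance t instead of pooled.
#' @return list(t, df, p) with a two-sided p.
#' @export
summaryTtest <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return list(statistic, df, p).
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Baseline clinical comparison table
#'
#' Per covariate: group summaries and a between-group test. Normally
#' distributed variables get mean +/- SD and the pooled t-test; skewed
#' variables get median (IQR) and the Wilcoxon rank-sum test; categorical
#' variables get counts and the uncorrected chi-square test.
#'
#' @param meta metadata data.frame with group plus covariate columns.
#' @param normal_vars covariates summarised as mean +/- SD (t-test).
#' @param skewed_vars covariates summarised as median (IQR) (Wilcoxon).
#' @param categorical_vars covariates tested by chi-square.
#' @return data.frame (variable, case_summary, control_summary, test, p).
#' @export
clinicalSummary <- function(meta,
                            normal_vars = c("total_cholesterol"),
                            skewed_vars = c("age", "bmi", "triglyceride",
                                            "ldl_cholesterol"),
                            categorical_vars = c("sex")) {
  case <- meta$group == "case"
  rows <- list()
  fmt_ms <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  fmt_iqr <- function(x) sprintf("%.2f (%.2f, %.2f)", stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
  for (v in intersect(normal_vars, names(meta))) {
    x <- meta[[v]][case]; y <- meta[[v]][!case]
    p <- summaryTtest(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y))$p
    rows[[v]] <- data.frame(variable = v, case_summary = fmt_ms(x),
                            control_summary = fmt_ms(y), test = "t", p = p)
  }
  for (v in intersect(skewed_vars, names(meta))) {
    x <- meta[[v]][case]; y <- meta[[v]][!case]
    p <- wilcoxonRankSum(x, y)$p
    rows[[v]] <- data.frame(variable = v, case_summary = fmt_iqr(x),
                            control_summary = fmt_iqr(y), test = "wilcoxon",
                            p = p)
  }
  for (v in intersect(categorical_vars, names(meta))) {
    tab <- table(meta[[v]], meta$group)
    p <- if (all(dim(tab) == 2)) chiSquare2x2(tab)$p else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    summ <- apply(tab, 2L, paste, collapse = "/")
    rows[[v]] <- data.frame(variable = v,
                            case_summary = summ[["case"]],
                            control_summary = summ[["control"]],
                            test = "chi_square", p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
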