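#' Shannon diversity index
#'
#' H = -sum(p_i log p_i) over the positive entries of a relative-abundance
#' profile. The logarithm base defaults to e (nats); pass \code{base = 2}
#' for bits.
#'
#' @param profile numeric vector of relative abundances (sums to 1 within
#'   1e-6).
#' @param base logarithm base.
#' @return H >= 0.
#' @export
shannonIndex <- function(profile, base = exp(1)) {
  if (any(profile < 0)) stop("negative abundances")
  s <- sum(profile)
  if (s <= 0) stop("all-zero profile")
  if (abs(s - 1) > 1e-6) stop("profile must sum to 1")
  p <- profile[profile > 0]
  -sum(p * log(p, base = base))
}

#' Bias-corrected Chao1 richness
#'
#' S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and F2 are the
#' numbers of singleton and doubleton features. The bias-corrected form
#' stays defined when no doubletons are observed. Requires integer counts
#' (the estimator is undefined on fractional abundances).
#'
#' @param counts non-negative integer count vector.
#' @return estimated richness >= observed richness.
#' @export
chaoRichness <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("Chao1 is defined on integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Pielou evenness
#'
#' J = H / ln(S_obs), the Shannon index relative to its maximum for the
#' observed number of taxa; J is 1 for a perfectly even profile.
#'
#' @param profile relative-abundance vector with at least 2 positive taxa.
#' @return J in [0, 1].
#' @export
pielouEvenness <- function(profile) {
  s_obs <- sum(profile > 0)
  if (s_obs < 2) stop("evenness undefined for fewer than 2 observed taxa")
  shannonIndex(profile) / log(s_obs)
}

#' Firmicutes/Bacteroidetes ratio
#'
#' @param phylum_profile named abundance vector containing entries
#'   \code{"Firmicutes"} and \code{"Bacteroidetes"}; scale-invariant.
#' @return F/B ratio (error if Bacteroidetes is absent or zero).
#' @export
fbRatio <- function(phylum_profile) {
  if (!all(c("Firmicutes", "Bacteroidetes") %in% names(phylum_profile)))
    stop("profile must contain Firmicutes and Bacteroidetes")
  b <- phylum_profile[["Bacteroidetes"]]
  if (b <= 0) stop("Bacteroidetes abundance is zero; ratio undefined")
  phylum_profile[["Firmicutes"]] / b
}

#' Sample-accumulation rarefaction curve
#'
#' For every m in 1..N, draws m samples with replacement and counts the
#' genes detected (depth > 0) in at least one drawn sample; the curve is the
#' mean over \code{iterations} repeats. This is the gene-richness
#' rarefaction used to judge whether a cohort's sequencing saturates the
#' gene catalogue.
#'
#' @param m gene-level [AbundanceMatrix-class].
#' @param iterations number of random draws per m (default 100).
#' @param seed RNG seed.
#' @return list with \code{m} (1..N), \code{mean_genes}, and the
#'   \code{iterations} x N matrix of per-draw gene counts.
#' @export
rarefactionCurve <- function(m, iterations = 100, seed = 1) {
  stopifnot(is(m, "AbundanceMatrix"))
  if (iterations < 1) stop("iterations must be >= 1")
  present <- abundances(m) > 0
  n <- ncol(present)
  if (n < 1) stop("need at least one sample")
  set.seed(seed)
  counts <- matrix(0L, iterations, n)
  for (it in seq_len(iterations)) {
    for (k in seq_len(n)) {
      drawn <- sample.int(n, k, replace = TRUE)
      counts[it, k] <- sum(rowSums(present[, drawn, drop = FALSE]) > 0)
    }
  }
  list(m = seq_len(n), mean_genes = colMeans(counts), draws = counts)
}

#' Per-sample diversity report
#'
#' Computes, for every sample: gene count (genes with positive depth),
#' Shannon index and Pielou evenness on the genus profile, bias-corrected
#' Chao1 on genus counts (relative abundances rescaled to integer counts),
#' and the Firmicutes/Bacteroidetes ratio from the phylum profile.
#'
#' @param genes gene-level depth [AbundanceMatrix-class].
#' @param genus relative genus [AbundanceMatrix-class].
#' @param phylum relative phylum [AbundanceMatrix-class].
#' @param count_scale factor used to turn relative genus abundances into
#'   pseudo-counts for Chao1.
#' @return data.frame with one row per sample.
#' @export
diversityReport <- function(genes, genus, phylum, count_scale = 1e6) {
  samples <- sampleIds(genus)
  gv <- abundances(genes)[, samples, drop = FALSE]
  uv <- abundances(genus)
  pv <- abundances(phylum)
  data.frame(
    sample_id = samples,
    gene_count = colSums(gv > 0),
    shannon = apply(uv, 2L, shannonIndex),
    chao = apply(round(uv * count_scale), 2L, chaoRichness),
    pielou = apply(uv, 2L, pielouEvenness),
    fb_ratio = apply(pv, 2L, fbRatio),
    row.names = NULL)
}

#' Two-group / k-group comparison of a per-sample statistic
#'
#' Kruskal-Wallis for any number of groups, or the Wilcoxon rank-sum test
#' for the two-group case (delegating to [wilcoxonRankSum()]).
#'
#' @param values numeric per-sample values.
#' @param groups group labels, same length.
#' @param test \code{"kruskal_wallis"} or \code{"wilcoxon"}.
#' @return list(statistic, p).
#' @export
compareGroups <- function(values, groups,
                          test = c("kruskal_wallis", "wilcoxon")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  if (test == "wilcoxon") {
    if (nlevels(groups) != 2) stop("Wilcoxon requires exactly two groups")
    sp <- split(values, groups)
    res <- wilcoxonRankSum(sp[[1]], sp[[2]])
    list(statistic = res$statistic, p = res$p)
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(statistic = unname(kt$statistic), p = kt$p.value)
  }
}
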