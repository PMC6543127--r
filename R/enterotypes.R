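#' Jensen-Shannon distance matrix
#'
#' D(a, b) = sqrt(JSD(a, b)) with the divergence in log base 2, so D is a
#' metric bounded in [0, 1]; zero-probability terms contribute nothing.
#' This is the community dissimilarity used for enterotype detection.
#'
#' @param profiles relative [AbundanceMatrix-class] (columns sum to 1).
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
jsdMatrix <- function(profiles) {
  stopifnot(is(profiles, "AbundanceMatrix"))
  v <- abundances(profiles)
  if (any(v < 0)) stop("negative abundances")
  n <- ncol(v)
  D <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  kl2 <- function(p, m) {
    i <- p > 0
    sum(p[i] * log2(p[i] / m[i]))
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      mid <- (v[, a] + v[, b]) / 2
      d <- sqrt(0.5 * kl2(v[, a], mid) + 0.5 * kl2(v[, b], mid))
      D[a, b] <- D[b, a] <- d
    }
  }
  D
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' Thin wrapper around \code{cluster::pam} (BUILD + SWAP k-medoids). The
#' procedure is deterministic for a given distance matrix; \code{seed} is
#' accepted for API symmetry with the stochastic stages.
#'
#' @param D symmetric distance matrix.
#' @param k number of clusters (2..n).
#' @param seed unused (PAM is deterministic); kept for interface symmetry.
#' @return list(labels = named integer 1..k, medoids = sample ids,
#'   objective = sum of distances to medoids).
#' @export
pamCluster <- function(D, k, seed = NULL) {
  n <- nrow(D)
  if (k > n) stop("k cannot exceed the number of samples")
  if (k < 1) stop("k must be positive")
  if (k == n) {
    # degenerate: every sample is its own medoid at zero cost
    ids <- rownames(D)
    return(list(labels = stats::setNames(seq_len(n), ids), medoids = ids,
                objective = 0))
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      variant = "original")
  list(labels = stats::setNames(as.integer(fit$clustering), rownames(D)),
       medoids = fit$medoids,
       objective = sum(D[cbind(seq_len(n), match(fit$medoids, rownames(D))[fit$clustering])]))
}

#' Distance-based Calinski-Harabasz index
#'
#' The coordinate-free generalisation of the CH criterion: total
#' squared-distance mass T = sum(D^2)/(2n) decomposes into within-cluster
#' mass W = sum over clusters of sum(D^2 within)/(2 n_c) and B = T - W;
#' CH(k) = (B / (k - 1)) / (W / (n - k)).
#'
#' @param D symmetric distance matrix.
#' @param labels cluster labels (>= 2 non-empty clusters).
#' @return CH >= 0.
#' @export
chIndex <- function(D, labels) {
  labels <- as.integer(as.factor(labels))
  n <- length(labels)
  k <- length(unique(labels))
  if (k < 2) stop("CH index needs at least 2 clusters")
  if (k >= n) stop("CH index undefined when every sample is a singleton")
  D2 <- D^2
  total <- sum(D2) / (2 * n)
  W <- 0
  for (cl in unique(labels)) {
    i <- labels == cl
    W <- W + sum(D2[i, i]) / (2 * sum(i))
  }
  B <- max(total - W, 0)
  if (W == 0) return(if (B == 0) 0 else Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the cluster count by the CH index
#'
#' Runs PAM for every candidate k and returns the argmax-CH solution with
#' the full CH curve retained (ties broken towards smaller k).
#'
#' @param D symmetric distance matrix.
#' @param k_range candidate cluster counts.
#' @param seed forwarded to [pamCluster()] (deterministic anyway).
#' @return list(k_selected, labels, medoids, ch_curve).
#' @export
selectK <- function(D, k_range = 2:10, seed = NULL) {
  k_range <- k_range[k_range < nrow(D)]
  if (!length(k_range)) stop("no feasible k below the sample count")
  fits <- lapply(k_range, function(k) pamCluster(D, k, seed))
  ch <- vapply(seq_along(k_range), function(i)
    chIndex(D, fits[[i]]$labels), numeric(1))
  names(ch) <- k_range
  best <- which.max(ch)
  list(k_selected = k_range[best], labels = fits[[best]]$labels,
       medoids = fits[[best]]$medoids, ch_curve = ch)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p by the "probability at most that of the
#' observed table" convention, with a 1e-7 relative tolerance for
#' floating-point ties.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return two-sided p-value.
#' @export
fisherExactTest <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-8))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero margin")
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); kk <- sum(table[, 1])
  support <- max(0L, kk - n2):min(kk, m)
  dens <- stats::dhyper(support, m, n2, kk)
  obs <- stats::dhyper(table[1, 1], m, n2, kk)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Enterotype-by-group association and dominant taxa
#'
#' Builds the cluster x group contingency table, tests association (Fisher's
#' exact test for the 2 x 2 case, Pearson chi-square otherwise) and names
#' each cluster's dominant taxon (highest mean relative abundance among its
#' samples).
#'
#' @param labels named cluster labels per sample.
#' @param meta sample metadata (sample_id, group).
#' @param profiles relative [AbundanceMatrix-class] used for dominant taxa
#'   (optional).
#' @return list(contingency, fisher_p, association_p, dominant_taxa).
#' @export
enterotypeAssociation <- function(labels, meta, profiles = NULL) {
  grp <- meta$group[match(names(labels), meta$sample_id)]
  contingency <- table(cluster = labels, group = grp)
  k <- nrow(contingency)
  if (k == 2 && ncol(contingency) == 2) {
    fisher_p <- fisherExactTest(unclass(contingency))
    association_p <- fisher_p
  } else {
    fisher_p <- NA_real_
    association_p <- suppressWarnings(
      stats::chisq.test(contingency, correct = FALSE)$p.value)
  }
  dominant <- character()
  if (!is.null(profiles)) {
    v <- abundances(profiles)[, names(labels), drop = FALSE]
    dominant <- vapply(sort(unique(labels)), function(cl) {
      mu <- rowMeans(v[, labels == cl, drop = FALSE])
      names(which.max(mu))
    }, character(1))
  }
  list(contingency = unclass(contingency), fisher_p = fisher_p,
       association_p = association_p, dominant_taxa = dominant)
}

#' Detect enterotypes from genus profiles
#'
#' The full community-typing stage: abundance/prevalence screen of genera
#' ([filterFeatures()], re-normalised), Jensen-Shannon distance, PAM over
#' candidate k with CH model selection, dominant genus per cluster, and the
#' cluster-by-group association test.
#'
#' @param genus relative genus [AbundanceMatrix-class].
#' @param meta sample metadata (sample_id, group), or NULL to skip the
#'   association step.
#' @param k_range candidate cluster counts.
#' @param min_mean,min_prevalence forwarded to [filterFeatures()].
#' @return An [EnterotypeResult-class].
#' @export
detectEnterotypes <- function(genus, meta = NULL, k_range = 2:10,
                              min_mean = 1e-4, min_prevalence = 6) {
  filtered <- filterFeatures(genus, min_mean, min_prevalence)
  v <- abundances(filtered)
  rel <- AbundanceMatrix(sweep(v, 2L, colSums(v), "/"), kind = "relative")
  D <- jsdMatrix(rel)
  sel <- selectK(D, k_range)
  if (!is.null(meta)) {
    assoc <- enterotypeAssociation(sel$labels, meta, rel)
  } else {
    assoc <- list(contingency = matrix(integer(), 0, 0),
                  fisher_p = NA_real_, association_p = NA_real_,
                  dominant_taxa = vapply(
                    sort(unique(sel$labels)), function(cl)
                      names(which.max(rowMeans(
                        abundances(rel)[, sel$labels == cl, drop = FALSE]))),
                    character(1)))
  }
  new("EnterotypeResult",
      kSelected = as.integer(sel$k_selected), labels = sel$labels,
      medoids = sel$medoids, chCurve = sel$ch_curve,
      dominantTaxa = assoc$dominant_taxa,
      contingency = as.matrix(assoc$contingency),
      fisherP = assoc$fisher_p, associationP = assoc$association_p,
      distance = D)
}
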