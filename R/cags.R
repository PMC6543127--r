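#' Marker-gene selection
#'
#' Genes whose depth differs between groups: per-gene two-sided Wilcoxon
#' rank-sum test with Benjamini-Hochberg adjustment, kept at q < alpha.
#'
#' @param genes gene-level depth [AbundanceMatrix-class].
#' @param meta sample metadata (sample_id, group).
#' @param alpha q-value threshold.
#' @return character vector of marker gene ids (subset of the input genes).
#' @export
markerGenes <- function(genes, meta, alpha = 0.05) {
  stopifnot(is(genes, "AbundanceMatrix"))
  v <- abundances(genes)
  grp <- meta$group[match(colnames(v), meta$sample_id)]
  if (length(unique(grp)) != 2) stop("exactly two groups required")
  case <- grp == unique(grp)[1]
  p <- apply(v, 1L, function(row) wilcoxonRankSum(row[case], row[!case])$p)
  rownames(v)[bhAdjust(p) < alpha]
}

#' Deterministic canopy clustering of co-abundant genes
#'
#' Groups genes whose depth profiles covary across samples. Seeds are taken
#' in descending mean-abundance order from the unclustered pool; a canopy is
#' every pool gene with Pearson correlation >= \code{r_threshold} to the
#' seed profile. The canopy centre is then re-set to the member-wise median
#' profile and membership re-evaluated until a fixed point (at most
#' \code{max_rounds} rounds); members leave the pool and seeding continues.
#' Clusters exceeding 50 genes (\code{min_size} = 51) are co-abundance gene
#' groups (CAGs); smaller clusters are reported separately, never as CAGs.
#'
#' @param profiles [AbundanceMatrix-class] of the candidate (marker) genes.
#' @param r_threshold Pearson correlation defining canopy membership.
#' @param min_size minimum CAG size (default 51, i.e. >50 genes).
#' @param max_rounds recentring iterations per canopy.
#' @return list(cags = named list of gene-id vectors ("cag_1", ...),
#'   small_clusters = named list of sub-threshold clusters).
#' @export
canopyCluster <- function(profiles, r_threshold = 0.9, min_size = 51,
                          max_rounds = 20) {
  stopifnot(is(profiles, "AbundanceMatrix"))
  v <- abundances(profiles)
  if (ncol(v) < 3) stop("correlation undefined with fewer than 3 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("constant gene profiles excluded: ",
            paste(head(rownames(v)[sds == 0], 3), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  # seed order: descending mean abundance, ties by id for determinism
  order_ids <- rownames(v)[order(-rowMeans(v), rownames(v))]
  pool <- order_ids
  clusters <- list()
  while (length(pool)) {
    seed <- pool[1]
    centre <- v[seed, ]
    members <- seed
    for (round in seq_len(max_rounds)) {
      r <- suppressWarnings(
        stats::cor(t(v[pool, , drop = FALSE]), centre))[, 1]
      r[is.na(r)] <- -1
      new_members <- pool[r >= r_threshold]
      if (!length(new_members)) new_members <- seed
      new_centre <- apply(v[new_members, , drop = FALSE], 2L, stats::median)
      if (setequal(new_members, members) &&
          isTRUE(all.equal(new_centre, centre))) break
      members <- new_members
      centre <- new_centre
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
    pool <- setdiff(pool, members)
  }
  big <- vapply(clusters, length, integer(1)) >= min_size
  cags <- clusters[big]
  names(cags) <- if (length(cags)) paste0("cag_", seq_along(cags)) else NULL
  small <- clusters[!big]
  names(small) <- if (length(small)) paste0("cluster_", seq_along(small)) else NULL
  list(cags = cags, small_clusters = small)
}

#' Length-weighted CAG abundance
#'
#' Per sample, the average gene depth weighted by gene length:
#' sum(depth_g * L_g) / sum(L_g) over the cluster's member genes.
#'
#' @param members character vector of member gene ids.
#' @param gene_depths gene-level depth [AbundanceMatrix-class].
#' @param gene_lengths named numeric vector of gene lengths (nt).
#' @return named numeric abundance vector over the samples.
#' @export
cagAbundance <- function(members, gene_depths, gene_lengths) {
  v <- abundances(gene_depths)
  if (!all(members %in% rownames(v)))
    stop("member genes missing from the depth matrix")
  L <- gene_lengths[members]
  if (anyNA(L)) stop("missing gene length for: ",
                     paste(head(members[is.na(L)], 3), collapse = ", "))
  colSums(v[members, , drop = FALSE] * L) / sum(L)
}

#' Rule-based CAG taxonomy from tracer-gene alignments
#'
#' Species call: some species covers >= 90% of the member genes with
#' nucleotide identity >= 95% and query overlap >= 70%. Failing that, genus
#' call: some genus covers >= 80% of the member genes with identity >= 85%
#' in both the DNA and protein alignments. Otherwise unassigned. Candidate
#' taxa are ranked by (fraction of genes mapped, then mean nucleotide
#' identity). Hits are assumed pre-filtered by the upstream e-value and
#' coverage contract.
#'
#' @param members character vector of the CAG's gene ids.
#' @param hits hit-table data.frame with columns gene_id, target_taxon,
#'   level (species/genus), nt_identity, aa_identity, query_overlap.
#' @return list(taxon, level) with level in species/genus/unassigned.
#' @export
assignTaxonomy <- function(members, hits) {
  n <- length(members)
  if (!n) stop("empty CAG")
  if (!nrow(hits)) return(list(taxon = NA_character_, level = "unassigned"))
  hits <- hits[hits$gene_id %in% members, , drop = FALSE]
  best <- function(h, qualifies, min_fraction) {
    ok <- h[qualifies(h), , drop = FALSE]
    if (!nrow(ok)) return(NULL)
    cand <- lapply(split(ok, ok$target_taxon), function(x)
      c(frac = length(unique(x$gene_id)) / n, ident = mean(x$nt_identity)))
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "frac"], -cand[, "ident"]), , drop = FALSE]
    if (cand[1, "frac"] >= min_fraction) rownames(cand)[1] else NULL
  }
  sp <- best(hits[hits$level == "species", , drop = FALSE],
             function(h) h$nt_identity >= 95 & h$query_overlap >= 0.70,
             0.90)
  if (!is.null(sp)) return(list(taxon = sp, level = "species"))
  ge <- best(hits[hits$level == "genus", , drop = FALSE],
             function(h) h$nt_identity >= 85 & h$aa_identity >= 85,
             0.80)
  if (!is.null(ge)) return(list(taxon = ge, level = "genus"))
  list(taxon = NA_character_, level = "unassigned")
}

#' Presence-based odds-ratio enrichment score
#'
#' Builds the 2x2 table of presence (abundance above the threshold) against
#' group and scores OR = (a d) / (b c), adding the Haldane-Anscombe 0.5 to
#' every cell whenever any cell is zero. Enrichment follows the standard
#' cutoffs: case-enriched when OR > 2, case-depleted when OR < 0.5,
#' otherwise neutral. \code{presence_threshold = "median"} uses the CAG's
#' overall median abundance as the detection split, which is appropriate
#' when abundances are strictly positive.
#'
#' @param abundance named per-sample CAG abundance vector.
#' @param meta sample metadata (sample_id, group with case/control).
#' @param presence_threshold numeric threshold, or \code{"median"}.
#' @return list(odds_ratio, enrichment, table).
#' @export
oddsRatioScore <- function(abundance, meta, presence_threshold = 0) {
  grp <- meta$group[match(names(abundance), meta$sample_id)]
  if (length(unique(grp)) != 2) stop("exactly two groups required")
  thr <- if (identical(presence_threshold, "median"))
    stats::median(abundance) else presence_threshold
  present <- abundance > thr
  case <- grp == "case"
  a <- sum(present & case); b <- sum(!present & case)
  cc <- sum(present & !case); d <- sum(!present & !case)
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  enrichment <- if (or > 2) "case_enriched" else
    if (or < 0.5) "case_depleted" else "neutral"
  list(odds_ratio = or, enrichment = enrichment,
       table = matrix(c(a, b, cc, d), 2, 2,
                      dimnames = list(c("present", "absent"),
                                      c("case", "control"))))
}

#' Spearman co-occurrence network
#'
#' Pairwise Spearman correlations between feature abundance profiles, with
#' Benjamini-Hochberg adjustment across all pairs; edges are kept when
#' |rho| >= rho_min and q < alpha. Constant features are excluded with a
#' warning. The edge list is Cytoscape-importable.
#'
#' @param features [AbundanceMatrix-class] or numeric matrix
#'   (features x samples), at least 4 samples.
#' @param rho_min minimum absolute correlation.
#' @param alpha q-value threshold.
#' @return data.frame(source, target, rho, p, q) of retained edges.
#' @export
cooccurrenceNetwork <- function(features, rho_min = 0.5, alpha = 0.05) {
  v <- if (is(features, "AbundanceMatrix")) abundances(features)
       else as.matrix(features)
  if (ncol(v) < 4) stop("need at least 4 samples")
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("constant features excluded from the network: ",
            paste(head(rownames(v)[sds == 0], 3), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  ids <- rownames(v)
  if (length(ids) < 2)
    return(data.frame(source = character(), target = character(),
                      rho = numeric(), p = numeric(), q = numeric()))
  pairs <- utils::combn(length(ids), 2)
  rho <- p <- numeric(ncol(pairs))
  for (e in seq_len(ncol(pairs))) {
    res <- spearmanCor(v[pairs[1, e], ], v[pairs[2, e], ])
    rho[e] <- res$rho; p[e] <- res$p
  }
  q <- bhAdjust(p)
  keep <- abs(rho) >= rho_min & q < alpha
  data.frame(source = ids[pairs[1, keep]], target = ids[pairs[2, keep]],
             rho = rho[keep], p = p[keep], q = q[keep])
}

#' Build co-abundance gene groups end to end
#'
#' The full CAG stage: marker-gene selection, deterministic canopy
#' clustering (clusters >50 genes become CAGs), length-weighted abundance,
#' tracer-gene taxonomy, and presence odds-ratio enrichment. Because
#' length-weighted CAG abundances are strictly positive in typical depth
#' data, the enrichment split defaults to each CAG's median abundance.
#'
#' @param genes gene-level depth [AbundanceMatrix-class].
#' @param gene_lengths named numeric gene lengths (nt).
#' @param hits tracer-gene hit table (see [assignTaxonomy()]).
#' @param meta sample metadata (sample_id, group).
#' @param alpha marker-gene q threshold.
#' @param r_threshold canopy correlation threshold.
#' @param min_size minimum CAG size (>50 genes).
#' @param presence_threshold forwarded to [oddsRatioScore()].
#' @return A [CAGSet-class].
#' @export
buildCAGs <- function(genes, gene_lengths, hits, meta, alpha = 0.05,
                      r_threshold = 0.9, min_size = 51,
                      presence_threshold = "median") {
  markers <- markerGenes(genes, meta, alpha)
  if (length(markers) < min_size)
    stop("fewer marker genes (", length(markers),
         ") than the minimum CAG size")
  cl <- canopyCluster(genes[markers, ], r_threshold, min_size)
  n_cag <- length(cl$cags)
  ab <- matrix(0, n_cag, ncol(genes),
               dimnames = list(names(cl$cags), sampleIds(genes)))
  tax <- data.frame(cag_id = character(), taxon = character(),
                    level = character(), stringsAsFactors = FALSE)
  enr <- data.frame(cag_id = character(), odds_ratio = numeric(),
                    enrichment = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n_cag)) {
    id <- names(cl$cags)[i]
    ab[i, ] <- cagAbundance(cl$cags[[i]], genes, gene_lengths)
    tx <- assignTaxonomy(cl$cags[[i]], hits)
    tax <- rbind(tax, data.frame(cag_id = id, taxon = tx$taxon,
                                 level = tx$level, stringsAsFactors = FALSE))
    or <- oddsRatioScore(ab[i, ], meta, presence_threshold)
    enr <- rbind(enr, data.frame(cag_id = id, odds_ratio = or$odds_ratio,
                                 enrichment = or$enrichment,
                                 stringsAsFactors = FALSE))
  }
  new("CAGSet", membership = cl$cags, abundance = ab, taxonomy = tax,
      enrichment = enr, smallClusters = cl$small_clusters)
}
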