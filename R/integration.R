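#' Spearman rank correlation with p-value
#'
#' Average ranks for ties; exact null distribution for n <= 9 without ties,
#' otherwise the t-approximation (as in \code{cor.test}).
#'
#' @param x,y numeric vectors, n >= 4, non-constant.
#' @return list(rho, p).
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  res <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", exact = !ties && length(x) <= 9))
  list(rho = unname(res$estimate), p = res$p.value)
}

#' Microbe-metabolite Spearman correlation grid
#'
#' Correlates selected taxa (rows) against selected metabolites (columns)
#' over the samples both data sets share. Asterisks follow the usual
#' heatmap convention on raw p-values (* p < 0.05, ** p < 0.01); a
#' Benjamini-Hochberg-adjusted matrix is returned alongside for honest
#' reuse but does not drive the stars.
#'
#' @param taxa relative [AbundanceMatrix-class] of taxon profiles.
#' @param peaks normalised peak-table data.frame whose rows carry the
#'   metabolite per-sample values.
#' @param taxa_ids taxa to correlate (rownames of \code{taxa}).
#' @param compounds compound names to correlate (matched against
#'   \code{peaks$compound_name}).
#' @return list(rho, p, q, stars): taxa x compounds matrices.
#' @export
correlationGrid <- function(taxa, peaks, taxa_ids, compounds) {
  tv <- abundances(taxa)
  missing_taxa <- setdiff(taxa_ids, rownames(tv))
  if (length(missing_taxa))
    stop("taxa not in the profile: ", paste(missing_taxa, collapse = ", "))
  areas <- peakAreas(peaks)
  idx <- match(compounds, peaks$compound_name)
  if (anyNA(idx))
    stop("compounds not in the peak table: ",
         paste(compounds[is.na(idx)], collapse = ", "))
  shared <- intersect(colnames(tv), colnames(areas))
  if (length(shared) < 4) stop("fewer than 4 shared samples")
  rho <- p <- matrix(NA_real_, length(taxa_ids), length(compounds),
                     dimnames = list(taxa_ids, compounds))
  for (i in seq_along(taxa_ids)) {
    for (j in seq_along(compounds)) {
      res <- spearmanCor(tv[taxa_ids[i], shared], areas[idx[j], shared])
      rho[i, j] <- res$rho
      p[i, j] <- res$p
    }
  }
  q <- matrix(bhAdjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  list(rho = rho, p = p, q = q, stars = stars)
}
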