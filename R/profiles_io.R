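#' Read a features-by-samples abundance table from TSV
#'
#' The expected dialect is the common metagenomic profile export:
#' tab-delimited UTF-8, no quoting, '.' decimal, a header row of sample ids,
#' and the feature id in the first column. Ragged rows, missing or
#' non-numeric cells, negative values and duplicate ids are rejected with
#' the offending row/column named.
#'
#' @param path path to the TSV file.
#' @param kind measurement unit recorded on the result; see
#'   [AbundanceMatrix()].
#' @return An [AbundanceMatrix-class].
#' @seealso [writeAbundanceMatrix()]
#' @export
readAbundanceMatrix <- function(path, kind = c("count", "depth", "relative",
                                               "peak_area")) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines))
    stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 which(ncols != ncols[1])[1], path,
                 ncols[which(ncols != ncols[1])[1]], ncols[1]))
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  features <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(features))
    stop("duplicate feature id: ", features[anyDuplicated(features)])
  if (anyDuplicated(samples))
    stop("duplicate sample id: ", samples[anyDuplicated(samples)])
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(features, samples))
  for (i in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(row) | body[[i]][-1] == "")
    if (length(bad))
      stop(sprintf("missing or non-numeric cell at feature '%s', sample '%s'",
                   features[i], samples[bad[1]]))
    neg <- which(row < 0)
    if (length(neg))
      stop(sprintf("negative value %g at feature '%s', sample '%s'",
                   row[neg[1]], features[i], samples[neg[1]]))
    vals[i, ] <- row
  }
  AbundanceMatrix(vals, kind = kind)
}

#' Write an AbundanceMatrix to TSV
#'
#' Inverse of [readAbundanceMatrix()]: the written file round-trips to an
#' identical matrix. The first column is named \code{feature_id}.
#'
#' @param m an [AbundanceMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceMatrix <- function(m, path) {
  stopifnot(is(m, "AbundanceMatrix"))
  v <- abundances(m)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
  if (nrow(v)) {
    body <- apply(v, 1L, function(r)
      paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = "\t"))
    writeLines(paste(rownames(v), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' A TSV with mandatory columns \code{sample_id} and \code{group}
#' (case/control) plus optional clinical covariates.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must contain columns 'sample_id' and 'group'")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(!nzchar(meta$group)) || anyNA(meta$group))
    stop("empty group labels in metadata")
  meta
}

#' @rdname readSampleMetadata
#' @param meta data.frame as returned by [readSampleMetadata()].
#' @export
writeSampleMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-feature annotation map
#'
#' TSV with columns \code{gene_id}, \code{feature_id}, \code{level}
#' (e.g. a taxon rank, "KO", "module" or "eggNOG").
#'
#' @param path TSV path.
#' @return data.frame(gene_id, feature_id, level).
#' @export
readAnnotationMap <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "feature_id") %in% names(map)))
    stop("annotation map must contain columns 'gene_id' and 'feature_id'")
  map
}

#' Convert depths or counts to relative abundance
#'
#' Divides every column by its sum so each sample's profile sums to 1.
#' Idempotent on already-relative input. A sample whose column is all zero
#' has no defined profile and is rejected by name.
#'
#' @param m an [AbundanceMatrix-class] of any kind.
#' @return An [AbundanceMatrix-class] of kind \code{"relative"}.
#' @export
relativeAbundance <- function(m) {
  stopifnot(is(m, "AbundanceMatrix"))
  v <- abundances(m)
  cs <- colSums(v)
  if (any(cs <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(v)[cs <= 0], collapse = ", "))
  AbundanceMatrix(sweep(v, 2L, cs, "/"), kind = "relative")
}

#' Sum gene abundances by annotation feature
#'
#' The abundance of an annotated feature (taxon, KEGG ortholog/module,
#' eggNOG family) in a sample is the sum of the abundances of the genes
#' annotated to it. Genes absent from the map are not silently dropped:
#' their per-sample total is recorded in
#' \code{S4Vectors::metadata(result)$unmapped}.
#'
#' @param genes gene-level [AbundanceMatrix-class].
#' @param map data.frame with columns \code{gene_id}, \code{feature_id}
#'   (see [readAnnotationMap()]). A gene may map to several features.
#' @return An [AbundanceMatrix-class] over the map's features, same kind as
#'   the input.
#' @export
aggregateByAnnotation <- function(genes, map) {
  stopifnot(is(genes, "AbundanceMatrix"))
  if (!nrow(map)) stop("annotation map is empty")
  v <- abundances(genes)
  map <- map[map$gene_id %in% rownames(v), , drop = FALSE]
  if (!nrow(map)) {
    warning("no annotated gene is present in the matrix")
    out <- AbundanceMatrix(
      matrix(0, 0, ncol(v), dimnames = list(character(), colnames(v))),
      kind = genes@kind)
  } else {
    feats <- sort(unique(map$feature_id))
    agg <- rowsum(v[map$gene_id, , drop = FALSE], group = map$feature_id)
    agg <- agg[feats, , drop = FALSE]
    # aggregating a relative table may lose the column-sum-1 property
    out <- AbundanceMatrix(agg, kind = if (genes@kind == "relative") "count"
                           else genes@kind)
  }
  unmapped <- setdiff(rownames(v), map$gene_id)
  S4Vectors::metadata(out)$unmapped <- list(
    gene_ids = unmapped,
    share = colSums(v[unmapped, , drop = FALSE]) / pmax(colSums(v), .Machine$double.xmin))
  out
}

#' Abundance/prevalence feature filter
#'
#' Keeps features whose mean relative abundance across all samples is at
#' least \code{min_mean} and that are detected (strictly positive) in at
#' least \code{min_prevalence} samples. Defaults reproduce the standard
#' genus-screen used before enterotyping and differential testing: mean
#' relative abundance >= 1e-4 and presence in >= 6 samples. Feature order
#' is preserved; raising either threshold can only remove features.
#'
#' @param m relative-kind [AbundanceMatrix-class].
#' @param min_mean minimum mean relative abundance (pooled over all samples).
#' @param min_prevalence minimum number of samples with positive abundance.
#' @return The filtered matrix (kind preserved; columns are intentionally
#'   NOT re-normalised, so the result is returned with kind "count" if any
#'   feature was removed from a relative table).
#' @export
filterFeatures <- function(m, min_mean = 1e-4, min_prevalence = 6) {
  stopifnot(is(m, "AbundanceMatrix"))
  if (m@kind != "relative")
    stop("filterFeatures expects a relative-kind matrix; see relativeAbundance()")
  v <- abundances(m)
  keep <- rowMeans(v) >= min_mean & rowSums(v > 0) >= min_prevalence
  out <- v[keep, , drop = FALSE]
  kind <- if (nrow(out) == nrow(v)) "relative" else "count"
  AbundanceMatrix(out, kind = kind)
}
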