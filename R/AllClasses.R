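#' AbundanceMatrix: features-by-samples abundance container
#'
#' An \code{AbundanceMatrix} holds a non-negative features x samples table
#' (gene depths, taxon counts, relative abundances or LC-MS peak areas) as a
#' \linkS4class{SummarizedExperiment} with a single assay named
#' \code{"abundance"}, plus a \code{kind} flag recording the measurement unit.
#' Columns of a \code{"relative"}-kind matrix must each sum to 1 (within
#' 1e-9); all other kinds only require non-negative values.
#'
#' @slot kind character scalar, one of \code{"depth"}, \code{"count"},
#'   \code{"relative"}, \code{"peak_area"}.
#'
#' @seealso [AbundanceMatrix()] for the constructor, [relativeAbundance()],
#'   [filterFeatures()], [aggregateByAnnotation()].
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix",
  contains = "SummarizedExperiment",
  slots = c(kind = "character"),
  prototype = prototype(kind = "count")
)

.validAbundanceMatrix <- function(object) {
  msg <- character()
  if (length(object@kind) != 1L ||
      !object@kind %in% c("depth", "count", "relative", "peak_area"))
    msg <- c(msg, "'kind' must be one of depth, count, relative, peak_area")
  v <- SummarizedExperiment::assay(object)
  if (!is.numeric(v))
    msg <- c(msg, "abundance values must be numeric")
  if (anyNA(v))
    msg <- c(msg, "abundance values must not contain NA")
  else if (length(v) && min(v) < 0)
    msg <- c(msg, "abundance values must be non-negative")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate feature ids")
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicate sample ids")
  if (identical(object@kind, "relative") && nrow(v) > 0L && ncol(v) > 0L) {
    cs <- colSums(v)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, sprintf(
        "relative-kind columns must sum to 1; offending sample(s): %s",
        paste(head(colnames(v)[abs(cs - 1) > 1e-9], 3L), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("AbundanceMatrix", .validAbundanceMatrix)

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Values must be non-negative.
#' @param kind measurement unit: \code{"depth"} (length-normalised read
#'   depth), \code{"count"}, \code{"relative"} (columns sum to 1) or
#'   \code{"peak_area"}.
#'
#' @return An [AbundanceMatrix-class] object.
#' @examples
#' m <- matrix(c(2, 2, 4, 1, 3, 6), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' am <- AbundanceMatrix(m, kind = "count")
#' relativeAbundance(am)
#' @export
AbundanceMatrix <- function(values, kind = c("count", "depth", "relative",
                                             "peak_area")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- if (nrow(values)) paste0("feature_", seq_len(nrow(values))) else character()
  if (is.null(colnames(values)))
    colnames(values) <- if (ncol(values)) paste0("sample_", seq_len(ncol(values))) else character()
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values))
  new("AbundanceMatrix", se, kind = kind)
}

#' EnterotypeResult: community-typing output
#'
#' Holds everything produced by [detectEnterotypes()]: the sample-to-sample
#' Jensen-Shannon distance matrix, partitioning-around-medoids labels at the
#' Calinski-Harabasz-optimal cluster count, the CH curve over candidate k,
#' the dominant genus per cluster, and the cluster-by-group association.
#'
#' @slot kSelected integer, number of clusters selected by the CH index.
#' @slot labels named integer vector of cluster labels (1..k) per sample.
#' @slot medoids character vector of medoid sample ids, one per cluster.
#' @slot chCurve named numeric vector, CH index per candidate k.
#' @slot dominantTaxa character vector, highest-mean genus per cluster.
#' @slot contingency cluster x group count matrix.
#' @slot fisherP two-sided Fisher exact p for the 2x2 case (NA otherwise).
#' @slot associationP association p-value actually reported (Fisher for
#'   2 clusters, chi-square otherwise).
#' @slot distance symmetric JSD matrix used for the clustering.
#' @exportClass EnterotypeResult
setClass("EnterotypeResult",
  slots = c(kSelected = "integer", labels = "integer", medoids = "character",
            chCurve = "numeric", dominantTaxa = "character",
            contingency = "matrix", fisherP = "numeric",
            associationP = "numeric", distance = "matrix"))

setValidity("EnterotypeResult", function(object) {
  msg <- character()
  k <- object@kSelected
  if (length(object@labels) &&
      !all(object@labels %in% seq_len(k)))
    msg <- c(msg, "labels must lie in 1..kSelected")
  if (length(object@contingency) && length(object@labels) &&
      sum(object@contingency) != length(object@labels))
    msg <- c(msg, "contingency must count every sample exactly once")
  if (length(msg)) msg else TRUE
})

#' PLSModel: NIPALS PLS-DA / OPLS-DA fit
#'
#' Stores the latent-structure decomposition produced by [plsdaFit()] or
#' [oplsdaFit()] on autoscaled data with a centred +/-1 class response:
#' per-component weights w (unit norm), scores t, X-loadings p and response
#' loadings q, plus any response-orthogonal components (OPLS), and the
#' centring/scaling vectors needed to project new samples.
#'
#' @slot weights p x A weight matrix (columns unit-norm).
#' @slot scores n x A score matrix (columns mutually orthogonal).
#' @slot loadings p x A X-loading matrix.
#' @slot q numeric response loading per component.
#' @slot orthoWeights,orthoScores,orthoLoadings orthogonal-component
#'   analogues (zero-column matrices for plain PLS-DA).
#' @slot center,scale numeric feature-wise centring and scaling vectors.
#' @slot yMean numeric, mean of the +/-1 response before centring.
#' @slot classLevels character(2); first level coded -1, second +1.
#' @slot droppedFeatures character, constant features removed before scaling.
#' @exportClass PLSModel
setClass("PLSModel",
  slots = c(weights = "matrix", scores = "matrix", loadings = "matrix",
            q = "numeric", orthoWeights = "matrix", orthoScores = "matrix",
            orthoLoadings = "matrix", center = "numeric", scale = "numeric",
            yMean = "numeric", classLevels = "character",
            droppedFeatures = "character"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (ncol(object@weights) != ncol(object@scores) ||
      ncol(object@weights) != length(object@q))
    msg <- c(msg, "weights, scores and q must agree on component count")
  if (ncol(object@weights)) {
    nw <- sqrt(colSums(object@weights^2))
    if (any(abs(nw - 1) > 1e-6))
      msg <- c(msg, "weight columns must be unit-norm")
  }
  if (length(msg)) msg else TRUE
})

#' CAGSet: co-abundance gene groups
#'
#' The result of [buildCAGs()] (or of [canopyCluster()] plus the downstream
#' annotation steps): per-CAG gene membership, the length-weighted abundance
#' profile, the tracer-gene taxonomy call, and the odds-ratio enrichment
#' class. Clusters that failed the >50-gene size rule are kept separately in
#' \code{smallClusters}.
#'
#' @slot membership named list, CAG id -> character vector of member genes.
#' @slot abundance CAG x sample matrix of length-weighted mean depths.
#' @slot taxonomy data.frame with columns cag_id, taxon, level.
#' @slot enrichment data.frame with columns cag_id, odds_ratio, enrichment.
#' @slot smallClusters named list of sub-threshold clusters (not CAGs).
#' @exportClass CAGSet
setClass("CAGSet",
  slots = c(membership = "list", abundance = "matrix",
            taxonomy = "data.frame", enrichment = "data.frame",
            smallClusters = "list"))

setValidity("CAGSet", function(object) {
  msg <- character()
  if (length(object@membership)) {
    sizes <- lengths(object@membership)
    if (any(sizes <= 50L))
      msg <- c(msg, "every CAG must have >50 member genes")
    if (nrow(object@abundance) &&
        !identical(names(object@membership), rownames(object@abundance)))
      msg <- c(msg, "membership and abundance must list the same CAGs")
  }
  if (length(object@abundance) && min(object@abundance) < 0)
    msg <- c(msg, "CAG abundance must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ClassifierReport: CAG-based discrimination stage output
#'
#' Produced by [trainCagClassifier()]: the stratified 80/20 split, the
#' permutation-importance ranking, the cross-validation error curve over
#' candidate feature counts, the selected count, train/test AUCs with
#' DeLong 95% confidence intervals, and per-sample class probabilities.
#'
#' @slot trainIds,testIds character sample ids of the split.
#' @slot importance data.frame (feature, importance), sorted descending.
#' @slot cvCurve data.frame (k, error): mean CV misclassification error.
#' @slot kSelected integer, argmin of the CV curve (ties -> smallest k).
#' @slot trainAUC,testAUC numeric AUC in [0, 1].
#' @slot trainCI,testCI numeric(2) DeLong confidence limits.
#' @slot probabilities data.frame (sample_id, group, set, prob_case).
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  slots = c(trainIds = "character", testIds = "character",
            importance = "data.frame", cvCurve = "data.frame",
            kSelected = "integer", trainAUC = "numeric", trainCI = "numeric",
            testAUC = "numeric", testCI = "numeric",
            probabilities = "data.frame"))

setValidity("ClassifierReport", function(object) {
  msg <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "train and test sets must be disjoint")
  for (a in c("trainAUC", "testAUC")) {
    v <- slot(object, a)
    if (length(v) && (v < 0 || v > 1)) msg <- c(msg, paste(a, "outside [0,1]"))
  }
  if (length(msg)) msg else TRUE
})
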