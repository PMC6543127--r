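#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundances", "AbundanceMatrix", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("abundanceKind", "AbundanceMatrix", function(x) x@kind)

#' @rdname AbundanceMatrix-class
#' @export
setMethod("featureIds", "AbundanceMatrix", function(x) rownames(x))

#' @rdname AbundanceMatrix-class
#' @export
setMethod("sampleIds", "AbundanceMatrix", function(x) colnames(x))

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix (%s): %d features x %d samples\n",
              object@kind, nrow(object), ncol(object)))
  if (nrow(object) && ncol(object)) {
    v <- abundances(object)
    cat(sprintf("  value range: [%.4g, %.4g]\n", min(v), max(v)))
  }
})

#' @rdname CAGSet-class
#' @export
setMethod("cagMembership", "CAGSet", function(x) x@membership)

#' @rdname CAGSet-class
#' @export
setMethod("cagTaxonomy", "CAGSet", function(x) x@taxonomy)

#' @rdname CAGSet-class
#' @export
setMethod("cagEnrichment", "CAGSet", function(x) x@enrichment)

#' @rdname CAGSet-class
#' @param object a [CAGSet-class].
#' @export
setMethod("abundances", "CAGSet", function(x) x@abundance)

setMethod("show", "CAGSet", function(object) {
  cat(sprintf("CAGSet: %d CAGs (>50 genes), %d sub-threshold clusters\n",
              length(object@membership), length(object@smallClusters)))
  if (length(object@membership)) {
    sz <- lengths(object@membership)
    cat(sprintf("  CAG sizes: %d-%d genes\n", min(sz), max(sz)))
    if (nrow(object@enrichment))
      print(table(object@enrichment$enrichment))
  }
})

#' @rdname EnterotypeResult-class
#' @export
setMethod("enterotypeLabels", "EnterotypeResult", function(x) x@labels)

#' @rdname EnterotypeResult-class
#' @export
setMethod("chCurve", "EnterotypeResult", function(x) x@chCurve)

setMethod("show", "EnterotypeResult", function(object) {
  cat(sprintf("EnterotypeResult: k = %d over %d samples\n",
              object@kSelected, length(object@labels)))
  if (length(object@dominantTaxa))
    cat("  dominant taxa:", paste(object@dominantTaxa, collapse = ", "), "\n")
  if (!is.na(object@associationP))
    cat(sprintf("  cluster-by-group association p = %.4g\n",
                object@associationP))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d predictive + %d orthogonal component(s), %d features\n",
              ncol(object@scores), ncol(object@orthoScores),
              nrow(object@weights)))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport: %d train / %d test samples\n",
              length(object@trainIds), length(object@testIds)))
  cat(sprintf("  k selected = %d (lowest CV error)\n", object@kSelected))
  cat(sprintf("  train AUC = %.4f (95%% CI %.4f-%.4f)\n",
              object@trainAUC, object@trainCI[1], object@trainCI[2]))
  cat(sprintf("  test  AUC = %.4f (95%% CI %.4f-%.4f)\n",
              object@testAUC, object@testCI[1], object@testCI[2]))
})
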