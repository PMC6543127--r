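#' @rdname AbundanceMatrix-class
#' @param x an object of the documented class.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("abundanceKind", function(x) standardGeneric("abundanceKind"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname CAGSet-class
#' @param x a [CAGSet-class].
#' @export
setGeneric("cagMembership", function(x) standardGeneric("cagMembership"))

#' @rdname CAGSet-class
#' @export
setGeneric("cagTaxonomy", function(x) standardGeneric("cagTaxonomy"))

#' @rdname CAGSet-class
#' @export
setGeneric("cagEnrichment", function(x) standardGeneric("cagEnrichment"))

#' @rdname EnterotypeResult-class
#' @param x an [EnterotypeResult-class].
#' @export
setGeneric("enterotypeLabels", function(x) standardGeneric("enterotypeLabels"))

#' @rdname EnterotypeResult-class
#' @export
setGeneric("chCurve", function(x) standardGeneric("chCurve"))
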