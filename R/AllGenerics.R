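#' Accessors for the intensity container and annotated calls
#'
#' \code{lrr} and \code{baf} return the probe-by-sample matrices,
#' \code{probeRanges} the probe \code{GRanges}, \code{sampleStatus} the named
#' case/control vector, \code{cnvCalls} the annotated call \code{GRanges} and
#' \code{geneHits} the per-(call, gene) overlap table.
#'
#' @param x a \linkS4class{CNVIntensitySet} or \linkS4class{AnnotatedCNVs}.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lrr", function(x) standardGeneric("lrr"))

#' @rdname accessors
#' @export
setGeneric("baf", function(x) standardGeneric("baf"))

#' @rdname accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))

#' @rdname accessors
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname accessors
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))

#' @rdname accessors
#' @export
setGeneric("geneHits", function(x) standardGeneric("geneHits"))

#' @rdname accessors
setMethod("lrr", "CNVIntensitySet", function(x) assay(x, "lrr"))

#' @rdname accessors
setMethod("baf", "CNVIntensitySet", function(x) assay(x, "baf"))

#' @rdname accessors
setMethod("probeRanges", "CNVIntensitySet", function(x) rowRanges(x))

#' @rdname accessors
setMethod("sampleStatus", "CNVIntensitySet", function(x) {
  setNames(as.character(colData(x)$status), colnames(x))
})

#' @rdname accessors
setMethod("cnvCalls", "AnnotatedCNVs", function(x) x@calls)

#' @rdname accessors
setMethod("geneHits", "AnnotatedCNVs", function(x) x@geneHits)

#' @rdname accessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @rdname accessors
setMethod("cohortSamples", "AnnotatedCNVs", function(x) x@samples)
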