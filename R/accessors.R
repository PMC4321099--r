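#' Accessors for ArraySample and TruthLedger
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param object an \linkS4class{ArraySample} or \linkS4class{TruthLedger}
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))
#' @rdname accessors
#' @export
setMethod("probes", "ArraySample", function(object) object@probes)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "ArraySample", function(object) object@sampleId)

#' @rdname accessors
#' @export
setGeneric("arm", function(object) standardGeneric("arm"))
#' @rdname accessors
#' @export
setMethod("arm", "ArraySample", function(object) object@arm)

#' @rdname accessors
#' @export
setGeneric("genotype", function(object) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setMethod("genotype", "ArraySample", function(object) object@genotype)

#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))
#' @rdname accessors
#' @export
setMethod("timepoint", "ArraySample", function(object) object@timepoint)

#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setMethod("condition", "ArraySample", function(object) object@condition)

#' @rdname accessors
#' @export
setGeneric("replicateIndex", function(object) standardGeneric("replicateIndex"))
#' @rdname accessors
#' @export
setMethod("replicateIndex", "ArraySample", function(object) object@replicate)

#' @rdname accessors
#' @export
setGeneric("responsiveMirnas",
           function(object) standardGeneric("responsiveMirnas"))
#' @rdname accessors
#' @export
setMethod("responsiveMirnas", "TruthLedger",
          function(object) object@responsiveMirnas)

#' @rdname accessors
#' @export
setGeneric("upregulatedByTimepoint",
           function(object) standardGeneric("upregulatedByTimepoint"))
#' @rdname accessors
#' @export
setMethod("upregulatedByTimepoint", "TruthLedger",
          function(object) object@upregulatedByTimepoint)

#' @rdname accessors
#' @export
setGeneric("targetPairs", function(object) standardGeneric("targetPairs"))
#' @rdname accessors
#' @export
setMethod("targetPairs", "TruthLedger", function(object) object@targetPairs)

#' @rdname accessors
#' @export
setGeneric("plantedSites", function(object) standardGeneric("plantedSites"))
#' @rdname accessors
#' @export
setMethod("plantedSites", "TruthLedger", function(object) object@plantedSites)

#' @rdname accessors
#' @export
setGeneric("decoys", function(object) standardGeneric("decoys"))
#' @rdname accessors
#' @export
setMethod("decoys", "TruthLedger", function(object) object@decoys)
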