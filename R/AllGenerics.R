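#' @rdname GenomeAssembly-class
#' @param x an object.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAssembly-class
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname AnchorSet-class
#' @param x an object.
#' @export
setGeneric("anchorBlocks", function(x) standardGeneric("anchorBlocks"))

#' @rdname ScoringParams-class
#' @param x an object.
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' @rdname ProjectionResult-class
#' @param x an object.
#' @export
setGeneric("projectionScore", function(x) standardGeneric("projectionScore"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("speciesPath", function(x) standardGeneric("speciesPath"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("stepDistances", function(x) standardGeneric("stepDistances"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))

#' @rdname EnrichmentTest-class
#' @param x an object.
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname EnrichmentTest-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
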