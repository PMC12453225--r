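#' @title Generics for epicorrect containers
#' @description S4 generics for the lattice, delivery and trajectory
#'   containers.  See the methods for details.
#' @param x,object an epicorrect object
#' @param ... passed to methods
#' @name epicorrect-generics
#' @keywords internal
NULL

#' @rdname epicorrect-generics
#' @export
setGeneric("correctedFraction", function(x) standardGeneric("correctedFraction"))

#' @rdname epicorrect-generics
#' @export
setGeneric("tp53Fraction", function(x) standardGeneric("tp53Fraction"))

#' @rdname epicorrect-generics
#' @export
setGeneric("tp53Hits", function(x) standardGeneric("tp53Hits"))

#' @rdname epicorrect-generics
#' @export
setGeneric("boundaryMode", function(x) standardGeneric("boundaryMode"))

#' @rdname epicorrect-generics
#' @export
setGeneric("cellRecords", function(x) standardGeneric("cellRecords"))

#' @rdname epicorrect-generics
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))

#' @rdname epicorrect-generics
#' @export
setGeneric("finalGrid", function(x) standardGeneric("finalGrid"))

#' @rdname epicorrect-generics
#' @export
setGeneric("outcomeOf", function(x) standardGeneric("outcomeOf"))

#' @rdname epicorrect-generics
#' @export
setGeneric("eventTimeOf", function(x) standardGeneric("eventTimeOf"))

#' @rdname epicorrect-generics
#' @export
setGeneric("applyCorrection", function(grid, plan, ...) standardGeneric("applyCorrection"))

#' @rdname epicorrect-generics
#' @export
setGeneric("vafData", function(x) standardGeneric("vafData"))

#' @rdname epicorrect-generics
#' @export
setGeneric("sampleManifest", function(x) standardGeneric("sampleManifest"))
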