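#' @rdname computeRPKM
#' @export
setGeneric("computeRPKM", function(x, ...) standardGeneric("computeRPKM"))

#' @rdname stageMeans
#' @export
setGeneric("stageMeans", function(x, ...) standardGeneric("stageMeans"))

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("sampleStages", function(x) standardGeneric("sampleStages"))

#' @rdname accessors
#' @export
setGeneric("stageLevels", function(x) standardGeneric("stageLevels"))

#' @rdname accessors
#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))
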