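#' @name gpbench-generics
#' @title Accessor generics
#' @description Accessors for the core S4 containers. Bioconductor-style
#'   accessor functions are the supported interface; direct slot access is
#'   not part of the API.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname gpbench-generics
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname gpbench-generics
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname gpbench-generics
#' @export
setGeneric("snpIDs", function(x) standardGeneric("snpIDs"))

#' @rdname gpbench-generics
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname gpbench-generics
#' @export
setGeneric("snpMAF", function(x) standardGeneric("snpMAF"))

#' @rdname gpbench-generics
#' @export
setGeneric("snpMissingRate", function(x) standardGeneric("snpMissingRate"))

#' @rdname gpbench-generics
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname gpbench-generics
#' @export
setGeneric("nSNPs", function(x) standardGeneric("nSNPs"))

#' @rdname gpbench-generics
#' @export
setGeneric("qtnIndices", function(x) standardGeneric("qtnIndices"))

#' @rdname gpbench-generics
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname gpbench-generics
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname gpbench-generics
#' @export
setGeneric("geneticValue", function(x) standardGeneric("geneticValue"))

#' @rdname gpbench-generics
#' @export
setGeneric("realizedPartition", function(x) standardGeneric("realizedPartition"))

#' @rdname gpbench-generics
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))
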