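#' @name tagseq-generics
#' @title Accessor generics
#' @description Accessors for the tagseq S4 classes; see the class pages for
#'   details of each slot.
#' @param x a tagseq object.
#' @param ... passed to methods.
NULL

#' @rdname tagseq-generics
#' @export
setGeneric("normFactors", function(x, ...) standardGeneric("normFactors"))

#' @rdname tagseq-generics
#' @export
setGeneric("referenceSample", function(x) standardGeneric("referenceSample"))

#' @rdname tagseq-generics
#' @export
setGeneric("logCPM", function(x, ...) standardGeneric("logCPM"))

#' @rdname tagseq-generics
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname tagseq-generics
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' @rdname tagseq-generics
#' @export
setGeneric("scanTable", function(x, ...) standardGeneric("scanTable"))

#' @rdname tagseq-generics
#' @export
setGeneric("significantGenes", function(x, ...)
  standardGeneric("significantGenes"))

#' @rdname tagseq-generics
#' @export
setGeneric("trueTags", function(x) standardGeneric("trueTags"))

#' @rdname tagseq-generics
#' @export
setGeneric("normalizeTMM", function(x, ...) standardGeneric("normalizeTMM"))

#' @rdname tagseq-generics
#' @export
setGeneric("tagScan", function(x, ...) standardGeneric("tagScan"))
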