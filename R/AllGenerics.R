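#' @rdname refValues
#' @export
setGeneric("refValues", function(object) standardGeneric("refValues"))

#' @rdname refValues
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname refValues
#' @export
setGeneric("refWeights", function(object) standardGeneric("refWeights"))

#' @rdname refValues
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))

#' @rdname fractions
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname fractions
#' @export
setGeneric("rawCoefficients",
    function(object) standardGeneric("rawCoefficients"))

#' @rdname dmctTable
#' @export
setGeneric("dmctTable", function(object, ...) standardGeneric("dmctTable"))

#' @rdname dmctTable
#' @export
setGeneric("dmctCalls", function(object) standardGeneric("dmctCalls"))
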