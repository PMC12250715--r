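#' @rdname IndexMatrix
#' @param x an object.
#' @export
setGeneric("evaluations", function(x) standardGeneric("evaluations"))

#' @rdname IndexMatrix
#' @export
setGeneric("objectLabels", function(x) standardGeneric("objectLabels"))

#' @rdname IndexMatrix
#' @export
setGeneric("criteriaLabels", function(x) standardGeneric("criteriaLabels"))

#' @rdname ICrAResult
#' @param x an object.
#' @export
setGeneric("agreement", function(x) standardGeneric("agreement"))

#' @rdname ICrAResult
#' @export
setGeneric("disagreement", function(x) standardGeneric("disagreement"))

#' @rdname ICrAResult
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))

#' @rdname ICrAResult
#' @export
setGeneric("counters", function(x) standardGeneric("counters"))
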