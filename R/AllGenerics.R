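#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @export
setGeneric("lineData", function(x) standardGeneric("lineData"))

#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @export
setGeneric("responseData", function(x) standardGeneric("responseData"))

#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @export
setGeneric("trail", function(x) standardGeneric("trail"))

#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @export
setGeneric("ppv", function(x) standardGeneric("ppv"))

#' @export
setGeneric("npv", function(x) standardGeneric("npv"))

#' @export
setGeneric("responseRate", function(x) standardGeneric("responseRate"))

#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
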