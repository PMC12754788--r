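#' @name accessors
#' @title Accessors for tobitGWAS S4 objects
#' @description Slot accessors; prefer these over direct `@` access.
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @return the slot value (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("variantPositions",
           function(x) standardGeneric("variantPositions"))

#' @rdname accessors
#' @export
setGeneric("realizedMAF", function(x) standardGeneric("realizedMAF"))

#' @rdname accessors
#' @export
setGeneric("observedValues", function(x) standardGeneric("observedValues"))

#' @rdname accessors
#' @export
setGeneric("lodValue", function(x) standardGeneric("lodValue"))

#' @rdname accessors
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @rdname accessors
#' @export
setGeneric("latentValues", function(x) standardGeneric("latentValues"))

#' @rdname accessors
#' @export
setGeneric("censoredProportion",
           function(x) standardGeneric("censoredProportion"))

#' @rdname accessors
#' @export
setGeneric("transformedValues",
           function(x) standardGeneric("transformedValues"))

#' @rdname accessors
#' @export
setGeneric("tiesPolicy", function(x) standardGeneric("tiesPolicy"))

#' @rdname accessors
#' @export
setGeneric("censorThreshold", function(x) standardGeneric("censorThreshold"))

#' @rdname accessors
#' @export
setGeneric("pseudoTime", function(x) standardGeneric("pseudoTime"))

#' @rdname accessors
#' @export
setGeneric("eventIndicator", function(x) standardGeneric("eventIndicator"))

#' @rdname accessors
#' @export
setGeneric("effectEstimate", function(x) standardGeneric("effectEstimate"))

#' @rdname accessors
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("gwasMetadata", function(x) standardGeneric("gwasMetadata"))
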