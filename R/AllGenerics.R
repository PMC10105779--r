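#' @rdname CalcCohort-accessors
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("hlaGenotypes", function(x) standardGeneric("hlaGenotypes"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("metaboliteMatrix", function(x, normal = FALSE) standardGeneric("metaboliteMatrix"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("lipidMatrix", function(x, normal = FALSE) standardGeneric("lipidMatrix"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("metaboliteAnnotation", function(x) standardGeneric("metaboliteAnnotation"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("lipidAnnotation", function(x) standardGeneric("lipidAnnotation"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("immuneGenes", function(x) standardGeneric("immuneGenes"))

#' @rdname CalcCohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname GenomeBuild-accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeBuild-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeBuild-accessors
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))
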