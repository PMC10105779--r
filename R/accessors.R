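#' Accessors for CalcCohort objects
#'
#' Slot access for the cohort container. `metaboliteMatrix()` and
#' `lipidMatrix()` return the paired adjacent-normal matrix when
#' `normal = TRUE`.
#'
#' @param x a [CalcCohort-class] object.
#' @param normal logical; return the paired-normal matrix instead of tumor.
#' @return The corresponding layer: a data.frame, numeric matrix, character
#'   vector (`immuneGenes`) or list (`cohortTruth`).
#' @name CalcCohort-accessors
NULL

#' @rdname CalcCohort-accessors
#' @export
setMethod("cohortTable", "CalcCohort", function(x) x@cohortTable)

#' @rdname CalcCohort-accessors
#' @export
setMethod("mutations", "CalcCohort", function(x) x@mutations)

#' @rdname CalcCohort-accessors
#' @export
setMethod("segments", "CalcCohort", function(x) x@segments)

#' @rdname CalcCohort-accessors
#' @export
setMethod("hlaGenotypes", "CalcCohort", function(x) x@hlaGenotypes)

#' @rdname CalcCohort-accessors
#' @export
setMethod("expressionMatrix", "CalcCohort", function(x) x@expression)

#' @rdname CalcCohort-accessors
#' @export
setMethod("metaboliteMatrix", "CalcCohort", function(x, normal = FALSE) {
  if (normal) x@metabolitesNormal else x@metabolites
})

#' @rdname CalcCohort-accessors
#' @export
setMethod("lipidMatrix", "CalcCohort", function(x, normal = FALSE) {
  if (normal) x@lipidsNormal else x@lipids
})

#' @rdname CalcCohort-accessors
#' @export
setMethod("metaboliteAnnotation", "CalcCohort", function(x) x@metaboliteAnnotation)

#' @rdname CalcCohort-accessors
#' @export
setMethod("lipidAnnotation", "CalcCohort", function(x) x@lipidAnnotation)

#' @rdname CalcCohort-accessors
#' @export
setMethod("immuneGenes", "CalcCohort", function(x) x@immuneGenes)

#' @rdname CalcCohort-accessors
#' @export
setMethod("cohortTruth", "CalcCohort", function(x) x@truth)

#' Accessors for GenomeBuild objects
#'
#' @param x a [GenomeBuild-class] object.
#' @return `chromNames()`: character vector; `chromLengths()`: named numeric
#'   vector of lengths (bp); `centromeres()`: data.frame with columns
#'   `chrom`, `cen_start`, `cen_end` (`NA` when absent).
#' @name GenomeBuild-accessors
NULL

#' @rdname GenomeBuild-accessors
#' @export
setMethod("chromNames", "GenomeBuild", function(x) x@chrom)

#' @rdname GenomeBuild-accessors
#' @export
setMethod("chromLengths", "GenomeBuild", function(x) {
  stats::setNames(x@seqlength, x@chrom)
})

#' @rdname GenomeBuild-accessors
#' @export
setMethod("centromeres", "GenomeBuild", function(x) {
  data.frame(chrom = x@chrom, cen_start = x@cenStart, cen_end = x@cenEnd,
             stringsAsFactors = FALSE)
})

setMethod("show", "GenomeBuild", function(object) {
  cat("GenomeBuild with", length(object@chrom), "chromosomes,",
      sprintf("%.1f Mb total", sum(object@seqlength) / 1e6), "\n")
  cat("  centromere model:",
      if (all(is.na(object@cenStart))) "absent" else "present", "\n")
})

setMethod("show", "CalcCohort", function(object) {
  ct <- object@cohortTable
  cat("CalcCohort with", nrow(ct), "samples\n")
  if (nrow(ct)) {
    tab <- table(ct$calc_group)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("  mutations: %d records | segments: %d | expression: %d x %d\n",
              nrow(object@mutations), nrow(object@segments),
              nrow(object@expression), ncol(object@expression)))
  cat(sprintf("  metabolites: %d x %d | lipids: %d x %d\n",
              nrow(object@metabolites), ncol(object@metabolites),
              nrow(object@lipids), ncol(object@lipids)))
})
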