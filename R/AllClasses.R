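#' @import methods
NULL

#' Genome build: chromosome lengths and centromere intervals
#'
#' Holds the chromosome table every scar score needs: names, lengths (bp) and,
#' optionally, centromere intervals used for arm-aware breakpoint counting.
#' Coordinates are 1-based inclusive throughout the package.
#'
#' @slot chrom character vector of unique chromosome names.
#' @slot seqlength numeric vector of chromosome lengths in bp (> 0).
#' @slot cenStart,cenEnd numeric vectors of centromere interval bounds in bp,
#'   `NA` when no centromere model is available for a chromosome.
#'
#' @seealso [GenomeBuild()], [syntheticGenomeBuild()], [readGenomeBuild()]
#' @export
setClass("GenomeBuild",
  representation(
    chrom = "character",
    seqlength = "numeric",
    cenStart = "numeric",
    cenEnd = "numeric"
  )
)

setValidity("GenomeBuild", function(object) {
  msg <- character()
  n <- length(object@chrom)
  if (anyDuplicated(object@chrom)) {
    msg <- c(msg, "chromosome names must be unique")
  }
  if (length(object@seqlength) != n || length(object@cenStart) != n ||
      length(object@cenEnd) != n) {
    msg <- c(msg, "all slots must have one entry per chromosome")
  }
  if (any(!is.finite(object@seqlength)) || any(object@seqlength <= 0)) {
    msg <- c(msg, "chromosome lengths must be positive")
  }
  has_cen <- !is.na(object@cenStart)
  if (any(has_cen != !is.na(object@cenEnd))) {
    msg <- c(msg, "cenStart and cenEnd must be NA together")
  }
  if (any(has_cen)) {
    bad <- has_cen & (object@cenStart < 1 | object@cenEnd > object@seqlength |
                        object@cenEnd < object@cenStart)
    if (any(bad)) {
      msg <- c(msg, sprintf("centromere interval outside chromosome: %s",
                            paste(object@chrom[bad], collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-omics cohort container
#'
#' Bundles every layer of a (synthetic or assembled) calcification cohort:
#' the clinical/sample table, somatic mutation catalog, allele-specific
#' copy-number segments, HLA class I genotypes, expression and metabolite /
#' lipid matrices (log2 scale, features x samples) with their annotation
#' sidecars, and the record of planted ground-truth effects.
#'
#' Validity enforces layer consistency: every sample id appearing in an omics
#' layer must be present in the cohort table (layers may cover a subset of the
#' cohort, emulating per-platform dropout, but never an orphan sample).
#'
#' @slot cohortTable data.frame of per-sample group labels, covariates and
#'   survival endpoints.
#' @slot mutations data.frame of somatic mutation records (MAF-like).
#' @slot segments data.frame of allele-specific copy-number segments.
#' @slot hlaGenotypes data.frame of two 4-digit alleles per HLA-I locus.
#' @slot expression numeric matrix, genes x samples, log2 scale.
#' @slot metabolites,metabolitesNormal numeric matrices, metabolites x samples
#'   (tumor and paired adjacent-normal), log2 abundance.
#' @slot lipids,lipidsNormal numeric matrices, lipids x samples, log2 abundance.
#' @slot metaboliteAnnotation data.frame mapping metabolite -> KEGG-style
#'   pathway and pathway category.
#' @slot lipidAnnotation data.frame mapping lipid -> LIPID MAPS category
#'   (FA/GL/GP/SP/ST) and main class.
#' @slot immuneGenes character vector: the designated immune signature genes.
#' @slot truth list recording every planted per-sample parameter.
#'
#' @seealso [generateCohort()], [cohortTable()], [mutations()], [segments()]
#' @export
setClass("CalcCohort",
  representation(
    cohortTable = "data.frame",
    mutations = "data.frame",
    segments = "data.frame",
    hlaGenotypes = "data.frame",
    expression = "matrix",
    metabolites = "matrix",
    metabolitesNormal = "matrix",
    lipids = "matrix",
    lipidsNormal = "matrix",
    metaboliteAnnotation = "data.frame",
    lipidAnnotation = "data.frame",
    immuneGenes = "character",
    truth = "list"
  )
)

setValidity("CalcCohort", function(object) {
  msg <- character()
  ids <- object@cohortTable$sample
  if (is.null(ids) || anyDuplicated(ids)) {
    msg <- c(msg, "cohortTable must have a 'sample' column with unique ids")
  }
  layer_ids <- list(
    mutations = unique(object@mutations$sample),
    segments = unique(object@segments$sample),
    hlaGenotypes = unique(object@hlaGenotypes$sample),
    expression = colnames(object@expression),
    metabolites = colnames(object@metabolites),
    lipids = colnames(object@lipids)
  )
  for (layer in names(layer_ids)) {
    orphan <- setdiff(layer_ids[[layer]], ids)
    if (length(orphan)) {
      msg <- c(msg, sprintf("orphan samples in layer '%s': %s", layer,
                            paste(utils::head(orphan, 3), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})
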