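#' Tumor mutation burden
#'
#' Number of nonsynonymous somatic mutations per megabase of captured coding
#' exome. Nonsynonymous classes are missense, nonsense, nonstop, splice
#' site, translation start site, in-frame and frameshift indels
#' (see [nonsynonymousClasses()]); silent mutations are excluded. The
#' default footprint, 35.618 Mb, is the coding footprint of the capture kit
#' behind the default analysis.
#'
#' @param mutations mutation table (columns `sample`, `classification`).
#' @param footprintMb size of the captured coding region in Mb (> 0).
#' @param samples optional sample ids to report (zero counts included);
#'   defaults to samples present in `mutations`.
#' @return data.frame with columns `sample`, `n_nonsynonymous`, `tmb`.
#' @export
computeTmb <- function(mutations, footprintMb = 35.618, samples = NULL) {
  if (!is.numeric(footprintMb) || length(footprintMb) != 1L ||
      !is.finite(footprintMb) || footprintMb <= 0) {
    stop("'footprintMb' must be a positive number", call. = FALSE)
  }
  nonsyn <- mutations$classification %in% NONSYN_CLASSES
  if (is.null(samples)) samples <- sort(unique(mutations$sample))
  counts <- table(factor(mutations$sample[nonsyn], levels = samples))
  data.frame(sample = samples,
             n_nonsynonymous = as.integer(counts),
             tmb = as.numeric(counts) / footprintMb,
             stringsAsFactors = FALSE)
}

#' Filter neoantigen candidates
#'
#' Applies the definition of a neoantigen to a table of precomputed
#' peptide-MHC binding predictions: the predicted affinity must be below
#' 500 nM and the corresponding gene's (batch-corrected) expression must
#' exceed 1. Both cutoffs are strict inequalities. Candidates with a missing
#' affinity are skipped with a warning.
#'
#' @param candidates data.frame with columns `affinity` (nM) and
#'   `expression`; other columns are carried through.
#' @param affinityCutNm affinity cutoff in nM, exclusive (default 500).
#' @param exprCut expression cutoff, exclusive (default 1).
#' @return the rows of `candidates` passing both filters.
#' @export
filterNeoantigens <- function(candidates, affinityCutNm = 500, exprCut = 1) {
  miss <- setdiff(c("affinity", "expression"), names(candidates))
  if (length(miss)) {
    stop("candidate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  na_aff <- is.na(candidates$affinity)
  if (any(na_aff)) {
    warning(sum(na_aff), " candidate(s) skipped: missing affinity")
    candidates <- candidates[!na_aff, , drop = FALSE]
  }
  if (any(candidates$affinity <= 0)) {
    stop("affinities must be positive", call. = FALSE)
  }
  keep <- candidates$affinity < affinityCutNm & candidates$expression > exprCut
  keep[is.na(keep)] <- FALSE
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
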