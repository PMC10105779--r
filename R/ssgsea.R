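# Single-sample gene-set enrichment (ssGSEA) scoring.

#' ssGSEA scores for a collection of gene sets
#'
#' Per sample, features are ranked (ties broken by average rank) and a
#' rank-weighted Kolmogorov-Smirnov running sum is computed for every gene
#' set: walking the features in decreasing rank order, in-set features add
#' their rank raised to `weightExponent` (normalized over the set) and
#' out-of-set features subtract a uniform step; the enrichment score is the
#' sum of the running statistic over all positions. Because only ranks
#' enter, scores are invariant under monotone transforms of a sample's
#' expression. With `normalize = TRUE` all scores are divided by the range
#' of the whole score matrix (cross-cohort min-max scaling).
#'
#' @param mat numeric features x samples matrix.
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param weightExponent rank-weighting exponent (default 0.25).
#' @param normalize min-max normalize across the whole matrix
#'   (default `TRUE`).
#' @return numeric sets x samples matrix.
#' @references Barbie et al. (2009) Nature 462:108-112.
#' @export
ssgseaScores <- function(mat, geneSets, weightExponent = 0.25,
                         normalize = TRUE) {
  if (!length(geneSets)) stop("no gene sets supplied", call. = FALSE)
  features <- rownames(mat)
  n <- length(features)
  memberships <- lapply(names(geneSets), function(nm) {
    idx <- which(features %in% geneSets[[nm]])
    if (!length(idx)) {
      stop(sprintf("gene set '%s' has no members in the matrix", nm),
           call. = FALSE)
    }
    if (length(idx) == n) {
      stop(sprintf("gene set '%s' covers every feature", nm), call. = FALSE)
    }
    idx
  })
  names(memberships) <- names(geneSets)

  scores <- matrix(0, length(geneSets), ncol(mat),
                   dimnames = list(names(geneSets), colnames(mat)))
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    ord <- order(-r, seq_len(n))  # decreasing rank, stable tie-break
    r_ord <- r[ord]
    for (k in seq_along(memberships)) {
      in_set <- logical(n)
      in_set[memberships[[k]]] <- TRUE
      in_ord <- in_set[ord]
      w <- ifelse(in_ord, r_ord^weightExponent, 0)
      step_in <- cumsum(w) / sum(w)
      step_out <- cumsum(!in_ord) / (n - sum(in_ord))
      scores[k, j] <- sum(step_in - step_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Infer tumor microenvironment cell infiltration
#'
#' Scores a reference compendium of cell-type marker gene sets (e.g. 24 TME
#' cell types) on the expression matrix with [ssgseaScores()]; rows of the
#' result are cell types.
#'
#' @param mat numeric genes x samples expression matrix.
#' @param cellReference named list of marker gene sets, one per cell type.
#' @param ... passed to [ssgseaScores()].
#' @return numeric cell types x samples matrix of infiltration scores.
#' @export
inferTme <- function(mat, cellReference, ...) {
  ssgseaScores(mat, cellReference, ...)
}
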