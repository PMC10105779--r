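#' Literature-signature score (3-step procedure)
#'
#' Scores one or more gene signatures on a log-expression matrix by the
#' three-step procedure used for literature-defined immune, immunotherapy
#' response and metabolic signatures: (1) mean-center each gene across all
#' samples, (2) average the centered values over the signature genes per
#' sample, (3) z-score the per-sample averages across the cohort. Scores
#' therefore always have cohort mean 0 and SD 1.
#'
#' @param mat numeric genes x samples matrix (log scale).
#' @param signature character vector of gene ids, or a named list of such
#'   vectors for multiple signatures.
#' @return a named numeric vector of per-sample scores, or, for a list of
#'   signatures, a signatures x samples matrix.
#' @export
signatureScore <- function(mat, signature) {
  if (is.list(signature)) {
    out <- t(vapply(signature, function(g) signatureScore(mat, g),
                    numeric(ncol(mat))))
    colnames(out) <- colnames(mat)
    return(out)
  }
  if (ncol(mat) < 2L) stop("at least two samples are required", call. = FALSE)
  genes <- intersect(signature, rownames(mat))
  if (!length(genes)) {
    stop("no signature genes found in the matrix", call. = FALSE)
  }
  if (length(genes) < length(unique(signature))) {
    warning(length(unique(signature)) - length(genes),
            " signature gene(s) absent from the matrix; dropped")
  }
  centered <- mat[genes, , drop = FALSE] - rowMeans(mat[genes, , drop = FALSE])
  avg <- colMeans(centered)
  s <- stats::sd(avg)
  if (s == 0) {
    warning("signature average is constant across samples; returning zeros")
    return(stats::setNames(rep(0, length(avg)), colnames(mat)))
  }
  stats::setNames((avg - mean(avg)) / s, colnames(mat))
}
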