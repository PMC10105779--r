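# k-means subtype assignment for expression and immune-score profiles.

kmeansAssign <- function(X, k, seed, nstart = 25) {
  if (nrow(X) < k) stop("fewer samples than clusters", call. = FALSE)
  set.seed(seed)
  if (k == 1L) {
    cl <- rep(1L, nrow(X))
  } else {
    cl <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)$cluster
  }
  sil <- rep(NA_real_, nrow(X))
  if (k > 1L && nrow(X) > k) {
    sil_obj <- cluster::silhouette(cl, stats::dist(X))
    sil <- sil_obj[, "sil_width"]
  }
  data.frame(sample = rownames(X),
             subtype = paste0("S", cl),
             silhouette = sil,
             stringsAsFactors = FALSE)
}

#' mRNA subtype assignment by k-means on high-variance genes
#'
#' Samples are clustered with k-means on the genes with the largest
#' standard deviation across the cohort (top 2000 by default; all genes if
#' fewer). Labels are cluster indices (`S1`..`Sk`); biological naming (LAR,
#' IM, BLIS, MES, ...) is attached downstream by the caller via marker
#' knowledge, never hard-coded here.
#'
#' @param mat numeric genes x samples log-expression matrix.
#' @param nTopSd number of top-SD genes to retain (default 2000).
#' @param k number of clusters (default 4).
#' @param seed integer RNG seed (k-means restarts).
#' @param nstart number of k-means restarts (default 25).
#' @return data.frame with columns `sample`, `subtype`, `silhouette` and
#'   attribute `kind = "mrna"`.
#' @export
clusterMrnaSubtype <- function(mat, nTopSd = 2000, k = 4, seed = 1L,
                               nstart = 25) {
  sds <- apply(mat, 1, stats::sd)
  top <- utils::head(order(sds, decreasing = TRUE), nTopSd)
  out <- kmeansAssign(t(mat[top, , drop = FALSE]), k, seed, nstart)
  structure(out, kind = "mrna")
}

#' Immune subtype assignment from TME cell scores
#'
#' Scales each cell type's scores across samples, then clusters samples by
#' k-means. The cluster number is caller-specified; use [silhouetteScan()]
#' to pick one.
#'
#' @param cellScores numeric cell types x samples matrix (e.g. from
#'   [inferTme()]).
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @param nstart number of k-means restarts (default 25).
#' @return data.frame with columns `sample`, `subtype`, `silhouette` and
#'   attribute `kind = "immune"`.
#' @export
clusterImmuneSubtype <- function(cellScores, k, seed = 1L, nstart = 25) {
  X <- t(cellScores)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant cell-type score(s); left unscaled")
    keep_scale <- sds > 0
    X[, keep_scale] <- scale(X[, keep_scale, drop = FALSE])
  } else {
    X <- scale(X)
  }
  out <- kmeansAssign(X, k, seed, nstart)
  structure(out, kind = "immune")
}

#' Mean silhouette across a range of cluster numbers
#'
#' A silhouette scan standing in for multi-index cluster-number votes:
#' k-means is run for each candidate `k` and the mean silhouette width is
#' reported.
#'
#' @param mat numeric features x samples matrix (samples are clustered).
#' @param kRange candidate cluster numbers (default 2:8).
#' @param seed integer RNG seed.
#' @param scaleFeatures scale features before clustering (default `TRUE`).
#' @return data.frame with columns `k`, `mean_silhouette`.
#' @export
silhouetteScan <- function(mat, kRange = 2:8, seed = 1L, scaleFeatures = TRUE) {
  X <- t(mat)
  if (scaleFeatures) {
    sds <- apply(X, 2, stats::sd)
    X[, sds > 0] <- scale(X[, sds > 0, drop = FALSE])
  }
  d <- stats::dist(X)
  res <- vapply(kRange, function(k) {
    set.seed(childSeed(seed, k))
    cl <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)$cluster
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = kRange, mean_silhouette = res)
}
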