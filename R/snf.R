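# Similarity network fusion: cross-diffusion of per-layer sample affinity
# networks into a single fused network, followed by spectral clustering.

# Scaled exponential-kernel affinity from a sample distance matrix.
# The local scale mu_ij averages each sample's mean distance to its K
# nearest neighbors with the pair distance itself.
affinityFromDist <- function(D, kNeighbors, alpha) {
  n <- nrow(D)
  K <- min(kNeighbors, n - 1L)
  meanK <- apply(D, 2, function(d) mean(sort(d)[2:(K + 1L)]))
  mu <- (outer(meanK, meanK, "+") + D) / 3
  mu[mu < .Machine$double.eps] <- .Machine$double.eps
  W <- exp(-D^2 / (alpha * mu))
  (W + t(W)) / 2
}

# Full-kernel normalization: off-diagonal mass 1/2, diagonal 1/2.
normalizeFull <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# k-nearest-neighbor kernel: row-normalized over each sample's K neighbors.
knnKernel <- function(W, kNeighbors) {
  n <- nrow(W)
  K <- min(kNeighbors, n - 1L)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    nb <- order(w, decreasing = TRUE)
    nb <- setdiff(nb, i)[seq_len(K)]
    S[i, nb] <- w[nb] / sum(w[nb])
  }
  S
}

#' Fuse sample-similarity networks across omics layers (SNF)
#'
#' Builds a scaled-exponential-kernel affinity per layer from pairwise
#' Euclidean distances on standardized features, then iteratively
#' cross-diffuses each layer's full kernel through the other layers'
#' k-nearest-neighbor kernels for a fixed number of iterations. The fused
#' network is the average of the converged layer kernels, symmetrized and
#' row-normalized.
#'
#' @param layers list of two or more numeric features x samples matrices
#'   with identical sample sets (column names).
#' @param kNeighbors neighborhood size K (default 20).
#' @param alpha kernel bandwidth hyperparameter (default 0.5).
#' @param iterations number of cross-diffusion iterations (default 20).
#' @param standardize z-score features within each layer first
#'   (default `TRUE`).
#' @return symmetric non-negative samples x samples fused similarity
#'   matrix.
#' @references Wang et al. (2014) Nat Methods 11:333-337.
#' @export
snfFuse <- function(layers, kNeighbors = 20, alpha = 0.5, iterations = 20,
                    standardize = TRUE) {
  if (length(layers) < 2L) stop("need at least two layers", call. = FALSE)
  ids <- colnames(layers[[1]])
  for (l in layers[-1]) {
    if (!identical(colnames(l), ids)) {
      stop("all layers must share an identical sample set", call. = FALSE)
    }
  }
  Ws <- lapply(layers, function(X) {
    if (standardize) {
      sds <- apply(X, 1, stats::sd)
      X[sds > 0, ] <- (X[sds > 0, , drop = FALSE] -
                         rowMeans(X[sds > 0, , drop = FALSE])) / sds[sds > 0]
    }
    D <- as.matrix(stats::dist(t(X)))
    affinityFromDist(D, kNeighbors, alpha)
  })
  P <- lapply(Ws, normalizeFull)
  S <- lapply(Ws, knnKernel, kNeighbors = kNeighbors)
  m <- length(P)
  for (it in seq_len(iterations)) {
    P_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1L)
      Pv <- S[[v]] %*% others %*% t(S[[v]])
      P_new[[v]] <- normalizeFull((Pv + t(Pv)) / 2)
    }
    P <- P_new
  }
  fused <- Reduce(`+`, P) / m
  fused <- fused / rowSums(fused)
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  fused
}

#' Spectral clustering of a fused similarity network
#'
#' Normalized spectral clustering: the top-k eigenvectors of the
#' symmetrically normalized affinity are row-normalized and clustered by
#' k-means.
#'
#' @param fused symmetric non-negative similarity matrix (from
#'   [snfFuse()]).
#' @param k number of clusters (default 3, the metabolite-subtype choice).
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 25).
#' @return data.frame with columns `sample`, `subtype`, `silhouette` and
#'   attribute `kind = "metabolite"`.
#' @export
snfCluster <- function(fused, k = 3, seed = 1L, nstart = 25) {
  n <- nrow(fused)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  d <- rowSums(fused)
  d[d == 0] <- 1
  Dinv <- 1 / sqrt(d)
  L <- t(fused * Dinv) * Dinv  # D^-1/2 W D^-1/2
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  rownames(U) <- rownames(fused)
  out <- kmeansAssign(U, k, seed, nstart)
  structure(out, kind = "metabolite")
}
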