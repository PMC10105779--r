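# SBS96 mutational catalogs and refitting against reference signatures.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Canonical COSMIC ordering of the 96 classes: substitutions C>A, C>G, C>T,
# T>A, T>C, T>G; within each, 5' flank then 3' flank in A,C,G,T order.
sbs96Levels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(BASES, BASES, function(l, r) {
      paste0(l, "[", s, "]", r)
    })))
  }))
}

#' Classes of the SBS96 catalog
#'
#' @return character vector of the 96 class labels in canonical COSMIC
#'   order, e.g. `"A[C>A]A"`.
#' @export
sbs96Classes <- function() sbs96Levels()

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch) {
    paste(rev(unname(COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Build SBS96 mutational catalogs
#'
#' Bins single-nucleotide variants into the canonical 96 trinucleotide
#' substitution classes. Mutations with a purine reference (A or G) are
#' reverse-complemented onto the pyrimidine strand first. Non-SNV records
#' (indels, multi-base alleles) are ignored, so each sample's catalog sums
#' to its number of contributing SNVs.
#'
#' @param mutations mutation table with columns `sample`, `ref`, `alt`,
#'   `context` (3-mer centered on the mutated base, same strand as `ref`).
#' @param samples optional sample ids forming the catalog columns.
#' @return integer matrix, 96 classes x samples.
#' @export
buildSbs96 <- function(mutations, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(mutations$sample))
  is_snv <- mutations$ref %in% BASES & mutations$alt %in% BASES &
    mutations$ref != mutations$alt
  mut <- mutations[is_snv, , drop = FALSE]
  if (nrow(mut)) {
    ctx <- toupper(mut$context)
    if (any(is.na(ctx) | nchar(ctx) != 3L)) {
      stop("trinucleotide context must be a 3-mer for every SNV",
           call. = FALSE)
    }
    if (any(substr(ctx, 2, 2) != mut$ref)) {
      stop("context center must equal the reference allele", call. = FALSE)
    }
    purine <- mut$ref %in% c("A", "G")
    ref <- ifelse(purine, COMPLEMENT[mut$ref], mut$ref)
    alt <- ifelse(purine, COMPLEMENT[mut$alt], mut$alt)
    ctx[purine] <- revcomp(ctx[purine])
    label <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                    substr(ctx, 3, 3))
  } else {
    label <- character(0)
  }
  lv <- sbs96Levels()
  mat <- vapply(samples, function(id) {
    as.integer(table(factor(label[mut$sample == id], levels = lv)))
  }, integer(96))
  mat <- matrix(mat, nrow = 96, dimnames = list(lv, samples))
  mat
}

# Non-negative least squares of catalog y against signature columns A.
nnlsFit <- function(A, y) {
  fit <- pracma::lsqnonneg(A, y)
  w <- fit$x
  w[w < 0] <- 0
  w
}

#' Refit SBS96 catalogs against reference signatures
#'
#' Decomposes each sample's SBS96 catalog into non-negative exposures to a
#' fixed set of reference signatures by non-negative least squares. An
#' optional sparsity pass then greedily removes signatures, starting from
#' the lowest exposure, as long as the cosine similarity between the
#' catalog and its reconstruction drops by less than `cosineDrop`.
#'
#' @param catalog numeric vector of length 96, or a 96 x samples matrix
#'   from [buildSbs96()].
#' @param reference signatures x 96 matrix; each signature row must be
#'   non-negative and sum to 1.
#' @param sparsify run the signature-dropping pass (default `TRUE`).
#' @param cosineDrop maximum tolerated cosine-similarity loss when dropping
#'   a signature (default 0.01).
#' @return data.frame with one row per sample: `sample`, one exposure
#'   column per reference signature, `residual` (L2 reconstruction error)
#'   and `cosine` (similarity of catalog and reconstruction).
#' @export
refitSignatures <- function(catalog, reference, sparsify = TRUE,
                            cosineDrop = 0.01) {
  if (is.null(dim(catalog))) {
    catalog <- matrix(catalog, ncol = 1, dimnames = list(names(catalog), "sample"))
  }
  if (nrow(catalog) != ncol(reference)) {
    stop(sprintf("catalog has %d classes but reference has %d columns",
                 nrow(catalog), ncol(reference)), call. = FALSE)
  }
  if (any(reference < 0)) stop("reference signatures must be non-negative",
                               call. = FALSE)
  rs <- rowSums(reference)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("each reference signature must sum to 1", call. = FALSE)
  }
  sig_names <- rownames(reference)
  if (is.null(sig_names)) sig_names <- paste0("Sig", seq_len(nrow(reference)))
  A <- t(reference)

  fitOne <- function(y) {
    if (sum(y) == 0) {
      return(list(w = stats::setNames(rep(0, nrow(reference)), sig_names),
                  residual = 0, cosine = 1))
    }
    active <- seq_len(nrow(reference))
    w <- nnlsFit(A[, active, drop = FALSE], y)
    cos_full <- cosineSim(y, A[, active, drop = FALSE] %*% w)
    if (sparsify) {
      repeat {
        pos <- which(w > 0)
        if (length(active) <= 1L || length(pos) <= 1L) break
        drop_local <- pos[which.min(w[pos])]
        cand <- active[-drop_local]
        w2 <- nnlsFit(A[, cand, drop = FALSE], y)
        cos2 <- cosineSim(y, A[, cand, drop = FALSE] %*% w2)
        if (cos_full - cos2 < cosineDrop) {
          active <- cand
          w <- w2
        } else {
          break
        }
      }
      # also drop never-used zero-exposure signatures outright
      keep <- w > 0
      if (any(!keep) && sum(keep) >= 1L) {
        active <- active[keep]
        w <- w[keep]
      }
    }
    full <- stats::setNames(rep(0, nrow(reference)), sig_names)
    full[active] <- w
    recon <- A %*% full
    list(w = full, residual = sqrt(sum((y - recon)^2)),
         cosine = cosineSim(y, recon))
  }

  rows <- lapply(seq_len(ncol(catalog)), function(j) {
    fit <- fitOne(catalog[, j])
    cbind(data.frame(sample = colnames(catalog)[j], stringsAsFactors = FALSE),
          as.data.frame(as.list(fit$w), check.names = FALSE),
          data.frame(residual = fit$residual, cosine = fit$cosine))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
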