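# Shared vocabularies and small helpers.

# Variant classifications counted as nonsynonymous for TMB and mutation
# frequency tables: protein-altering plus splice/translation-start events.
NONSYN_CLASSES <- c(
  "missense", "nonsense", "nonstop", "splice_site",
  "translation_start_site", "in_frame_indel", "frameshift_indel"
)

VARIANT_CLASSES <- c(NONSYN_CLASSES, "silent")

CALC_GROUPS <- c("negative", "probably_benign", "low_moderate", "high_suspicion")

#' Variant classification vocabulary
#'
#' The closed vocabulary of somatic variant classifications, and the subset
#' counted as nonsynonymous (protein-altering plus splice-site and
#' translation-start events) for tumor mutation burden and gene-level
#' mutation frequency tables.
#'
#' @return character vector of class labels.
#' @export
variantClasses <- function() VARIANT_CLASSES

#' @rdname variantClasses
#' @export
nonsynonymousClasses <- function() NONSYN_CLASSES

#' Calcification group vocabulary
#'
#' The four mammographic calcification groups: no calcifications
#' (`negative`), BI-RADS 2-3 (`probably_benign`), BI-RADS 4A-4B
#' (`low_moderate`) and BI-RADS 4C-5 (`high_suspicion`).
#'
#' @return character vector of the four group labels.
#' @export
calcGroups <- function() CALC_GROUPS

# Derive a child RNG seed from a top-level seed; keeps all derived seeds
# inside 32-bit integer range.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Expand a scalar or named per-group value into a full named per-group vector.
perGroup <- function(x, what = deparse(substitute(x))) {
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(CALC_GROUPS)), CALC_GROUPS))
  }
  if (is.null(names(x)) || !all(CALC_GROUPS %in% names(x))) {
    stop(sprintf("'%s' must be a scalar or named for all groups: %s",
                 what, paste(CALC_GROUPS, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(x[CALC_GROUPS]), CALC_GROUPS)
}

stopifnotProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", what), call. = FALSE)
  }
}

# Columns required of a segment table; validates and canonicalizes allele
# order (nMajor >= nMinor) -- scar rules are order-insensitive.
canonicalizeSegments <- function(seg) {
  needed <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(needed, names(seg))
  if (length(miss)) {
    stop("segment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(seg$end < seg$start)) stop("segment with end < start", call. = FALSE)
  if (any(seg$nMajor < 0 | seg$nMinor < 0)) {
    stop("negative allele copy number", call. = FALSE)
  }
  swap <- seg$nMajor < seg$nMinor
  if (any(swap)) {
    tmp <- seg$nMajor[swap]
    seg$nMajor[swap] <- seg$nMinor[swap]
    seg$nMinor[swap] <- tmp
  }
  seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  # reject overlaps within sample x chromosome
  key <- paste(seg$sample, seg$chrom)
  for (k in unique(key)) {
    s <- seg[key == k, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      bad <- which(s$start[-1L] <= s$end[-nrow(s)])[1L]
      stop(sprintf("overlapping segments for %s at %d-%d / %d-%d", k,
                   s$start[bad], s$end[bad], s$start[bad + 1L], s$end[bad + 1L]),
           call. = FALSE)
    }
  }
  seg
}

cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
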