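# Genomic-scar scores of homologous recombination deficiency.
#
# All three components operate on allele-specific copy-number segments
# (ASCAT-style nMajor/nMinor) for one sample at a time. "Longer than"
# thresholds are strict inequalities throughout.

# Split one sample's segments into per-chromosome sorted data.frames.
splitByChrom <- function(seg) {
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  split(seg, seg$chrom)
}

# Collapse consecutive segments satisfying `flag` into maximal runs.
# Returns data.frame(start, end, first, last) where first/last say whether
# the run contains the first/last covered segment of the chromosome.
maximalRuns <- function(segs, flag) {
  n <- nrow(segs)
  if (!n || !any(flag)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      first = logical(0), last = logical(0)))
  }
  r <- rle(flag)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = segs$start[idx_start[keep]],
    end = segs$end[idx_end[keep]],
    first = idx_start[keep] == 1L,
    last = idx_end[keep] == n
  )
}

#' Telomeric allelic imbalance score (NtAI)
#'
#' Counts subchromosomal regions of allelic imbalance (`nMajor != nMinor`)
#' longer than `minLenMb` that extend to a telomere. A region spanning the
#' whole covered chromosome is not counted (it is not subchromosomal); each
#' chromosome can contribute at most two regions, one per telomere.
#'
#' @param segments segment table for a single sample (columns `chrom`,
#'   `start`, `end`, `nMajor`, `nMinor`; `nMajor >= nMinor`).
#' @param build a [GenomeBuild-class]; chromosomes are validated against it.
#' @param minLenMb minimum region length in Mb, strict (default 11).
#' @param includeLoh logical; count LOH regions (`nMinor == 0`) as imbalance
#'   (default `TRUE`, the standard NtAI definition).
#' @return integer count.
#' @references Birkbak et al. (2012) Cancer Discov 2:366-375.
#' @export
computeNtai <- function(segments, build, minLenMb = 11, includeLoh = TRUE) {
  chromLen(build, unique(segments$chrom))  # validates chromosomes
  total <- 0L
  for (segs in splitByChrom(segments)) {
    imb <- segs$nMajor != segs$nMinor
    if (!includeLoh) imb <- imb & segs$nMinor > 0
    runs <- maximalRuns(segs, imb)
    if (!nrow(runs)) next
    telomeric <- (runs$first | runs$last) & !(runs$first & runs$last)
    long <- (runs$end - runs$start + 1) > minLenMb * 1e6
    total <- total + sum(telomeric & long)
  }
  as.integer(total)
}

#' Loss-of-heterozygosity scar score
#'
#' Counts maximal LOH runs (`nMinor == 0`, `nMajor > 0`) longer than
#' `minLenMb` but shorter than the whole chromosome. Runs on excluded
#' chromosomes (chromosome 17 by default) are not counted.
#'
#' @inheritParams computeNtai
#' @param minLenMb minimum run length in Mb, strict (default 15).
#' @param excludeChrom chromosomes whose LOH runs are ignored
#'   (default `"17"`).
#' @return integer count.
#' @references Abkevich et al. (2012) Br J Cancer 107:1776-1782.
#' @export
computeLohScore <- function(segments, build, minLenMb = 15,
                            excludeChrom = "17") {
  chromLen(build, unique(segments$chrom))
  total <- 0L
  by_chrom <- splitByChrom(segments)
  for (chrom in names(by_chrom)) {
    if (chrom %in% as.character(excludeChrom)) next
    segs <- by_chrom[[chrom]]
    runs <- maximalRuns(segs, segs$nMinor == 0 & segs$nMajor > 0)
    if (!nrow(runs)) next
    subchrom <- !(runs$first & runs$last)
    long <- (runs$end - runs$start + 1) > minLenMb * 1e6
    total <- total + sum(subchrom & long)
  }
  as.integer(total)
}

# Smoothing for LST: delete segments shorter than smooth_bp, closing each
# gap by extending the left neighbor (the right neighbor for a leading
# segment), then merge adjacent segments with identical allele states.
smoothSegments <- function(segs, smooth_bp) {
  segs <- mergeSameState(segs)
  repeat {
    n <- nrow(segs)
    if (n <= 1L) break
    len <- segs$end - segs$start + 1
    small <- which(len < smooth_bp)
    if (!length(small)) break
    i <- small[1L]
    if (i > 1L) {
      segs$end[i - 1L] <- segs$end[i]
    } else {
      segs$start[i + 1L] <- segs$start[i]
    }
    segs <- segs[-i, , drop = FALSE]
    # merge identical adjacent states
    segs <- mergeSameState(segs)
  }
  mergeSameState(segs)
}

mergeSameState <- function(segs) {
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  same <- segs$nMajor[-1L] == segs$nMajor[-n] &
    segs$nMinor[-1L] == segs$nMinor[-n]
  if (!any(same)) return(segs)
  grp <- cumsum(c(TRUE, !same))
  out <- segs[!duplicated(grp), , drop = FALSE]
  out$end <- tapply(segs$end, grp, max)
  out$start <- tapply(segs$start, grp, min)
  rownames(out) <- NULL
  out
}

#' Large-scale state transition score (LST)
#'
#' Counts copy-number breakpoints whose two flanking regions are each longer
#' than `minFlankMb`, after smoothing away regions shorter than `smoothMb`.
#' When the genome build carries a centromere model and `armAware = TRUE`,
#' segments are split at the centromere midpoint and breakpoints are counted
#' within each chromosome arm (the convention of the original LST
#' literature); otherwise whole chromosomes are scanned.
#'
#' @inheritParams computeNtai
#' @param minFlankMb minimum flanking-region length in Mb, strict
#'   (default 10).
#' @param smoothMb regions shorter than this (Mb) are removed before
#'   breakpoint counting (default 3).
#' @param armAware split at centromeres when available (default `TRUE`).
#' @return integer count.
#' @references Popova et al. (2012) Cancer Res 72:5454-5462.
#' @export
computeLst <- function(segments, build, minFlankMb = 10, smoothMb = 3,
                       armAware = TRUE) {
  chromLen(build, unique(segments$chrom))
  total <- 0L
  by_chrom <- splitByChrom(segments)
  for (chrom in names(by_chrom)) {
    segs <- by_chrom[[chrom]]
    i <- match(chrom, build@chrom)
    mid <- if (armAware && !is.na(build@cenStart[i])) {
      (build@cenStart[i] + build@cenEnd[i]) / 2
    } else {
      NA_real_
    }
    arms <- if (is.na(mid)) list(segs) else splitAtPoint(segs, mid)
    for (arm in arms) {
      if (!nrow(arm)) next
      sm <- smoothSegments(arm, smoothMb * 1e6)
      n <- nrow(sm)
      if (n < 2L) next
      len <- sm$end - sm$start + 1
      total <- total + sum(len[-n] > minFlankMb * 1e6 &
                             len[-1L] > minFlankMb * 1e6)
    }
  }
  as.integer(total)
}

# Split a sorted segment table at a genomic point; segments crossing the
# point are divided into a left part (<= point) and a right part.
splitAtPoint <- function(segs, point) {
  left <- segs[segs$end <= point, , drop = FALSE]
  right <- segs[segs$start > point, , drop = FALSE]
  cross <- segs[segs$start <= point & segs$end > point, , drop = FALSE]
  if (nrow(cross)) {
    l <- cross; l$end <- floor(point)
    r <- cross; r$start <- floor(point) + 1
    left <- rbind(left, l)
    right <- rbind(r, right)
  }
  list(left[order(left$start), , drop = FALSE],
       right[order(right$start), , drop = FALSE])
}

#' Homologous recombination deficiency (HRD) score
#'
#' The HRD scar score is the sum of three independent components computed
#' from allele-specific copy-number segments: telomeric allelic imbalance
#' ([computeNtai()]), LOH ([computeLohScore()]) and large-scale state
#' transitions ([computeLst()]).
#'
#' @param segments segment table for one or more samples (column `sample`
#'   required when more than one is present).
#' @param build a [GenomeBuild-class].
#' @param ... passed on to the component scores (`minLenMb`, `armAware`, ...,
#'   matched by name to the respective component).
#' @param ntaiArgs,lohArgs,lstArgs named lists of arguments forwarded to the
#'   respective component score.
#' @return data.frame with columns `sample`, `ntai`, `loh`, `lst`, `hrd`.
#' @export
computeHrd <- function(segments, build, ntaiArgs = list(), lohArgs = list(),
                       lstArgs = list(), ...) {
  segments <- canonicalizeSegments(
    if (!"sample" %in% names(segments)) cbind(sample = "sample", segments)
    else segments)
  per_sample <- split(segments, segments$sample)
  out <- lapply(names(per_sample), function(id) {
    seg <- per_sample[[id]]
    ntai <- do.call(computeNtai, c(list(seg, build), ntaiArgs))
    loh <- do.call(computeLohScore, c(list(seg, build), lohArgs))
    lst <- do.call(computeLst, c(list(seg, build), lstArgs))
    data.frame(sample = id, ntai = ntai, loh = loh, lst = lst,
               hrd = ntai + loh + lst, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
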