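# Clustered-mutation detection from inter-mutational distances (IMD).
#
# The sample-specific IMD threshold is calibrated against a uniform-placement
# background: each sample's catalog is re-simulated (positions re-drawn
# uniformly per chromosome, counts preserved) and a candidate threshold
# qualifies when at least `clusteredFraction` of the real mutations below it
# cannot be explained by the background, at simulation q-value < `qCut`.

# Per-mutation IMD: distance to the nearest mutation on the same chromosome.
nearestImd <- function(pos_by_chrom) {
  unlist(lapply(pos_by_chrom, function(p) {
    if (length(p) < 2L) return(numeric(0))
    p <- sort(p)
    d <- diff(p)
    pmin(c(Inf, d), c(d, Inf))
  }), use.names = FALSE)
}

#' Sample-specific IMD threshold from background simulations
#'
#' Scans the sample's observed inter-mutational distances as candidate
#' thresholds. For each candidate `t`, the number of real mutations with
#' nearest-neighbor IMD below `t` is compared with `nSimulations` uniform
#' re-placements of the same per-chromosome mutation counts. The candidate
#' qualifies when (i) the fraction of real below-threshold mutations in
#' excess of the simulated expectation is at least `clusteredFraction` and
#' (ii) the BH-adjusted simulation p-value (fraction of simulations with as
#' many below-threshold mutations as observed) is below `qCut`. The largest
#' qualifying threshold is returned; `NA` when none qualifies or fewer than
#' two mutations share a chromosome.
#'
#' The background re-places positions uniformly within each chromosome
#' (sequence context is not preserved), a desk-scale simplification of
#' context-preserving mutation shuffling.
#'
#' @param mutations mutation table for a single sample (columns `chrom`,
#'   `pos`).
#' @param build a [GenomeBuild-class] supplying chromosome lengths.
#' @param nSimulations number of background simulations (default 100).
#' @param qCut simulation q-value cutoff (default 0.1).
#' @param clusteredFraction required excess fraction (default 0.9).
#' @param seed integer seed for the background simulations.
#' @return numeric threshold in bp, or `NA`. Attributes: `n_simulations`,
#'   `candidates` (the scan table).
#' @export
imdThreshold <- function(mutations, build, nSimulations = 100, qCut = 0.1,
                         clusteredFraction = 0.9, seed = 1L) {
  pos_by_chrom <- split(mutations$pos, mutations$chrom)
  real_imd <- nearestImd(pos_by_chrom)
  real_imd <- real_imd[is.finite(real_imd)]
  if (!length(real_imd)) {
    return(structure(NA_real_, n_simulations = nSimulations,
                     candidates = NULL))
  }
  lens <- chromLen(build, names(pos_by_chrom))
  counts <- lengths(pos_by_chrom)

  set.seed(seed)
  sim_imds <- vector("list", nSimulations)
  for (s in seq_len(nSimulations)) {
    sim_pos <- lapply(seq_along(counts), function(i) {
      sample.int(lens[i], counts[i], replace = FALSE)
    })
    imd <- nearestImd(sim_pos)
    sim_imds[[s]] <- sort(imd[is.finite(imd)])
  }

  candidates <- sort(unique(real_imd))
  real_sorted <- sort(real_imd)
  r_below <- findInterval(candidates, real_sorted)  # count <= t
  sim_below <- vapply(sim_imds, function(si) {
    findInterval(candidates, si)
  }, numeric(length(candidates)))
  sim_below <- matrix(sim_below, nrow = length(candidates))
  expected <- rowMeans(sim_below)
  excess_frac <- ifelse(r_below > 0, (r_below - expected) / r_below, 0)
  p <- vapply(seq_along(candidates), function(i) {
    (1 + sum(sim_below[i, ] >= r_below[i])) / (nSimulations + 1)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  ok <- excess_frac >= clusteredFraction & q < qCut
  scan <- data.frame(threshold = candidates, n_real = r_below,
                     expected_background = expected,
                     excess_fraction = excess_frac, p = p, q = q,
                     qualifies = ok)
  thr <- if (any(ok)) max(candidates[ok]) else NA_real_
  structure(thr, n_simulations = nSimulations, candidates = scan)
}

#' Classify clustered mutations from a sample-specific IMD threshold
#'
#' Maximal runs of mutations with consecutive inter-mutational distance at
#' or below the threshold form clusters (never across chromosomes).
#' Clusters are subclassified as: doublet-base substitution (`DBS`, exactly
#' two mutations at adjacent positions), multi-base substitution (`MBS`,
#' three or more mutations all at adjacent positions), diffuse
#' hypermutation (`omikli`, two or three mutations with at least one IMD
#' greater than 1 bp) and longer events (`kataegis`, four or more mutations
#' with at least one IMD greater than 1 bp). Every other mutation is
#' `non_clustered`.
#'
#' @param mutations mutation table for one sample (columns `chrom`, `pos`;
#'   auto-sorted).
#' @param threshold IMD cutoff in bp, typically from [imdThreshold()]; `NA`
#'   classifies everything as `non_clustered`.
#' @return `mutations` with added columns `cluster_id` (NA outside
#'   clusters), `cluster_class`, and `imd_threshold`.
#' @export
classifyClusteredMutations <- function(mutations, threshold) {
  ord <- order(mutations$chrom, mutations$pos)
  mut <- mutations[ord, , drop = FALSE]
  n <- nrow(mut)
  cluster_id <- rep(NA_integer_, n)
  cls <- rep("non_clustered", n)
  if (n && !is.na(threshold)) {
    next_cluster <- 0L
    for (idx in split(seq_len(n), mut$chrom)) {
      p <- mut$pos[idx]
      if (length(p) < 2L) next
      linked <- diff(p) <= threshold
      r <- rle(linked)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        members <- idx[starts[k]:(ends[k] + 1L)]
        next_cluster <- next_cluster + 1L
        cluster_id[members] <- next_cluster
        imds <- diff(mut$pos[members])
        m <- length(members)
        cls[members] <- if (all(imds == 1)) {
          if (m == 2L) "DBS" else "MBS"
        } else if (m <= 3L) "omikli" else "kataegis"
      }
    }
  }
  mut$cluster_id <- cluster_id
  mut$cluster_class <- cls
  mut$imd_threshold <- threshold
  rownames(mut) <- NULL
  mut
}
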