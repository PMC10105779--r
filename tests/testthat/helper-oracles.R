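# Independent brute-force oracles. These deliberately take a different
# route than the package code (bin vectors instead of segment runs, subset
# enumeration instead of active-set NNLS, explicit loops instead of
# vectorized cumulative sums).

# --- segment fixtures -------------------------------------------------

makeSegs <- function(chrom, start, end, nMajor, nMinor, sample = "s1") {
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, nMajor = nMajor, nMinor = nMinor,
             stringsAsFactors = FALSE)
}

# Random fully-tiling allele-specific profile on a lattice of whole Mb.
randomProfile <- function(build, maxBreaks = 6,
                          states = list(c(1, 1), c(2, 1), c(2, 0), c(1, 0),
                                        c(2, 2), c(3, 1), c(3, 0))) {
  rows <- lapply(seq_along(chromNames(build)), function(ci) {
    L_mb <- chromLengths(build)[ci] / 1e6
    k <- sample(0:maxBreaks, 1)
    breaks <- sort(sample(seq_len(L_mb - 1), k))
    bounds <- c(0, breaks, L_mb)
    st <- states[sample(length(states), length(bounds) - 1, replace = TRUE)]
    data.frame(sample = "s1", chrom = chromNames(build)[ci],
               start = utils::head(bounds, -1) * 1e6 + 1,
               end = utils::tail(bounds, -1) * 1e6,
               nMajor = vapply(st, `[`, numeric(1), 1),
               nMinor = vapply(st, `[`, numeric(1), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- scar-score oracle on bin vectors ---------------------------------

# One chromosome's segments -> per-bin state matrix (2 x nbins).
segsToBins <- function(segs, L, binBp = 5e5) {
  nb <- L / binBp
  maj <- rep(NA_real_, nb); mino <- rep(NA_real_, nb)
  mids <- (seq_len(nb) - 0.5) * binBp
  for (i in seq_len(nrow(segs))) {
    inside <- mids >= segs$start[i] - 1 & mids <= segs$end[i]
    maj[inside] <- segs$nMajor[i]
    mino[inside] <- segs$nMinor[i]
  }
  rbind(maj, mino)
}

runsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

oracleScars <- function(seg, build, binBp = 5e5, excludeChrom = "17",
                        armAware = FALSE) {
  ntai <- 0L; loh <- 0L; lst <- 0L
  for (chrom in unique(seg$chrom)) {
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    L <- unname(chromLengths(build)[chrom])
    st <- segsToBins(s, L, binBp)
    nb <- ncol(st)

    # NtAI: imbalance runs touching exactly one telomere, > 11 Mb
    imb <- st[1, ] != st[2, ]
    rr <- runsOf(imb)
    for (j in which(rr$value)) {
      len <- (rr$end[j] - rr$start[j] + 1) * binBp
      touch_p <- rr$start[j] == 1L
      touch_q <- rr$end[j] == nb
      if (xor(touch_p, touch_q) && len > 11e6) ntai <- ntai + 1L
    }

    # LOH: nMinor == 0 & nMajor > 0 runs, > 15 Mb, subchromosomal
    if (!chrom %in% excludeChrom) {
      lo <- st[2, ] == 0 & st[1, ] > 0
      rr <- runsOf(lo)
      for (j in which(rr$value)) {
        len <- (rr$end[j] - rr$start[j] + 1) * binBp
        whole <- rr$start[j] == 1L && rr$end[j] == nb
        if (!whole && len > 15e6) loh <- loh + 1L
      }
    }

    # LST: per arm, smooth < 3 Mb into left neighbor, breakpoints with
    # both flanks > 10 Mb
    ci <- match(chrom, chromNames(build))
    cen <- centromeres(build)
    arm_bins <- if (armAware && !is.na(cen$cen_start[ci])) {
      mid <- (cen$cen_start[ci] + cen$cen_end[ci]) / 2
      cut_bin <- floor(mid / binBp)
      list(seq_len(cut_bin), (cut_bin + 1):nb)
    } else {
      list(seq_len(nb))
    }
    for (bins in arm_bins) {
      lab <- paste(st[1, bins], st[2, bins])
      repeat {
        rr <- runsOf(lab)
        lens <- (rr$end - rr$start + 1) * binBp
        small <- which(lens < 3e6)
        if (!length(small) || nrow(rr) == 1L) break
        j <- small[1L]
        fill <- if (j > 1L) rr$value[j - 1L] else rr$value[j + 1L]
        lab[rr$start[j]:rr$end[j]] <- fill
      }
      rr <- runsOf(lab)
      if (nrow(rr) >= 2L) {
        lens <- (rr$end - rr$start + 1) * binBp
        lst <- lst + sum(lens[-nrow(rr)] > 10e6 & lens[-1L] > 10e6)
      }
    }
  }
  list(ntai = ntai, loh = loh, lst = lst, hrd = ntai + loh + lst)
}

# --- NNLS oracle by subset enumeration --------------------------------

oracleNnls <- function(A, y) {
  p <- ncol(A)
  best_res <- sum(y^2)
  best_w <- rep(0, p)
  for (size in seq_len(p)) {
    for (S in utils::combn(p, size, simplify = FALSE)) {
      fit <- stats::lm.fit(A[, S, drop = FALSE], y)
      w <- fit$coefficients
      w[is.na(w)] <- 0
      if (all(w >= -1e-9)) {
        res <- sum(fit$residuals^2)
        if (res < best_res - 1e-12) {
          best_res <- res
          best_w <- rep(0, p); best_w[S] <- pmax(w, 0)
        }
      }
    }
  }
  list(w = best_w, residual = sqrt(best_res))
}

# --- SBS96 oracle via string munging ----------------------------------

oracleSbs96Label <- function(ref, alt, ctx) {
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  if (ref %in% c("A", "G")) {
    ctx <- rc(ctx)
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
}

# --- BH oracle --------------------------------------------------------

oracleBh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# --- ssGSEA oracle: explicit running-sum loop -------------------------

oracleSsgsea <- function(expr_col, set_members, features, alpha = 0.25) {
  r <- unname(rank(expr_col, ties.method = "average"))
  ord <- order(-r, seq_along(r))
  n <- length(features)
  in_set <- features %in% set_members
  m <- sum(in_set)
  sum_w <- sum(r[in_set]^alpha)
  running <- 0; cum_in <- 0; cum_out <- 0
  for (i in ord) {
    if (in_set[i]) cum_in <- cum_in + r[i]^alpha / sum_w
    else cum_out <- cum_out + 1 / (n - m)
    running <- running + (cum_in - cum_out)
  }
  running
}

# --- DA oracle: explicit per-pathway recount --------------------------

oracleDa <- function(mat, groups, annotation, positive, alpha = 0.05,
                     minSize = 3) {
  pos <- groups == positive
  out <- list()
  for (pw in unique(annotation$pathway)) {
    members <- unique(annotation$feature[annotation$pathway == pw])
    members <- members[members %in% rownames(mat)]
    if (length(members) < minSize) next
    inc <- 0L; dec <- 0L
    for (f in members) {
      pv <- stats::wilcox.test(mat[f, pos], mat[f, !pos], exact = FALSE)$p.value
      md <- stats::median(mat[f, pos]) - stats::median(mat[f, !pos])
      if (pv < alpha && md > 0) inc <- inc + 1L
      if (pv < alpha && md < 0) dec <- dec + 1L
    }
    out[[pw]] <- (inc - dec) / length(members)
  }
  out
}

# --- misc -------------------------------------------------------------

adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
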