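#' HLA class I status: germline homogeneity and tumor LOH
#'
#' Germline status is `homogeneous` when any of HLA-A/B/C carries two
#' identical 4-digit alleles, else `heterogeneous`. Tumor HLA-I LOH is called
#' when any segment overlapping any HLA-I locus has a minor allele copy
#' number of zero; `non_loh` when every locus is covered by segments with
#' `nMinor > 0`; `indeterminate` when some locus has no covering segment
#' (and no LOH was seen elsewhere).
#'
#' @param genotypes data.frame with columns `sample`, `locus`
#'   (`HLA-A`/`HLA-B`/`HLA-C`), `allele1`, `allele2` (strings like
#'   `"A*02:01"`).
#' @param segments allele-specific segment table covering the cohort
#'   (column `sample` required).
#' @param hlaLoci data.frame with columns `locus`, `chrom`, `start`, `end`
#'   (default: the toy loci of [syntheticHlaLoci()]).
#' @return data.frame with columns `sample`, `germline`
#'   (`homogeneous`/`heterogeneous`), `tumor_loh`
#'   (`loh`/`non_loh`/`indeterminate`).
#' @export
callHlaStatus <- function(genotypes, segments, hlaLoci = syntheticHlaLoci()) {
  needed <- c("sample", "locus", "allele1", "allele2")
  miss <- setdiff(needed, names(genotypes))
  if (length(miss)) {
    stop("genotype table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- grepl("^[A-Z]+\\*[0-9]+:[0-9]+$", genotypes$allele1) &
    grepl("^[A-Z]+\\*[0-9]+:[0-9]+$", genotypes$allele2)
  if (!all(ok)) {
    stop("malformed 4-digit HLA allele at row(s): ",
         paste(utils::head(which(!ok), 3), collapse = ", "), call. = FALSE)
  }
  segments <- canonicalizeSegments(segments)
  samples <- unique(genotypes$sample)
  out <- lapply(samples, function(id) {
    g <- genotypes[genotypes$sample == id, , drop = FALSE]
    germline <- if (any(g$allele1 == g$allele2)) "homogeneous" else "heterogeneous"
    seg <- segments[segments$sample == id, , drop = FALSE]
    loh_seen <- FALSE
    all_covered <- TRUE
    for (k in seq_len(nrow(hlaLoci))) {
      ov <- seg$chrom == hlaLoci$chrom[k] &
        seg$start <= hlaLoci$end[k] & seg$end >= hlaLoci$start[k]
      if (!any(ov)) {
        all_covered <- FALSE
      } else if (any(seg$nMinor[ov] == 0)) {
        loh_seen <- TRUE
      }
    }
    tumor_loh <- if (loh_seen) "loh" else if (all_covered) "non_loh" else "indeterminate"
    data.frame(sample = id, germline = germline, tumor_loh = tumor_loh,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
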