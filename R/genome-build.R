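#' Construct a GenomeBuild
#'
#' @param chrom character vector of chromosome names.
#' @param length numeric vector of chromosome lengths in bp.
#' @param cenStart,cenEnd optional centromere interval bounds in bp; `NA`
#'   (default) disables the centromere model for a chromosome, in which case
#'   LST breakpoints are counted whole-chromosome.
#' @return a [GenomeBuild-class] object.
#' @examples
#' GenomeBuild(c("1", "2"), c(100e6, 80e6))
#' @export
GenomeBuild <- function(chrom, length, cenStart = NA_real_, cenEnd = NA_real_) {
  n <- base::length(chrom)
  new("GenomeBuild",
      chrom = as.character(chrom),
      seqlength = as.numeric(length),
      cenStart = rep_len(as.numeric(cenStart), n),
      cenEnd = rep_len(as.numeric(cenEnd), n))
}

#' Built-in synthetic genome build
#'
#' A small genome of 10 chromosomes of 100 Mb each, centromeres at 48-52 Mb,
#' used by the synthetic cohort generator so that no reference genome needs
#' to be shipped. HLA class I toy loci live on chromosome "6"
#' (see [syntheticHlaLoci()]).
#'
#' @param centromeres logical; include the centromere model (default `TRUE`).
#' @return a [GenomeBuild-class] with chromosomes `"1"` to `"10"`.
#' @export
syntheticGenomeBuild <- function(centromeres = TRUE) {
  GenomeBuild(
    chrom = as.character(1:10),
    length = rep(100e6, 10),
    cenStart = if (centromeres) rep(48e6, 10) else NA_real_,
    cenEnd = if (centromeres) rep(52e6, 10) else NA_real_
  )
}

#' Toy HLA class I loci on the synthetic genome
#'
#' Genomic intervals for HLA-A/B/C on synthetic chromosome "6", mimicking the
#' layout of the human MHC. Used by [callHlaStatus()] and the generator.
#'
#' @return data.frame with columns `locus`, `chrom`, `start`, `end`.
#' @export
syntheticHlaLoci <- function() {
  data.frame(
    locus = c("HLA-A", "HLA-B", "HLA-C"),
    chrom = "6",
    start = c(29.90e6, 31.20e6, 31.30e6),
    end = c(29.95e6, 31.25e6, 31.35e6),
    stringsAsFactors = FALSE
  )
}

#' Read a genome build from a cytoband-style TSV
#'
#' Expects tab-separated columns `chrom`, `length`, and optionally
#' `cen_start`, `cen_end` (bp, 1-based inclusive).
#'
#' @param path path to the TSV file.
#' @return a [GenomeBuild-class] object.
#' @export
readGenomeBuild <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "length"), names(tab))
  if (length(miss)) {
    stop("genome build file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  GenomeBuild(tab$chrom, tab$length,
              cenStart = if ("cen_start" %in% names(tab)) tab$cen_start else NA_real_,
              cenEnd = if ("cen_end" %in% names(tab)) tab$cen_end else NA_real_)
}

#' Write a genome build to TSV
#'
#' @param build a [GenomeBuild-class] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenomeBuild <- function(build, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates=1-based-inclusive", con)
  tab <- data.frame(chrom = build@chrom, length = build@seqlength,
                    cen_start = build@cenStart, cen_end = build@cenEnd)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Lookup a chromosome length; errors on unknown chromosome.
chromLen <- function(build, chrom) {
  i <- match(chrom, build@chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  build@seqlength[i]
}
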