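# Readers and writers for every on-disk format the pipeline touches.
# All coordinates are 1-based inclusive; every writer says so in a header
# comment. Readers validate strictly and reject rather than coerce.

maf_cols <- c("sample", "gene", "chrom", "pos", "ref", "alt", "classification")

requireCols <- function(tab, needed, what) {
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a MAF-like mutation table
#'
#' Tab-separated somatic mutation catalog with columns `sample`, `gene`,
#' `chrom`, `pos`, `ref`, `alt`, `classification` and optionally `context`
#' (trinucleotide context centered on the position). Classifications must
#' come from [variantClasses()]; a logical `nonsynonymous` column is added
#' according to [nonsynonymousClasses()].
#'
#' @param path path to the TSV file.
#' @param build optional [GenomeBuild-class]; when supplied, chromosomes are
#'   checked against it.
#' @return data.frame of mutation records.
#' @seealso [writeMaf()], [computeTmb()], [buildSbs96()]
#' @export
readMaf <- function(path, build = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  requireCols(tab, maf_cols, "MAF file")
  tab$pos <- suppressWarnings(as.numeric(tab$pos))
  if (anyNA(tab$pos) || any(tab$pos < 1)) {
    stop("MAF file: non-numeric or < 1 position", call. = FALSE)
  }
  bad <- !tab$classification %in% VARIANT_CLASSES
  if (any(bad)) {
    stop("MAF file: unknown classification(s): ",
         paste(unique(tab$classification[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(tab$ref == tab$alt)) stop("MAF file: ref equals alt", call. = FALSE)
  if (!is.null(build)) {
    unknown <- setdiff(unique(tab$chrom), build@chrom)
    if (length(unknown)) {
      stop("MAF file: unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!"context" %in% names(tab)) tab$context <- NA_character_
  tab$nonsynonymous <- tab$classification %in% NONSYN_CLASSES
  tab
}

#' @rdname readMaf
#' @param mutations data.frame of mutation records.
#' @export
writeMaf <- function(mutations, path) {
  requireCols(mutations, maf_cols, "mutation table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates=1-based-inclusive", con)
  keep <- intersect(c(maf_cols, "context"), names(mutations))
  utils::write.table(mutations[, keep, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated table with columns `sample`, `chrom`, `start`, `end`,
#' `nMajor`, `nMinor` (ASCAT-style allele-specific copy numbers, 1-based
#' inclusive coordinates). On ingest the allele order is canonicalized to
#' `nMajor >= nMinor` (all scar rules are order-insensitive); per-sample,
#' per-chromosome segments are sorted and overlaps are rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated segments.
#' @seealso [writeSegments()], [computeHrd()]
#' @export
readSegments <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  requireCols(tab, c("sample", "chrom", "start", "end", "nMajor", "nMinor"),
              "segment file")
  tab$chrom <- as.character(tab$chrom)
  canonicalizeSegments(tab)
}

#' @rdname readSegments
#' @param segments data.frame of segments.
#' @export
writeSegments <- function(segments, path) {
  segments <- canonicalizeSegments(segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates=1-based-inclusive", con)
  utils::write.table(
    segments[, c("sample", "chrom", "start", "end", "nMajor", "nMinor")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, members... Duplicate members within a set are
#' deduplicated; empty sets are rejected.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop(sprintf("GMT line %d defines an empty set '%s'", i, fields[[1]]),
           call. = FALSE)
    }
    sets[[fields[[1]]]] <- members
  }
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a features x samples abundance matrix from TSV
#'
#' First column holds feature ids (must be unique), header row holds sample
#' ids, payload is numeric. `NA` handling is governed by `naPolicy`:
#' `"drop"` removes any feature with a missing value, `"impute_min"`
#' replaces missing values with the feature's observed minimum,
#' `"keep"` leaves them in place.
#'
#' @param path path to the TSV file.
#' @param naPolicy one of `"drop"`, `"impute_min"`, `"keep"`.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
readMatrixTsv <- function(path, naPolicy = c("drop", "impute_min", "keep")) {
  naPolicy <- match.arg(naPolicy)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a feature column plus samples",
                           call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  payload <- tab[, -1, drop = FALSE]
  for (j in seq_along(payload)) {
    col <- payload[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad)) {
        stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                     ids[bad[1]], names(payload)[j]), call. = FALSE)
      }
      payload[[j]] <- as.numeric(col)
    }
  }
  mat <- as.matrix(payload)
  rownames(mat) <- ids
  if (anyNA(mat)) {
    if (naPolicy == "drop") {
      mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    } else if (naPolicy == "impute_min") {
      for (i in which(rowSums(is.na(mat)) > 0)) {
        mat[i, is.na(mat[i, ])] <- min(mat[i, ], na.rm = TRUE)
      }
    }
  }
  mat
}

#' @rdname readMatrixTsv
#' @param mat numeric matrix with rownames and colnames.
#' @param featureCol name for the feature id column.
#' @export
writeMatrixTsv <- function(mat, path, featureCol = "feature") {
  con <- file(path, "w")
  on.exit(close(con))
  tab <- data.frame(rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- featureCol
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort sample table
#'
#' Tab-separated per-sample table with columns `sample` (unique ids) and
#' `calc_group` (one of [calcGroups()]), plus clinical covariates and the
#' survival endpoints `os_time`/`os_event`, `dmfs_time`/`dmfs_event`,
#' `rfs_time`/`rfs_event` when present (times in months, non-negative).
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  requireCols(tab, c("sample", "calc_group"), "cohort file")
  if (anyDuplicated(tab$sample)) stop("duplicate sample ids", call. = FALSE)
  bad <- !tab$calc_group %in% CALC_GROUPS
  if (any(bad)) {
    stop("unknown calcification group(s): ",
         paste(unique(tab$calc_group[bad]), collapse = ", "), call. = FALSE)
  }
  for (col in grep("_time$", names(tab), value = TRUE)) {
    if (any(tab[[col]] < 0, na.rm = TRUE)) {
      stop("negative survival time in column ", col, call. = FALSE)
    }
  }
  tab
}

#' @rdname readCohort
#' @param cohort data.frame with at least `sample` and `calc_group`.
#' @export
writeCohort <- function(cohort, path) {
  requireCols(cohort, c("sample", "calc_group"), "cohort table")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# times=months", con)
  utils::write.table(cohort, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GISTIC all-thresholded-by-genes matrix
#'
#' Gene x sample matrix of thresholded copy-number calls in {-2, -1, 0, 1, 2}.
#' Amplification events are calls of +2 and deep deletions are calls of -2;
#' use [gisticEventMatrix()] to derive binary event matrices.
#'
#' @param path path to the TSV file (first column gene ids).
#' @return integer matrix of calls.
#' @export
readGisticThresholded <- function(path) {
  mat <- readMatrixTsv(path, naPolicy = "keep")
  if (anyNA(mat) || any(mat != round(mat)) || any(mat < -2 | mat > 2)) {
    stop("GISTIC calls must be integers in {-2,...,2}", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Binary event matrix from GISTIC thresholded calls
#'
#' @param calls matrix from [readGisticThresholded()].
#' @param type `"amplification"` (call == +2) or `"deep_deletion"`
#'   (call == -2).
#' @return logical gene x sample matrix.
#' @export
gisticEventMatrix <- function(calls, type = c("amplification", "deep_deletion")) {
  type <- match.arg(type)
  if (type == "amplification") calls == 2L else calls == -2L
}

#' Binary gene x sample mutation event matrix
#'
#' @param mutations mutation table (see [readMaf()]).
#' @param samples sample ids forming the columns (defaults to those present).
#' @param genes gene ids forming the rows (defaults to those present).
#' @param nonsynOnly count only nonsynonymous records (default `TRUE`).
#' @return logical gene x sample matrix.
#' @export
mutationEventMatrix <- function(mutations, samples = NULL, genes = NULL,
                                nonsynOnly = TRUE) {
  if (nonsynOnly) {
    keep <- if ("nonsynonymous" %in% names(mutations)) {
      mutations$nonsynonymous
    } else {
      mutations$classification %in% NONSYN_CLASSES
    }
    mutations <- mutations[keep, , drop = FALSE]
  }
  if (is.null(samples)) samples <- sort(unique(mutations$sample))
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  mat <- matrix(FALSE, length(genes), length(samples),
                dimnames = list(genes, samples))
  hit <- mutations$gene %in% genes & mutations$sample %in% samples
  if (any(hit)) {
    mat[cbind(match(mutations$gene[hit], genes),
              match(mutations$sample[hit], samples))] <- TRUE
  }
  mat
}
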