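# Metabolite and lipid analytics: tumor-vs-normal prefiltering, pathway
# differential-abundance (DA) scores, and lipid subclass fold changes.

#' Tumor-vs-normal feature prefiltering
#'
#' Keeps features showing a significant tumor-normal difference (two-sided
#' Wilcoxon rank-sum test, Benjamini-Hochberg FDR < `fdrCut`, both strict)
#' AND an absolute log2 fold change above `lfcCut`, then truncates to the
#' `topSd` features with the largest SD across tumor samples. Matrices are
#' expected on the log2 scale, so the fold change is a difference of group
#' means. Without a normal matrix the test is skipped with a warning and
#' only the SD truncation is applied.
#'
#' @param tumor numeric features x samples matrix (log2 scale).
#' @param normal matching features x samples matrix of adjacent normals,
#'   or `NULL`.
#' @param fdrCut BH FDR cutoff, exclusive (default 0.01).
#' @param lfcCut absolute log2 fold-change cutoff, exclusive (default 1).
#' @param topSd retain at most this many surviving features by tumor SD
#'   (`NULL` keeps all); the study design uses 200 for polar metabolites
#'   and 400 for lipids.
#' @return the filtered tumor matrix; attribute `stats` holds the
#'   per-feature test table.
#' @export
prefilterFeatures <- function(tumor, normal, fdrCut = 0.01, lfcCut = 1,
                              topSd = NULL) {
  if (is.null(normal)) {
    warning("no normal matrix supplied; skipping the tumor-normal test")
    keep <- rownames(tumor)
    stats_tab <- NULL
  } else {
    feats <- intersect(rownames(tumor), rownames(normal))
    if (!length(feats)) stop("tumor and normal share no features", call. = FALSE)
    p <- vapply(feats, function(f) {
      stats::wilcox.test(tumor[f, ], normal[f, ], exact = FALSE)$p.value
    }, numeric(1))
    lfc <- rowMeans(tumor[feats, , drop = FALSE]) -
      rowMeans(normal[feats, , drop = FALSE])
    fdr <- stats::p.adjust(p, method = "BH")
    stats_tab <- data.frame(feature = feats, log2fc = lfc, p = p, fdr = fdr,
                            row.names = NULL, stringsAsFactors = FALSE)
    keep <- feats[fdr < fdrCut & abs(lfc) > lfcCut]
  }
  out <- tumor[keep, , drop = FALSE]
  if (!is.null(topSd) && nrow(out) > topSd) {
    sds <- apply(out, 1, stats::sd)
    out <- out[utils::head(order(sds, decreasing = TRUE), topSd), ,
               drop = FALSE]
  }
  attr(out, "stats") <- stats_tab
  out
}

#' Pathway differential-abundance (DA) score
#'
#' For each metabolite a two-sided Mann-Whitney U test compares the
#' `positive` group against the reference; a metabolite is called increased
#' (decreased) when its raw p-value is below `alpha` and the median
#' difference (positive minus reference) is positive (negative). Per
#' pathway, `DA = (increased - decreased) / measured`, so DA is 1 when
#' every profiled metabolite of a pathway is up and -1 when every one is
#' down. Pathways with fewer than `minPathwaySize` profiled metabolites are
#' excluded.
#'
#' @param mat numeric metabolites x samples matrix.
#' @param groups per-sample group labels (length `ncol(mat)`).
#' @param annotation data.frame mapping metabolites to pathways, columns
#'   `feature`, `pathway` (one row per membership; optional `category`).
#' @param positive label of the group of interest; contrasts are
#'   positive-minus-reference.
#' @param alpha raw p-value cutoff for the per-metabolite test
#'   (default 0.05).
#' @param minPathwaySize minimum profiled metabolites per pathway
#'   (default 3).
#' @return data.frame with columns `pathway` (and `category` if supplied),
#'   `n_measured`, `n_increased`, `n_decreased`, `da_score`; attribute
#'   `metabolites` holds the per-metabolite test table.
#' @export
daScore <- function(mat, groups, annotation, positive, alpha = 0.05,
                    minPathwaySize = 3) {
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("'groups' must have one label per sample", call. = FALSE)
  }
  if (!positive %in% groups) stop("'positive' group absent", call. = FALSE)
  pos <- groups == positive
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  feats <- intersect(rownames(mat), unique(annotation$feature))
  if (!length(feats)) stop("annotation matches no features", call. = FALSE)

  p <- vapply(feats, function(f) {
    stats::wilcox.test(mat[f, pos], mat[f, !pos], exact = FALSE)$p.value
  }, numeric(1))
  med_diff <- vapply(feats, function(f) {
    stats::median(mat[f, pos]) - stats::median(mat[f, !pos])
  }, numeric(1))
  direction <- ifelse(p < alpha & med_diff > 0, 1L,
                      ifelse(p < alpha & med_diff < 0, -1L, 0L))
  met_tab <- data.frame(feature = feats, p = p, median_diff = med_diff,
                        direction = direction, row.names = NULL,
                        stringsAsFactors = FALSE)

  ann <- annotation[annotation$feature %in% feats, , drop = FALSE]
  pathways <- split(ann$feature, ann$pathway)
  rows <- lapply(names(pathways), function(pw) {
    members <- unique(pathways[[pw]])
    if (length(members) < minPathwaySize) return(NULL)
    d <- direction[match(members, feats)]
    inc <- sum(d == 1L); dec <- sum(d == -1L)
    data.frame(pathway = pw, n_measured = length(members),
               n_increased = inc, n_decreased = dec,
               da_score = (inc - dec) / length(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), n_measured = integer(0),
                      n_increased = integer(0), n_decreased = integer(0),
                      da_score = numeric(0))
  }
  if ("category" %in% names(annotation)) {
    out$category <- annotation$category[match(out$pathway, annotation$pathway)]
  }
  rownames(out) <- NULL
  attr(out, "metabolites") <- met_tab
  out
}

#' Lipid subclass log2 fold-change distributions
#'
#' Per lipid, a log2 fold change between the `positive` and reference
#' groups is computed either as the log2 ratio of group means (for
#' linear-scale abundances, the default) or as the difference of group
#' means (for log2-scale matrices). Fold changes are then summarized per
#' lipid subclass (median and interquartile range).
#'
#' @param mat numeric lipids x samples matrix.
#' @param groups per-sample group labels.
#' @param annotation data.frame with columns `feature`, `category`
#'   (FA/GL/GP/SP/ST), `main_class`.
#' @param positive label of the group of interest.
#' @param method `"ratio_of_means"` (linear-scale input) or
#'   `"difference_of_log_means"` (log2-scale input).
#' @return data.frame with one row per subclass: `main_class`, `category`,
#'   `n_lipids`, `median_log2fc`, `q25`, `q75`; attribute `lipids` holds
#'   per-lipid fold changes.
#' @export
lipidSubclassFc <- function(mat, groups, annotation, positive,
                            method = c("ratio_of_means",
                                       "difference_of_log_means")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  pos <- groups == positive
  if (!any(pos) || all(pos)) stop("'positive' must split the samples",
                                  call. = FALSE)
  feats <- intersect(rownames(mat), unique(annotation$feature))
  if (!length(feats)) stop("annotation matches no lipids", call. = FALSE)
  fc <- vapply(feats, function(f) {
    if (method == "ratio_of_means") {
      log2(mean(mat[f, pos]) / mean(mat[f, !pos]))
    } else {
      mean(mat[f, pos]) - mean(mat[f, !pos])
    }
  }, numeric(1))
  ann <- annotation[match(feats, annotation$feature), , drop = FALSE]
  lip_tab <- data.frame(feature = feats, main_class = ann$main_class,
                        category = ann$category, log2fc = fc,
                        row.names = NULL, stringsAsFactors = FALSE)
  empty <- setdiff(unique(annotation$main_class), unique(ann$main_class))
  if (length(empty)) {
    warning("subclass(es) with no measured lipids skipped: ",
            paste(empty, collapse = ", "))
  }
  rows <- lapply(split(lip_tab, lip_tab$main_class), function(d) {
    q <- stats::quantile(d$log2fc, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(main_class = d$main_class[1], category = d$category[1],
               n_lipids = nrow(d), median_log2fc = q[2], q25 = q[1],
               q75 = q[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lipids") <- lip_tab
  out
}
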