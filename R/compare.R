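# Cohort-level group contrasts and multiple-testing control.

#' Logistic contrast of a binary feature between two groups
#'
#' Fits a binomial-family logistic regression of the feature on group
#' membership (plus optional covariates) and reports the odds ratio for the
#' first contrast group versus the second with a Wald 95% CI. When the 2x2
#' feature-by-group table has a zero cell (or the fit fails), the function
#' falls back to Fisher's exact test and flags it in the `method` column.
#'
#' @param feature per-sample binary vector (logical or 0/1).
#' @param groups per-sample group labels.
#' @param contrast length-2 character vector `c(groupOfInterest,
#'   reference)`; samples outside the two groups are dropped. The reference
#'   may be `"rest"` to pool every other group.
#' @param covariates optional data.frame of per-sample adjustment
#'   covariates.
#' @return one-row data.frame: `contrast`, `estimate` (odds ratio),
#'   `ci_low`, `ci_high`, `p`, `method` (`"logistic"` or `"fisher"`), `n`.
#' @export
compareCategorical <- function(feature, groups, contrast, covariates = NULL) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least two groups",
                                        call. = FALSE)
  sel <- selectContrast(groups, contrast)
  y <- as.integer(feature[sel$idx])
  if (anyNA(y) || !all(y %in% 0:1)) stop("feature must be binary",
                                         call. = FALSE)
  if (sum(y) == 0 && sum(1 - y) == 0) stop("empty feature", call. = FALSE)
  g <- factor(sel$grp, levels = c(sel$ref, sel$pos))
  cov <- if (!is.null(covariates)) covariates[sel$idx, , drop = FALSE] else NULL

  tab <- table(g, y)
  zero_cell <- nrow(tab) < 2L || ncol(tab) < 2L || any(tab == 0)
  est <- ci <- c(NA_real_, NA_real_)
  method <- "logistic"
  pval <- NA_real_
  if (!zero_cell) {
    dat <- data.frame(.y = y, .g = g)
    if (!is.null(cov)) dat <- cbind(dat, cov)
    fit <- tryCatch(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(.y ~ ., data = dat,
                                    family = stats::binomial()))
      })
    co <- if (is.null(fit)) NULL else summary(fit)$coefficients
    row <- paste0(".g", sel$pos)
    if (!is.null(co) && row %in% rownames(co) && is.finite(co[row, 2]) &&
        co[row, 2] < 10) {
      b <- co[row, 1]; se <- co[row, 2]
      est <- exp(b)
      ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
      pval <- co[row, 4]
    } else {
      zero_cell <- TRUE  # separation or failed fit: fall back
    }
  }
  if (zero_cell) {
    method <- "fisher"
    tab2 <- table(factor(sel$grp, levels = c(sel$pos, sel$ref)),
                  factor(y, levels = c(1, 0)))
    ft <- stats::fisher.test(tab2)
    est <- unname(ft$estimate)
    ci <- ft$conf.int
    pval <- ft$p.value
  }
  data.frame(contrast = paste(sel$pos, "vs", sel$ref),
             estimate = unname(est[1]), ci_low = ci[1], ci_high = ci[2],
             p = pval, method = method, n = length(y),
             stringsAsFactors = FALSE)
}

selectContrast <- function(groups, contrast) {
  if (length(contrast) != 2L) stop("'contrast' must have two entries",
                                   call. = FALSE)
  pos <- contrast[1]
  ref <- contrast[2]
  if (identical(ref, "rest")) {
    idx <- seq_along(groups)
    grp <- ifelse(groups == pos, pos, "rest")
  } else {
    idx <- which(groups %in% contrast)
    grp <- groups[idx]
  }
  if (!any(grp == pos) || !any(grp == ref)) {
    stop("contrast group(s) absent from data", call. = FALSE)
  }
  list(idx = idx, grp = grp, pos = pos, ref = ref)
}

#' Gaussian-family contrast of a continuous feature between two groups
#'
#' Fits a linear (gaussian-family) model of the feature on group membership
#' plus optional covariates; the estimate is the adjusted mean difference
#' (group of interest minus reference) with a Wald 95% CI. A two-sided
#' Wilcoxon rank-sum p-value on the unadjusted feature is reported
#' alongside (`p_rank`).
#'
#' @inheritParams compareCategorical
#' @param feature per-sample numeric vector.
#' @return one-row data.frame: `contrast`, `estimate` (mean difference),
#'   `ci_low`, `ci_high`, `p` (model Wald), `p_rank` (Wilcoxon), `n`.
#' @export
compareContinuous <- function(feature, groups, contrast, covariates = NULL) {
  groups <- as.character(groups)
  sel <- selectContrast(groups, contrast)
  y <- as.numeric(feature[sel$idx])
  g <- factor(sel$grp, levels = c(sel$ref, sel$pos))
  if (min(table(g)) < 2L) stop("each group needs at least two samples",
                               call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("constant feature; returning null contrast")
    return(data.frame(contrast = paste(sel$pos, "vs", sel$ref), estimate = 0,
                      ci_low = 0, ci_high = 0, p = 1, p_rank = 1,
                      n = length(y), stringsAsFactors = FALSE))
  }
  dat <- data.frame(.y = y, .g = g)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[sel$idx, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  co <- summary(fit)$coefficients
  row <- paste0(".g", sel$pos)
  b <- co[row, 1]; se <- co[row, 2]
  p_rank <- stats::wilcox.test(y[g == sel$pos], y[g == sel$ref],
                               exact = FALSE)$p.value
  data.frame(contrast = paste(sel$pos, "vs", sel$ref), estimate = b,
             ci_low = b - stats::qnorm(0.975) * se,
             ci_high = b + stats::qnorm(0.975) * se,
             p = co[row, 4], p_rank = p_rank, n = length(y),
             stringsAsFactors = FALSE)
}

#' Per-gene, per-group event frequencies with pairwise contrasts
#'
#' Computes the fraction of samples carrying each event (mutation or
#' GISTIC-derived) within every group, then runs [compareCategorical()] per
#' gene for each requested contrast, controlling the FDR across genes
#' within each contrast by Benjamini-Hochberg.
#'
#' @param events logical/binary gene x sample matrix (e.g. from
#'   [mutationEventMatrix()] or [gisticEventMatrix()]).
#' @param groups per-sample group labels aligned with the columns.
#' @param contrasts list of length-2 character vectors; the default is the
#'   primary comparisons of the study design: high suspicion vs probably
#'   benign and high suspicion vs calcification-negative.
#' @param covariates optional per-sample covariate data.frame.
#' @return list with elements `frequencies` (gene x group fraction matrix)
#'   and `contrasts` (tidy data.frame with `gene`, `contrast`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `fdr`, `method`).
#' @export
featureFrequencyTable <- function(events, groups,
                                  contrasts = list(
                                    c("high_suspicion", "probably_benign"),
                                    c("high_suspicion", "negative")),
                                  covariates = NULL) {
  groups <- as.character(groups)
  if (length(groups) != ncol(events)) {
    stop("'groups' must label every sample column", call. = FALSE)
  }
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  lv <- unique(groups)
  freq <- t(apply(events, 1, function(e) {
    tapply(as.numeric(e), factor(groups, levels = lv), mean)
  }))
  colnames(freq) <- lv

  rows <- list()
  for (ct in contrasts) {
    per_gene <- lapply(rownames(events), function(g) {
      res <- compareCategorical(as.numeric(events[g, ]), groups, ct,
                                covariates = covariates)
      cbind(gene = g, res)
    })
    tab <- do.call(rbind, per_gene)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    rows[[length(rows) + 1L]] <- tab
  }
  contrasts_tab <- do.call(rbind, rows)
  rownames(contrasts_tab) <- NULL
  list(frequencies = freq, contrasts = contrasts_tab)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with input validation; a thin, named wrapper
#' around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, each >= the raw value's BH bound).
#' @export
adjustFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
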