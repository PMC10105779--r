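#' Adjusted Cox proportional-hazards contrast
#'
#' Fits a multivariate Cox model of the chosen endpoint (overall survival,
#' distant metastasis-free survival or relapse-free survival) on the group
#' contrast plus adjustment covariates, and reports the adjusted hazard
#' ratio with Wald 95% CI. The default covariate set (age, tumor size
#' category, nodal status) is recorded in the output so every run is
#' self-describing.
#'
#' @param cohort cohort table with columns `sample`, `calc_group`,
#'   `<endpoint>_time` (months) and `<endpoint>_event`, plus covariates.
#' @param endpoint one of `"os"`, `"dmfs"`, `"rfs"`.
#' @param contrast length-2 character vector `c(groupOfInterest,
#'   reference)`; `"rest"` pools all other groups as reference.
#' @param covariates column names to adjust for (default `age`,
#'   `tumor_size`, `nodal_status`; only those present are used).
#' @param minEvents minimum number of events required (default 10).
#' @return one-row data.frame: `endpoint`, `contrast`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_events`, `covariates`, `converged`.
#' @export
coxHazard <- function(cohort, endpoint = c("os", "dmfs", "rfs"), contrast,
                      covariates = c("age", "tumor_size", "nodal_status"),
                      minEvents = 10) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  miss <- setdiff(c(tcol, ecol, "calc_group"), names(cohort))
  if (length(miss)) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sel <- selectContrast(as.character(cohort$calc_group), contrast)
  dat <- cohort[sel$idx, , drop = FALSE]
  dat$.g <- factor(sel$grp, levels = c(sel$ref, sel$pos))
  n_events <- sum(dat[[ecol]])
  if (n_events == 0) stop("no events for endpoint ", endpoint, call. = FALSE)
  if (n_events < minEvents) {
    stop(sprintf("only %d events for endpoint %s (minimum %d)", n_events,
                 endpoint, minEvents), call. = FALSE)
  }
  covariates <- intersect(covariates, names(dat))
  fmla <- stats::reformulate(c(".g", covariates),
                             response = sprintf("survival::Surv(%s, %s)",
                                                tcol, ecol))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fmla, data = dat),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  row <- paste0(".g", sel$pos)
  b <- co[row, "coef"]; se <- co[row, "se(coef)"]
  data.frame(endpoint = endpoint, contrast = paste(sel$pos, "vs", sel$ref),
             hr = exp(b),
             ci_low = exp(b - stats::qnorm(0.975) * se),
             ci_high = exp(b + stats::qnorm(0.975) * se),
             p = co[row, "Pr(>|z|)"], n = nrow(dat), n_events = n_events,
             covariates = paste(covariates, collapse = "+"),
             converged = converged, stringsAsFactors = FALSE)
}
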