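# End-to-end orchestration: simulate (optional) -> scars -> immune scores ->
# metabolome -> frequency contrasts -> survival, with tidy TSV outputs and a
# run manifest.

pipelineStage <- function(name, expr, log) {
  t0 <- Sys.time()
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %s: done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full calcification-contrast pipeline
#'
#' Executes every stage on a synthetic or user-supplied cohort and writes
#' tidy result tables plus a manifest. The configuration is a list (or a
#' YAML file path) with either a `simulate` block of [cohortSpec()]
#' arguments, or file paths (`cohort`, `maf`, `segments`, `expression`,
#' `metabolites`, `metabolites_normal`, `lipids`, `metabolite_annotation`,
#' `lipid_annotation`). Optional fields: `contrast` (default
#' `c("high_suspicion", "rest")`), `covariates` for the Cox models, `seed`.
#'
#' Stages that lack their input layer are skipped, with an explicit note in
#' the manifest. Outputs: `scars.tsv`, `immune_scores.tsv`, `da_scores.tsv`,
#' `lipid_subclass_fc.tsv`, `frequencies.tsv`, `survival.tsv`,
#' `manifest.json`.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory.
#' @param quiet suppress progress messages (default `FALSE`).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  contrast <- if (!is.null(config$contrast)) {
    unlist(config$contrast)
  } else {
    c("high_suspicion", "rest")
  }

  skipped <- character(0)
  results <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    cohort_obj <- pipelineStage("simulate", {
      generateCohort(do.call(cohortSpec, sim_args))
    }, log)
    ct <- cohortTable(cohort_obj)
    muts <- mutations(cohort_obj)
    segs <- segments(cohort_obj)
    expr <- expressionMatrix(cohort_obj)
    met <- metaboliteMatrix(cohort_obj)
    met_norm <- metaboliteMatrix(cohort_obj, normal = TRUE)
    lip <- lipidMatrix(cohort_obj)
    met_ann <- metaboliteAnnotation(cohort_obj)
    lip_ann <- lipidAnnotation(cohort_obj)
    imm_genes <- immuneGenes(cohort_obj)
  } else {
    ct <- pipelineStage("read_cohort", readCohort(config$cohort), log)
    muts <- if (!is.null(config$maf)) readMaf(config$maf) else NULL
    segs <- if (!is.null(config$segments)) readSegments(config$segments) else NULL
    expr <- if (!is.null(config$expression)) readMatrixTsv(config$expression) else NULL
    met <- if (!is.null(config$metabolites)) readMatrixTsv(config$metabolites) else NULL
    met_norm <- if (!is.null(config$metabolites_normal)) {
      readMatrixTsv(config$metabolites_normal)
    } else NULL
    lip <- if (!is.null(config$lipids)) readMatrixTsv(config$lipids) else NULL
    met_ann <- if (!is.null(config$metabolite_annotation)) {
      utils::read.delim(config$metabolite_annotation, stringsAsFactors = FALSE)
    } else NULL
    lip_ann <- if (!is.null(config$lipid_annotation)) {
      utils::read.delim(config$lipid_annotation, stringsAsFactors = FALSE)
    } else NULL
    imm_genes <- if (!is.null(config$immune_genes)) {
      unlist(config$immune_genes)
    } else NULL
  }
  build <- syntheticGenomeBuild()
  grp <- stats::setNames(ct$calc_group, ct$sample)

  ## scars + TMB
  if (!is.null(segs) && nrow(segs)) {
    scars <- pipelineStage("scars", computeHrd(segs, build), log)
    if (!is.null(muts)) {
      tmb <- computeTmb(muts)
      scars <- merge(scars, tmb, by = "sample", all = TRUE)
    }
    utils::write.table(scars, file.path(outDir, "scars.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$scars <- scars
  } else {
    skipped <- c(skipped, "scars: no segment layer")
  }

  ## immune scoring
  if (!is.null(expr) && !is.null(imm_genes) &&
      length(intersect(imm_genes, rownames(expr)))) {
    imm <- pipelineStage("immune", {
      score <- signatureScore(expr, imm_genes)
      data.frame(sample = names(score), signature = "immune_signature",
                 score = unname(score), stringsAsFactors = FALSE)
    }, log)
    utils::write.table(imm, file.path(outDir, "immune_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$immune <- imm
    imm_test <- compareContinuous(
      stats::setNames(imm$score, imm$sample)[ct$sample],
      ct$calc_group, contrast)
    results$immune_contrast <- imm_test
  } else {
    skipped <- c(skipped, "immune: no expression layer or immune gene set")
  }

  ## metabolome DA
  if (!is.null(met) && !is.null(met_ann)) {
    da <- pipelineStage("metabolome", {
      msub <- met[, colnames(met) %in% ct$sample, drop = FALSE]
      daScore(msub, grp[colnames(msub)], met_ann, positive = contrast[1])
    }, log)
    utils::write.table(da, file.path(outDir, "da_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$da <- da
  } else {
    skipped <- c(skipped, "metabolome: no metabolite layer or annotation")
  }

  ## lipid subclasses
  if (!is.null(lip) && !is.null(lip_ann)) {
    lfc <- pipelineStage("lipids", {
      lsub <- lip[, colnames(lip) %in% ct$sample, drop = FALSE]
      lipidSubclassFc(lsub, grp[colnames(lsub)], lip_ann,
                      positive = contrast[1],
                      method = "difference_of_log_means")
    }, log)
    utils::write.table(lfc, file.path(outDir, "lipid_subclass_fc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$lipid_fc <- lfc
  } else {
    skipped <- c(skipped, "lipids: no lipid layer or annotation")
  }

  ## mutation frequency contrasts
  if (!is.null(muts) && nrow(muts)) {
    freq <- pipelineStage("frequencies", {
      ev <- mutationEventMatrix(muts, samples = ct$sample)
      common <- rowMeans(ev) >= 0.05  # genes mutated in >= 5% of samples
      if (!any(common)) {
        common <- rank(-rowMeans(ev), ties.method = "first") <= 10
      }
      featureFrequencyTable(ev[common, , drop = FALSE], ct$calc_group,
                            contrasts = list(contrast))
    }, log)
    utils::write.table(freq$contrasts, file.path(outDir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$frequencies <- freq
  } else {
    skipped <- c(skipped, "frequencies: no mutation layer")
  }

  ## survival
  if (all(c("os_time", "os_event") %in% names(ct))) {
    surv <- pipelineStage("survival", {
      rows <- lapply(c("os", "dmfs", "rfs"), function(ep) {
        tryCatch(coxHazard(ct, ep, contrast,
                           covariates = unlist(config$covariates %||%
                                                 c("age", "tumor_size",
                                                   "nodal_status"))),
                 error = function(e) NULL)
      })
      do.call(rbind, rows)
    }, log)
    if (is.null(surv)) {
      skipped <- c(skipped, "survival: no endpoint had enough events")
    } else {
      utils::write.table(surv, file.path(outDir, "survival.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      results$survival <- surv
    }
  } else {
    skipped <- c(skipped, "survival: no follow-up columns")
  }

  manifest <- list(
    seed = seed,
    contrast = contrast,
    n_samples = nrow(ct),
    stages_skipped = as.list(skipped),
    config_hash = digestConfig(config),
    package_version = as.character(utils::packageVersion("calcomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of the configuration list (order-normalized JSON, summed
# byte-wise); good enough to detect config drift between runs.
digestConfig <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(bytes * seq_along(bytes)) %% 4294967291)
}
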