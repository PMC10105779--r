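# Synthetic multi-omics cohort generator. Every layer carries planted,
# parameterized group effects so downstream estimators can be checked
# against known truth.

#' Specification of a synthetic calcification cohort
#'
#' Collects every knob of the generator and validates it. Per-group
#' arguments accept a scalar (recycled to all four groups) or a vector
#' named by [calcGroups()]. Defaults emulate the study conditions: a
#' 312-sample cohort, ~56 somatic mutations per sample, an elevated PIK3CA
#' mutation frequency (29.6% vs ~16%) in the high-suspicion group, a -1 SD
#' immune-signature shift and a +1.5 log2 lipid-pathway shift in the
#' high-suspicion group, and a hazard ratio of 2 for overall survival.
#'
#' @param nSamples cohort size (>= 1).
#' @param groupProportions named fractions over the four groups, summing
#'   to 1.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec including the seed.
#' @param mutationRate expected somatic mutations per sample, per group.
#' @param pik3caFreq per-group probability of a PIK3CA driver mutation.
#' @param scarNtai,scarLoh,scarLst per-group expected counts of planted
#'   telomeric-imbalance, LOH and state-transition events.
#' @param hlaLohFreq per-group probability of HLA class I LOH.
#' @param immuneShift per-group additive shift (in SD units) on immune
#'   signature genes (log2 expression scale).
#' @param lipidShift per-group additive log2 shift on lipid-pathway
#'   metabolites and dysregulated lipid subclasses.
#' @param hazardRatio per-group multiplicative hazard versus baseline.
#' @param censorRate fraction of samples administratively censored.
#' @param baselineHazard exponential baseline hazard per month.
#' @param nGenes,nImmuneGenes,nMetabolites,nLipids layer sizes.
#' @param genePanelSize number of gene symbols background mutations are
#'   scattered over.
#' @param missingness named per-layer fractions of samples to drop from a
#'   layer (default all 0).
#' @return a validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(nSamples = 312,
                       groupProportions = c(negative = 0.55,
                                            probably_benign = 0.22,
                                            low_moderate = 0.08,
                                            high_suspicion = 0.15),
                       seed = 1L,
                       mutationRate = 56,
                       pik3caFreq = c(negative = 0.156,
                                      probably_benign = 0.163,
                                      low_moderate = 0.163,
                                      high_suspicion = 0.296),
                       scarNtai = 3, scarLoh = 3, scarLst = 2,
                       hlaLohFreq = 0.15,
                       immuneShift = c(negative = 0, probably_benign = 0,
                                       low_moderate = 0,
                                       high_suspicion = -1),
                       lipidShift = c(negative = 0, probably_benign = 0,
                                      low_moderate = 0,
                                      high_suspicion = 1.5),
                       hazardRatio = c(negative = 1, probably_benign = 1,
                                       low_moderate = 1,
                                       high_suspicion = 2),
                       censorRate = 0.3,
                       baselineHazard = 0.006,
                       nGenes = 1000, nImmuneGenes = 50,
                       nMetabolites = 300, nLipids = 200,
                       genePanelSize = 2000,
                       missingness = c(mutations = 0, segments = 0,
                                       expression = 0, metabolites = 0,
                                       lipids = 0)) {
  if (!is.numeric(nSamples) || nSamples < 1) {
    stop("'nSamples' must be >= 1", call. = FALSE)
  }
  gp <- perGroup(groupProportions, "groupProportions")
  if (abs(sum(gp) - 1) > 1e-9) {
    stop("'groupProportions' must sum to 1", call. = FALSE)
  }
  stopifnotProb(gp, "groupProportions")
  spec <- list(
    nSamples = as.integer(nSamples),
    groupProportions = gp,
    seed = as.integer(seed),
    mutationRate = perGroup(mutationRate, "mutationRate"),
    pik3caFreq = perGroup(pik3caFreq, "pik3caFreq"),
    scarNtai = perGroup(scarNtai, "scarNtai"),
    scarLoh = perGroup(scarLoh, "scarLoh"),
    scarLst = perGroup(scarLst, "scarLst"),
    hlaLohFreq = perGroup(hlaLohFreq, "hlaLohFreq"),
    immuneShift = perGroup(immuneShift, "immuneShift"),
    lipidShift = perGroup(lipidShift, "lipidShift"),
    hazardRatio = perGroup(hazardRatio, "hazardRatio"),
    censorRate = as.numeric(censorRate),
    baselineHazard = as.numeric(baselineHazard),
    nGenes = as.integer(nGenes),
    nImmuneGenes = as.integer(nImmuneGenes),
    nMetabolites = as.integer(nMetabolites),
    nLipids = as.integer(nLipids),
    genePanelSize = as.integer(genePanelSize),
    missingness = missingness
  )
  stopifnotProb(spec$pik3caFreq, "pik3caFreq")
  stopifnotProb(spec$hlaLohFreq, "hlaLohFreq")
  stopifnotProb(spec$censorRate, "censorRate")
  if (any(spec$hazardRatio <= 0)) stop("hazard ratios must be > 0",
                                       call. = FALSE)
  class(spec) <- "CohortSpec"
  spec
}

#' Generate survival endpoints with planted hazard differences
#'
#' Event times are exponential with a per-group multiplicative hazard over
#' a fixed baseline; relapse and distant-metastasis latencies are drawn so
#' that RFS time never exceeds OS time. Censoring is uniform
#' administrative: a common censoring horizon is calibrated so the expected
#' censored fraction matches `censorRate`.
#'
#' @param cohort data.frame with columns `sample` and `calc_group`.
#' @param hazardRatio per-group multiplicative hazard (scalar or named).
#' @param censorRate target censored fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param baselineHazard exponential baseline hazard per month
#'   (default 0.006).
#' @return `cohort` with columns `os_time`, `os_event`, `dmfs_time`,
#'   `dmfs_event`, `rfs_time`, `rfs_event` added (times in months).
#' @export
generateSurvival <- function(cohort, hazardRatio, censorRate, seed = 1L,
                             baselineHazard = 0.006) {
  if (!is.numeric(censorRate) || censorRate < 0 || censorRate > 1) {
    stop("'censorRate' must lie in [0, 1]", call. = FALSE)
  }
  hr <- perGroup(hazardRatio, "hazardRatio")
  set.seed(seed)
  n <- nrow(cohort)
  lam <- baselineHazard * unname(hr[cohort$calc_group])
  t_death <- stats::rexp(n, rate = lam)
  # relapse/distant metastasis occur before death for a subset of samples
  t_rel <- ifelse(stats::runif(n) < 0.7, stats::runif(n) * t_death, t_death)
  t_dm <- ifelse(stats::runif(n) < 0.6, stats::runif(n) * t_death, t_death)

  if (censorRate >= 1) {
    horizon <- 0
    cens <- rep(0, n)
  } else if (censorRate <= 0) {
    cens <- rep(Inf, n)
  } else {
    # P(C < T) for C ~ U(0, tau), T ~ Exp(lambda) is (1 - e^(-l tau))/(l tau);
    # calibrate tau against the cohort-average hazard.
    lbar <- mean(lam)
    f <- function(tau) (1 - exp(-lbar * tau)) / (lbar * tau) - censorRate
    tau <- tryCatch(stats::uniroot(f, c(1e-6, 1e6))$root,
                    error = function(e) 1 / (lbar * censorRate))
    cens <- stats::runif(n, 0, tau)
  }
  os_time <- pmin(t_death, cens)
  os_event <- as.integer(t_death <= cens)
  rfs_raw <- pmin(t_rel, t_death)
  dmfs_raw <- t_dm
  cohort$os_time <- os_time
  cohort$os_event <- os_event
  cohort$dmfs_time <- pmin(dmfs_raw, cens)
  cohort$dmfs_event <- as.integer(dmfs_raw <= cens)
  cohort$rfs_time <- pmin(rfs_raw, cens)
  cohort$rfs_event <- as.integer(rfs_raw <= cens)
  cohort
}

# Carve an interval with a new allele state out of a per-chromosome segment
# list, keeping segments disjoint and sorted.
carveSegment <- function(segs, start, end, nMajor, nMinor) {
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$end < start || s$start > end) {
      out[[length(out) + 1L]] <- s
      next
    }
    if (s$start < start) {
      left <- s; left$end <- start - 1
      out[[length(out) + 1L]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end + 1
      out[[length(out) + 1L]] <- right
    }
  }
  new_seg <- segs[1, ]
  new_seg$start <- start; new_seg$end <- end
  new_seg$nMajor <- nMajor; new_seg$nMinor <- nMinor
  out[[length(out) + 1L]] <- new_seg
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Generate a full synthetic multi-omics cohort
#'
#' Draws group labels, clinical covariates and survival endpoints, then
#' builds every omics layer with the planted effects of the spec:
#' mutation catalogs (with group-specific PIK3CA frequency and a
#' trinucleotide context for every SNV), allele-specific copy-number
#' segments carrying planted telomeric imbalance, LOH runs, state
#' transitions and HLA LOH, log2 expression with the immune-signature
#' shift, and metabolite/lipid matrices (with paired normals) carrying the
#' lipid-pathway shift. All planted parameters are recorded in the `truth`
#' slot.
#'
#' @param spec a [cohortSpec()].
#' @return a [CalcCohort-class] object.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n <- spec$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  groups <- sample(CALC_GROUPS, n, replace = TRUE,
                   prob = spec$groupProportions)

  cohort <- data.frame(
    sample = ids,
    calc_group = groups,
    age = pmin(80, pmax(25, round(stats::rnorm(n, 50, 10)))),
    tumor_size = sample(c("T1", "T2", "T3"), n, replace = TRUE,
                        prob = c(0.40, 0.45, 0.15)),
    nodal_status = sample(c("N0", "Npos"), n, replace = TRUE,
                          prob = c(0.55, 0.45)),
    architectural_distortion = stats::rbinom(
      n, 1, ifelse(groups == "high_suspicion", 0.30, 0.12)),
    stringsAsFactors = FALSE
  )
  cohort <- generateSurvival(cohort, spec$hazardRatio, spec$censorRate,
                             seed = childSeed(spec$seed, 1L),
                             baselineHazard = spec$baselineHazard)

  build <- syntheticGenomeBuild()
  chroms <- chromNames(build)
  chrom_len <- unname(chromLengths(build))

  ## --- mutations -----------------------------------------------------
  set.seed(childSeed(spec$seed, 2L))
  gene_panel <- sprintf("GENE%04d", seq_len(spec$genePanelSize))
  class_probs <- c(missense = 0.60, nonsense = 0.05, nonstop = 0.01,
                   splice_site = 0.05, translation_start_site = 0.01,
                   in_frame_indel = 0.03, frameshift_indel = 0.06,
                   silent = 0.19)
  pik3ca_hit <- stats::rbinom(n, 1, spec$pik3caFreq[groups]) == 1L
  mut_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- stats::rpois(1, spec$mutationRate[groups[i]])
    if (m == 0 && !pik3ca_hit[i]) next
    df <- NULL
    if (m > 0) {
      cls <- sample(names(class_probs), m, replace = TRUE, prob = class_probs)
      chrom_i <- sample(chroms, m, replace = TRUE)
      pos <- floor(stats::runif(m) * chrom_len[match(chrom_i, chroms)]) + 1
      is_indel <- cls %in% c("in_frame_indel", "frameshift_indel")
      ref <- sample(BASES, m, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
      alt[is_indel] <- "-"
      ctx <- paste0(sample(BASES, m, replace = TRUE), ref,
                    sample(BASES, m, replace = TRUE))
      ctx[is_indel] <- NA_character_
      df <- data.frame(sample = ids[i],
                       gene = sample(gene_panel, m, replace = TRUE),
                       chrom = chrom_i, pos = pos, ref = ref, alt = alt,
                       classification = cls, context = ctx,
                       stringsAsFactors = FALSE)
    }
    if (pik3ca_hit[i]) {
      ref1 <- sample(BASES, 1)
      alt1 <- sample(setdiff(BASES, ref1), 1)
      df <- rbind(df, data.frame(
        sample = ids[i], gene = "PIK3CA", chrom = "3",
        pos = floor(stats::runif(1) * chrom_len[3]) + 1, ref = ref1,
        alt = alt1, classification = "missense",
        context = paste0(sample(BASES, 1), ref1, sample(BASES, 1)),
        stringsAsFactors = FALSE))
    }
    mut_rows[[i]] <- df
  }
  mutations <- do.call(rbind, mut_rows)
  rownames(mutations) <- NULL
  mutations$nonsynonymous <- mutations$classification %in% NONSYN_CLASSES

  ## --- allele-specific segments with planted scars --------------------
  set.seed(childSeed(spec$seed, 3L))
  hla <- syntheticHlaLoci()
  hla_loh <- stats::rbinom(n, 1, spec$hlaLohFreq[groups]) == 1L
  planted <- data.frame(sample = ids, ntai_events = 0L, loh_events = 0L,
                        lst_events = 0L, stringsAsFactors = FALSE)
  seg_rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_chrom <- lapply(seq_along(chroms), function(ci) {
      data.frame(sample = ids[i], chrom = chroms[ci], start = 1,
                 end = chrom_len[ci], nMajor = 1, nMinor = 1,
                 stringsAsFactors = FALSE)
    })
    names(per_chrom) <- chroms
    n_tai <- stats::rpois(1, spec$scarNtai[groups[i]])
    for (k in seq_len(n_tai)) {
      ci <- sample(chroms, 1)
      L <- chrom_len[match(ci, chroms)]
      len <- stats::runif(1, 12e6, 40e6)
      if (stats::runif(1) < 0.5) {
        per_chrom[[ci]] <- carveSegment(per_chrom[[ci]], 1, floor(len), 2, 1)
      } else {
        per_chrom[[ci]] <- carveSegment(per_chrom[[ci]], L - floor(len) + 1,
                                        L, 2, 1)
      }
    }
    n_loh <- stats::rpois(1, spec$scarLoh[groups[i]])
    for (k in seq_len(n_loh)) {
      ci <- sample(chroms, 1)
      L <- chrom_len[match(ci, chroms)]
      len <- floor(stats::runif(1, 16e6, 44e6))
      start <- floor(stats::runif(1, 2e6, L - 2e6 - len))
      per_chrom[[ci]] <- carveSegment(per_chrom[[ci]], start,
                                      start + len - 1, 1, 0)
    }
    n_lst <- stats::rpois(1, spec$scarLst[groups[i]])
    for (k in seq_len(n_lst)) {
      ci <- sample(chroms, 1)
      L <- chrom_len[match(ci, chroms)]
      len <- floor(stats::runif(1, 12e6, 30e6))
      start <- floor(stats::runif(1, 11e6, L - 11e6 - len))
      per_chrom[[ci]] <- carveSegment(per_chrom[[ci]], start,
                                      start + len - 1, 2, 2)
    }
    if (hla_loh[i]) {
      per_chrom[["6"]] <- carveSegment(per_chrom[["6"]], 29.0e6, 32.0e6, 1, 0)
    }
    planted$ntai_events[i] <- n_tai
    planted$loh_events[i] <- n_loh
    planted$lst_events[i] <- n_lst
    seg_rows[[i]] <- do.call(rbind, per_chrom)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  segments <- canonicalizeSegments(segments)

  ## --- HLA genotypes ---------------------------------------------------
  set.seed(childSeed(spec$seed, 4L))
  allele_pool <- list(
    "HLA-A" = sprintf("A*%02d:01", c(1, 2, 3, 11, 24, 33)),
    "HLA-B" = sprintf("B*%02d:01", c(7, 8, 15, 35, 44, 58)),
    "HLA-C" = sprintf("C*%02d:01", c(1, 3, 4, 7, 8, 12)))
  geno_rows <- lapply(ids, function(id) {
    do.call(rbind, lapply(names(allele_pool), function(loc) {
      a1 <- sample(allele_pool[[loc]], 1)
      a2 <- if (stats::runif(1) < 0.12) a1 else sample(allele_pool[[loc]], 1)
      data.frame(sample = id, locus = loc, allele1 = a1, allele2 = a2,
                 stringsAsFactors = FALSE)
    }))
  })
  hla_genotypes <- do.call(rbind, geno_rows)

  ## --- expression ------------------------------------------------------
  set.seed(childSeed(spec$seed, 5L))
  checkpoint_genes <- c("PDCD1", "CD274", "CTLA4", "LAG3")
  imm_genes <- c(sprintf("IMM%03d", seq_len(spec$nImmuneGenes)),
                 checkpoint_genes)
  n_filler <- max(0L, spec$nGenes - length(imm_genes))
  genes <- c(imm_genes, sprintf("EXP%04d", seq_len(n_filler)))
  mu_g <- stats::rnorm(length(genes), 8, 2)
  expr <- matrix(stats::rnorm(length(genes) * n, mu_g, 1),
                 nrow = length(genes), dimnames = list(genes, ids))
  shift <- spec$immuneShift[groups]
  expr[imm_genes, ] <- expr[imm_genes, ] +
    matrix(shift, length(imm_genes), n, byrow = TRUE)

  ## --- metabolites ------------------------------------------------------
  set.seed(childSeed(spec$seed, 6L))
  lipid_pathways <- c("Fatty acid metabolism", "Glycerolipid metabolism",
                      "Sphingolipid metabolism",
                      "Glycerophospholipid metabolism")
  other_pathways <- c("Glycolysis / Gluconeogenesis", "Citrate cycle",
                      "Purine metabolism", "Pyrimidine metabolism",
                      "Alanine, aspartate and glutamate metabolism",
                      "Arginine biosynthesis", "Pentose phosphate pathway",
                      "Glutathione metabolism")
  pw_names <- c(lipid_pathways, other_pathways)
  per_pw <- ceiling(spec$nMetabolites / length(pw_names))
  met_ann <- data.frame(
    feature = sprintf("MET%04d", seq_len(spec$nMetabolites)),
    pathway = rep(pw_names, each = per_pw)[seq_len(spec$nMetabolites)],
    stringsAsFactors = FALSE)
  met_ann$category <- ifelse(met_ann$pathway %in% lipid_pathways,
                             "lipid_metabolism", "other")
  mu_m <- stats::rnorm(spec$nMetabolites, 20, 2)
  met <- matrix(stats::rnorm(spec$nMetabolites * n, mu_m, 1),
                nrow = spec$nMetabolites,
                dimnames = list(met_ann$feature, ids))
  lip_shift <- spec$lipidShift[groups]
  lipid_rows <- met_ann$category == "lipid_metabolism"
  met[lipid_rows, ] <- met[lipid_rows, ] +
    matrix(lip_shift, sum(lipid_rows), n, byrow = TRUE)
  # paired normals: ~40% of metabolites carry a planted tumor-normal offset
  tn_diff <- ifelse(stats::runif(spec$nMetabolites) < 0.4,
                    sample(c(-1, 1), spec$nMetabolites, replace = TRUE) *
                      stats::runif(spec$nMetabolites, 1.2, 3), 0)
  met_norm <- matrix(stats::rnorm(spec$nMetabolites * n, mu_m - tn_diff, 1),
                     nrow = spec$nMetabolites,
                     dimnames = list(met_ann$feature, ids))

  ## --- lipids -----------------------------------------------------------
  set.seed(childSeed(spec$seed, 7L))
  lipid_classes <- data.frame(
    category = c("FA", "FA", "GL", "GP", "SP", "SP", "ST"),
    main_class = c("fatty acids", "fatty esters", "triradylglycerols",
                   "glycerophosphocholines", "ceramides",
                   "neutral glycosphingolipids", "sterols"),
    stringsAsFactors = FALSE)
  shifted_classes <- c("fatty acids", "fatty esters", "triradylglycerols",
                       "ceramides", "neutral glycosphingolipids")
  cls_idx <- sample(seq_len(nrow(lipid_classes)), spec$nLipids,
                    replace = TRUE)
  lip_ann <- data.frame(feature = sprintf("LIP%04d", seq_len(spec$nLipids)),
                        category = lipid_classes$category[cls_idx],
                        main_class = lipid_classes$main_class[cls_idx],
                        stringsAsFactors = FALSE)
  mu_l <- stats::rnorm(spec$nLipids, 18, 2)
  lip <- matrix(stats::rnorm(spec$nLipids * n, mu_l, 1),
                nrow = spec$nLipids, dimnames = list(lip_ann$feature, ids))
  shifted_rows <- lip_ann$main_class %in% shifted_classes
  lip[shifted_rows, ] <- lip[shifted_rows, ] +
    matrix(lip_shift, sum(shifted_rows), n, byrow = TRUE)
  tn_diff_l <- ifelse(stats::runif(spec$nLipids) < 0.4,
                      sample(c(-1, 1), spec$nLipids, replace = TRUE) *
                        stats::runif(spec$nLipids, 1.2, 3), 0)
  lip_norm <- matrix(stats::rnorm(spec$nLipids * n, mu_l - tn_diff_l, 1),
                     nrow = spec$nLipids, dimnames = list(lip_ann$feature, ids))

  ## --- per-layer missingness -------------------------------------------
  set.seed(childSeed(spec$seed, 8L))
  dropLayer <- function(frac) {
    if (frac <= 0) return(character(0))
    sample(ids, floor(frac * n))
  }
  mi <- spec$missingness
  getm <- function(nm) if (nm %in% names(mi)) mi[[nm]] else 0
  drop_mut <- dropLayer(getm("mutations"))
  drop_seg <- dropLayer(getm("segments"))
  drop_expr <- dropLayer(getm("expression"))
  drop_met <- dropLayer(getm("metabolites"))
  drop_lip <- dropLayer(getm("lipids"))
  if (length(drop_mut)) mutations <- mutations[!mutations$sample %in% drop_mut, ]
  if (length(drop_seg)) segments <- segments[!segments$sample %in% drop_seg, ]
  if (length(drop_expr)) expr <- expr[, !colnames(expr) %in% drop_expr]
  if (length(drop_met)) {
    met <- met[, !colnames(met) %in% drop_met]
    met_norm <- met_norm[, !colnames(met_norm) %in% drop_met]
  }
  if (length(drop_lip)) {
    lip <- lip[, !colnames(lip) %in% drop_lip]
    lip_norm <- lip_norm[, !colnames(lip_norm) %in% drop_lip]
  }

  truth <- list(
    spec = spec,
    group = stats::setNames(groups, ids),
    pik3ca = stats::setNames(pik3ca_hit, ids),
    hla_loh = stats::setNames(hla_loh, ids),
    planted_scars = planted,
    immune_shift = stats::setNames(unname(spec$immuneShift[groups]), ids),
    lipid_shift = stats::setNames(unname(lip_shift), ids),
    immune_genes = imm_genes,
    shifted_lipid_classes = shifted_classes,
    tumor_normal_offset = stats::setNames(tn_diff, met_ann$feature)
  )

  new("CalcCohort",
      cohortTable = cohort,
      mutations = mutations,
      segments = segments,
      hlaGenotypes = hla_genotypes,
      expression = expr,
      metabolites = met,
      metabolitesNormal = met_norm,
      lipids = lip,
      lipidsNormal = lip_norm,
      metaboliteAnnotation = met_ann,
      lipidAnnotation = lip_ann,
      immuneGenes = imm_genes,
      truth = truth)
}

#' Write every cohort layer to disk
#'
#' Writes the cohort table, MAF-like mutation table, segment table,
#' matrices and annotation sidecars as TSV (1-based inclusive coordinates,
#' stated in each header) plus a `truth.json` with the planted parameters.
#'
#' @param cohort a [CalcCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeCohortLayers <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(dir, "cohort.tsv"),
    maf = file.path(dir, "mutations.maf.tsv"),
    segments = file.path(dir, "segments.tsv"),
    expression = file.path(dir, "expression.tsv"),
    metabolites = file.path(dir, "metabolites.tsv"),
    metabolites_normal = file.path(dir, "metabolites_normal.tsv"),
    lipids = file.path(dir, "lipids.tsv"),
    lipids_normal = file.path(dir, "lipids_normal.tsv"),
    metabolite_annotation = file.path(dir, "metabolite_annotation.tsv"),
    lipid_annotation = file.path(dir, "lipid_annotation.tsv"),
    truth = file.path(dir, "truth.json"))
  writeCohort(cohortTable(cohort), paths["cohort"])
  writeMaf(mutations(cohort), paths["maf"])
  writeSegments(segments(cohort), paths["segments"])
  writeMatrixTsv(expressionMatrix(cohort), paths["expression"], "gene")
  writeMatrixTsv(metaboliteMatrix(cohort), paths["metabolites"], "metabolite")
  writeMatrixTsv(metaboliteMatrix(cohort, normal = TRUE),
                 paths["metabolites_normal"], "metabolite")
  writeMatrixTsv(lipidMatrix(cohort), paths["lipids"], "lipid")
  writeMatrixTsv(lipidMatrix(cohort, normal = TRUE), paths["lipids_normal"],
                 "lipid")
  utils::write.table(metaboliteAnnotation(cohort),
                     paths["metabolite_annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lipidAnnotation(cohort), paths["lipid_annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohortTruth(cohort)
  truth$spec <- unclass(truth$spec)
  # named vectors serialize as JSON objects keyed by sample/feature id
  for (nm in c("group", "pik3ca", "hla_loh", "immune_shift", "lipid_shift",
               "tumor_normal_offset")) {
    truth[[nm]] <- as.list(truth[[nm]])
  }
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
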