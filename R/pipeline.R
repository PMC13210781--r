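#' Pipeline configuration
#'
#' Collects every threshold, mode and path the pipeline needs in one
#' declarative object. Inputs are either a simulation block (the synthetic
#' cohort generator defines the inputs) or paths to a VCF and a phenotype
#' TSV. The resolved configuration is always written next to the outputs,
#' so a run can be audited and reproduced exactly.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing every stochastic step of a run.
#' @param simulate `NULL`, or a named list of [sim_config()] arguments
#'   (the seed is injected from `seed`).
#' @param genotypes,phenotypes,blocklist Input file paths (VCF, TSV, one id
#'   per line); ignored when `simulate` is given, except `blocklist` which
#'   is always honoured.
#' @param thresholds Named list overriding any of: `maf_min` (0.05),
#'   `hwe_min` (1e-6), `cr_min` (0.90), `prune_r2` (0.5), `prune_window_kb`
#'   (500), `p_candidate` (5e-6), `clump_r2` (0.001), `clump_window_kb`
#'   (500), `p_pleiotropy` (0.05), `f_min` (10), `p_screen` (0.05),
#'   `n_pcs` (4).
#' @param modes Named list overriding any of: `outcome_screen`
#'   (`"marginal"`; `"conditional"` adjusts the screen for the exposure),
#'   `screens` (`"exclude"` drops failing instruments, `"warn"` records the
#'   failure and fits anyway), `vcov` (`"classical"`/`"robust"`), `df`
#'   (`"t"`/`"normal"`), `multiplicity` (`"none"`, `"bonferroni"`,
#'   `"benjamini_hochberg"`), `transform` (`"none"`, `"log"`,
#'   `"inverse_normal"` applied to each metabolite before the scan and the
#'   model), `standardize` (logical, per-SD score scale), `alpha` (0.05).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            genotypes = NULL, phenotypes = NULL,
                            blocklist = NULL, thresholds = list(),
                            modes = list()) {
  th <- utils::modifyList(list(
    maf_min = 0.05, hwe_min = 1e-6, cr_min = 0.90,
    prune_r2 = 0.5, prune_window_kb = 500,
    p_candidate = 5e-6, clump_r2 = 0.001, clump_window_kb = 500,
    p_pleiotropy = 0.05, f_min = 10, p_screen = 0.05, n_pcs = 4L),
    thresholds)
  md <- utils::modifyList(list(
    outcome_screen = "marginal", screens = "exclude", vcov = "classical",
    df = "t", multiplicity = "none", transform = "none",
    standardize = FALSE, alpha = 0.05), modes)
  stopifnot(th$maf_min >= 0, th$maf_min <= 0.5,
            th$hwe_min >= 0, th$hwe_min <= 1,
            th$cr_min >= 0, th$cr_min <= 1,
            th$prune_r2 >= 0, th$prune_r2 <= 1,
            th$clump_r2 >= 0, th$clump_r2 <= 1,
            th$p_candidate > 0, th$p_candidate <= 1,
            th$p_pleiotropy > 0, th$p_pleiotropy <= 1,
            th$p_screen > 0, th$p_screen <= 1,
            th$f_min >= 0, th$n_pcs >= 0)
  md$outcome_screen <- match.arg(md$outcome_screen,
                                 c("marginal", "conditional"))
  md$screens <- match.arg(md$screens, c("exclude", "warn"))
  md$vcov <- match.arg(md$vcov, c("classical", "robust"))
  md$df <- match.arg(md$df, c("t", "normal"))
  md$multiplicity <- match.arg(md$multiplicity,
                               c("none", "bonferroni", "benjamini_hochberg"))
  md$transform <- match.arg(md$transform, c("none", "log", "inverse_normal"))
  if (is.null(simulate) && (is.null(genotypes) || is.null(phenotypes))) {
    stop("provide either a simulate block or genotype and phenotype paths")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, genotypes = genotypes,
                 phenotypes = phenotypes, blocklist = blocklist,
                 thresholds = th, modes = md),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds the same fields as [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

transform_metabolite <- function(x, transform) {
  switch(transform,
         none = x,
         log = {
           if (any(x <= 0, na.rm = TRUE)) {
             stop("log transform requires strictly positive metabolite values")
           }
           log(x)
         },
         inverse_normal = {
           r <- rank(x, na.last = "keep")
           stats::qnorm((r - 0.5) / sum(!is.na(x)))
         })
}

#' Run the full MR-GxE pipeline
#'
#' Executes the stages in order — input (simulate or read), variant QC,
#' LD pruning and principal components, then per metabolite: association
#' scan, candidate selection, LD clumping, pleiotropy/blocklist screening,
#' score construction, instrument validation, the two-stage least-squares
#' fit, pattern classification and (for multi-variant scores) leave-one-out
#' — writing each stage's table, per-filter record counts, and a manifest.
#' A rerun with an identical configuration and inputs is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (named list), invisibly. Files written under
#'   `config$out_dir`: `resolved_config.yaml`, `qc_report.tsv`,
#'   `assoc_<metabolite>.tsv`, `prs_weights_<metabolite>.tsv`,
#'   `scores.tsv`, `instrument_diagnostics.tsv`, `results.tsv`,
#'   `loo_<metabolite>.tsv`, `forest_data.tsv`, `report.txt`,
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  md <- config$modes
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  # --- input stage -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    gm <- simulate_genotypes(cfg)
    cohort <- simulate_cohort(cfg, gm)
    phenotypes <- cohort$phenotypes
    write_cohort(gm, phenotypes, config$out_dir, truth = cohort$truth)
  } else {
    if (!file.exists(config$genotypes)) {
      stop("input stage: genotype file not found: ", config$genotypes)
    }
    if (!file.exists(config$phenotypes)) {
      stop("input stage: phenotype file not found: ", config$phenotypes)
    }
    gm <- read_vcf_genotypes(config$genotypes)
    phenotypes <- read_phenotypes(config$phenotypes)
    if (!identical(phenotypes$sample_id, gm$sample_ids)) {
      idx <- match(gm$sample_ids, phenotypes$sample_id)
      if (anyNA(idx)) {
        stop("input stage: phenotype table is missing sample(s): ",
             paste(utils::head(gm$sample_ids[is.na(idx)], 5), collapse = ", "))
      }
      phenotypes <- phenotypes[idx, , drop = FALSE]
    }
  }
  blocklist <- if (!is.null(config$blocklist)) {
    if (!file.exists(config$blocklist)) {
      stop("input stage: blocklist file not found: ", config$blocklist)
    }
    read_blocklist(config$blocklist)
  } else {
    character(0)
  }
  counts$variants_in <- n_variants(gm)

  # --- variant QC --------------------------------------------------------
  qc <- variant_qc(gm, maf_min = th$maf_min, hwe_min = th$hwe_min,
                   cr_min = th$cr_min)
  gm <- qc$genotypes
  utils::write.table(qc$report, file.path(config$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$variants_qc_pass <- n_variants(gm)
  counts$variants_qc_removed <- table_reasons(qc$report$reasons[!qc$report$passed])

  # --- principal components ---------------------------------------------
  pruned_ids <- ld_prune(gm, r2_max = th$prune_r2,
                         window_kb = th$prune_window_kb)
  counts$variants_pruned_for_pcs <- length(pruned_ids)
  pcs <- if (th$n_pcs > 0L) {
    compute_pcs(subset_variants(gm, pruned_ids), n_pcs = th$n_pcs)
  } else {
    matrix(numeric(0), nrow = n_samples(gm), ncol = 0L)
  }
  covariates <- cbind(age = phenotypes$age, sex = phenotypes$sex,
                      bmi = phenotypes$bmi, pcs)

  # --- per-metabolite analysis -------------------------------------------
  metabolites <- grep("^metabolite_", names(phenotypes), value = TRUE)
  outcome <- phenotypes$hba1c
  treatment <- phenotypes$metformin
  results <- list(); diagnostics <- list(); scores <- list()
  for (met in metabolites) {
    exposure <- transform_metabolite(phenotypes[[met]], md$transform)
    assoc <- snp_scan(gm, exposure, covariates)
    utils::write.table(assoc,
                       file.path(config$out_dir, paste0("assoc_", met, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cand <- select_candidates(assoc, p_max = th$p_candidate)
    clumped <- clump(cand, gm, r2_max = th$clump_r2,
                     window_kb = th$clump_window_kb)
    screened <- pleiotropy_filter(clumped, gm, outcome,
                                  confounders = covariates[, c("age", "sex", "bmi")],
                                  blocklist = blocklist,
                                  p_screen = th$p_pleiotropy)
    counts[[paste0(met, "_candidates")]] <- nrow(cand)
    counts[[paste0(met, "_clumped")]] <- nrow(clumped)
    counts[[paste0(met, "_screened")]] <- nrow(screened)
    counts[[paste0(met, "_screen_removed")]] <-
      table_reasons(attr(screened, "removed")$reason)
    if (nrow(screened) == 0L) {
      diagnostics[[met]] <- data.frame(
        metabolite = met, f_statistic = NA_real_, r2_first_stage = NA_real_,
        p_outcome = NA_real_, p_treatment = NA_real_,
        outcome_mode = md$outcome_screen, retained = FALSE,
        reasons = "no_variants", stringsAsFactors = FALSE)
      next
    }
    model <- prs_model_from_scan(screened, met)
    utils::write.table(
      cbind(screened[, c("variant_id", "chrom", "pos", "effect_allele",
                         "beta", "se", "p")]),
      file.path(config$out_dir, paste0("prs_weights_", met, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    prs <- compute_prs(model, gm)
    scores[[met]] <- prs
    diag <- validate_instrument(prs, exposure, outcome, treatment,
                                covariates, f_min = th$f_min,
                                p_screen = th$p_screen,
                                outcome_mode = md$outcome_screen,
                                metabolite = met)
    diagnostics[[met]] <- as.data.frame(diag)
    if (!diag$retained && md$screens == "exclude") next
    if (!diag$retained) {
      warning("instrument for ", met, " failed screens (", diag$reasons,
              "); fitting anyway (screens = \"warn\")")
    }
    fit <- mr_gxe(outcome, exposure, prs, treatment, covariates,
                  vcov_type = md$vcov, df_type = md$df,
                  standardize = md$standardize)
    loo_flagged <- NA
    if (nrow(model) >= 2L) {
      loo <- leave_one_out(model, gm, outcome, exposure, treatment,
                           covariates, alpha = md$alpha,
                           vcov_type = md$vcov, df_type = md$df,
                           standardize = md$standardize)
      utils::write.table(
        as.data.frame(loo),
        file.path(config$out_dir, paste0("loo_", met, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      loo_flagged <- sum(loo$influential)
    }
    results[[met]] <- data.frame(
      metabolite = met,
      beta_gxe = fit$coefficients[["gxe"]], se_gxe = fit$se[["gxe"]],
      p_gxe = fit$p[["gxe"]],
      beta_exposure = fit$coefficients[["exposure"]],
      se_exposure = fit$se[["exposure"]], p_exposure = fit$p[["exposure"]],
      n = fit$n, n_variants = nrow(model),
      first_stage_f = fit$first_stage$f_statistic,
      pattern = classify_pattern(fit, alpha = md$alpha),
      loo_influential = loo_flagged, stringsAsFactors = FALSE)
  }

  diagnostics <- do.call(rbind, c(diagnostics, list(make.row.names = FALSE)))
  utils::write.table(diagnostics,
                     file.path(config$out_dir, "instrument_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(scores) > 0L) {
    sc <- data.frame(sample_id = gm$sample_ids, scores,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(sc, file.path(config$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results <- if (length(results) > 0L) {
    do.call(rbind, c(results, list(make.row.names = FALSE)))
  } else {
    data.frame(metabolite = character(0), beta_gxe = numeric(0),
               se_gxe = numeric(0), p_gxe = numeric(0),
               beta_exposure = numeric(0), se_exposure = numeric(0),
               p_exposure = numeric(0), n = integer(0),
               n_variants = integer(0), first_stage_f = numeric(0),
               pattern = character(0), loo_influential = integer(0),
               stringsAsFactors = FALSE)
  }
  results$p_gxe_adjusted <- adjust_multiplicity(results$p_gxe,
                                                md$multiplicity)
  utils::write.table(results, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(results) > 0L) {
    utils::write.table(forest_data(results, alpha = md$alpha),
                       file.path(config$out_dir, "forest_data.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(render_report(results, diagnostics,
                           alpha = md$alpha, outcome_mode = md$outcome_screen),
             file.path(config$out_dir, "report.txt"))
  resolved <- unclass(config)
  yaml::write_yaml(resolved, file.path(config$out_dir, "resolved_config.yaml"))

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  # the resolved config echoes run-specific absolute paths, so it is listed
  # but not hashed; everything else must be bit-identical across reruns
  files <- files[!basename(files) %in% c("manifest.json",
                                         "resolved_config.yaml")]
  manifest <- list(
    package = "mrgxe",
    version = as.character(utils::packageVersion("mrgxe")),
    seed = config$seed,
    thresholds = th, modes = md,
    counts = counts,
    n_samples = n_samples(gm),
    metabolites = metabolites,
    file_hashes = as.list(tools::md5sum(files)))
  names(manifest$file_hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

table_reasons <- function(reasons) {
  if (length(reasons) == 0L) return(list())
  as.list(table(unlist(strsplit(reasons, ";", fixed = TRUE))))
}

#' Forest-plot data export
#'
#' Long-format table of the paired baseline and interaction estimates with
#' 95% confidence intervals and significance flags — the data behind the
#' conventional forest-style summary of treatment-modified effects.
#'
#' @param results Results data frame from [run_pipeline()] (or the same
#'   columns assembled by hand).
#' @param alpha Significance level for the flag.
#' @return Data frame: `metabolite`, `term` (`exposure`/`gxe`), `estimate`,
#'   `ci_low`, `ci_high`, `p`, `significant`.
#' @export
forest_data <- function(results, alpha = 0.05) {
  q <- stats::qnorm(1 - alpha / 2)
  long <- rbind(
    data.frame(metabolite = results$metabolite, term = "exposure",
               estimate = results$beta_exposure,
               ci_low = results$beta_exposure - q * results$se_exposure,
               ci_high = results$beta_exposure + q * results$se_exposure,
               p = results$p_exposure, stringsAsFactors = FALSE),
    data.frame(metabolite = results$metabolite, term = "gxe",
               estimate = results$beta_gxe,
               ci_low = results$beta_gxe - q * results$se_gxe,
               ci_high = results$beta_gxe + q * results$se_gxe,
               p = results$p_gxe, stringsAsFactors = FALSE))
  long$significant <- long$p < alpha
  long[order(long$metabolite, long$term), ]
}

#' Render a human-readable results report
#'
#' Formats the paired interaction/baseline estimate table with pattern
#' labels, the instrument diagnostics (screen mode stated prominently),
#' and reason codes for excluded instruments.
#'
#' @param results Results data frame (possibly empty).
#' @param diagnostics Instrument diagnostics data frame.
#' @param alpha Significance level used for pattern labels.
#' @param outcome_mode Outcome-screen mode in force, echoed in the header.
#' @return Character vector of report lines.
#' @export
render_report <- function(results, diagnostics, alpha = 0.05,
                          outcome_mode = "marginal") {
  lines <- c("MR-GxE pipeline report",
             "======================",
             sprintf("outcome screen mode: %s; alpha = %g", outcome_mode,
                     alpha),
             "")
  if (nrow(results) > 0L) {
    header <- sprintf("%-16s %9s %8s %10s %9s %8s %10s %6s %-16s",
                      "metabolite", "b_gxe", "se", "p", "b_expo", "se", "p",
                      "n", "pattern")
    rows <- sprintf("%-16s %9.4f %8.4f %10.3g %9.4f %8.4f %10.3g %6d %-16s",
                    results$metabolite, results$beta_gxe, results$se_gxe,
                    results$p_gxe, results$beta_exposure,
                    results$se_exposure, results$p_exposure, results$n,
                    results$pattern)
    lines <- c(lines, "Effect estimates:", header, rows, "")
  } else {
    lines <- c(lines, "No instruments survived screening; no effect rows.",
               "")
  }
  lines <- c(lines, "Instrument diagnostics:")
  for (i in seq_len(nrow(diagnostics))) {
    d <- diagnostics[i, ]
    lines <- c(lines, sprintf(
      "  %-16s F = %8.3g  p_outcome = %8.3g  p_treatment = %8.3g  %s%s",
      d$metabolite, d$f_statistic, d$p_outcome, d$p_treatment,
      if (d$retained) "retained" else "excluded",
      if (nzchar(d$reasons)) paste0(" [", d$reasons, "]") else ""))
  }
  lines
}
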