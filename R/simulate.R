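#' Simulation configuration for synthetic cohorts
#'
#' Defines the study conditions of a synthetic genotype/phenotype cohort:
#' an LD-blocked biallelic genotype panel, a metabolite exposure with a
#' sparse genetic architecture, an unobserved confounder shared between
#' exposure and outcome (the endogeneity that motivates an instrumental
#' variable), a binary treatment assigned independently of genotype, and an
#' outcome built from the structural model
#' \deqn{Y = \alpha + \beta_{exposure} X + \beta_{G\times E} (S \cdot T) +
#'   covariates + \lambda_Y U + \epsilon_Y}
#' where `S` is the true genetic score and `T` the treatment indicator.
#'
#' @param n_samples,n_variants,n_causal Cohort and panel sizes; `n_causal`
#'   variants (chosen at random) carry nonzero weights on the exposure.
#' @param maf_range Range (min, max) within (0, 0.5] from which each
#'   variant's ALT-allele frequency is drawn uniformly.
#' @param ld_block_size Number of consecutive variants per LD block.
#' @param ld_rho Within-block latent correlation in [0, 1); variants in
#'   different blocks are independent.
#' @param effect_sd Standard deviation of the per-causal-variant weights on
#'   the exposure (exposure units per ALT allele).
#' @param confounder_strength_x,confounder_strength_y Loadings of the shared
#'   standard-normal confounder on exposure and outcome. Setting both
#'   nonzero makes naive OLS of outcome on exposure biased by roughly their
#'   product.
#' @param beta_exposure True causal effect of the exposure on the outcome
#'   (outcome units per exposure unit).
#' @param beta_gxe True coefficient on the score-by-treatment product
#'   (outcome units per score unit, among the treated).
#' @param treatment_prevalence Probability of treatment, in (0, 1);
#'   treatment is Bernoulli, independent of genotype.
#' @param covariate_effects_x,covariate_effects_y Named length-3 vectors
#'   (age, sex, bmi) of covariate loadings on exposure and outcome.
#' @param noise_sd_x,noise_sd_y Residual standard deviations.
#' @param missing_rate Probability that any single genotype call is missing.
#' @param gxe_mode `"score"` (default): the interaction term in the outcome
#'   is score-by-treatment, matching the fitted model; `"exposure"`: an
#'   alternate effect-modification mode using exposure-by-treatment, for
#'   robustness exploration only.
#' @param seed Integer seed; identical seeds reproduce identical cohorts
#'   bit for bit. `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_samples = 2743L, n_variants = 1000L, n_causal = 30L,
                       maf_range = c(0.05, 0.5), ld_block_size = 20L,
                       ld_rho = 0.3, effect_sd = 0.15,
                       confounder_strength_x = 1,
                       confounder_strength_y = 0.5,
                       beta_exposure = 0.2, beta_gxe = -0.1,
                       treatment_prevalence = 0.3,
                       covariate_effects_x = c(age = 0.01, sex = 0.10, bmi = 0.02),
                       covariate_effects_y = c(age = 0.01, sex = 0.05, bmi = 0.01),
                       noise_sd_x = 1, noise_sd_y = 1, missing_rate = 0,
                       gxe_mode = c("score", "exposure"), seed = NULL) {
  gxe_mode <- match.arg(gxe_mode)
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              n_causal = as.integer(n_causal),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = as.numeric(ld_rho),
              effect_sd = as.numeric(effect_sd),
              confounder_strength_x = as.numeric(confounder_strength_x),
              confounder_strength_y = as.numeric(confounder_strength_y),
              beta_exposure = as.numeric(beta_exposure),
              beta_gxe = as.numeric(beta_gxe),
              treatment_prevalence = as.numeric(treatment_prevalence),
              covariate_effects_x = as.numeric(covariate_effects_x),
              covariate_effects_y = as.numeric(covariate_effects_y),
              noise_sd_x = as.numeric(noise_sd_x),
              noise_sd_y = as.numeric(noise_sd_y),
              missing_rate = as.numeric(missing_rate),
              gxe_mode = gxe_mode,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_samples < 1L || cfg$n_variants < 1L) {
    stop("n_samples and n_variants must be positive")
  }
  if (cfg$n_causal < 0L || cfg$n_causal > cfg$n_variants) {
    stop("n_causal must be between 0 and n_variants")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (cfg$treatment_prevalence <= 0 || cfg$treatment_prevalence >= 1) {
    stop("treatment_prevalence must be in (0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (length(cfg$covariate_effects_x) != 3L ||
      length(cfg$covariate_effects_y) != 3L) {
    stop("covariate effect vectors must have length 3 (age, sex, bmi)")
  }
  if (cfg$ld_block_size < 1L) stop("ld_block_size must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Each variant's ALT-allele frequency is drawn uniformly from
#' `maf_range`. Within a block of `ld_block_size` consecutive variants, the
#' two allele draws of each sample come from thresholding a latent Gaussian
#' that mixes a per-haplotype block factor with idiosyncratic noise at
#' correlation `ld_rho`; blocks are mutually independent. Blocks are laid
#' out on autosomes 1-22 with 1 kb spacing within a block and 2 Mb between
#' blocks on the same chromosome, so different blocks never share a
#' clumping window.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()] with attribute `"sim_allele_freq"` holding
#'   the sampled ALT-allele frequencies (simulation truth, not consumed by
#'   the analysis pipeline).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  rho <- config$ld_rho
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]
  thr <- matrix(stats::qnorm(p), n, m, byrow = TRUE)
  draw_haplotype <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0) {
      for (b in unique(block)) {
        idx <- which(block == b)
        f <- stats::rnorm(n)
        z[, idx] <- sqrt(rho) * f + sqrt(1 - rho) * z[, idx]
      }
    }
    z < thr
  }
  dosage <- draw_haplotype() + draw_haplotype()
  storage.mode(dosage) <- "double"
  if (config$missing_rate > 0) {
    dosage[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  block_rank <- stats::ave(block, chrom, FUN = function(b) {
    match(b, unique(b))
  })
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- as.integer((block_rank - 1L) * 2e6 + (within - 1L) * 1000L + 1L)
  variants <- data.frame(
    id = sprintf("snp%0*d", nchar(m), seq_len(m)),
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, variants,
                        sample_ids = sprintf("QS%0*d", nchar(n), seq_len(n)))
  attr(gm, "sim_allele_freq") <- p
  gm
}

#' Simulate phenotypes and the true structural model
#'
#' Draws covariates (age uniform on 20-70 years, sex Bernoulli(0.5), BMI
#' normal(28, 5) truncated below at 15), a latent standard-normal
#' confounder, causal variant weights, treatment independent of genotype,
#' then builds exposure and outcome from the structural model described in
#' [sim_config()]. Missing causal dosages enter the true score via
#' mean imputation.
#'
#' @param config The [sim_config()] used for `genotypes`.
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()].
#' @return A list with `phenotypes` (data frame: `sample_id`, `age`, `sex`,
#'   `bmi`, `metformin`, `hba1c`, `metabolite_1`) and `truth` (class
#'   `"true_model"`): causal variant ids, weights, the confounder values,
#'   the true score and the true coefficients. The truth object exists for
#'   recovery assertions only and is never consumed by the pipeline.
#' @export
simulate_cohort <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  n <- n_samples(genotypes)
  m <- n_variants(genotypes)
  if (n != config$n_samples || m != config$n_variants) {
    stop("genotype matrix dimensions do not match the configuration")
  }
  # large odd offset keeps the phenotype stream disjoint from the genotype
  # streams of nearby seeds (callers routinely seed replicates consecutively)
  if (!is.null(config$seed)) set.seed(config$seed + 1000003L)
  age <- stats::runif(n, 20, 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  bmi <- pmax(stats::rnorm(n, 28, 5), 15)
  u <- stats::rnorm(n)
  causal_idx <- sort(sample.int(m, config$n_causal))
  w <- stats::rnorm(config$n_causal, 0, config$effect_sd)
  g <- genotypes$dosage[, causal_idx, drop = FALSE]
  if (anyNA(g)) {
    cm <- colMeans(g, na.rm = TRUE)
    na_at <- which(is.na(g), arr.ind = TRUE)
    g[na_at] <- cm[na_at[, 2L]]
  }
  s <- as.vector(g %*% w)
  cx <- config$covariate_effects_x
  cy <- config$covariate_effects_y
  x <- s + cx[1] * age + cx[2] * sex + cx[3] * bmi +
    config$confounder_strength_x * u +
    stats::rnorm(n, 0, config$noise_sd_x)
  trt <- stats::rbinom(n, 1L, config$treatment_prevalence)
  gxe <- if (config$gxe_mode == "score") s * trt else x * trt
  y <- 5 + config$beta_exposure * x + config$beta_gxe * gxe +
    cy[1] * age + cy[2] * sex + cy[3] * bmi +
    config$confounder_strength_y * u +
    stats::rnorm(n, 0, config$noise_sd_y)
  phenotypes <- data.frame(sample_id = genotypes$sample_ids,
                           age = age, sex = sex, bmi = bmi,
                           metformin = trt, hba1c = y, metabolite_1 = x,
                           stringsAsFactors = FALSE)
  truth <- structure(list(
    causal_variant_ids = genotypes$variants$id[causal_idx],
    causal_weights = w,
    confounder_values = u,
    true_score = s,
    true_beta_exposure = config$beta_exposure,
    true_beta_gxe = config$beta_gxe,
    gxe_mode = config$gxe_mode), class = "true_model")
  list(phenotypes = phenotypes, truth = truth)
}

#' Polygenic-score model holding the generator's true weights
#'
#' Convenience for calibration studies: wraps the causal weights stored in a
#' `true_model` as a [prs_model()], so the true genetic score can be rebuilt
#' through the same scoring code path the pipeline uses.
#'
#' @param truth The `truth` component returned by [simulate_cohort()].
#' @param metabolite Metabolite name recorded on the model.
#' @return A [prs_model()].
#' @export
true_prs_model <- function(truth, metabolite = "metabolite_1") {
  stopifnot(inherits(truth, "true_model"))
  prs_model(metabolite = metabolite,
            variant_id = truth$causal_variant_ids,
            effect_allele = rep("alt", length(truth$causal_variant_ids)),
            weight = truth$causal_weights)
}

#' Write a simulated cohort to disk
#'
#' Emits genotypes as VCF v4.2, phenotypes as TSV, and (optionally) the
#' simulation truth as JSON, under `dir`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Phenotype data frame.
#' @param dir Output directory (created if needed).
#' @param truth Optional `true_model` to serialise alongside.
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(genotypes, phenotypes, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"))
  write_vcf(genotypes, paths[["genotypes"]])
  write_phenotypes(phenotypes, paths[["phenotypes"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(unclass(truth), paths[["truth"]],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
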