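# Fixtures built in code at test time.

# 10-variant QC fixture over 200 samples: variants 2 (low MAF), 5 (extreme
# heterozygote excess) and 8 (20% missing calls) each violate exactly one
# filter; variant 10 sits exactly on the MAF boundary and must be retained.
make_qc_fixture <- function() {
  n <- 200L
  hwe_col <- function(n_AA, n_Aa, n_aa) {
    c(rep(0, n_AA), rep(1, n_Aa), rep(2, n_aa))
  }
  cols <- list(
    v01 = hwe_col(98, 84, 18),          # clean, MAF 0.30
    v02 = hwe_col(196, 4, 0),           # MAF 0.01 -> low_maf
    v03 = hwe_col(98, 84, 18),
    v04 = hwe_col(128, 64, 8),          # MAF 0.20
    v05 = hwe_col(0, 200, 0),           # all heterozygous -> hwe_fail
    v06 = hwe_col(98, 84, 18),
    v07 = hwe_col(72, 96, 32),          # MAF 0.40
    v08 = c(hwe_col(79, 67, 14), rep(NA_real_, 40)),  # call rate 0.8
    v09 = hwe_col(98, 84, 18),
    v10 = hwe_col(180, 20, 0)           # MAF exactly 0.05, boundary
  )
  # scramble each column so genotype order is not informative
  set.seed(42)
  dosage <- vapply(cols, function(x) x[sample.int(n)], numeric(n))
  variants <- data.frame(id = names(cols), chrom = "2",
                         pos = seq(1000L, by = 10000L, length.out = 10L),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, sample_ids = paste0("S", seq_len(n)))
}

# Deterministic 12-sample instrument fixture used by the normal-equation
# oracle checks of the first stage and the screens.
make_small_instrument_fixture <- function() {
  prs <- c(0.1, 1.4, -0.8, 2.2, 0.5, -1.6, 0.9, 1.1, -0.3, 1.9, 0.2, -1.2)
  age <- c(31, 55, 47, 62, 28, 39, 51, 44, 36, 58, 49, 33)
  exposure <- c(0.35, 1.82, -0.41, 2.65, 0.88, -1.12, 1.31, 1.05, 0.02,
                2.21, 0.47, -0.83)
  outcome <- c(5.4, 6.1, 5.2, 6.7, 5.6, 4.9, 5.9, 6.0, 5.3, 6.5, 5.5, 5.0)
  treatment <- c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
  list(prs = prs, age = age, exposure = exposure, outcome = outcome,
       treatment = treatment)
}

# Small random genotype matrix for combinatorial oracle checks.
random_gm <- function(seed, n = 120L, m = 18L, block = 5L, rho = 0.9) {
  cfg <- sim_config(n_samples = n, n_variants = m, n_causal = 1L,
                    maf_range = c(0.15, 0.5), ld_block_size = block,
                    ld_rho = rho, seed = seed)
  simulate_genotypes(cfg)
}

# Candidate table with random p-values over all variants of a matrix.
random_candidates <- function(gm, seed) {
  set.seed(seed)
  v <- gm$variants
  data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
             effect_allele = "alt", beta = rnorm(nrow(v)),
             se = runif(nrow(v), 0.1, 0.5), p = runif(nrow(v)),
             n = nrow(gm$dosage), stringsAsFactors = FALSE)
}

# One replicate of the planted-pleiotropy leave-one-out design: a 20-SNP
# instrument in which SNP 1 also has a direct dosage-by-treatment path to
# the outcome (true interaction coefficient is zero). Mixed-sign weights
# keep the score near mean zero, so the pleiotropic path is identified by
# SNP 1's membership in the score, not by a shared treated-group shift.
loo_pleiotropy_replicate <- function(seed, n = 1500L, m = 20L, delta = 1.5) {
  gm <- simulate_genotypes(sim_config(
    n_samples = n, n_variants = m, n_causal = m, ld_rho = 0,
    maf_range = c(0.2, 0.4), seed = seed))
  set.seed(seed + 5e5)
  g <- gm$dosage
  w <- rep(c(0.3, -0.3), m / 2)
  s <- as.vector(g %*% w)
  x <- s + rnorm(n)
  trt <- rbinom(n, 1L, 0.5)
  y <- 5 + 0.2 * x + delta * g[, 1L] * trt + rnorm(n)
  model <- prs_model("m1", gm$variants$id, rep("alt", m), w)
  leave_one_out(model, gm, y, x, trt, covariates = NULL)
}
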