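test_that("the association scan recovers a planted per-allele effect", {
  gm <- random_gm(201, n = 500, m = 10, block = 1, rho = 0)
  set.seed(202)
  exposure <- 0.5 * gm$dosage[, 4] + rnorm(500, 0, 0.01)
  res <- snp_scan(gm, exposure)
  hit <- res[res$variant_id == gm$variants$id[4], ]
  expect_gt(hit$beta, 0.45)
  expect_lt(hit$beta, 0.55)
  expect_lt(hit$p, 5e-6)
})

test_that("null p-values are uniform across independent variants", {
  gm <- simulate_genotypes(sim_config(
    n_samples = 300, n_variants = 1000, n_causal = 1, ld_block_size = 1,
    ld_rho = 0, seed = 210))
  set.seed(211)
  exposure <- rnorm(300)
  res <- snp_scan(gm, exposure)
  ks <- ks.test(res$p[!is.na(res$p)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a single-variant scan equals the lm() normal-equation fit", {
  gm <- random_gm(220, n = 80, m = 3, block = 1, rho = 0)
  set.seed(221)
  covs <- data.frame(age = runif(80, 20, 70), sex = rbinom(80, 1, 0.5))
  exposure <- 0.3 * gm$dosage[, 2] + 0.02 * covs$age + rnorm(80)
  res <- snp_scan(gm, exposure, covs)
  ref <- summary(lm(exposure ~ gm$dosage[, 2] + age + sex,
                    data = covs))$coefficients[2, ]
  row <- res[2, ]
  expect_equal(row$beta, unname(ref["Estimate"]), tolerance = 1e-8)
  expect_equal(row$se, unname(ref["Std. Error"]), tolerance = 1e-8)
  expect_equal(row$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
})

test_that("scan handles missing dosages and monomorphic variants", {
  d <- cbind(a = c(0, 1, 2, 1, 0, 2, 1, 0, 2, 1),
             b = c(1, NA, 0, 2, 1, NA, 0, 1, 2, 0),
             c = rep(1, 10))
  variants <- data.frame(id = c("a", "b", "c"), chrom = "1",
                         pos = c(100L, 200L, 300L), ref = "A", alt = "G")
  gm <- genotype_matrix(d, variants)
  set.seed(230)
  exposure <- rnorm(10)
  res <- snp_scan(gm, exposure)
  expect_equal(res$n[2], 8L)  # missing excluded per variant
  ok <- !is.na(d[, 2])
  ref <- summary(lm(exposure[ok] ~ d[ok, 2]))$coefficients[2, ]
  expect_equal(res$beta[2], unname(ref["Estimate"]), tolerance = 1e-10)
  expect_true(is.na(res$p[3]))  # monomorphic flagged undefined
})

test_that("candidate selection applies a strict p-value threshold", {
  assoc <- data.frame(variant_id = c("a", "b", "c", "d"), chrom = "1",
                      pos = 1:4 * 1000L, effect_allele = "alt",
                      beta = 1, se = 1,
                      p = c(5e-6, 4.9999e-6, 1e-8, NA), n = 100)
  kept <- select_candidates(assoc, p_max = 5e-6)
  expect_identical(kept$variant_id, c("b", "c"))  # boundary value excluded
  expect_identical(nrow(select_candidates(assoc[0, ])), 0L)
  all_in <- assoc[1:3, ]; all_in$p <- 1e-8
  expect_equal(nrow(select_candidates(all_in)), 3L)
})

test_that("clumping keeps the smallest-p index of a correlated trio", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2, 0, 1)
  dosage <- cbind(s1 = g, s2 = g, s3 = g)  # r2 = 1 among all three
  variants <- data.frame(id = c("s1", "s2", "s3"), chrom = "5",
                         pos = c(1000L, 2000L, 3000L), ref = "A", alt = "G")
  gm <- genotype_matrix(dosage, variants)
  cand <- data.frame(variant_id = c("s1", "s2", "s3"), chrom = "5",
                     pos = c(1000L, 2000L, 3000L), effect_allele = "alt",
                     beta = 1, se = 1, p = c(1e-6, 1e-8, 1e-7), n = 12)
  out <- clump(cand, gm, r2_max = 0.001, window_kb = 500)
  expect_identical(out$variant_id, "s2")  # p = 1e-8 wins
})

test_that("variants beyond the clumping window are always retained", {
  g1 <- c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2)
  dosage <- cbind(far1 = g1, far2 = g1)
  variants <- data.frame(id = c("far1", "far2"), chrom = "7",
                         pos = c(1000L, 601000L), ref = "A", alt = "G")
  gm <- genotype_matrix(dosage, variants)
  cand <- data.frame(variant_id = c("far1", "far2"), chrom = "7",
                     pos = c(1000L, 601000L), effect_allele = "alt",
                     beta = 1, se = 1, p = c(1e-8, 1e-7), n = 10)
  out <- clump(cand, gm, r2_max = 0.001, window_kb = 500)
  expect_equal(nrow(out), 2L)
})

test_that("clumping matches the brute-force greedy oracle", {
  for (seed in 1:20) {
    gm <- random_gm(seed + 300, n = 100, m = 18, block = 5, rho = 0.9)
    cand <- random_candidates(gm, seed + 400)
    for (r2_max in c(0.001, 0.2)) {
      got <- sort(clump(cand, gm, r2_max = r2_max, window_kb = 500)$variant_id)
      expect_identical(got, oracle_clump_ids(cand, gm, r2_max, 500))
    }
  }
})

test_that("clumped output is mutually independent below the threshold", {
  gm <- random_gm(555, n = 150, m = 20, block = 4, rho = 0.8)
  cand <- random_candidates(gm, 556)
  out <- clump(cand, gm, r2_max = 0.2, window_kb = 500)
  if (nrow(out) > 1L) {
    for (i in 1:(nrow(out) - 1L)) {
      for (j in (i + 1L):nrow(out)) {
        if (out$chrom[i] == out$chrom[j] &&
            abs(out$pos[i] - out$pos[j]) <= 5e5) {
          r2 <- suppressWarnings(
            ld_r2(gm$dosage[, out$variant_id[i]],
                  gm$dosage[, out$variant_id[j]]))
          expect_lte(r2, 0.2)
        }
      }
    }
  }
  # each index carries the minimum p among candidates it absorbed
  expect_true(min(cand$p) %in% out$p)
})

test_that("pleiotropy screening removes planted direct-outcome variants", {
  gm <- random_gm(600, n = 800, m = 6, block = 1, rho = 0)
  set.seed(601)
  outcome <- 0.5 * gm$dosage[, 3] + rnorm(800)   # direct HbA1c path
  confounders <- data.frame(age = runif(800, 20, 70),
                            sex = rbinom(800, 1, 0.5),
                            bmi = rnorm(800, 28, 5))
  cand <- random_candidates(gm, 602)
  out <- pleiotropy_filter(cand, gm, outcome, confounders)
  expect_false(gm$variants$id[3] %in% out$variant_id)
  removed <- attr(out, "removed")
  expect_true(grepl("assoc_hba1c",
                    removed$reason[removed$variant_id == gm$variants$id[3]]))
})

test_that("blocklisted variants are removed even when otherwise clean", {
  gm <- random_gm(610, n = 400, m = 5, block = 1, rho = 0)
  set.seed(611)
  outcome <- rnorm(400)
  confounders <- data.frame(age = runif(400, 20, 70),
                            sex = rbinom(400, 1, 0.5),
                            bmi = rnorm(400, 28, 5))
  cand <- random_candidates(gm, 612)
  block_id <- gm$variants$id[2]
  out <- pleiotropy_filter(cand, gm, outcome, confounders,
                           blocklist = block_id)
  expect_false(block_id %in% out$variant_id)
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$variant_id == block_id], "blocklist")
})

test_that("null variants are removed at roughly the screening rate", {
  # four independent 5%-level screens: expected removal ~ 1 - 0.95^4 = 18.5%
  gm <- simulate_genotypes(sim_config(
    n_samples = 400, n_variants = 400, n_causal = 1, ld_block_size = 1,
    ld_rho = 0, seed = 620))
  set.seed(621)
  outcome <- rnorm(400)
  confounders <- data.frame(age = runif(400, 20, 70),
                            sex = rbinom(400, 1, 0.5),
                            bmi = rnorm(400, 28, 5))
  cand <- random_candidates(gm, 622)
  out <- pleiotropy_filter(cand, gm, outcome, confounders)
  frac_removed <- 1 - nrow(out) / nrow(cand)
  expect_gt(frac_removed, 0.09)
  expect_lt(frac_removed, 0.30)
})

test_that("polygenic scores are exact weighted dosage sums", {
  dosage <- rbind(c(2, 1), c(0, 2), c(1, 0), c(2, 2), c(1, 1))
  variants <- data.frame(id = c("v1", "v2"), chrom = "1",
                         pos = c(100L, 200L), ref = "A", alt = "G")
  gm <- genotype_matrix(dosage, variants,
                        sample_ids = paste0("S", 1:5))
  model <- prs_model("met", c("v1", "v2"), c("alt", "alt"), c(0.5, -0.2))
  score <- compute_prs(model, gm)
  expect_equal(unname(score[1]), 2 * 0.5 + 1 * (-0.2))  # 0.8
  zero <- prs_model("met", c("v1", "v2"), c("alt", "alt"), c(0, 0))
  expect_true(all(compute_prs(zero, gm) == 0))
})

test_that("missing dosages are mean-imputed in the score", {
  # non-missing mean dosage at v2 is (2+1+0+2)/4 = 1.25 -> adjust to 1.2
  dosage <- rbind(c(2, NA), c(0, 2), c(1, 1), c(2, 0), c(1, 2), c(0, 1))
  # column v2 mean over non-missing: (2+1+0+2+1)/5 = 1.2
  variants <- data.frame(id = c("v1", "v2"), chrom = "1",
                         pos = c(100L, 200L), ref = "A", alt = "G")
  gm <- genotype_matrix(dosage, variants)
  model <- prs_model("met", c("v1", "v2"), c("alt", "alt"), c(0.5, -0.2))
  score <- compute_prs(model, gm)
  expect_equal(unname(score[1]), 2 * 0.5 + 1.2 * (-0.2))  # 0.76
})

test_that("scores are linear in the model weights", {
  gm <- random_gm(700, n = 60, m = 8, block = 2, rho = 0.4)
  ids <- gm$variants$id
  set.seed(701)
  wa <- rnorm(8); wb <- rnorm(8)
  sa <- compute_prs(prs_model("m", ids, rep("alt", 8), wa), gm)
  sb <- compute_prs(prs_model("m", ids, rep("alt", 8), wb), gm)
  sab <- compute_prs(prs_model("m", ids, rep("alt", 8), wa + wb), gm)
  expect_equal(sab, sa + sb, tolerance = 1e-12)
})

test_that("score model contracts are enforced", {
  gm <- random_gm(710, n = 20, m = 3, block = 1, rho = 0)
  expect_error(compute_prs(prs_model("m", character(0), character(0),
                                     numeric(0)), gm), "empty")
  expect_error(
    compute_prs(prs_model("m", "absent", "alt", 1), gm), "absent")
  expect_error(prs_model("m", c("a", "a"), c("alt", "alt"), c(1, 2)),
               "unique")
  # REF-coded effect allele flips the counted dosage
  model_ref <- prs_model("m", gm$variants$id[1], "ref", 1)
  model_alt <- prs_model("m", gm$variants$id[1], "alt", 1)
  expect_equal(compute_prs(model_ref, gm),
               2 - compute_prs(model_alt, gm))
})
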