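test_that("2SLS equals OLS when the exposure instruments itself", {
  set.seed(900)
  n <- 300L
  prs <- rnorm(n)
  exposure <- prs                      # exogenous, self-instrumented
  treatment <- rbinom(n, 1, 0.4)
  covs <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  outcome <- 5 + 0.3 * exposure - 0.1 * prs * treatment +
    0.01 * covs$age + rnorm(n)
  fit <- mr_gxe(outcome, exposure, prs, treatment, covs)
  gxe <- prs * treatment
  ref <- lm(outcome ~ exposure + gxe + age + sex, data = covs)
  expect_equal(unname(coef(fit)[c("exposure", "gxe")]),
               unname(coef(ref)[c("exposure", "gxe")]), tolerance = 1e-8)
  expect_equal(unname(fit$se[c("exposure", "gxe")]),
               unname(coef(summary(ref))[c("exposure", "gxe"), 2]),
               tolerance = 1e-8)
})

test_that("the fit matches the dense projection-matrix oracle", {
  set.seed(910)
  for (r in 1:10) {
    n <- sample(10:30, 1)
    treatment <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both arms guaranteed
    prs <- rnorm(n)
    exposure <- prs + 0.5 * rnorm(n)
    cov1 <- rnorm(n)
    outcome <- 1 + 0.4 * exposure - 0.2 * prs * treatment + 0.1 * cov1 +
      rnorm(n)
    fit <- mr_gxe(outcome, exposure, prs, treatment,
                  covariates = cbind(cov1 = cov1))
    gxe <- prs * treatment
    W <- cbind(1, exposure, gxe, cov1)
    Z <- cbind(1, prs, gxe, cov1)
    ref <- oracle_2sls(outcome, W, Z)
    expect_equal(unname(coef(fit)), unname(ref$coef), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(ref$se), tolerance = 1e-8)
    expect_equal(unname(fit$vcov), unname(ref$vcov), tolerance = 1e-8)
  }
})

test_that("estimates are invariant to affine covariate rescaling", {
  set.seed(920)
  n <- 400L
  prs <- rnorm(n)
  treatment <- rbinom(n, 1, 0.4)
  u <- rnorm(n)
  exposure <- prs + u + rnorm(n)
  covs <- cbind(age = runif(n, 20, 70), bmi = rnorm(n, 28, 5))
  outcome <- 5 + 0.3 * exposure - 0.1 * prs * treatment + 0.5 * u +
    0.01 * covs[, "age"] + rnorm(n)
  f1 <- mr_gxe(outcome, exposure, prs, treatment, covs)
  covs2 <- cbind(age = (covs[, "age"] - 45) / 10, bmi = covs[, "bmi"] * 3)
  f2 <- mr_gxe(outcome, exposure, prs, treatment, covs2)
  expect_equal(coef(f1)[c("exposure", "gxe")],
               coef(f2)[c("exposure", "gxe")], tolerance = 1e-8)
  expect_equal(f1$se[c("exposure", "gxe")],
               f2$se[c("exposure", "gxe")], tolerance = 1e-8)
})

test_that("degenerate designs raise specific errors", {
  set.seed(930)
  n <- 50L
  prs <- rnorm(n)
  exposure <- prs + rnorm(n)
  outcome <- rnorm(n)
  expect_error(mr_gxe(outcome, exposure, prs, rep(0, n)), "degenerate")
  expect_error(mr_gxe(outcome, exposure, prs, rep(1, n)), "degenerate")
  trt <- rbinom(n, 1, 0.5)
  covs <- cbind(a = rnorm(n))
  covs2 <- cbind(a = covs[, 1], b = 2 * covs[, 1])
  expect_error(mr_gxe(outcome, exposure, prs, trt, covs2), "b")
  expect_error(mr_gxe(outcome, exposure, prs, trt[-1]), "length")
})

test_that("complete-case handling drops and counts incomplete rows", {
  set.seed(940)
  n <- 120L
  prs <- rnorm(n)
  trt <- rbinom(n, 1, 0.5)
  exposure <- prs + rnorm(n)
  outcome <- 1 + 0.3 * exposure + rnorm(n)
  exposure[c(3, 10)] <- NA
  outcome[5] <- NA
  fit <- mr_gxe(outcome, exposure, prs, trt)
  expect_equal(fit$n, n - 3L)
  expect_equal(fit$n_dropped, 3L)
  keep <- !(seq_len(n) %in% c(3, 5, 10))
  ref <- mr_gxe(outcome[keep], exposure[keep], prs[keep], trt[keep])
  expect_equal(coef(fit), coef(ref), tolerance = 1e-12)
})

test_that("robust and normal-reference modes change only the inference", {
  set.seed(950)
  n <- 300L
  prs <- rnorm(n)
  trt <- rbinom(n, 1, 0.4)
  exposure <- prs + rnorm(n)
  outcome <- 1 + 0.3 * exposure - 0.1 * prs * trt + rnorm(n) * (1 + trt)
  f_c <- mr_gxe(outcome, exposure, prs, trt)
  f_r <- mr_gxe(outcome, exposure, prs, trt, vcov_type = "robust")
  expect_equal(coef(f_c), coef(f_r), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f_c$se, f_r$se)))
  f_n <- mr_gxe(outcome, exposure, prs, trt, df_type = "normal")
  expect_equal(unname(f_n$p["gxe"]),
               2 * pnorm(-abs(f_n$t[["gxe"]])), tolerance = 1e-12)
})

test_that("standardize rescales the score without changing its t statistic", {
  set.seed(960)
  n <- 250L
  prs <- rnorm(n, 0, 3)
  trt <- rbinom(n, 1, 0.4)
  exposure <- prs + rnorm(n)
  outcome <- 1 + 0.2 * exposure - 0.05 * prs * trt + rnorm(n)
  f0 <- mr_gxe(outcome, exposure, prs, trt)
  f1 <- mr_gxe(outcome, exposure, prs, trt, standardize = TRUE)
  expect_equal(f1$coefficients[["gxe"]],
               f0$coefficients[["gxe"]] * sd(prs), tolerance = 1e-8)
  expect_equal(f1$t[["gxe"]], f0$t[["gxe"]], tolerance = 1e-8)
})

test_that("Wald tests follow their reference distribution", {
  set.seed(970)
  n <- 200L
  prs <- rnorm(n)
  trt <- rbinom(n, 1, 0.5)
  exposure <- prs + rnorm(n)
  outcome <- 1 + 0.3 * exposure + rnorm(n)
  fit <- mr_gxe(outcome, exposure, prs, trt)
  w <- wald_test(fit, "gxe")
  expect_equal(w$statistic,
               fit$coefficients[["gxe"]] / fit$se[["gxe"]])
  expect_equal(w$p, 2 * pt(-abs(w$statistic), fit$df_residual))
  expect_error(wald_test(fit, "nope"), "no coefficient")
  # under the normal reference the two-sided tail is used directly
  fit_n <- mr_gxe(outcome, exposure, prs, trt, df_type = "normal")
  w_n <- wald_test(fit_n, "gxe")
  expect_equal(w_n$p, 2 * pnorm(-abs(w_n$statistic)), tolerance = 1e-12)
})

test_that("pattern classification reproduces the published sign structure", {
  labels <- classify_pattern(
    beta_exposure = c(-0.028, 0.031, 0.040, -0.304, -0.085, -0.044),
    p_exposure = c(2.70e-2, 1.32e-2, 3.80e-3, 1.61e-5, 5.51e-8, 3.82e-3),
    beta_gxe = c(-0.024, -0.052, -0.051, 0.175, 0.124, 0.118),
    p_gxe = c(1.39e-24, 6.67e-20, 3.82e-23, 1.48e-25, 1.62e-8, 5.34e-7))
  expect_identical(labels, c("strengthened", "reversed", "reversed",
                             "attenuated", "attenuated", "attenuated"))
  expect_identical(
    classify_pattern(beta_exposure = 0.01, p_exposure = 0.4,
                     beta_gxe = -0.027, p_gxe = 1e-5),
    "conditional_only")
  expect_identical(
    classify_pattern(beta_exposure = 0.2, p_exposure = 0.001,
                     beta_gxe = 0.01, p_gxe = 0.6),
    "none")
})

test_that("multiplicity adjustment follows the standard procedures", {
  p <- c(0.01, 0.02, 0.03)
  expect_identical(adjust_multiplicity(p, "none"), p)
  expect_equal(adjust_multiplicity(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.04), "benjamini_hochberg"),
               c(0.03, 0.03, 0.04))
  expect_error(adjust_multiplicity(p, "holm"), "arg")
})

test_that("dropping a zero-weight variant leaves the fit unchanged", {
  gm <- random_gm(980, n = 200, m = 5, block = 1, rho = 0)
  set.seed(981)
  w <- c(0.4, 0.3, 0, 0.5, 0.2)
  model <- prs_model("m", gm$variants$id, rep("alt", 5), w)
  s <- compute_prs(model, gm)
  trt <- rbinom(200, 1, 0.5)
  exposure <- s + rnorm(200)
  outcome <- 1 + 0.3 * exposure - 0.1 * s * trt + rnorm(200)
  loo <- leave_one_out(model, gm, outcome, exposure, trt)
  full <- attr(loo, "full_fit")
  zero_row <- loo[loo$dropped_variant_id == gm$variants$id[3], ]
  expect_lt(abs(zero_row$beta_gxe - full$coefficients[["gxe"]]), 1e-10)
  expect_lt(abs(zero_row$delta_beta_gxe), 1e-10)
  expect_false(zero_row$influential)
})

test_that("leave-one-out rejects single-variant models", {
  gm <- random_gm(990, n = 50, m = 2, block = 1, rho = 0)
  model <- prs_model("m", gm$variants$id[1], "alt", 0.5)
  expect_error(leave_one_out(model, gm, rnorm(50), rnorm(50),
                             rbinom(50, 1, 0.5)), "single-variant")
})

test_that("a homogeneous valid instrument is rarely flagged", {
  set.seed(995)
  rates <- vapply(1:10, function(r) {
    gm <- simulate_genotypes(sim_config(
      n_samples = 800, n_variants = 10, n_causal = 10, ld_rho = 0,
      maf_range = c(0.2, 0.4), seed = 1000 + r))
    w <- rep(0.3, 10)
    s <- as.vector(gm$dosage %*% w)
    trt <- rbinom(800, 1, 0.5)
    exposure <- s + rnorm(800)
    outcome <- 5 + 0.3 * exposure - 0.3 * s * trt + rnorm(800)
    model <- prs_model("m", gm$variants$id, rep("alt", 10), w)
    loo <- leave_one_out(model, gm, outcome, exposure, trt)
    mean(loo$influential)
  }, numeric(1))
  expect_lt(mean(rates), 0.05)
})

test_that("fit accessors and printing behave like a standard model object", {
  set.seed(998)
  n <- 150L
  prs <- rnorm(n)
  trt <- rbinom(n, 1, 0.4)
  exposure <- prs + rnorm(n)
  outcome <- 1 + 0.3 * exposure - 0.1 * prs * trt + rnorm(n)
  covs <- data.frame(age = runif(n, 20, 70))
  fit <- mr_gxe(outcome, exposure, prs, trt, covs)
  expect_equal(nobs(fit), n)
  expect_equal(length(residuals(fit)), n)
  expect_equal(fitted(fit) + residuals(fit), outcome, tolerance = 1e-10)
  ci <- confint(fit)
  expect_true(ci["gxe", 1] < coef(fit)[["gxe"]],
              ci["gxe", 2] > coef(fit)[["gxe"]])
  expect_true(isSymmetric(vcov(fit), tol = 1e-12))
  expect_gte(min(eigen(vcov(fit), only.values = TRUE)$values), -1e-10)
  expect_output(print(fit), "beta_gxe")
  expect_output(print(summary(fit)), "First-stage")
})

test_that("weak instruments inflate exposure bias relative to strong ones", {
  # monotonicity check at planted first-stage F near 5 versus near 50
  bias_at <- function(effect_sd, seeds) {
    vapply(seeds, function(r) {
      cfg <- sim_config(n_samples = 500, n_variants = 20, n_causal = 20,
                        effect_sd = effect_sd, seed = r)
      gm <- simulate_genotypes(cfg)
      co <- simulate_cohort(cfg, gm)
      ph <- co$phenotypes
      prs <- compute_prs(true_prs_model(co$truth), gm)
      fit <- mr_gxe(ph$hba1c, ph$metabolite_1, prs, ph$metformin,
                    ph[, c("age", "sex", "bmi")])
      abs(coef(fit)[["exposure"]] - 0.2)
    }, numeric(1))
  }
  weak <- bias_at(0.05, 92000 + 1:50)     # F ~ 5
  strong <- bias_at(0.158, 93000 + 1:50)  # F ~ 50
  expect_gt(median(weak), median(strong))
})
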