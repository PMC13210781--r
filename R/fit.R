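#' One-sample two-stage least squares with a score-by-treatment interaction
#'
#' Fits the gene-environment interaction Mendelian randomization model
#' \deqn{HbA1c \sim exposure + G{\times}E + covariates \;\|\;
#'       PRS + G{\times}E + covariates}
#' where the endogenous exposure (a metabolite level) is instrumented by
#' its polygenic score and the product term `gxe = prs * treatment` enters
#' both sides as an included exogenous variable. `beta_exposure` is the
#' causal effect of the exposure on the outcome in the whole cohort;
#' `beta_gxe` is the treatment-dependent modification of the genetic effect
#' (zero for every untreated sample by construction).
#'
#' Coefficients solve `(W' P_Z W)^{-1} W' P_Z y` with `W = [1, exposure,
#' gxe, covariates]`, `Z = [1, prs, gxe, covariates]` and `P_Z` the
#' projection onto the instrument space, computed through QR decompositions
#' (no explicit inversion of raw cross-products). The default covariance is
#' the classical 2SLS estimator `sigma^2 (W' P_Z W)^{-1}` with `sigma^2`
#' from the structural residuals `y - W b` (observed exposure, not its
#' first-stage fit); a heteroskedasticity-robust (HC0 sandwich) covariance
#' is available. Rows with any missing value are dropped (complete-case
#' analysis; the count is recorded).
#'
#' @param outcome Numeric outcome vector (HbA1c).
#' @param exposure Numeric endogenous exposure (metabolite level).
#' @param prs Numeric instrument (polygenic score).
#' @param treatment 0/1 treatment vector; both levels must be present (an
#'   all-treated or all-untreated cohort makes the product term collinear
#'   with the score, or zero, and is a hard error).
#' @param covariates Optional covariate table (age, sex, BMI, principal
#'   components ...), treated as exogenous.
#' @param vcov_type `"classical"` (default) or `"robust"`.
#' @param df_type `"t"` (default): p-values and confidence intervals from
#'   the t distribution on `n - k` degrees of freedom; `"normal"`: standard
#'   normal reference.
#' @param standardize Divide the score (and hence the product term) by the
#'   score's standard deviation, putting `beta_gxe` on a per-SD scale for
#'   cross-metabolite comparability? Default `FALSE` (natural scale).
#'
#' @return An object of class `"mrgxe"` with components `coefficients`,
#'   `se`, `vcov`, `p`, `n`, `n_dropped`, `df_residual`, `sigma2`,
#'   `residuals` (structural), `fitted`, `first_stage` (partial F of the
#'   score given the exogenous regressors), `condition` (condition numbers
#'   of the instrument and regressor designs) and the call. Methods:
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `residuals`, `fitted`,
#'   `nobs`.
#' @seealso [wald_test()], [classify_pattern()], [leave_one_out()]
#' @export
mr_gxe <- function(outcome, exposure, prs, treatment, covariates = NULL,
                   vcov_type = c("classical", "robust"),
                   df_type = c("t", "normal"), standardize = FALSE) {
  vcov_type <- match.arg(vcov_type)
  df_type <- match.arg(df_type)
  cl <- match.call()
  n_all <- length(outcome)
  if (length(exposure) != n_all || length(prs) != n_all ||
      length(treatment) != n_all) {
    stop("outcome, exposure, prs and treatment lengths differ")
  }
  Cmat <- as_covariate_matrix(covariates, n_all)
  ok <- !is.na(outcome) & !is.na(exposure) & !is.na(prs) &
    !is.na(treatment) & stats::complete.cases(Cmat)
  n <- sum(ok)
  n_dropped <- n_all - n
  y <- as.numeric(outcome[ok])
  x <- as.numeric(exposure[ok])
  z <- as.numeric(prs[ok])
  trt <- treatment[ok]
  Cmat <- Cmat[ok, , drop = FALSE]
  if (!all(trt %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (all(trt == 0) || all(trt == 1)) {
    stop("treatment is degenerate (all ", trt[1],
         "): the score-by-treatment term is ",
         if (all(trt == 0)) "identically zero" else "collinear with the score")
  }
  if (standardize) {
    s_sd <- stats::sd(z)
    if (s_sd == 0) stop("score has zero variance; cannot standardize")
    z <- z / s_sd
  }
  gxe <- z * trt
  Z <- cbind(`(Intercept)` = 1, prs = z, gxe = gxe, Cmat)
  W <- cbind(`(Intercept)` = 1, exposure = x, gxe = gxe, Cmat)
  k <- ncol(W)
  if (n < k + 1L) stop("too few complete cases (", n, ") for ", k,
                       " coefficients")
  qz <- check_full_rank(Z, "instrument")
  W_hat <- qr.fitted(qz, W)
  colnames(W_hat) <- colnames(W)
  qw <- check_full_rank(W_hat, "projected regressor")
  beta <- qr.coef(qw, y)
  fitted <- as.vector(W %*% beta)
  res <- y - fitted
  df_residual <- n - k
  sigma2 <- sum(res^2) / df_residual
  bread <- xtx_inverse(qw)  # (W' P_Z W)^{-1}
  if (vcov_type == "classical") {
    V <- sigma2 * bread
  } else {
    meat <- crossprod(W_hat * res)
    V <- bread %*% meat %*% bread
  }
  dimnames(V) <- list(colnames(W), colnames(W))
  se <- sqrt(diag(V))
  tval <- beta / se
  p <- if (df_type == "t") 2 * stats::pt(-abs(tval), df_residual) else
    2 * stats::pnorm(-abs(tval))
  fs <- first_stage(z, x, cbind(gxe = gxe, Cmat))
  structure(list(
    coefficients = beta, se = se, vcov = V, t = tval, p = p,
    n = n, n_dropped = n_dropped, df_residual = df_residual,
    sigma2 = sigma2, residuals = res, fitted = fitted,
    first_stage = fs,
    condition = c(instrument = kappa(Z, exact = FALSE),
                  regressor = kappa(W, exact = FALSE)),
    vcov_type = vcov_type, df_type = df_type, standardize = standardize,
    call = cl), class = "mrgxe")
}

#' @export
print.mrgxe <- function(x, digits = 4, ...) {
  cat("One-sample MR-GxE two-stage least squares fit\n")
  cat("  n =", x$n,
      if (x$n_dropped > 0) paste0("(", x$n_dropped, " incomplete rows dropped)"),
      "\n")
  cat(sprintf("  beta_exposure = %.*g (SE %.*g, p = %.3g)\n", digits,
              x$coefficients[["exposure"]], digits, x$se[["exposure"]],
              x$p[["exposure"]]))
  cat(sprintf("  beta_gxe      = %.*g (SE %.*g, p = %.3g)\n", digits,
              x$coefficients[["gxe"]], digits, x$se[["gxe"]],
              x$p[["gxe"]]))
  cat(sprintf("  first-stage F = %.4g\n", x$first_stage$f_statistic))
  invisible(x)
}

#' @export
summary.mrgxe <- function(object, alpha = 0.05, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$t,
               `Pr(>|t|)` = object$p)
  structure(list(coefficients = tab, n = object$n,
                 n_dropped = object$n_dropped, sigma2 = object$sigma2,
                 first_stage = object$first_stage,
                 vcov_type = object$vcov_type, df_type = object$df_type,
                 pattern = classify_pattern(object, alpha = alpha),
                 alpha = alpha, call = object$call),
            class = "summary.mrgxe")
}

#' @export
print.summary.mrgxe <- function(x, ...) {
  cat("One-sample MR-GxE two-stage least squares\n\nCall:\n  ")
  print(x$call)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nn = %d (%d dropped); residual variance %.5g; %s SEs, %s reference\n",
              x$n, x$n_dropped, x$sigma2, x$vcov_type, x$df_type))
  cat(sprintf("First-stage partial F = %.4g (partial R2 = %.4g)\n",
              x$first_stage$f_statistic, x$first_stage$r2_first_stage))
  cat(sprintf("Effect pattern at alpha = %g: %s\n", x$alpha, x$pattern))
  invisible(x)
}

#' @export
coef.mrgxe <- function(object, ...) object$coefficients

#' @export
vcov.mrgxe <- function(object, ...) object$vcov

#' @export
residuals.mrgxe <- function(object, ...) object$residuals

#' @export
fitted.mrgxe <- function(object, ...) object$fitted

#' @export
nobs.mrgxe <- function(object, ...) object$n

#' @export
confint.mrgxe <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  q <- if (object$df_type == "t") {
    stats::qt(1 - (1 - level) / 2, object$df_residual)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  out <- cbind(est[parm] - q * object$se[parm],
               est[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' Wald test of a single fitted coefficient
#'
#' `t = estimate / SE`, two-sided p-value from the fit's reference
#' distribution (t on `n - k` degrees of freedom by default).
#'
#' @param fit An [mr_gxe()] fit.
#' @param coefficient Coefficient name, e.g. `"gxe"` or `"exposure"`.
#' @return List: `statistic`, `p`.
#' @export
wald_test <- function(fit, coefficient = "gxe") {
  stopifnot(inherits(fit, "mrgxe"))
  if (!coefficient %in% names(fit$coefficients)) {
    stop("no coefficient named '", coefficient, "'")
  }
  if (fit$se[[coefficient]] == 0) stop("standard error is zero")
  list(statistic = unname(fit$t[[coefficient]]),
       p = unname(fit$p[[coefficient]]))
}
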