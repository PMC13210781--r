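#' First-stage instrument strength
#'
#' Partial F-statistic for adding the polygenic score to the covariate-only
#' regression of the exposure:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - k_full))` with one
#' numerator degree of freedom. A perfect instrument (zero full-model
#' residual) reports `Inf`. Values at or below 10 conventionally indicate a
#' weak instrument.
#'
#' @param prs Numeric score vector.
#' @param exposure Numeric metabolite vector.
#' @param covariates Optional covariate table.
#' @return List: `f_statistic`, `r2_first_stage` (partial R-squared of the
#'   score), `df1`, `df2`, `p`, `n`.
#' @export
first_stage <- function(prs, exposure, covariates = NULL) {
  n_all <- length(exposure)
  C <- cbind(`(Intercept)` = rep(1, n_all),
             as_covariate_matrix(covariates, n_all))
  ok <- stats::complete.cases(C) & !is.na(exposure) & !is.na(prs)
  y <- exposure[ok]
  C <- C[ok, , drop = FALSE]
  z <- prs[ok]
  n <- length(y)
  k_full <- ncol(C) + 1L
  if (n < k_full + 2L) stop("too few complete cases for the first stage")
  qc <- check_full_rank(C, "covariate")
  X_full <- cbind(C, prs = z)
  qf <- check_full_rank(X_full, "first-stage")
  rss_r <- sum(qr.resid(qc, y)^2)
  rss_f <- sum(qr.resid(qf, y)^2)
  df2 <- n - k_full
  if (rss_f <= .Machine$double.eps * max(rss_r, 1)) {
    f <- Inf
    r2 <- 1
    p <- 0
  } else {
    f <- (rss_r - rss_f) / (rss_f / df2)
    r2 <- (rss_r - rss_f) / rss_r
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  list(f_statistic = f, r2_first_stage = r2, df1 = 1L, df2 = df2, p = p,
       n = n)
}

#' Outcome screen of a candidate instrument
#'
#' p-value of the score coefficient in a least-squares fit of the outcome
#' on score plus covariates. The default `"marginal"` mode is the literal
#' exclusion rule (a score associated with the outcome is rejected); the
#' `"conditional"` mode additionally adjusts for the exposure, which keeps
#' a strong valid instrument from being rejected purely through its path via
#' the exposure. The mode in force should be reported with any diagnostics.
#'
#' @param prs Score vector.
#' @param outcome Outcome vector (HbA1c).
#' @param covariates Optional covariate table.
#' @param exposure Exposure vector, required for `mode = "conditional"`.
#' @param mode `"marginal"` (default) or `"conditional"`.
#' @return The two-sided p-value of the score coefficient.
#' @export
outcome_screen <- function(prs, outcome, covariates = NULL, exposure = NULL,
                           mode = c("marginal", "conditional")) {
  mode <- match.arg(mode)
  n <- length(outcome)
  X <- cbind(`(Intercept)` = rep(1, n), as_covariate_matrix(covariates, n))
  if (mode == "conditional") {
    if (is.null(exposure)) stop("conditional mode requires the exposure")
    X <- cbind(X, exposure = as.numeric(exposure))
  }
  fit <- ols_fit(outcome, cbind(X, prs = as.numeric(prs)), "outcome screen")
  unname(fit$p[["prs"]])
}

#' Collider screen: score-treatment association
#'
#' p-value of the association between the score and the binary treatment —
#' the slope test in a regression of score on treatment, equivalent to the
#' equal-variance two-sample t-test of score between treatment groups.
#' Treatment assignment driven by the instrument would open a collider path
#' when the analysis conditions on treatment.
#'
#' @param prs Score vector.
#' @param treatment 0/1 vector with both levels present.
#' @return Two-sided p-value.
#' @export
collider_screen <- function(prs, treatment) {
  ok <- !is.na(prs) & !is.na(treatment)
  trt <- treatment[ok]
  if (!all(trt %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (length(unique(trt)) < 2L) {
    stop("treatment has a single level; collider screen undefined")
  }
  fit <- ols_fit(prs[ok], cbind(`(Intercept)` = 1, treatment = trt),
                 "collider screen")
  unname(fit$p[["treatment"]])
}

#' Validate a polygenic score as an instrument
#'
#' Runs the three instrument screens and applies the retention rule:
#' first-stage F strictly above `f_min`, and both the outcome screen and
#' the collider screen at or above `p_screen`.
#'
#' @param prs Score vector.
#' @param exposure Metabolite vector.
#' @param outcome Outcome vector (HbA1c).
#' @param treatment 0/1 treatment vector.
#' @param covariates Optional covariate table (used by the first stage and
#'   the outcome screen).
#' @param f_min Weak-instrument bound (strict `>` retains); default 10.
#' @param p_screen Screen significance level; default 0.05.
#' @param outcome_mode Passed to [outcome_screen()].
#' @param metabolite Name recorded on the diagnostics.
#' @return A one-row data frame of class `"instrument_diagnostics"`:
#'   `metabolite`, `f_statistic`, `r2_first_stage`, `p_outcome`,
#'   `p_treatment`, `outcome_mode`, `retained`, `reasons`.
#' @export
validate_instrument <- function(prs, exposure, outcome, treatment,
                                covariates = NULL, f_min = 10,
                                p_screen = 0.05,
                                outcome_mode = c("marginal", "conditional"),
                                metabolite = "metabolite") {
  outcome_mode <- match.arg(outcome_mode)
  fs <- first_stage(prs, exposure, covariates)
  p_out <- outcome_screen(prs, outcome, covariates,
                          exposure = exposure, mode = outcome_mode)
  p_trt <- collider_screen(prs, treatment)
  reasons <- c(if (!(fs$f_statistic > f_min)) "weak_instrument",
               if (p_out < p_screen) "outcome_assoc",
               if (p_trt < p_screen) "treatment_assoc")
  out <- data.frame(metabolite = metabolite,
                    f_statistic = fs$f_statistic,
                    r2_first_stage = fs$r2_first_stage,
                    p_outcome = p_out, p_treatment = p_trt,
                    outcome_mode = outcome_mode,
                    retained = length(reasons) == 0L,
                    reasons = paste(reasons, collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("instrument_diagnostics", "data.frame")
  out
}
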