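#' Classify the treatment-dependence pattern of a fitted effect pair
#'
#' Maps the (sign, significance) structure of the baseline causal estimate
#' `beta_exposure` and the interaction estimate `beta_gxe` to a qualitative
#' label, for an outcome whose positive direction is harmful (higher HbA1c
#' is worse glycaemic control):
#'
#' * `"strengthened"` — both significant at `alpha`, same sign: treatment
#'   amplifies the baseline genetic effect.
#' * `"reversed"` — both significant, opposite signs, harmful baseline
#'   (`beta_exposure > 0`): treatment turns a deleterious genetic effect
#'   toward benefit.
#' * `"attenuated"` — both significant, opposite signs, protective baseline
#'   (`beta_exposure < 0`): treatment erodes a protective genetic effect.
#' * `"conditional_only"` — baseline non-significant, interaction
#'   significant: a genetic effect visible only under treatment.
#' * `"none"` — interaction non-significant.
#'
#' Because the interaction coefficient sits on the score scale and the
#' baseline coefficient on the exposure scale, their magnitudes are not
#' directly comparable; opposite-sign cases are therefore resolved by the
#' direction of the baseline effect, not by which estimate is larger.
#'
#' @param fit An [mr_gxe()] fit; alternatively supply the four numeric
#'   arguments directly (vectorised, e.g. over the rows of a results
#'   table).
#' @param beta_exposure,p_exposure,beta_gxe,p_gxe Estimates and two-sided
#'   p-values; ignored when `fit` is given.
#' @param alpha Significance level, default 0.05.
#' @return Character vector of labels among `strengthened`, `reversed`,
#'   `attenuated`, `conditional_only`, `none`.
#' @export
classify_pattern <- function(fit = NULL, beta_exposure = NULL,
                             p_exposure = NULL, beta_gxe = NULL,
                             p_gxe = NULL, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (inherits(fit, "mrgxe")) {
    beta_exposure <- fit$coefficients[["exposure"]]
    p_exposure <- fit$p[["exposure"]]
    beta_gxe <- fit$coefficients[["gxe"]]
    p_gxe <- fit$p[["gxe"]]
  } else if (!is.null(fit)) {
    stop("'fit' must be an mr_gxe() fit (or NULL when estimates are given)")
  }
  if (is.null(beta_exposure) || is.null(p_exposure) || is.null(beta_gxe) ||
      is.null(p_gxe)) {
    stop("supply a fit or all four of beta_exposure, p_exposure, ",
         "beta_gxe, p_gxe")
  }
  n <- max(length(beta_exposure), length(beta_gxe))
  be <- rep_len(beta_exposure, n); pe <- rep_len(p_exposure, n)
  bg <- rep_len(beta_gxe, n); pg <- rep_len(p_gxe, n)
  vapply(seq_len(n), function(i) {
    if (is.na(pg[i]) || pg[i] >= alpha) return("none")
    if (is.na(pe[i]) || pe[i] >= alpha) return("conditional_only")
    if (sign(be[i]) == sign(bg[i])) return("strengthened")
    if (be[i] > 0) "reversed" else "attenuated"
  }, character(1))
}

#' Multiple-testing adjustment across metabolites
#'
#' @param pvalues Numeric vector of raw p-values.
#' @param method `"none"`, `"bonferroni"` or `"benjamini_hochberg"`.
#' @return Adjusted p-values, monotone in the input and clipped at 1.
#' @export
adjust_multiplicity <- function(pvalues,
                                method = c("none", "bonferroni",
                                           "benjamini_hochberg")) {
  method <- match.arg(method)
  stats::p.adjust(pvalues, method = switch(method, none = "none",
                                           bonferroni = "bonferroni",
                                           benjamini_hochberg = "BH"))
}
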