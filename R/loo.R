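#' Leave-one-out sensitivity analysis of the interaction estimate
#'
#' Drops each score variant in turn, rebuilds the polygenic score and the
#' score-by-treatment term without it, refits the two-stage least-squares
#' model, and records the change in the interaction estimate together with
#' sign-flip and significance-flip flags. A single variant whose removal
#' flips the sign or the significance of `beta_gxe` is marked influential —
#' the signature of a variant driving the interaction through a pathway of
#' its own (horizontal pleiotropy) rather than through the shared score.
#'
#' @param model A [prs_model()] with at least two variants.
#' @param gm The [genotype_matrix()].
#' @param outcome,exposure,treatment Per-sample vectors as in [mr_gxe()].
#' @param covariates Optional covariate table.
#' @param alpha Significance level for the flip flags.
#' @param ... Further arguments passed to [mr_gxe()].
#' @return A data frame of class `"mrgxe_loo"`, one row per dropped
#'   variant: `dropped_variant_id`, `beta_gxe`, `se_gxe`, `p_gxe`,
#'   `delta_beta_gxe`, `sign_flip`, `significance_flip`, `influential`.
#'   The full-model fit is attached as attribute `"full_fit"`.
#' @export
leave_one_out <- function(model, gm, outcome, exposure, treatment,
                          covariates = NULL, alpha = 0.05, ...) {
  stopifnot(inherits(model, "prs_model"))
  if (nrow(model) < 2L) {
    stop("leave-one-out is undefined for a single-variant model")
  }
  full_prs <- compute_prs(model, gm)
  full <- mr_gxe(outcome, exposure, full_prs, treatment, covariates, ...)
  b_full <- full$coefficients[["gxe"]]
  sig_full <- full$p[["gxe"]] < alpha
  rows <- lapply(seq_len(nrow(model)), function(i) {
    sub <- model[-i, , drop = FALSE]
    class(sub) <- class(model)
    attr(sub, "metabolite") <- attr(model, "metabolite")
    prs_i <- compute_prs(sub, gm)
    fit <- mr_gxe(outcome, exposure, prs_i, treatment, covariates, ...)
    b <- fit$coefficients[["gxe"]]
    p <- fit$p[["gxe"]]
    data.frame(dropped_variant_id = model$variant_id[i],
               beta_gxe = b, se_gxe = fit$se[["gxe"]], p_gxe = p,
               delta_beta_gxe = b - b_full,
               sign_flip = sign(b) != sign(b_full),
               significance_flip = (p < alpha) != sig_full,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$influential <- out$sign_flip | out$significance_flip
  class(out) <- c("mrgxe_loo", "data.frame")
  attr(out, "full_fit") <- full
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.mrgxe_loo <- function(x, ...) {
  full <- attr(x, "full_fit")
  cat("Leave-one-out sensitivity over", nrow(x), "score variants\n")
  cat(sprintf("  full-model beta_gxe = %.4g (p = %.3g)\n",
              full$coefficients[["gxe"]], full$p[["gxe"]]))
  infl <- x$dropped_variant_id[x$influential]
  if (length(infl) == 0L) {
    cat("  no influential variants at alpha =", attr(x, "alpha"), "\n")
  } else {
    cat("  influential:", paste(infl, collapse = ", "), "\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}
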