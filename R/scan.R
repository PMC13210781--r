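#' Per-variant association scan of a metabolite exposure
#'
#' For each variant, ordinary least squares of the exposure on the
#' ALT-allele dosage plus covariates (by convention age, sex, BMI and the
#' leading genotype principal components), over the samples non-missing at
#' that variant; the reported p-value is the two-sided t-test on the dosage
#' coefficient. Monomorphic variants are flagged with `NA` statistics and
#' never become score candidates.
#'
#' @param gm A [genotype_matrix()].
#' @param exposure Numeric vector of metabolite levels, one per sample.
#' @param covariates Optional data frame / matrix of adjustment covariates.
#' @return Data frame (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `beta`, `se`, `p`, `n`), one row per variant, in matrix order.
#' @export
snp_scan <- function(gm, exposure, covariates = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_samples(gm)
  if (length(exposure) != n) stop("exposure length does not match samples")
  C <- cbind(`(Intercept)` = rep(1, n), as_covariate_matrix(covariates, n))
  base_ok <- stats::complete.cases(C) & !is.na(exposure)
  d <- gm$dosage[base_ok, , drop = FALSE]
  y <- exposure[base_ok]
  C <- C[base_ok, , drop = FALSE]
  check_full_rank(C, "covariate")
  m <- ncol(d)
  beta <- se <- p <- rep(NA_real_, m)
  nn <- integer(m)
  has_na <- colSums(is.na(d)) > 0L
  # Fast path (no missing calls): residualise exposure and all dosages on
  # the covariates once (Frisch-Waugh), then per-variant simple slopes.
  fast <- which(!has_na)
  if (length(fast) > 0L) {
    qc <- qr(C)
    yr <- qr.resid(qc, y)
    gr <- qr.resid(qc, d[, fast, drop = FALSE])
    gtg <- colSums(gr^2)
    mono <- matrixStats_colVars(d[, fast, drop = FALSE]) == 0
    gty <- colSums(gr * yr)
    df <- length(y) - ncol(C) - 1L
    b <- gty / gtg
    rss <- pmax(sum(yr^2) - b^2 * gtg, 0)
    s <- sqrt(rss / df / gtg)
    pv <- 2 * stats::pt(-abs(b / s), df)
    bad <- mono | gtg <= 0
    b[bad] <- s[bad] <- pv[bad] <- NA_real_
    beta[fast] <- b; se[fast] <- s; p[fast] <- pv
    nn[fast] <- length(y)
  }
  for (j in which(has_na)) {
    ok <- !is.na(d[, j])
    nn[j] <- sum(ok)
    g <- d[ok, j]
    if (nn[j] < ncol(C) + 2L || stats::var(g) == 0) next
    fit <- ols_fit(y[ok], cbind(dosage = g, C[ok, , drop = FALSE]),
                   "association")
    beta[j] <- fit$coef[["dosage"]]
    se[j] <- fit$se[["dosage"]]
    p[j] <- fit$p[["dosage"]]
  }
  data.frame(variant_id = gm$variants$id, chrom = gm$variants$chrom,
             pos = gm$variants$pos,
             effect_allele = gm$variants$effect_allele,
             beta = beta, se = se, p = p, n = nn,
             stringsAsFactors = FALSE)
}

# colVars without a dependency; x has no NAs on this path
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1L)
}

#' Select score candidates by association p-value
#'
#' Retains associations with `p < p_max` (strict inequality, so a p-value
#' exactly at the threshold is excluded). Undefined (monomorphic) results
#' are dropped.
#'
#' @param assoc Association data frame from [snp_scan()].
#' @param p_max Significance threshold; default the conventional
#'   metabolome-wide 5e-6.
#' @return The qualifying subset of `assoc`.
#' @export
select_candidates <- function(assoc, p_max = 5e-6) {
  out <- assoc[!is.na(assoc$p) & assoc$p < p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of association candidates
#'
#' Repeatedly promotes the remaining candidate with the smallest p-value to
#' index variant and discards all remaining candidates on the same
#' chromosome within `window_kb` kilobases whose r-squared with the index
#' exceeds `r2_max`. Ties on p are broken by chromosome then position
#' (smaller first) for determinism.
#'
#' @param candidates Association data frame (rows of [snp_scan()] output).
#' @param gm The [genotype_matrix()] the candidates came from.
#' @param r2_max LD threshold (strictly above is discarded).
#' @param window_kb Window half-width in kilobases.
#' @return The index-variant rows of `candidates`, in genomic order.
#' @export
clump <- function(candidates, gm, r2_max = 0.001, window_kb = 500) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(candidates) == 0L) return(candidates)
  col <- match(candidates$variant_id, gm$variants$id)
  if (anyNA(col)) {
    stop("candidate variant(s) absent from genotype matrix: ",
         paste(candidates$variant_id[is.na(col)], collapse = ", "))
  }
  chrom_num <- suppressWarnings(as.numeric(sub("^chr", "", candidates$chrom)))
  ord <- order(candidates$p, chrom_num, candidates$pos)
  window <- window_kb * 1000
  remaining <- ord
  index <- integer(0)
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    index <- c(index, i)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    same <- candidates$chrom[remaining] == candidates$chrom[i] &
      abs(candidates$pos[remaining] - candidates$pos[i]) <= window
    if (any(same)) {
      r2 <- vapply(remaining[same], function(j) {
        suppressWarnings(ld_r2(gm$dosage[, col[i]], gm$dosage[, col[j]]))
      }, numeric(1))
      kill <- remaining[same][!is.na(r2) & r2 > r2_max]
      remaining <- setdiff(remaining, kill)
    }
  }
  out <- candidates[sort(index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pleiotropy and blocklist screening of score candidates
#'
#' Removes candidates showing a marginal association (covariate-free simple
#' regression on dosage, two-sided t-test) at `p < p_screen` with the
#' outcome or with any measured confounder (age, sex, BMI — sex screened by
#' the same linear model), and candidates present in the user-supplied
#' blocklist of variants previously reported associated with the outcome.
#'
#' @param candidates Association data frame (e.g. [clump()] output).
#' @param gm The [genotype_matrix()].
#' @param outcome Numeric outcome vector (HbA1c), one per sample.
#' @param confounders Data frame / matrix of measured confounders to screen
#'   against (columns screened one at a time).
#' @param blocklist Character vector of variant ids to remove a priori.
#' @param p_screen Screening threshold (strict `<` removes).
#' @return The surviving subset of `candidates`, with attribute `"removed"`:
#'   a data frame (`variant_id`, `reason`) naming each removal, reasons
#'   `blocklist` or `assoc_<trait>` (semicolon-joined when several apply).
#' @export
pleiotropy_filter <- function(candidates, gm, outcome, confounders,
                              blocklist = character(0), p_screen = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_samples(gm)
  traits <- c(list(hba1c = as.numeric(outcome)),
              as.list(as.data.frame(as_covariate_matrix(confounders, n))))
  col <- match(candidates$variant_id, gm$variants$id)
  if (anyNA(col)) {
    stop("candidate variant(s) absent from genotype matrix: ",
         paste(candidates$variant_id[is.na(col)], collapse = ", "))
  }
  reasons <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    g <- gm$dosage[, col[i]]
    r <- character(0)
    if (candidates$variant_id[i] %in% blocklist) r <- c(r, "blocklist")
    for (tn in names(traits)) {
      p <- marginal_assoc_p(g, traits[[tn]])
      if (!is.na(p) && p < p_screen) r <- c(r, paste0("assoc_", tn))
    }
    reasons[[i]] <- r
  }
  removed <- lengths(reasons) > 0L
  out <- candidates[!removed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    variant_id = candidates$variant_id[removed],
    reason = vapply(reasons[removed], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  out
}

# p-value of the slope in trait ~ dosage over complete pairs
marginal_assoc_p <- function(g, trait) {
  ok <- !is.na(g) & !is.na(trait)
  n <- sum(ok)
  if (n < 3L) return(NA_real_)
  x <- g[ok]; y <- trait[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tval), n - 2)
}

#' Polygenic-score model
#'
#' A set of variant weights defining one metabolite instrument. Weights are
#' the association-scan betas on the counted effect allele (ALT by
#' convention).
#'
#' @param metabolite Metabolite name.
#' @param variant_id Character vector of unique variant ids.
#' @param effect_allele `"alt"` or `"ref"` per variant.
#' @param weight Numeric weights (metabolite units per effect allele).
#' @return Object of class `"prs_model"` (a data frame with metadata).
#' @export
prs_model <- function(metabolite, variant_id, effect_allele, weight) {
  if (anyDuplicated(variant_id)) stop("variant ids must be unique")
  if (!all(effect_allele %in% c("alt", "ref"))) {
    stop('effect_allele must be "alt" or "ref"')
  }
  if (length(variant_id) != length(weight) ||
      length(variant_id) != length(effect_allele)) {
    stop("variant_id, effect_allele and weight lengths differ")
  }
  structure(
    data.frame(variant_id = as.character(variant_id),
               effect_allele = as.character(effect_allele),
               weight = as.numeric(weight), stringsAsFactors = FALSE),
    metabolite = as.character(metabolite),
    class = c("prs_model", "data.frame"))
}

#' Build a score model from surviving scan candidates
#'
#' @param candidates Filtered association data frame.
#' @param metabolite Metabolite name recorded on the model.
#' @return A [prs_model()] with weights taken from the scan betas.
#' @export
prs_model_from_scan <- function(candidates, metabolite) {
  prs_model(metabolite = metabolite,
            variant_id = candidates$variant_id,
            effect_allele = candidates$effect_allele,
            weight = candidates$beta)
}

#' Compute per-sample polygenic scores
#'
#' Unaveraged weighted sum of effect-allele dosages (the conventional "sum"
#' score): for each sample, the sum over model variants of weight times
#' dosage, where dosage counts the model's effect allele (`2 - d` when the
#' effect allele is REF) and a missing call is replaced by that variant's
#' mean dosage over non-missing samples. No allele-frequency centring is
#' applied.
#'
#' @param model A [prs_model()] whose variants must all be present in `gm`.
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of scores, one per sample.
#' @export
compute_prs <- function(model, gm) {
  stopifnot(inherits(model, "prs_model"), inherits(gm, "genotype_matrix"))
  if (nrow(model) == 0L) stop("empty score model")
  col <- match(model$variant_id, gm$variants$id)
  if (anyNA(col)) {
    stop("model variant(s) absent from genotype matrix: ",
         paste(model$variant_id[is.na(col)], collapse = ", "))
  }
  d <- gm$dosage[, col, drop = FALSE]
  flip <- model$effect_allele == "ref"
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    if (anyNA(cm)) {
      stop("variant(s) with no genotyped samples: ",
           paste(model$variant_id[is.na(cm)], collapse = ", "))
    }
    na_at <- which(is.na(d), arr.ind = TRUE)
    d[na_at] <- cm[na_at[, 2L]]
  }
  score <- as.vector(d %*% model$weight)
  names(score) <- gm$sample_ids
  score
}
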