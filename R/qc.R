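#' Minor-allele frequency from dosages
#'
#' @param dosages Numeric vector of ALT-allele dosages (0/1/2, `NA` allowed).
#' @return MAF in [0, 0.5]: `min(f, 1 - f)` where `f` is the ALT-allele
#'   frequency over non-missing calls.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages are missing")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom Pearson chi-square test of observed genotype counts
#' against Hardy-Weinberg proportions at the estimated allele frequency.
#' Monomorphic input gives chi-square 0, p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return The p-value; the chi-square statistic is attached as attribute
#'   `"statistic"`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  q <- (2 * n_aa + n_Aa) / (2 * n)  # alternate-allele frequency
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  nz <- expected > 0
  chisq <- sum((counts[nz] - expected[nz])^2 / expected[nz])
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(p, statistic = chisq)
}

hwe_p_from_dosages <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  as.numeric(hwe_test(sum(d == 0), sum(d == 1), sum(d == 2)))
}

#' Variant-level quality control
#'
#' Applies the standard variant filters as a conjunction: autosomal
#' chromosome, MAF at or above `maf_min`, Hardy-Weinberg p-value at or
#' above `hwe_min`, and call rate at or above `cr_min`. All thresholds are
#' removal criteria read with strict inequality (a variant with MAF exactly
#' `maf_min` is retained), and filter order is irrelevant.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min,hwe_min,cr_min Removal thresholds: variants with
#'   MAF < `maf_min`, HWE p < `hwe_min` or call rate < `cr_min` are dropped.
#' @param autosomal_only Drop variants outside chromosomes 1-22?
#' @return A list with `genotypes` (the filtered matrix) and `report`, a
#'   per-variant data frame (`variant_id`, `maf`, `hwe_p`, `call_rate`,
#'   `autosomal`, `passed`, `reasons`). An empty post-filter matrix is a
#'   warning, not an error.
#' @export
variant_qc <- function(gm, maf_min = 0.05, hwe_min = 1e-6, cr_min = 0.90,
                       autosomal_only = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  nonmiss <- colSums(!is.na(d))
  call_rate <- nonmiss / nrow(d)
  maf <- vapply(seq_len(ncol(d)), function(j) {
    if (nonmiss[j] == 0) NA_real_ else compute_maf(d[, j])
  }, numeric(1))
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (nonmiss[j] == 0) NA_real_ else hwe_p_from_dosages(d[, j])
  }, numeric(1))
  autosomal <- chrom_is_autosomal(gm$variants$chrom)
  fail_auto <- autosomal_only & !autosomal
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- is.na(hwe_p) | hwe_p < hwe_min
  fail_cr <- call_rate < cr_min
  passed <- !(fail_auto | fail_maf | fail_hwe | fail_cr)
  reasons <- vapply(seq_len(ncol(d)), function(j) {
    r <- c(if (fail_auto[j]) "non_autosomal",
           if (fail_maf[j]) "low_maf",
           if (fail_hwe[j]) "hwe_fail",
           if (fail_cr[j]) "low_call_rate")
    paste(r, collapse = ";")
  }, character(1))
  report <- data.frame(variant_id = gm$variants$id, maf = maf, hwe_p = hwe_p,
                       call_rate = call_rate, autosomal = autosomal,
                       passed = passed, reasons = reasons,
                       stringsAsFactors = FALSE)
  out <- subset_variants(gm, gm$variants$id[passed])
  if (ncol(out$dosage) == 0L) {
    warning("no variants pass quality control")
  }
  list(genotypes = out, report = report)
}

#' Squared linkage-disequilibrium correlation between two variants
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples.
#' The measure is symmetric, sign-free, and invariant to affine recoding of
#' either dosage vector.
#'
#' @param v1,v2 Dosage vectors of equal length.
#' @return r-squared in [0, 1], or `NA` (with a warning) when either vector
#'   has zero variance over the complete pairs.
#' @export
ld_r2 <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("dosage vectors differ in length")
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 2L) stop("fewer than two pairwise-complete samples")
  x <- v1[ok]; y <- v2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero dosage variance: LD r-squared undefined")
    return(NA_real_)
  }
  min(stats::cor(x, y)^2, 1)
}

#' Greedy LD pruning
#'
#' Left-to-right scan in position order within each chromosome: a variant is
#' dropped when its r-squared with any already-retained variant at most
#' `window_kb` kilobases away exceeds `r2_max`. Of a correlated pair the
#' earlier position is kept, making the result deterministic. The retained
#' set therefore has all within-window pairwise r-squared at or below
#' `r2_max`.
#'
#' @param gm A [genotype_matrix()].
#' @param r2_max Maximum tolerated r-squared (strictly above is pruned).
#' @param window_kb Window half-width in kilobases.
#' @return Character vector of retained variant ids, in genomic order.
#' @export
ld_prune <- function(gm, r2_max = 0.5, window_kb = 500) {
  stopifnot(inherits(gm, "genotype_matrix"))
  window <- window_kb * 1000
  kept <- character(0)
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)  # positions already sorted
    retained <- integer(0)
    for (j in idx) {
      near <- retained[abs(gm$variants$pos[retained] - gm$variants$pos[j]) <=
                         window]
      drop <- FALSE
      for (k in near) {
        r2 <- suppressWarnings(ld_r2(gm$dosage[, k], gm$dosage[, j]))
        if (!is.na(r2) && r2 > r2_max) { drop <- TRUE; break }
      }
      if (!drop) retained <- c(retained, j)
    }
    kept <- c(kept, gm$variants$id[retained])
  }
  kept
}

#' Genotype principal components
#'
#' Column-standardises dosages (mean 0, unit variance; missing calls
#' replaced by the column mean, i.e. zero after centring), drops
#' zero-variance variants, and takes the singular value decomposition.
#' Scores are ordered by decreasing eigenvalue; each component's sign is
#' fixed so that its largest-magnitude variant loading is positive.
#'
#' @param gm A [genotype_matrix()] (typically LD-pruned first).
#' @param n_pcs Number of components, at most `min(n_samples, n_variants)`.
#' @return Numeric matrix of scores (samples by `n_pcs`), columns named
#'   `PC1`, `PC2`, ...
#' @export
compute_pcs <- function(gm, n_pcs = 4L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_pcs <- as.integer(n_pcs)
  d <- gm$dosage
  if (n_pcs > min(dim(d))) {
    stop("n_pcs exceeds min(n_samples, n_variants)")
  }
  if (n_pcs == 0L) {
    return(matrix(numeric(0), nrow = nrow(d), ncol = 0L,
                  dimnames = list(gm$sample_ids, NULL)))
  }
  cm <- colMeans(d, na.rm = TRUE)
  if (anyNA(d)) {
    na_at <- which(is.na(d), arr.ind = TRUE)
    d[na_at] <- cm[na_at[, 2L]]
  }
  d <- sweep(d, 2L, colMeans(d))
  sds <- sqrt(colSums(d^2) / (nrow(d) - 1L))
  keep <- sds > 0
  d <- sweep(d[, keep, drop = FALSE], 2L, sds[keep], "/")
  if (ncol(d) < n_pcs) {
    stop("fewer polymorphic variants than requested components")
  }
  sv <- svd(d, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)] * flip, n_pcs, n_pcs)
  dimnames(scores) <- list(gm$sample_ids, paste0("PC", seq_len(n_pcs)))
  scores
}
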