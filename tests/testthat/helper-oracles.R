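# Independent brute-force oracles. These implement the textbook
# definitions directly (dense projection matrices, literal greedy scans)
# and share no code with the implementation paths they check.

# Explicit 2SLS: form P_Z densely, solve the normal equations with solve().
oracle_2sls <- function(y, W, Z) {
  PZ <- Z %*% solve(crossprod(Z)) %*% t(Z)
  A <- t(W) %*% PZ %*% W
  beta <- solve(A, t(W) %*% PZ %*% y)
  res <- y - W %*% beta
  n <- length(y)
  k <- ncol(W)
  sigma2 <- sum(res^2) / (n - k)
  V <- sigma2 * solve(A)
  list(coef = drop(beta), se = sqrt(diag(V)), vcov = V, sigma2 = sigma2)
}

# Literal greedy clumping: smallest p becomes index, discard same-chromosome
# candidates within the window at r^2 above threshold, repeat.
oracle_clump_ids <- function(cand, gm, r2_max, window_kb) {
  window <- window_kb * 1000
  chrom_num <- as.numeric(cand$chrom)
  remaining <- cand[order(cand$p, chrom_num, cand$pos), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    idx <- remaining[1L, ]
    kept <- c(kept, idx$variant_id)
    remaining <- remaining[-1L, , drop = FALSE]
    if (nrow(remaining) == 0L) break
    drop <- logical(nrow(remaining))
    for (j in seq_len(nrow(remaining))) {
      if (remaining$chrom[j] == idx$chrom &&
          abs(remaining$pos[j] - idx$pos) <= window) {
        x <- gm$dosage[, idx$variant_id]
        z <- gm$dosage[, remaining$variant_id[j]]
        ok <- !is.na(x) & !is.na(z)
        if (sum(ok) >= 2 && var(x[ok]) > 0 && var(z[ok]) > 0) {
          if (cor(x[ok], z[ok])^2 > r2_max) drop[j] <- TRUE
        }
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Literal greedy positional pruning scan.
oracle_prune_ids <- function(gm, r2_max, window_kb) {
  window <- window_kb * 1000
  kept <- character(0)
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    retained <- integer(0)
    for (j in idx) {
      drop <- FALSE
      for (k in retained) {
        if (abs(gm$variants$pos[k] - gm$variants$pos[j]) <= window) {
          x <- gm$dosage[, k]; z <- gm$dosage[, j]
          ok <- !is.na(x) & !is.na(z)
          if (sum(ok) >= 2 && var(x[ok]) > 0 && var(z[ok]) > 0 &&
              cor(x[ok], z[ok])^2 > r2_max) {
            drop <- TRUE
            break
          }
        }
      }
      if (!drop) retained <- c(retained, j)
    }
    kept <- c(kept, gm$variants$id[retained])
  }
  sort(kept)
}
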