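# Shared least-squares internals. k is always tiny (a handful of
# covariates), so QR on the design is cheap and numerically safe.

check_full_rank <- function(X, label = "design") {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("column", seq_len(ncol(X)))
    bad <- nm[q$pivot[(q$rank + 1L):ncol(X)]]
    stop(label, " matrix is rank deficient; linearly dependent column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  q
}

# Unscaled (X'X)^{-1} from a qr object, undoing column pivoting.
xtx_inverse <- function(q) {
  R <- qr.R(q)
  inv <- chol2inv(R)
  piv <- q$pivot
  out <- matrix(NA_real_, ncol(inv), ncol(inv))
  out[piv, piv] <- inv
  out
}

# OLS of y on X (X includes its own intercept column). Returns coefficient
# table with classical t-based inference.
ols_fit <- function(y, X, label = "design") {
  ok <- stats::complete.cases(X) & !is.na(y)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (n < k + 1L) stop("too few complete cases for the ", label, " fit")
  q <- check_full_rank(X, label)
  beta <- qr.coef(q, y)
  res <- y - as.vector(X %*% beta)
  df <- n - k
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtx_inverse(q)))
  names(se) <- colnames(X)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(coef = beta, se = se, t = tval, p = p, df = df, n = n,
       rss = sum(res^2), residuals = res)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  }
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("covariate rows do not match sample count")
  if (is.null(colnames(X))) colnames(X) <- paste0("cov", seq_len(ncol(X)))
  X
}
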