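# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Least-squares fit of y on columns of X (X includes the intercept column).
# Returns coefficients, residual standard error, df, and (X'X)^-1 for
# leverage-based prediction intervals. Errors on rank deficiency, naming an
# aliased column.
ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop("Rank-deficient design: collinear or constant column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  resid <- y - drop(X %*% coefs)
  df_residual <- nrow(X) - ncol(X)
  sigma <- if (df_residual > 0) sqrt(sum(resid^2) / df_residual) else NA_real_
  # undo column pivoting: chol2inv(R) inverts (XP)'(XP) = P'(X'X)P
  inv_perm <- chol2inv(qr.R(qx))
  unpivot <- order(qx$pivot)
  xtx_inv <- inv_perm[unpivot, unpivot, drop = FALSE]
  list(coefficients = coefs, sigma = sigma, df_residual = df_residual,
       residuals = resid, xtx_inv = xtx_inv)
}
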