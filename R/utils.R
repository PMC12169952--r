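# Internal numerical helpers shared across modules.

#' Weighted quantiles with type-7-style interpolation
#'
#' Computes quantiles of a weighted sample by linear interpolation on the
#' cumulative weight scale. Plotting positions are
#' `(cumw_i - w_i) / (W - mean(w))`, which reduces exactly to
#' `stats::quantile(..., type = 7)` when all weights are equal.
#'
#' @param x numeric vector.
#' @param probs probabilities in `[0, 1]`.
#' @param w nonnegative weights, recycled to `length(x)`; default equal.
#' @return numeric vector of quantiles, named like `quantile()`.
#' @export
weighted_quantile <- function(x, probs, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  stopifnot(length(x) > 0L, all(w >= 0), any(w > 0), all(probs >= 0 & probs <= 1))
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  W <- cw[length(cw)]
  pos <- (cw - w) / (W - mean(w))
  pos <- pmin(pmax(pos, 0), 1)
  out <- stats::approx(pos, x, xout = probs, rule = 2, ties = "ordered")$y
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}

#' Weighted mean with NA handling
#' @noRd
wmean <- function(x, w) {
  stats::weighted.mean(x, w, na.rm = TRUE)
}

#' Nearest correlation matrix by eigenvalue clipping
#'
#' Repairs a symmetric matrix that is not positive definite by clipping
#' eigenvalues at a small floor and rescaling to unit diagonal.
#' @param R symmetric matrix intended as a correlation matrix.
#' @param eps eigenvalue floor.
#' @return a positive-definite correlation matrix.
#' @keywords internal
nearest_pd_corr <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values > eps)) return(R)
  warning("correlation matrix not positive definite; nearest-PD repair applied")
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  (R2 + t(R2)) / 2
}

# Multivariate normal draws via Cholesky; Sigma must be PD.
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% chol(Sigma), 2, mu, `+`)
}

# Inverse-Wishart draw: Sigma ~ IW(df, S) with density \propto
# |Sigma|^{-(df+p+1)/2} exp(-tr(S Sigma^{-1})/2).
riwish <- function(df, S) {
  W <- stats::rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

# Truncated standard-deviation-1 normal draws, vectorised.
# mean m, truncated to be positive where pos is TRUE, negative otherwise.
rtnorm_sign <- function(m, pos) {
  u <- stats::runif(length(m))
  p0 <- stats::pnorm(-m)                # P(z - m < -m) = P(z < 0)
  p0 <- pmin(pmax(p0, 1e-12), 1 - 1e-12)
  q <- ifelse(pos, p0 + u * (1 - p0), u * p0)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  m + stats::qnorm(q)
}

# Box-Cox transform; lambda = 0 means log.
boxcox_tr <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# Back-transform of a Box-Cox mean with second-order Taylor bias
# correction: E[g^{-1}(t + e)] ~= g^{-1}(t) + sigma2/2 * d2/dt2 g^{-1}(t).
# Values where lambda*t + 1 <= 0 map to 0 (the transform's boundary).
boxcox_bt_mean <- function(t, lambda, sigma2) {
  if (abs(lambda) < 1e-12) {
    exp(t) * (1 + sigma2 / 2)
  } else {
    base <- lambda * t + 1
    out <- numeric(length(t))
    ok <- base > 0
    b <- base[ok]
    out[ok] <- b^(1 / lambda) + (sigma2 / 2) * (1 - lambda) * b^(1 / lambda - 2)
    pmax(out, 0)
  }
}

# Profile criterion for choosing a Box-Cox lambda on a grid: the
# standard normalised profile log-likelihood of residuals after removing
# a linear model fit (including the Jacobian term).
boxcox_grid_loglik <- function(y, X, lambda) {
  t <- boxcox_tr(y, lambda)
  r <- stats::lm.fit(X, t)$residuals
  n <- length(y)
  -n / 2 * log(sum(r^2) / n) + (lambda - 1) * sum(log(y))
}

# Stable hash of an R object (used for run metadata).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
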