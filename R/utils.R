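# Internal helpers shared across modules.

# Complement of A/C/G/T allele codes (vectorised).
allele_complement <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic <- function(ea, oa) {
  ea == allele_complement(oa)
}

# Two-sided p-value from a z statistic.
p_from_z <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# Weighted least squares of y on columns of X (no intercept), weights w.
# Returns coefficients, their fixed-effect covariance (unit-dispersion), and
# the weighted residual sum of squares.
wls_fit <- function(X, y, w) {
  X <- as.matrix(X)
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  qr_x <- qr(XtX)
  if (qr_x$rank < ncol(X)) {
    abort("design matrix is rank deficient", class = "mrscreen_collinear")
  }
  beta <- solve(qr_x, crossprod(Xw, yw))
  res <- yw - Xw %*% beta
  list(
    coef = drop(beta),
    vcov = solve(qr_x),
    rss = sum(res^2)
  )
}

# Draw from a multivariate normal with PSD covariance sigma (rows = draws);
# eigen-based square root so singular covariances (perfectly correlated
# exposures) are handled.
rmvnorm_chol <- function(n, sigma) {
  k <- ncol(sigma)
  es <- eigen(sigma, symmetric = TRUE)
  root <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  matrix(rnorm(n * k), n, k) %*% root
}

check_psd <- function(m, what = "matrix") {
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    abort(paste(what, "must be symmetric"), class = "mrscreen_config")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(paste(what, "must be positive semi-definite"),
          class = "mrscreen_config")
  }
  invisible(m)
}

# Derive a reproducible child seed from a base seed and an index; kept well
# inside the 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1103L + as.double(i) * 12289L) %% 2147483629)
}
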