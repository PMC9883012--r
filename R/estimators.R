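mr_result_row <- function(method, estimate, se, pvalue, n_snv,
                          df = NA_real_, exposure_type = "continuous") {
  crit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  tibble(
    method = method,
    estimate = estimate,
    se = se,
    ci_low = estimate - crit * se,
    ci_high = estimate + crit * se,
    pvalue = pvalue,
    n_snv = as.integer(n_snv),
    or = if (identical(exposure_type, "continuous")) exp(estimate)
         else NA_real_
  )
}

exposure_type_of <- function(hset) {
  em <- attr(hset, "exposure_meta")
  if (is.null(em)) "continuous" else em$trait_type
}

need_instruments <- function(hset, k, method) {
  if (nrow(hset) < k) {
    abort(sprintf("%s requires at least %d instruments (got %d)",
                  method, k, nrow(hset)),
          class = "mrscreen_insufficient")
  }
}

#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate `b_Y / b_X`, with the first-order delta
#' standard error `se_Y / |b_X|`.
#'
#' @param hset An `mr_harmonised` set with exactly one row (or a row index
#'   into a larger set via `i`).
#' @param i Row to use (default 1).
#' @return A one-row `mr_result` tibble.
#' @export
mr_wald_ratio <- function(hset, i = 1) {
  need_instruments(hset, 1, "wald_ratio")
  est <- hset$b_y[i] / hset$b_x[i]
  se <- hset$se_y[i] / abs(hset$b_x[i])
  mr_result_row("wald_ratio", est, se, p_from_z(est / se), 1,
                exposure_type = exposure_type_of(hset))
}

# Core IVW computations shared by mr_ivw and qc_battery.
ivw_core <- function(b_x, b_y, se_y) {
  w <- 1 / se_y^2
  sxx <- sum(w * b_x^2)
  theta <- sum(w * b_x * b_y) / sxx
  se_fe <- sqrt(1 / sxx)
  q <- sum(w * (b_y - theta * b_x)^2)
  list(theta = theta, se_fe = se_fe, q = q)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome betas on exposure betas through the origin
#' with weights `1 / se_Y^2`. Under multiplicative random effects (the
#' primary analysis model of the screen) the fixed-effect standard error is
#' inflated by `max(1, sqrt(Q / (J - 1)))`, so heterogeneous instruments
#' widen the interval but never narrow it. Two-sided p-values from the normal
#' distribution.
#'
#' @param hset An `mr_harmonised` set with at least 2 instruments.
#' @param effects `"multiplicative_random"` (default) or `"fixed"`.
#' @return A one-row `mr_result` tibble with attributes `q` (Cochran's Q) and
#'   `q_df`.
#' @export
mr_ivw <- function(hset, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  need_instruments(hset, 2, "ivw")
  core <- ivw_core(hset$b_x, hset$b_y, hset$se_y)
  J <- nrow(hset)
  se <- if (effects == "multiplicative_random") {
    core$se_fe * max(1, sqrt(core$q / (J - 1)))
  } else {
    core$se_fe
  }
  out <- mr_result_row(
    if (effects == "fixed") "ivw_fe" else "ivw_mre",
    core$theta, se, p_from_z(core$theta / se), J,
    exposure_type = exposure_type_of(hset))
  attr(out, "q") <- core$q
  attr(out, "q_df") <- J - 1L
  out
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept,
#' after orienting every instrument so the exposure beta is non-negative.
#' The intercept estimates the average directional pleiotropic effect and its
#' test doubles as the pleiotropy diagnostic; the slope is the
#' pleiotropy-adjusted causal estimate. Standard errors are inflated by
#' `max(1, sqrt(Q_egger / (J - 2)))` and p-values use a t distribution on
#' J - 2 degrees of freedom.
#'
#' @param hset An `mr_harmonised` set with at least 3 instruments.
#' @return A list with `slope` and `intercept`, each a one-row `mr_result`.
#' @export
mr_egger <- function(hset) {
  need_instruments(hset, 3, "egger")
  flip <- sign(hset$b_x)
  flip[flip == 0] <- 1
  bx <- hset$b_x * flip
  by <- hset$b_y * flip
  w <- 1 / hset$se_y^2
  X <- cbind(intercept = 1, slope = bx)
  if (length(unique(bx)) < 2) {
    abort("degenerate Egger fit: all oriented exposure betas identical",
          class = "mrscreen_collinear")
  }
  fit <- wls_fit(X, by, w)
  J <- nrow(hset)
  q_egger <- fit$rss
  infl <- max(1, sqrt(q_egger / (J - 2)))
  ses <- sqrt(diag(fit$vcov)) * infl
  tvals <- fit$coef / ses
  pvals <- 2 * pt(-abs(tvals), df = J - 2)
  etype <- exposure_type_of(hset)
  list(
    slope = mr_result_row("egger_slope", fit$coef[["slope"]], ses[[2]],
                          pvals[[2]], J, df = J - 2, exposure_type = etype),
    intercept = mr_result_row("egger_intercept", fit$coef[["intercept"]],
                              ses[[1]], pvals[[1]], J, df = J - 2,
                              exposure_type = "binary")
  )
}

# Weighted median of values x with weights w (normalised), by linear
# interpolation across cumulative weights.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(x[1])
  if (cum[length(cum)] <= 0.5) return(x[length(x)])
  below <- max(which(cum < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

ratio_and_weights <- function(hset) {
  ratio <- hset$b_y / hset$b_x
  se1 <- hset$se_y / abs(hset$b_x)  # first-order ratio SE
  list(ratio = ratio, w = 1 / se1^2)
}

# Parametric bootstrap over (b_x, b_y) for ratio-based estimators.
ratio_bootstrap_se <- function(hset, n_boot, seed, stat_fn) {
  J <- nrow(hset)
  withr::local_seed(seed)
  bx <- matrix(rnorm(J * n_boot, hset$b_x, hset$se_x), nrow = J)
  by <- matrix(rnorm(J * n_boot, hset$b_y, hset$se_y), nrow = J)
  se_y <- hset$se_y
  ests <- vapply(seq_len(n_boot), function(b) {
    ratio <- by[, b] / bx[, b]
    w <- (bx[, b] / se_y)^2
    stat_fn(ratio, w)
  }, numeric(1))
  sd(ests)
}

#' Weighted-median causal estimate
#'
#' The inverse-variance-weighted 50th percentile of the per-variant Wald
#' ratios (linear interpolation across cumulative weights): consistent as
#' long as at least half the weight comes from valid instruments. The
#' standard error comes from a parametric bootstrap resampling the exposure
#' and outcome betas from Gaussians at their standard errors, under a fixed
#' seed.
#'
#' @param hset An `mr_harmonised` set with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = 1L) {
  need_instruments(hset, 3, "weighted_median")
  rw <- ratio_and_weights(hset)
  est <- weighted_median_value(rw$ratio, rw$w)
  se <- ratio_bootstrap_se(hset, n_boot, seed, weighted_median_value)
  mr_result_row("weighted_median", est, se, p_from_z(est / se), nrow(hset),
                exposure_type = exposure_type_of(hset))
}

# Weighted kernel-density mode of ratio estimates with a modified-Silverman
# bandwidth.
weighted_mode_value <- function(ratio, w, bandwidth_factor = 1.0) {
  disp <- min(sd(ratio), mad(ratio))
  h <- bandwidth_factor * 0.9 * disp * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: the mode is the heaviest point mass
    return(ratio[which.max(w)])
  }
  d <- density(ratio, weights = w / sum(w), bw = h, n = 512)
  d$x[which.max(d$y)]
}

#' Weighted-mode causal estimate
#'
#' Kernel-density estimate over the per-variant Wald ratios with
#' inverse-variance weights and a modified-Silverman bandwidth scaled by
#' `bandwidth_factor`; the estimate is the density argmax. Consistent when
#' the largest group of instruments sharing a ratio is valid (the plurality
#' assumption). Bootstrap standard error as for [mr_weighted_median()].
#'
#' @param hset An `mr_harmonised` set with at least 3 instruments.
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_mode <- function(hset, bandwidth_factor = 1.0, n_boot = 1000,
                             seed = 1L) {
  need_instruments(hset, 3, "weighted_mode")
  rw <- ratio_and_weights(hset)
  est <- weighted_mode_value(rw$ratio, rw$w, bandwidth_factor)
  se <- ratio_bootstrap_se(hset, n_boot, seed, function(r, w) {
    weighted_mode_value(r, w, bandwidth_factor)
  })
  mr_result_row("weighted_mode", est, se, p_from_z(est / se), nrow(hset),
                exposure_type = exposure_type_of(hset))
}

#' Radial IVW estimate (modified second-order weights)
#'
#' The slope of the radial IVW fit whose weights are iterated with the
#' current slope estimate (see [radial_outlier_filter()] for the outlier
#' usage).
#'
#' @param hset An `mr_harmonised` set with at least 2 instruments.
#' @return A one-row `mr_result` tibble.
#' @export
mr_radial_ivw <- function(hset) {
  need_instruments(hset, 2, "radial_ivw")
  fit <- radial_fit(hset)
  J <- nrow(hset)
  se_fe <- sqrt(1 / sum(fit$weights))
  q <- sum(fit$q_j)
  se <- se_fe * max(1, sqrt(q / (J - 1)))
  mr_result_row("radial_ivw", fit$theta, se, p_from_z(fit$theta / se), J,
                exposure_type = exposure_type_of(hset))
}

#' Run the full univariable estimator battery
#'
#' @param hset An `mr_harmonised` set.
#' @param n_boot,seed Bootstrap settings for median and mode.
#' @return An `mr_result` tibble with one row per method.
#' @export
mr_battery <- function(hset, n_boot = 1000, seed = 1L) {
  rows <- list(mr_ivw(hset, "fixed"), mr_ivw(hset, "multiplicative_random"))
  if (nrow(hset) >= 3) {
    eg <- mr_egger(hset)
    rows <- c(rows, list(eg$slope, eg$intercept,
                         mr_weighted_median(hset, n_boot, seed),
                         mr_weighted_mode(hset, n_boot = n_boot,
                                          seed = child_seed(seed, 2)),
                         mr_radial_ivw(hset)))
  }
  bind_rows(rows)
}
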