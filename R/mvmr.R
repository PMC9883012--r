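# Multivariable MR: joint instrument sets, conditional instrument strength,
# IVW-MVMR and Q-statistic minimisation under an assumed phenotypic
# correlation.

# Iterated conditional instrument-strength statistic for exposure k given the
# others: weights include the delta-regression coefficients and the assumed
# correlation rho between exposure measurement errors. Reduces to the mean
# F-statistic when K = 1.
conditional_f_one <- function(bX, seX, k, rho = 0, max_iter = 50,
                              tol = 1e-10) {
  J <- nrow(bX)
  K <- ncol(bX)
  b_k <- bX[, k]
  se_k <- seX[, k]
  if (K == 1) {
    return(sum((b_k / se_k)^2) / J)
  }
  B <- bX[, -k, drop = FALSE]
  S <- seX[, -k, drop = FALSE]
  delta <- rep(0, K - 1)
  w <- 1 / se_k^2
  for (it in seq_len(max_iter)) {
    fit <- wls_fit(B, b_k, w)
    delta_new <- fit$coef
    denom <- se_k^2 + drop((S^2) %*% delta_new^2)
    if (K - 1 >= 2 && rho != 0) {
      for (l in seq_len(K - 2)) {
        for (m in seq(l + 1, K - 1)) {
          denom <- denom +
            2 * delta_new[l] * delta_new[m] * rho * S[, l] * S[, m]
        }
      }
    }
    denom <- pmax(denom, .Machine$double.eps)
    w <- 1 / denom
    if (max(abs(delta_new - delta)) < tol) {
      delta <- delta_new
      break
    }
    delta <- delta_new
  }
  q_x <- sum(w * (b_k - drop(B %*% delta))^2)
  q_x / J
}

conditional_f <- function(bX, seX, rho = 0) {
  vapply(seq_len(ncol(bX)), function(k) conditional_f_one(bX, seX, k, rho),
         numeric(1))
}

#' Build a joint instrument set for multivariable MR
#'
#' Takes the union of each exposure's instruments (starting at genome-wide
#' significance), clumps them jointly with the univariable rules (indexing on
#' the smallest per-variant p-value across exposures), harmonises every
#' exposure and the outcome to a single allele convention, and computes
#' per-exposure conditional F-statistics. Whenever an exposure's conditional
#' F is 10 or below, its selection threshold is relaxed by a factor of 10 (to
#' a floor of `threshold_floor`) and the set rebuilt; the relaxation ladder is
#' logged. If the floor is reached with conditional F still at or below 10
#' the set is returned flagged weak.
#'
#' @param exposures List of K >= 2 `mr_sumstats` tables.
#' @param outcome The outcome `mr_sumstats` table.
#' @param ld An [ld_reference()].
#' @param start_threshold Initial per-exposure selection threshold.
#' @param threshold_floor Maximum (most relaxed) threshold.
#' @param r2_max,window_kb Clumping parameters.
#' @param rho Assumed phenotypic correlation used in the conditional-F
#'   weights (default 0).
#' @return An `mvmr_set` list: `data` (tibble with `variant_id`, `b_y`,
#'   `se_y` and per-exposure `b_x_k` / `se_x_k` columns), `exposure_ids`,
#'   `thresholds`, `conditional_f`, `weak` flag, `ladder_log`.
#' @export
build_mvmr_set <- function(exposures, outcome, ld,
                           start_threshold = 5e-8, threshold_floor = 5e-5,
                           r2_max = 0.001, window_kb = 10000, rho = 0) {
  K <- length(exposures)
  if (K < 2) {
    abort("multivariable MR requires at least 2 exposures",
          class = "mrscreen_input")
  }
  thresholds <- rep(start_threshold, K)
  ladder_log <- list()
  exposure_ids <- map_chr(exposures, ~ meta_of(.x)$trait_id)
  repeat {
    mset <- assemble_mvmr_set(exposures, outcome, ld, thresholds,
                              r2_max, window_kb)
    bX <- as.matrix(mset$data[paste0("b_x_", seq_len(K))])
    seX <- as.matrix(mset$data[paste0("se_x_", seq_len(K))])
    cf <- if (nrow(bX) > K) conditional_f(bX, seX, rho)
          else rep(0, K)
    ladder_log[[length(ladder_log) + 1]] <-
      tibble(exposure = exposure_ids, threshold = thresholds,
             conditional_f = cf, n_snv = nrow(bX))
    weak <- cf <= 10
    if (!any(weak) || all(thresholds[weak] >= threshold_floor)) {
      return(structure(
        list(data = mset$data, exposure_ids = exposure_ids,
             exposure_meta = map(exposures, meta_of),
             thresholds = thresholds, conditional_f = cf,
             weak = any(weak), ladder_log = bind_rows(ladder_log)),
        class = "mvmr_set"))
    }
    relax <- weak & thresholds < threshold_floor
    thresholds[relax] <- thresholds[relax] * 10
  }
}

# Assemble the joint, harmonised instrument table at given thresholds.
assemble_mvmr_set <- function(exposures, outcome, ld, thresholds,
                              r2_max, window_kb) {
  K <- length(exposures)
  cand <- unique(unlist(map2(exposures, thresholds, function(e, thr) {
    e$variant_id[e$pvalue < thr]
  })))
  # joint clumping indexes on the smallest p-value across exposures
  pmin_tab <- map(exposures, ~ setNames(.x$pvalue, .x$variant_id))
  pmin_all <- vapply(cand, function(v) {
    min(map_dbl(pmin_tab, ~ .x[v] %||% NA_real_), na.rm = TRUE)
  }, numeric(1))
  ref <- as_tibble(exposures[[1]])
  clump_frame <- summary_stats(
    tibble(variant_id = cand,
           chrom = ref$chrom[match(cand, ref$variant_id)],
           pos = ref$pos[match(cand, ref$variant_id)],
           ea = ref$ea[match(cand, ref$variant_id)],
           oa = ref$oa[match(cand, ref$variant_id)],
           eaf = NA_real_, beta = 1, se = 1,
           pvalue = pmin_all, n = NA_integer_),
    trait_meta("joint"))
  kept <- clump(clump_frame$variant_id, clump_frame, ld,
                r2_max = r2_max, window_kb = window_kb)

  # harmonise everything to exposure 1's allele convention
  rows <- list()
  for (v in kept) {
    e1 <- ref[ref$variant_id == v, ]
    if (nrow(e1) == 0) next
    ok <- TRUE
    b_x <- numeric(K); se_x <- numeric(K)
    b_x[1] <- e1$beta; se_x[1] <- e1$se
    for (k in seq_len(K)[-1]) {
      ek <- as_tibble(exposures[[k]])
      r <- ek[ek$variant_id == v, ]
      if (nrow(r) == 0) { ok <- FALSE; break }
      al <- align_alleles(e1$ea, e1$oa, r$ea, r$oa, r$beta, r$eaf,
                          ref_eaf = e1$eaf)
      if (is.na(al$beta)) { ok <- FALSE; break }
      b_x[k] <- al$beta; se_x[k] <- r$se
    }
    if (!ok) next
    od <- as_tibble(outcome)
    o <- od[od$variant_id == v, ]
    if (nrow(o) == 0) next
    al <- align_alleles(e1$ea, e1$oa, o$ea, o$oa, o$beta, o$eaf,
                        ref_eaf = e1$eaf)
    if (is.na(al$beta)) next
    row <- c(list(variant_id = v, b_y = al$beta, se_y = o$se),
             setNames(as.list(b_x), paste0("b_x_", seq_len(K))),
             setNames(as.list(se_x), paste0("se_x_", seq_len(K))))
    rows[[length(rows) + 1]] <- as_tibble(row)
  }
  data <- if (length(rows)) bind_rows(rows) else
    as_tibble(c(list(variant_id = character(), b_y = numeric(),
                     se_y = numeric()),
                setNames(rep(list(numeric()), K),
                         paste0("b_x_", seq_len(K))),
                setNames(rep(list(numeric()), K),
                         paste0("se_x_", seq_len(K)))))
  list(data = data)
}

mvmr_matrices <- function(mset) {
  K <- length(mset$exposure_ids)
  list(
    bX = as.matrix(mset$data[paste0("b_x_", seq_len(K))]),
    seX = as.matrix(mset$data[paste0("se_x_", seq_len(K))]),
    b_y = mset$data$b_y,
    se_y = mset$data$se_y,
    K = K, J = nrow(mset$data)
  )
}

# Adjusted heterogeneity statistic whose denominator propagates exposure
# measurement error under assumed correlation rho.
q_adjusted <- function(theta, bX, seX, b_y, se_y, rho = 0) {
  K <- ncol(bX)
  denom <- se_y^2 + drop((seX^2) %*% theta^2)
  if (K >= 2 && rho != 0) {
    for (l in seq_len(K - 1)) {
      for (m in seq(l + 1, K)) {
        denom <- denom + 2 * theta[l] * theta[m] * rho * seX[, l] * seX[, m]
      }
    }
  }
  denom <- pmax(denom, .Machine$double.eps)
  sum((b_y - drop(bX %*% theta))^2 / denom)
}

#' IVW multivariable MR
#'
#' Weighted multiple regression of outcome betas on the K exposure beta
#' columns without intercept, weights `1 / se_Y^2`; per-exposure conditional
#' F-statistics; adjusted Cochran's Q (propagating exposure measurement
#' error at correlation `rho`) with heterogeneity signalled at p < 0.05.
#'
#' @param mset An `mvmr_set` from [build_mvmr_set()] (J > K required).
#' @param rho Assumed phenotypic correlation for the adjusted Q and
#'   conditional F (default 0).
#' @return An `mvmr_result` list: `estimates` (tibble per exposure with
#'   estimate, se, CI, p, conditional F), `adjusted_q`, `adjusted_q_df`,
#'   `adjusted_q_pvalue`, `heterogeneous`.
#' @export
mvmr_ivw <- function(mset, rho = 0) {
  m <- mvmr_matrices(mset)
  if (m$J <= m$K) {
    abort("need more instruments than exposures", class = "mrscreen_input")
  }
  fit <- tryCatch(
    wls_fit(m$bX, m$b_y, 1 / m$se_y^2),
    error = function(e) {
      cors <- abs(cor(m$bX))
      diag(cors) <- 0
      worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      abort(paste0("collinear exposures: ",
                   mset$exposure_ids[worst[1]], " and ",
                   mset$exposure_ids[worst[2]]),
            class = "mrscreen_collinear")
    })
  theta <- fit$coef
  q <- q_adjusted(theta, m$bX, m$seX, m$b_y, m$se_y, rho)
  q_df <- m$J - m$K
  se <- sqrt(diag(fit$vcov)) * max(1, sqrt(fit$rss / q_df))
  cf <- conditional_f(m$bX, m$seX, rho)
  est <- tibble(
    exposure = mset$exposure_ids,
    estimate = unname(theta), se = unname(se),
    ci_low = unname(theta - qnorm(0.975) * se),
    ci_high = unname(theta + qnorm(0.975) * se),
    pvalue = p_from_z(theta / se),
    conditional_f = cf
  )
  structure(
    list(estimates = est, adjusted_q = q, adjusted_q_df = q_df,
         adjusted_q_pvalue = pchisq(q, q_df, lower.tail = FALSE),
         heterogeneous = pchisq(q, q_df, lower.tail = FALSE) < 0.05,
         n_snv = m$J),
    class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> J = %d, adjusted Q = %.2f (p = %.3g)\n",
              x$n_snv, x$adjusted_q, x$adjusted_q_pvalue))
  print(x$estimates)
  invisible(x)
}

#' Q-statistic minimisation estimate for multivariable MR
#'
#' Minimises over the causal-effect vector the adjusted heterogeneity
#' statistic whose denominator propagates exposure measurement error under an
#' assumed phenotypic correlation `rho`; used when the adjusted Q signals
#' heterogeneity, and typically run at both low (0.1) and high (0.9)
#' correlation to check the conclusion is stable. Starts from the IVW-MVMR
#' solution; confidence intervals come from inverting the per-component
#' profile of the statistic at the chi-squared(1) 95% cut-off.
#'
#' @param mset An `mvmr_set`.
#' @param rho Assumed phenotypic correlation in `[-1, 1]`.
#' @return A tibble per exposure: `estimate`, `ci_low`, `ci_high`, plus
#'   attributes `q_min` (minimised statistic) and `rho`.
#' @export
qmin_estimate <- function(mset, rho = 0.1) {
  stopifnot(rho >= -1, rho <= 1)
  m <- mvmr_matrices(mset)
  if (m$J <= m$K) {
    abort("need more instruments than exposures", class = "mrscreen_input")
  }
  start <- wls_fit(m$bX, m$b_y, 1 / m$se_y^2)$coef
  obj <- function(theta) q_adjusted(theta, m$bX, m$seX, m$b_y, m$se_y, rho)
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0) {
    abort(paste0("Q minimisation did not converge (best Q = ",
                 signif(opt$value, 6), ")"),
          class = "mrscreen_nonconvergence")
  }
  theta_hat <- opt$par
  q_min <- opt$value
  cut <- q_min + qchisq(0.95, df = 1)

  profile_q <- function(k, value) {
    if (m$K == 1) return(obj(value))
    inner <- function(rest) {
      th <- numeric(m$K)
      th[k] <- value
      th[-k] <- rest
      obj(th)
    }
    optim(theta_hat[-k], inner, method = "BFGS",
          control = list(maxit = 200))$value
  }
  bound <- function(k, dir) {
    step <- max(abs(theta_hat[k]), 0.1)
    lo <- theta_hat[k]
    hi <- theta_hat[k] + dir * step
    for (i in 1:40) {
      if (profile_q(k, hi) >= cut) break
      lo <- hi
      hi <- hi + dir * step
    }
    if (profile_q(k, hi) < cut) return(dir * Inf)
    stats::uniroot(function(v) profile_q(k, v) - cut, lower = min(lo, hi),
                   upper = max(lo, hi), tol = 1e-6)$root
  }
  ci <- t(vapply(seq_len(m$K),
                 function(k) c(bound(k, -1), bound(k, 1)), numeric(2)))
  out <- tibble(
    exposure = mset$exposure_ids,
    estimate = unname(theta_hat),
    ci_low = ci[, 1], ci_high = ci[, 2]
  )
  attr(out, "q_min") <- q_min
  attr(out, "rho") <- rho
  out
}
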