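#' Quality-control battery for one exposure-outcome analysis
#'
#' Computes the diagnostic suite accompanying the primary MRE IVW estimate:
#'
#' * mean per-variant F-statistic `(b_X / se_X)^2`, with a weak-instruments
#'   flag when the mean is 10 or below;
#' * Cochran's Q against the IVW fit with a chi-squared (J - 1) p-value and a
#'   heterogeneity flag at p < 0.05;
#' * the MR-Egger intercept with a pleiotropy flag at p < 0.05;
#' * the I-squared statistic of the instrument-exposure associations
#'   (`(Q_GX - (J - 1)) / Q_GX`, floored at 0), flagging a NOME violation —
#'   Egger biased towards the null — when below 0.9;
#' * leave-one-out: J refits of the MRE IVW each omitting one instrument,
#'   flagged unstable when any refit p-value reaches 0.05 while the full-set
#'   p-value is below 0.05.
#'
#' @param hset An `mr_harmonised` set with at least 2 instruments.
#' @param nominal_alpha Flag threshold for Q, intercept and leave-one-out
#'   p-values (default 0.05).
#' @return An `mr_qc` list: `mean_f`, `cochran_q`, `q_df`, `q_pvalue`,
#'   `i2_gx`, `egger_intercept` (one-row `mr_result` or `NULL` when J < 3),
#'   `loo` (tibble of leave-one-out refits), `flags` (character vector),
#'   `n_snv`.
#' @export
qc_battery <- function(hset, nominal_alpha = 0.05) {
  need_instruments(hset, 2, "qc_battery")
  J <- nrow(hset)
  f_j <- (hset$b_x / hset$se_x)^2
  mean_f <- mean(f_j)

  full <- mr_ivw(hset)
  q <- attr(full, "q")
  q_df <- J - 1L
  q_pvalue <- pchisq(q, df = q_df, lower.tail = FALSE)

  # I^2 of the instrument-exposure association strengths (NOME diagnostic):
  # heterogeneity of |b_X| weighted by 1/se_X^2
  wx <- 1 / hset$se_x^2
  bx_abs <- abs(hset$b_x)
  mu_gx <- sum(wx * bx_abs) / sum(wx)
  q_gx <- sum(wx * (bx_abs - mu_gx)^2)
  i2_gx <- if (q_gx > 0) max(0, (q_gx - (J - 1)) / q_gx) else 0

  egger_int <- NULL
  if (J >= 3) {
    egger_int <- tryCatch(mr_egger(hset)$intercept, error = function(e) NULL)
  }

  loo <- map(seq_len(J), function(j) {
    sub <- harmonised_subset(hset, seq_len(J) != j, "loo_omitted")
    res <- mr_ivw(sub)
    tibble(left_out = hset$variant_id[j], estimate = res$estimate,
           se = res$se, pvalue = res$pvalue)
  })
  loo <- bind_rows(loo)

  flags <- character(0)
  if (mean_f <= 10) flags <- c(flags, "weak_instruments")
  if (q_pvalue < nominal_alpha) flags <- c(flags, "heterogeneous")
  if (!is.null(egger_int) && egger_int$pvalue < nominal_alpha) {
    flags <- c(flags, "pleiotropy_detected")
  }
  if (i2_gx < 0.9) flags <- c(flags, "nome_violation")
  if (full$pvalue < nominal_alpha && any(loo$pvalue >= nominal_alpha)) {
    flags <- c(flags, "loo_unstable")
  }

  structure(
    list(mean_f = mean_f, cochran_q = q, q_df = q_df, q_pvalue = q_pvalue,
         i2_gx = i2_gx, egger_intercept = egger_int, loo = loo,
         flags = flags, n_snv = J, ivw = full),
    class = "mr_qc"
  )
}

#' @export
print.mr_qc <- function(x, ...) {
  cat(sprintf(
    "<mr_qc> J = %d, mean F = %.1f, Q = %.2f (p = %.3g), I2_GX = %.3f\n",
    x$n_snv, x$mean_f, x$cochran_q, x$q_pvalue, x$i2_gx))
  cat("flags:", if (length(x$flags)) paste(x$flags, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
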