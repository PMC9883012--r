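#' Screen configuration
#'
#' Tunable parameters for a phenome-wide screen: the FDR and nominal alpha
#' levels of the composite significance criteria, batches excluded wholesale
#' (e.g. batches with known sample overlap with the outcome cohort), the
#' minimum post-clumping instrument count, and all instrument-processing
#' thresholds.
#'
#' @param fdr_alpha FDR threshold for the primary MRE IVW p-value.
#' @param nominal_alpha Nominal threshold for the robust-measure and
#'   leave-one-out criteria.
#' @param excluded_batches Character vector of batch tags to exclude.
#' @param min_instruments Minimum instrument count (default 6).
#' @param ladder Instrument-selection p-value ladder.
#' @param r2_max,window_kb Clumping parameters.
#' @param proxy_r2_min Minimum proxy r-squared.
#' @param palindrome_maf Palindrome ambiguity threshold.
#' @param radial_alpha Radial outlier alpha.
#' @param outcome_filter_first Apply the outcome-significance filter before
#'   radial filtering (default `TRUE`).
#' @param n_boot,seed Bootstrap settings for the robust estimators.
#' @return An `mr_screen_config` list.
#' @export
screen_config <- function(fdr_alpha = 0.05, nominal_alpha = 0.05,
                          excluded_batches = c("ukb", "met-d"),
                          min_instruments = 6,
                          ladder = c(5e-8, 5e-7, 5e-6, 5e-5),
                          r2_max = 0.001, window_kb = 10000,
                          proxy_r2_min = 0.9, palindrome_maf = 0.42,
                          radial_alpha = 0.05, outcome_filter_first = TRUE,
                          n_boot = 1000, seed = 1L) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, nominal_alpha > 0,
            nominal_alpha < 1)
  structure(as.list(environment()), class = "mr_screen_config")
}

#' De-duplicate traits by normalised name
#'
#' When the same trait has been analysed by multiple GWAS, keeps one study per
#' normalised trait name (case-folded, whitespace-collapsed): the largest
#' sample size wins; ties are broken by the largest mean F-statistic, then by
#' lexicographic trait id.
#'
#' @param traits A data frame with columns `trait_id`, `trait_name`,
#'   `sample_size` and optionally `mean_f`.
#' @return The de-duplicated tibble, with a `removed` attribute listing the
#'   dropped trait ids.
#' @export
dedup_traits <- function(traits) {
  traits <- as_tibble(traits)
  if (!"mean_f" %in% names(traits)) traits$mean_f <- NA_real_
  key <- tolower(gsub("\\s+", " ", trimws(traits$trait_name)))
  ord <- order(key, -traits$sample_size, -ifelse(is.na(traits$mean_f), -Inf,
                                                 traits$mean_f),
               traits$trait_id)
  sorted <- traits[ord, ]
  keep <- !duplicated(key[ord])
  out <- sorted[keep, ]
  attr(out, "removed") <- sorted$trait_id[!keep]
  out
}

# Run the per-trait univariable pipeline; returns a list with the harmonised
# set, battery, qc, selection and a status/reason.
run_trait_pipeline <- function(exposure, outcome, ld, cfg) {
  sel <- select_instruments(exposure, ld, min_count = cfg$min_instruments,
                            ladder = cfg$ladder, r2_max = cfg$r2_max,
                            window_kb = cfg$window_kb)
  if (!sel$sufficient) {
    return(list(status = "excluded", reason = "insufficient_instruments",
                selection = sel))
  }
  hset <- harmonise(exposure, outcome, sel, ld,
                    palindrome_maf = cfg$palindrome_maf,
                    proxy_r2_min = cfg$proxy_r2_min)
  steps <- if (cfg$outcome_filter_first) c("sig", "radial")
           else c("radial", "sig")
  for (s in steps) {
    if (s == "sig") {
      hset <- filter_outcome_significance(hset)
    } else if (nrow(hset) >= 3) {
      hset <- radial_outlier_filter(hset, alpha = cfg$radial_alpha)$hset
    }
  }
  if (nrow(hset) < max(3, 2)) {
    return(list(status = "excluded", reason = "too_few_instruments_after_qc",
                selection = sel, hset = hset))
  }
  res <- tryCatch({
    battery <- mr_battery(hset, n_boot = cfg$n_boot, seed = cfg$seed)
    qc <- qc_battery(hset, nominal_alpha = cfg$nominal_alpha)
    list(status = "analysed", selection = sel, hset = hset,
         battery = battery, qc = qc)
  }, error = function(e) {
    list(status = "excluded", reason = conditionMessage(e), selection = sel,
         hset = hset)
  })
  res
}

battery_get <- function(battery, method) {
  battery[battery$method == method, ]
}

#' Run a phenome-wide univariable MR screen
#'
#' For each exposure: batch exclusion, adaptive instrument selection with
#' clumping, harmonisation (with proxy substitution), the
#' outcome-significance and radial outlier filters, the estimator battery and
#' the QC suite. Benjamini-Hochberg FDR correction is applied across the MRE
#' IVW p-values of all analysed (non-excluded) traits. A trait's verdict is
#' `significant` only when all four composite criteria hold: (a) FDR-adjusted
#' IVW p below `fdr_alpha`; (b) weighted-median p below `nominal_alpha`;
#' (c) weighted-mode p below `nominal_alpha`; (d) every leave-one-out refit
#' p below `nominal_alpha`. Estimator failures downgrade a trait to
#' `excluded` (with the error as reason) rather than aborting the screen.
#'
#' @param exposures A list of `mr_sumstats` exposure tables.
#' @param outcome The outcome `mr_sumstats` table.
#' @param ld An [ld_reference()].
#' @param cfg A [screen_config()].
#' @return An `mr_screen` tibble with one row per input trait: identifiers,
#'   threshold used, instrument count, primary estimate (beta, OR where
#'   applicable), raw and FDR-adjusted p-values, robust-measure p-values, QC
#'   flags, verdict and exclusion reason, plus list-columns `selection`,
#'   `battery` and `qc` holding the full per-trait objects.
#' @export
run_screen <- function(exposures, outcome, ld, cfg = screen_config()) {
  stopifnot(length(exposures) >= 1)
  details <- map(exposures, function(exposure) {
    meta <- meta_of(exposure)
    if (meta$batch %in% cfg$excluded_batches) {
      return(list(status = "excluded", reason = "batch", meta = meta))
    }
    out <- run_trait_pipeline(exposure, outcome, ld, cfg)
    out$meta <- meta
    out
  })

  rows <- map(details, function(d) {
    meta <- d$meta
    base <- tibble(
      trait_id = meta$trait_id, trait_name = meta$trait_name,
      batch = meta$batch, sample_size = meta$sample_size,
      trait_type = meta$trait_type,
      threshold = if (!is.null(d$selection)) d$selection$threshold_used
                  else NA_real_,
      n_snv = NA_integer_, estimate = NA_real_, se = NA_real_,
      or = NA_real_, pvalue = NA_real_, wm_pvalue = NA_real_,
      mode_pvalue = NA_real_, loo_max_p = NA_real_, mean_f = NA_real_,
      qc_flags = NA_character_,
      status = d$status,
      exclusion_reason = d$reason %||% NA_character_
    )
    if (d$status != "analysed") return(base)
    ivw <- battery_get(d$battery, "ivw_mre")
    wm <- battery_get(d$battery, "weighted_median")
    wmode <- battery_get(d$battery, "weighted_mode")
    base$n_snv <- ivw$n_snv
    base$estimate <- ivw$estimate
    base$se <- ivw$se
    base$or <- ivw$or
    base$pvalue <- ivw$pvalue
    base$wm_pvalue <- wm$pvalue
    base$mode_pvalue <- wmode$pvalue
    base$loo_max_p <- max(d$qc$loo$pvalue)
    base$mean_f <- d$qc$mean_f
    base$qc_flags <- paste(d$qc$flags, collapse = ";")
    base
  })
  res <- bind_rows(rows)

  analysed <- res$status == "analysed"
  res$fdr_p <- NA_real_
  res$fdr_p[analysed] <- p.adjust(res$pvalue[analysed], method = "BH")
  res$verdict <- ifelse(analysed, "not_significant", "excluded")
  sig <- analysed &
    !is.na(res$fdr_p) & res$fdr_p < cfg$fdr_alpha &
    res$wm_pvalue < cfg$nominal_alpha &
    res$mode_pvalue < cfg$nominal_alpha &
    res$loo_max_p < cfg$nominal_alpha
  res$verdict[sig] <- "significant"

  res$selection <- map(details, ~ .x$selection %||% NULL)
  res$battery <- map(details, ~ .x$battery %||% NULL)
  res$qc <- map(details, ~ .x$qc %||% NULL)
  structure(res, class = c("mr_screen", class(tibble())), config = cfg)
}

#' Replicate significant screen hits against a second outcome
#'
#' Re-runs the full per-trait pipeline against a second outcome for the
#' traits with a `significant` verdict, and attaches the results without
#' altering the primary verdicts (failure to replicate is not evidence of
#' no effect).
#'
#' @param screen An `mr_screen` result from [run_screen()].
#' @param exposures The exposure list used for the primary screen.
#' @param second_outcome A second outcome `mr_sumstats` table.
#' @param ld An [ld_reference()].
#' @param cfg A [screen_config()] (defaults to the primary screen's).
#' @return The `mr_screen` tibble with added columns `rep_estimate`,
#'   `rep_pvalue`, `rep_wm_pvalue`, `rep_mode_pvalue` (NA for traits not
#'   replicated).
#' @export
replicate_screen <- function(screen, exposures, second_outcome, ld,
                             cfg = NULL) {
  cfg <- cfg %||% attr(screen, "config")
  ids <- map_chr(exposures, ~ meta_of(.x)$trait_id)
  screen$rep_estimate <- NA_real_
  screen$rep_pvalue <- NA_real_
  screen$rep_wm_pvalue <- NA_real_
  screen$rep_mode_pvalue <- NA_real_
  sig_idx <- which(screen$verdict == "significant")
  for (i in sig_idx) {
    exposure <- exposures[[match(screen$trait_id[i], ids)]]
    d <- run_trait_pipeline(exposure, second_outcome, ld, cfg)
    if (d$status != "analysed") next
    screen$rep_estimate[i] <- battery_get(d$battery, "ivw_mre")$estimate
    screen$rep_pvalue[i] <- battery_get(d$battery, "ivw_mre")$pvalue
    screen$rep_wm_pvalue[i] <- battery_get(d$battery,
                                           "weighted_median")$pvalue
    screen$rep_mode_pvalue[i] <- battery_get(d$battery,
                                             "weighted_mode")$pvalue
  }
  screen
}

#' Reverse-direction MR
#'
#' Swaps the roles of exposure and outcome and runs the standard univariable
#' pipeline, returning the MRE IVW result. A non-significant reverse estimate
#' supports the forward causal direction.
#'
#' @param exposure,outcome `mr_sumstats` tables (forward orientation).
#' @param ld An [ld_reference()].
#' @param cfg A [screen_config()].
#' @return A one-row `mr_result` tibble with attribute `degenerate` set when
#'   exposure and outcome are the same trait.
#' @export
reverse_mr <- function(exposure, outcome, ld, cfg = screen_config()) {
  d <- run_trait_pipeline(outcome, exposure, ld, cfg)
  if (d$status != "analysed") {
    abort(paste0("reverse MR not possible: ",
                 d$reason %||% "pipeline failure"),
          class = "mrscreen_insufficient")
  }
  res <- battery_get(d$battery, "ivw_mre")
  attr(res, "degenerate") <-
    identical(meta_of(exposure)$trait_id, meta_of(outcome)$trait_id)
  res
}
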