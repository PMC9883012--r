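#' Greedy LD clumping
#'
#' Thins a candidate set to approximately independent index variants:
#' repeatedly takes the remaining candidate with the smallest exposure p-value
#' as an index and discards all remaining candidates with r-squared above
#' `r2_max` within `window_kb` kilobases on the same chromosome.
#'
#' @param candidates Character vector of variant ids (must be present in
#'   `exposure`).
#' @param exposure An `mr_sumstats` table supplying p-values and positions.
#' @param ld An [ld_reference()]. Candidates absent from the reference are
#'   treated as independent (r-squared 0) and reported via a warning.
#' @param r2_max Maximum tolerated r-squared between retained variants.
#' @param window_kb Clumping window in kilobases.
#'
#' @return Character vector of retained variant ids, in retention order.
#' @export
clump <- function(candidates, exposure, ld, r2_max = 0.001,
                  window_kb = 10000) {
  if (length(candidates) == 0) return(character(0))
  df <- as_tibble(exposure)[as_tibble(exposure)$variant_id %in% candidates, ]
  if (nrow(df) < length(candidates)) {
    abort("some candidates are absent from the exposure data",
          class = "mrscreen_input")
  }
  unknown <- setdiff(candidates, ld$blocks$variant_id)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown),
                " candidate(s) absent from the LD reference; treated as",
                " independent"))
  }
  df <- df[order(df$pvalue, df$variant_id), ]
  kept <- character(0)
  window_bp <- window_kb * 1000
  while (nrow(df) > 0) {
    idx <- df[1, ]
    kept <- c(kept, idx$variant_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    in_window <- df$chrom == idx$chrom &
      !is.na(df$pos) & !is.na(idx$pos) &
      abs(df$pos - idx$pos) <= window_bp
    if (any(in_window)) {
      r2 <- ld_r2(ld, rep(idx$variant_id, sum(in_window)),
                  df$variant_id[in_window])
      discard <- df$variant_id[in_window][r2 > r2_max]
      df <- df[!df$variant_id %in% discard, , drop = FALSE]
    }
  }
  kept
}

#' Adaptive p-value-ladder instrument selection
#'
#' Selects instruments for an exposure trait at the smallest p-value threshold
#' on the ladder 5e-8, 5e-7, 5e-6, 5e-5 at which more than `min_count - 1`
#' post-clumping instruments are available. The analysis starts at genome-wide
#' significance and relaxes the threshold by a factor of 10 at a time up to
#' the predefined maximum of 5e-5; if even that rung yields fewer than
#' `min_count` instruments the selection is returned flagged insufficient
#' (insufficiency is a flag, not an error).
#'
#' @param exposure An `mr_sumstats` table.
#' @param ld An [ld_reference()] used for clumping.
#' @param min_count Minimum instrument count (default 6, encoding "more than
#'   5 instruments").
#' @param ladder Increasing p-value thresholds to try.
#' @param r2_max,window_kb Clumping parameters (see [clump()]).
#'
#' @return An `mr_selection` list: `threshold_used`, `instruments` (retained
#'   ids in clumping order), `n_selected`, `sufficient`, and `ladder_log`
#'   (a tibble of every threshold attempted with its post-clumping count).
#' @export
select_instruments <- function(exposure, ld, min_count = 6,
                               ladder = c(5e-8, 5e-7, 5e-6, 5e-5),
                               r2_max = 0.001, window_kb = 10000) {
  stopifnot(min_count >= 1, nrow(exposure) > 0)
  ladder <- sort(ladder)
  log_rows <- list()
  selected <- character(0)
  threshold_used <- ladder[length(ladder)]
  sufficient <- FALSE
  for (thr in ladder) {
    cand <- exposure$variant_id[exposure$pvalue < thr]
    sel <- clump(cand, exposure, ld, r2_max = r2_max, window_kb = window_kb)
    log_rows[[length(log_rows) + 1]] <- tibble(threshold = thr,
                                               count = length(sel))
    if (length(sel) >= min_count) {
      selected <- sel
      threshold_used <- thr
      sufficient <- TRUE
      break
    }
    selected <- sel
    threshold_used <- thr
  }
  structure(
    list(threshold_used = threshold_used,
         instruments = selected,
         n_selected = length(selected),
         sufficient = sufficient,
         ladder_log = bind_rows(log_rows)),
    class = "mr_selection"
  )
}

#' @export
print.mr_selection <- function(x, ...) {
  cat(sprintf("<mr_selection> %d instrument(s) at p < %g%s\n",
              x$n_selected, x$threshold_used,
              if (x$sufficient) "" else " [insufficient]"))
  invisible(x)
}

#' Find an LD proxy for an instrument missing from the outcome data
#'
#' Among outcome variants in LD with `missing_id` at r-squared at or above
#' `r2_min`, returns the highest-r-squared candidate together with the allele
#' phase (which proxy allele tracks the index variant's effect allele). Ties
#' are broken by the smaller outcome p-value, then lexicographic id.
#'
#' @param missing_id Variant id absent from the outcome.
#' @param outcome An `mr_sumstats` table.
#' @param ld An [ld_reference()].
#' @param r2_min Minimum acceptable r-squared (default 0.9).
#'
#' @return A one-row tibble (`proxy_id`, `r2`, `index_allele`,
#'   `proxy_allele`) or `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(missing_id, outcome, ld, r2_min = 0.9) {
  partners <- ld_partners(ld, missing_id, r2_min = r2_min)
  partners <- partners[partners$partner %in% outcome$variant_id, ]
  if (nrow(partners) == 0) return(NULL)
  pv <- setNames(outcome$pvalue, outcome$variant_id)[partners$partner]
  ord <- order(-partners$r2, pv, partners$partner)
  best <- partners[ord[1], ]
  tibble(proxy_id = best$partner, r2 = best$r2,
         index_allele = best$index_allele, proxy_allele = best$partner_allele)
}

# Align one outcome row's (ea, oa, beta, eaf) to a reference allele pair.
# Returns list(beta, eaf, status) with status in
# {ok, flipped, palindromic_ambiguous, irreconcilable, missing_eaf}.
align_alleles <- function(ref_ea, ref_oa, ea, oa, beta, eaf,
                          ref_eaf = NA_real_, palindrome_maf = 0.42) {
  flip <- function() list(beta = -beta, eaf = 1 - eaf, status = "flipped")
  keep <- function() list(beta = beta, eaf = eaf, status = "ok")
  fail <- function(s) list(beta = NA_real_, eaf = NA_real_, status = s)
  if (is_palindromic(ref_ea, ref_oa)) {
    # labels cannot resolve strand; use allele frequency
    if (!(ea %in% c(ref_ea, ref_oa)) || !(oa %in% c(ref_ea, ref_oa)) ||
        ea == oa) {
      return(fail("irreconcilable"))
    }
    if (is.na(eaf) || is.na(ref_eaf)) return(fail("missing_eaf"))
    maf_ref <- pmin(ref_eaf, 1 - ref_eaf)
    maf_out <- pmin(eaf, 1 - eaf)
    if (maf_ref > palindrome_maf || maf_out > palindrome_maf) {
      return(fail("palindromic_ambiguous"))
    }
    eaf_labelled <- if (ea == ref_ea) eaf else 1 - eaf
    beta_labelled <- if (ea == ref_ea) beta else -beta
    if ((ref_eaf - 0.5) * (eaf_labelled - 0.5) > 0) {
      # same physical allele as labelled
      return(list(beta = beta_labelled, eaf = eaf_labelled,
                  status = if (ea == ref_ea) "ok" else "flipped"))
    }
    # frequencies disagree: labels are on the opposite strand
    return(list(beta = -beta_labelled, eaf = 1 - eaf_labelled,
                status = "strand"))
  }
  if (ea == ref_ea && oa == ref_oa) return(keep())
  if (ea == ref_oa && oa == ref_ea) return(flip())
  cea <- allele_complement(ea)
  coa <- allele_complement(oa)
  if (cea == ref_ea && coa == ref_oa) return(keep())
  if (cea == ref_oa && coa == ref_ea) return(flip())
  fail("irreconcilable")
}

#' Harmonise exposure and outcome associations to a shared allele convention
#'
#' For each selected instrument (or its LD proxy when the instrument is
#' absent from the outcome data), expresses the outcome beta per additional
#' copy of the exposure's effect allele: swapped allele orders flip the beta
#' sign, strand-complement encodings are complemented then aligned, and
#' palindromic variants are resolved by allele frequency — or dropped when the
#' minor allele frequency exceeds `palindrome_maf` in either dataset (or when
#' frequency is missing). Irreconcilable allele pairs are dropped. All drops
#' are logged with reasons.
#'
#' @param exposure,outcome `mr_sumstats` tables.
#' @param selection An `mr_selection` from [select_instruments()], or a
#'   character vector of instrument ids.
#' @param ld An [ld_reference()] used for proxy lookup.
#' @param palindrome_maf Palindromic variants with minor allele frequency
#'   above this value in either dataset are dropped (default 0.42).
#' @param proxy_r2_min Minimum proxy r-squared (see [find_proxy()]); set to
#'   `NA` to disable proxy substitution.
#'
#' @return An `mr_harmonised` tibble with columns `variant_id`, `ea`, `oa`,
#'   `b_x`, `se_x`, `p_x`, `eaf_x`, `b_y`, `se_y`, `p_y`, `eaf_y`,
#'   `proxy_id`, `proxy_r2`, carrying `exposure_meta`, `outcome_meta` and a
#'   `drop_log` attribute.
#' @export
harmonise <- function(exposure, outcome, selection, ld,
                      palindrome_maf = 0.42, proxy_r2_min = 0.9) {
  ids <- if (inherits(selection, "mr_selection")) selection$instruments
         else as.character(selection)
  exp_df <- as_tibble(exposure)
  out_df <- as_tibble(outcome)
  out_idx <- match(ids, out_df$variant_id)
  rows <- vector("list", length(ids))
  drops <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    e <- exp_df[exp_df$variant_id == id, ]
    if (nrow(e) == 0) {
      drops[[length(drops) + 1]] <- tibble(variant_id = id,
                                           reason = "absent_from_exposure")
      next
    }
    proxy_id <- NA_character_
    proxy_r2 <- NA_real_
    if (is.na(out_idx[i])) {
      prx <- if (!is.na(proxy_r2_min)) find_proxy(id, outcome, ld,
                                                  r2_min = proxy_r2_min)
             else NULL
      if (is.null(prx)) {
        drops[[length(drops) + 1]] <- tibble(variant_id = id,
                                             reason = "absent_from_outcome")
        next
      }
      o <- out_df[out_df$variant_id == prx$proxy_id, ]
      # align the proxy's outcome beta to the proxy's exposure-strand allele
      # labels (using its exposure record when available), then orient via
      # the recorded phase so the beta is expressed per copy of the index
      # variant's effect allele
      pe <- exp_df[exp_df$variant_id == prx$proxy_id, ]
      if (nrow(pe) == 1) {
        al <- align_alleles(pe$ea, pe$oa, o$ea, o$oa, o$beta, o$eaf,
                            ref_eaf = pe$eaf,
                            palindrome_maf = palindrome_maf)
        proxy_ref_ea <- pe$ea
      } else {
        al <- align_alleles(prx$proxy_allele,
                            setdiff(c(o$ea, o$oa), prx$proxy_allele)[1],
                            o$ea, o$oa, o$beta, o$eaf,
                            ref_eaf = e$eaf, palindrome_maf = palindrome_maf)
        proxy_ref_ea <- prx$proxy_allele
      }
      if (is.na(al$beta)) {
        drops[[length(drops) + 1]] <- tibble(variant_id = id,
                                             reason = paste0("proxy_",
                                                             al$status))
        next
      }
      # beta is per proxy_ref_ea; the phase says prx$proxy_allele tracks
      # prx$index_allele of the index variant
      if (prx$proxy_allele != proxy_ref_ea) al$beta <- -al$beta
      if (prx$index_allele != e$ea) al$beta <- -al$beta
      proxy_id <- prx$proxy_id
      proxy_r2 <- prx$r2
      o_b <- al$beta; o_eaf <- NA_real_; o_se <- o$se; o_p <- o$pvalue
    } else {
      o <- out_df[out_idx[i], ]
      al <- align_alleles(e$ea, e$oa, o$ea, o$oa, o$beta, o$eaf,
                          ref_eaf = e$eaf, palindrome_maf = palindrome_maf)
      if (is.na(al$beta)) {
        drops[[length(drops) + 1]] <- tibble(variant_id = id,
                                             reason = al$status)
        next
      }
      o_b <- al$beta; o_eaf <- al$eaf; o_se <- o$se; o_p <- o$pvalue
    }
    rows[[i]] <- tibble(
      variant_id = id, ea = e$ea, oa = e$oa,
      b_x = e$beta, se_x = e$se, p_x = e$pvalue, eaf_x = e$eaf,
      b_y = o_b, se_y = o_se, p_y = o_p, eaf_y = o_eaf,
      proxy_id = proxy_id, proxy_r2 = proxy_r2
    )
  }
  out <- bind_rows(rows[!map_lgl(rows, is.null)])
  if (nrow(out) == 0) {
    out <- tibble(variant_id = character(), ea = character(),
                  oa = character(), b_x = numeric(), se_x = numeric(),
                  p_x = numeric(), eaf_x = numeric(), b_y = numeric(),
                  se_y = numeric(), p_y = numeric(), eaf_y = numeric(),
                  proxy_id = character(), proxy_r2 = numeric())
  }
  new_harmonised(out,
                 exposure_meta = meta_of(exposure),
                 outcome_meta = meta_of(outcome),
                 drop_log = if (length(drops)) bind_rows(drops)
                            else tibble(variant_id = character(),
                                        reason = character()))
}

#' Construct a harmonised instrument set directly
#'
#' Builds an `mr_harmonised` set from aligned per-instrument association
#' vectors, bypassing allele harmonisation — useful when associations are
#' already expressed per copy of the same allele (e.g. simulation studies or
#' externally harmonised data).
#'
#' @param b_x,se_x Exposure betas and standard errors.
#' @param b_y,se_y Outcome betas and standard errors (same allele as `b_x`).
#' @param p_x,p_y P-values; derived from the normal approximation when
#'   omitted.
#' @param variant_id Instrument identifiers.
#' @param exposure_meta,outcome_meta Optional [trait_meta()] objects.
#' @return An `mr_harmonised` tibble.
#' @export
harmonised_set <- function(b_x, se_x, b_y, se_y,
                           p_x = p_from_z(b_x / se_x),
                           p_y = p_from_z(b_y / se_y),
                           variant_id = sprintf("rs%06d", seq_along(b_x)),
                           exposure_meta = trait_meta("exposure"),
                           outcome_meta = trait_meta("outcome")) {
  stopifnot(all(se_x > 0), all(se_y > 0))
  df <- tibble(
    variant_id = variant_id, ea = "A", oa = "G",
    b_x = b_x, se_x = se_x, p_x = p_x, eaf_x = NA_real_,
    b_y = b_y, se_y = se_y, p_y = p_y, eaf_y = NA_real_,
    proxy_id = NA_character_, proxy_r2 = NA_real_
  )
  new_harmonised(df, exposure_meta, outcome_meta,
                 drop_log = tibble(variant_id = character(),
                                   reason = character()))
}

new_harmonised <- function(df, exposure_meta, outcome_meta, drop_log) {
  structure(as_tibble(df),
            class = c("mr_harmonised", class(tibble())),
            exposure_meta = exposure_meta,
            outcome_meta = outcome_meta,
            drop_log = drop_log)
}

#' @export
print.mr_harmonised <- function(x, ...) {
  em <- attr(x, "exposure_meta"); om <- attr(x, "outcome_meta")
  cat(sprintf("<mr_harmonised> %s -> %s: %d instrument(s), %d dropped\n",
              if (is.null(em)) "?" else em$trait_id,
              if (is.null(om)) "?" else om$trait_id,
              nrow(x), nrow(attr(x, "drop_log") %||% tibble())))
  NextMethod()
}

# Rebuild an mr_harmonised after row filtering, appending to the drop log.
harmonised_subset <- function(hset, keep, reason) {
  dropped <- hset$variant_id[!keep]
  log <- attr(hset, "drop_log") %||% tibble(variant_id = character(),
                                            reason = character())
  if (length(dropped) > 0) {
    log <- bind_rows(log, tibble(variant_id = dropped, reason = reason))
  }
  new_harmonised(as_tibble(hset)[keep, ],
                 exposure_meta = attr(hset, "exposure_meta"),
                 outcome_meta = attr(hset, "outcome_meta"),
                 drop_log = log)
}

#' Remove instruments more significant for the outcome than the exposure
#'
#' Drops every instrument whose outcome p-value is smaller than its exposure
#' p-value — a simple directionality guard against reverse-causal and grossly
#' pleiotropic variants. Idempotent; never increases the row count.
#'
#' @param hset An `mr_harmonised` set.
#' @return The filtered `mr_harmonised` set (removals logged).
#' @export
filter_outcome_significance <- function(hset) {
  harmonised_subset(hset, !(hset$p_y < hset$p_x), "outcome_more_significant")
}

#' Radial-MR outlier filtering with modified second-order weights
#'
#' Computes the radial (Galbraith) IVW fit with modified second-order weights
#' — weights that depend on the current slope estimate and are iterated to
#' convergence — and the per-variant contributions to Cochran's Q. Variants
#' whose contribution exceeds the upper-tail chi-squared(1) critical value at
#' `alpha` are removed and the fit repeated until no outliers remain.
#'
#' @param hset An `mr_harmonised` set with at least 3 instruments (smaller
#'   sets are returned unchanged with a warning).
#' @param alpha Upper-tail significance level for the per-variant Q
#'   contribution (default 0.05).
#' @param max_iter Maximum weight-update iterations per fit.
#' @return A list: `hset` (filtered set), `removed` (tibble of removed
#'   variants with their Q contributions), `q` (total Q of the final fit),
#'   `q_contributions` (per retained variant).
#' @export
radial_outlier_filter <- function(hset, alpha = 0.05, max_iter = 100) {
  if (nrow(hset) < 3) {
    warn("fewer than 3 instruments; radial outlier filtering skipped")
    return(list(hset = hset,
                removed = tibble(variant_id = character(), q = numeric()),
                q = NA_real_, q_contributions = numeric(0)))
  }
  removed <- list()
  current <- hset
  crit <- qchisq(1 - alpha, df = 1)
  repeat {
    fit <- radial_fit(current, max_iter = max_iter)
    worst <- which(fit$q_j > crit)
    if (length(worst) == 0 || nrow(current) <= 3) break
    removed[[length(removed) + 1]] <-
      tibble(variant_id = current$variant_id[worst], q = fit$q_j[worst])
    current <- harmonised_subset(current,
                                 !(seq_len(nrow(current)) %in% worst),
                                 "radial_outlier")
  }
  fit <- radial_fit(current, max_iter = max_iter)
  list(hset = current,
       removed = if (length(removed)) bind_rows(removed)
                 else tibble(variant_id = character(), q = numeric()),
       q = sum(fit$q_j),
       q_contributions = setNames(fit$q_j, current$variant_id))
}

# One radial IVW fit with modified second-order weights iterated to
# convergence. Returns the slope and per-variant Q contributions.
radial_fit <- function(hset, max_iter = 100, tol = 1e-10) {
  ratio <- hset$b_y / hset$b_x
  # first-order weights to start
  w <- hset$b_x^2 / hset$se_y^2
  theta <- sum(w * ratio) / sum(w)
  for (i in seq_len(max_iter)) {
    w_new <- hset$b_x^2 / (hset$se_y^2 + theta^2 * hset$se_x^2)
    theta_new <- sum(w_new * ratio) / sum(w_new)
    if (abs(theta_new - theta) < tol) {
      theta <- theta_new; w <- w_new
      break
    }
    theta <- theta_new; w <- w_new
  }
  q_j <- w * (ratio - theta)^2
  list(theta = theta, weights = w, q_j = q_j)
}
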