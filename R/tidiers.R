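# broom-style tidiers for fitted objects.

#' @method tidy mr_qc
#' @export
tidy.mr_qc <- function(x, ...) {
  x$loo
}

#' @method glance mr_qc
#' @export
glance.mr_qc <- function(x, ...) {
  tibble(
    n_snv = x$n_snv, mean_f = x$mean_f, cochran_q = x$cochran_q,
    q_df = x$q_df, q_pvalue = x$q_pvalue, i2_gx = x$i2_gx,
    egger_intercept = if (is.null(x$egger_intercept)) NA_real_
                      else x$egger_intercept$estimate,
    egger_intercept_p = if (is.null(x$egger_intercept)) NA_real_
                        else x$egger_intercept$pvalue,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @method tidy mvmr_result
#' @export
tidy.mvmr_result <- function(x, ...) {
  rename(x$estimates, term = "exposure")
}

#' @method glance mvmr_result
#' @export
glance.mvmr_result <- function(x, ...) {
  tibble(n_snv = x$n_snv, adjusted_q = x$adjusted_q,
         adjusted_q_df = x$adjusted_q_df,
         adjusted_q_pvalue = x$adjusted_q_pvalue,
         heterogeneous = x$heterogeneous)
}

#' @method tidy bma_result
#' @export
tidy.bma_result <- function(x, ...) {
  rename(x$traits, term = "trait_id")
}

#' @method glance bma_result
#' @export
glance.bma_result <- function(x, ...) {
  tibble(
    n_traits = nrow(x$traits),
    n_models = nrow(x$models),
    n_outliers_removed = nrow(x$outliers_removed),
    n_pruned = length(x$pruned_traits),
    n_perm = x$n_perm,
    top_trait = x$traits$trait_id[1],
    top_mip = x$traits$mip[1]
  )
}

#' @method tidy mr_selection
#' @export
tidy.mr_selection <- function(x, ...) {
  x$ladder_log
}

#' @method glance mr_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble(
    n_traits = nrow(x),
    n_analysed = sum(x$status == "analysed"),
    n_excluded = sum(x$status != "analysed"),
    n_significant = sum(x$verdict == "significant")
  )
}
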