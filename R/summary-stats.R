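#' Trait metadata
#'
#' Describes one GWAS trait: its identifier, human-readable name, sample size,
#' whether it is binary or continuous, and the batch/population tags used for
#' screen-level exclusion rules.
#'
#' @param trait_id Unique trait identifier (e.g. `"met-c-935"`).
#' @param trait_name Human-readable trait name.
#' @param sample_size GWAS sample size.
#' @param trait_type `"continuous"` or `"binary"`. Continuous exposures are
#'   reported both on the beta scale and as odds ratios per SD; binary
#'   exposures report beta only.
#' @param batch Source batch tag (e.g. `"ukb"`, `"met-d"`); screens can
#'   exclude whole batches.
#' @param population Population label (e.g. `"EUR"`).
#'
#' @return A `trait_meta` object (named list).
#' @export
trait_meta <- function(trait_id, trait_name = trait_id, sample_size = NA_integer_,
                       trait_type = c("continuous", "binary"),
                       batch = "synthetic", population = "EUR") {
  trait_type <- match.arg(trait_type)
  structure(
    list(
      trait_id = as.character(trait_id),
      trait_name = as.character(trait_name),
      sample_size = as.integer(sample_size),
      trait_type = trait_type,
      batch = as.character(batch),
      population = as.character(population)
    ),
    class = "trait_meta"
  )
}

#' @export
print.trait_meta <- function(x, ...) {
  cat(sprintf("<trait_meta> %s (%s), n = %s, type = %s, batch = %s\n",
              x$trait_id, x$trait_name, x$sample_size, x$trait_type, x$batch))
  invisible(x)
}

sumstats_cols <- c("variant_id", "chrom", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pvalue", "n")

#' Build a validated GWAS summary-statistics table
#'
#' Validates per-variant association records and attaches trait metadata. Rows
#' violating the record invariants (non-SNV alleles, identical alleles,
#' non-positive standard errors, p-values outside (0, 1], allele frequencies
#' outside (0, 1), duplicated variant identifiers) are dropped and logged.
#'
#' @param x A data frame with columns `variant_id`, `ea`, `oa`, `beta`, `se`,
#'   `pvalue` and optionally `chrom`, `pos`, `eaf`, `n`.
#' @param meta A [trait_meta()] object.
#'
#' @return A tibble of class `mr_sumstats` with attributes `meta` (the trait
#'   metadata) and `drop_log` (a tibble of dropped rows with reasons).
#' @export
summary_stats <- function(x, meta) {
  stopifnot(inherits(meta, "trait_meta"))
  x <- as_tibble(x)
  required <- c("variant_id", "ea", "oa", "beta", "se", "pvalue")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrscreen_format")
  }
  if (nrow(x) == 0) {
    abort("summary statistics table is empty", class = "mrscreen_empty")
  }
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- x[sumstats_cols]
  x <- mutate(x,
    variant_id = as.character(.data$variant_id),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    ea = toupper(as.character(.data$ea)),
    oa = toupper(as.character(.data$oa)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pvalue = as.numeric(.data$pvalue),
    n = as.integer(.data$n)
  )

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(x))
  bad_allele <- !(x$ea %in% bases) | !(x$oa %in% bases)
  reason[bad_allele] <- "non_snv_allele"
  same_allele <- !bad_allele & x$ea == x$oa
  reason[same_allele] <- "identical_alleles"
  bad_se <- is.na(reason) & (!is.finite(x$se) | x$se <= 0)
  reason[bad_se] <- "nonpositive_se"
  bad_beta <- is.na(reason) & !is.finite(x$beta)
  reason[bad_beta] <- "missing_beta"
  bad_p <- is.na(reason) & (!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1)
  reason[bad_p] <- "invalid_pvalue"
  bad_eaf <- is.na(reason) & !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)
  reason[bad_eaf] <- "invalid_eaf"
  dup <- is.na(reason) & duplicated(x$variant_id)
  reason[dup] <- "duplicate_variant_id"

  drop_log <- tibble(variant_id = x$variant_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  out <- x[is.na(reason), ]
  structure(out,
            class = c("mr_sumstats", class(tibble())),
            meta = meta,
            drop_log = drop_log)
}

#' @export
print.mr_sumstats <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<mr_sumstats> trait %s: %d variants (%d dropped on read)\n",
              meta$trait_id, nrow(x), nrow(attr(x, "drop_log"))))
  NextMethod()
}

#' Trait metadata accessor
#' @param x An `mr_sumstats` object (or any object carrying a `meta` attribute).
#' @return The [trait_meta()] object.
#' @export
meta_of <- function(x) attr(x, "meta")

#' Read GWAS summary statistics from a TSV file
#'
#' Reads the tab-separated summary-statistics dialect (columns `SNP`, `CHR`,
#' `BP`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`; `.` or empty for missing)
#' and validates it through [summary_stats()].
#'
#' @param path Path to a TSV file.
#' @param meta A [trait_meta()] object for the trait.
#' @return An `mr_sumstats` tibble.
#' @export
read_summary_stats <- function(path, meta) {
  raw <- readr::read_tsv(path, na = c(".", "", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  required <- c("SNP", "EA", "OA", "BETA", "SE", "P")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrscreen_format")
  }
  if (nrow(raw) == 0) {
    abort(paste0("empty summary-statistics file: ", path),
          class = "mrscreen_empty")
  }
  df <- tibble(
    variant_id = as.character(raw$SNP),
    chrom = if ("CHR" %in% names(raw)) as.character(raw$CHR) else NA_character_,
    pos = if ("BP" %in% names(raw)) as.integer(raw$BP) else NA_integer_,
    ea = as.character(raw$EA),
    oa = as.character(raw$OA),
    eaf = if ("EAF" %in% names(raw)) as.numeric(raw$EAF) else NA_real_,
    beta = as.numeric(raw$BETA),
    se = as.numeric(raw$SE),
    pvalue = as.numeric(raw$P),
    n = if ("N" %in% names(raw)) as.integer(raw$N) else NA_integer_
  )
  # multi-character alleles (indels) are rejected by summary_stats validation
  summary_stats(df, meta)
}

#' Write summary statistics to the TSV dialect
#'
#' @param x An `mr_sumstats` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  out <- tibble(
    SNP = x$variant_id, CHR = x$chrom, BP = x$pos, EA = x$ea, OA = x$oa,
    EAF = x$eaf, BETA = x$beta, SE = x$se, P = x$pvalue, N = x$n
  )
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Writes any per-record result tibble with a deterministic column order
#' (the order of the input schema); round-trips through [read_results_table()].
#'
#' @param records A data frame of results sharing one schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as_tibble(records)
  keep <- !map_lgl(records, is.list)
  readr::write_tsv(records[keep], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, na = c(".", "", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}
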