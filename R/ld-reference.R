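#' Linkage-disequilibrium reference
#'
#' A block-diagonal LD reference: variants are partitioned into blocks, with
#' pairwise r-squared recorded within blocks (zero across blocks) and, for each
#' correlated pair, the allele phase — which allele of one variant co-occurs
#' with which allele of the other. Phase is what makes proxy substitution
#' well-defined: the proxy's aligned allele tracks the index variant's effect
#' allele.
#'
#' @param blocks A data frame with columns `variant_id`, `block`.
#' @param pairs A data frame with columns `variant_a`, `allele_a`, `variant_b`,
#'   `allele_b`, `r2` listing correlated pairs (each unordered pair once).
#'
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(blocks, pairs) {
  blocks <- as_tibble(blocks)
  pairs <- as_tibble(pairs)
  stopifnot(all(c("variant_id", "block") %in% names(blocks)),
            all(c("variant_a", "allele_a", "variant_b", "allele_b", "r2")
                %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
    abort("r2 values must lie in [0, 1]", class = "mrscreen_config")
  }
  structure(list(blocks = blocks, pairs = pairs), class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d variants in %d blocks, %d correlated pairs\n",
              nrow(x$blocks), length(unique(x$blocks$block)), nrow(x$pairs)))
  invisible(x)
}

# Pairwise r2 lookup; variants absent from the reference (or in different
# blocks) are treated as independent (r2 = 0).
ld_r2 <- function(ld, a, b) {
  if (length(a) == 0) return(numeric(0))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  lut <- setNames(ld$pairs$r2, key(ld$pairs$variant_a, ld$pairs$variant_b))
  out <- unname(lut[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

# All LD partners of `id` with r2 >= r2_min, with phase (which partner allele
# tracks `phase_allele` of the index variant).
ld_partners <- function(ld, id, r2_min = 0) {
  p <- ld$pairs
  fwd <- p[p$variant_a == id & p$r2 >= r2_min, ]
  rev <- p[p$variant_b == id & p$r2 >= r2_min, ]
  bind_rows(
    tibble(partner = fwd$variant_b, index_allele = fwd$allele_a,
           partner_allele = fwd$allele_b, r2 = fwd$r2),
    tibble(partner = rev$variant_a, index_allele = rev$allele_b,
           partner_allele = rev$allele_a, r2 = rev$r2)
  )
}

#' Write / read an LD reference as a pair of TSV files
#'
#' Serialises the block assignment and the correlated-pair table to
#' `<stem>_blocks.tsv` and `<stem>_pairs.tsv`.
#'
#' @param ld An [ld_reference()] object.
#' @param stem Path stem for the two TSV files.
#' @return `stem` (for write), an `ld_reference` (for read).
#' @export
write_ld_reference <- function(ld, stem) {
  readr::write_tsv(ld$blocks, paste0(stem, "_blocks.tsv"), progress = FALSE)
  readr::write_tsv(ld$pairs, paste0(stem, "_pairs.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_ld_reference
#' @export
read_ld_reference <- function(stem) {
  blocks <- readr::read_tsv(paste0(stem, "_blocks.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  pairs <- readr::read_tsv(paste0(stem, "_pairs.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  ld_reference(blocks, pairs)
}
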