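# Independent oracles and small fixture builders used across test files.

# Brute-force greedy clumping oracle: an independent, deliberately naive
# implementation that enumerates the greedy-by-p independent set using a full
# pairwise r2 matrix.
oracle_clump <- function(candidates, exposure, ld, r2_max = 0.001,
                         window_kb = 10000) {
  df <- as.data.frame(exposure)
  df <- df[df$variant_id %in% candidates, ]
  df <- df[order(df$pvalue, df$variant_id), ]
  n <- nrow(df)
  if (n == 0) return(character(0))
  r2m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same_chr <- identical(df$chrom[i], df$chrom[j])
      close <- !is.na(df$pos[i]) && !is.na(df$pos[j]) &&
        abs(df$pos[i] - df$pos[j]) <= window_kb * 1000
      r2m[i, j] <- if (i == j) 1
                   else if (same_chr && close) {
                     mrscreen:::ld_r2(ld, df$variant_id[i], df$variant_id[j])
                   } else 0
    }
  }
  alive <- rep(TRUE, n)
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[r2m[i, ] > r2_max] <- FALSE
  }
  df$variant_id[kept]
}

# Brute-force Benjamini-Hochberg oracle (direct step-up definition).
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord] * n / seq_len(n)
  for (i in seq_len(n)) {
    adj[i] <- min(sorted[i:n])
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Small synthetic summary-statistics table with independent variants.
make_sumstats <- function(beta, se, pvalue = NULL, ids = NULL,
                          chrom = "1", pos = NULL, ea = "A", oa = "G",
                          eaf = 0.3, trait_id = "trait", n = 10000L,
                          batch = "synthetic", trait_name = trait_id) {
  m <- length(beta)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 20000000L
  summary_stats(
    tibble::tibble(variant_id = ids, chrom = chrom, pos = pos,
                   ea = ea, oa = oa, eaf = eaf, beta = beta, se = se,
                   pvalue = pvalue, n = n),
    trait_meta(trait_id, trait_name, n, "continuous", batch = batch))
}

# LD reference in which every variant is independent.
empty_ld <- function(ids) {
  ld_reference(
    tibble::tibble(variant_id = ids, block = seq_along(ids)),
    tibble::tibble(variant_a = character(), allele_a = character(),
                   variant_b = character(), allele_b = character(),
                   r2 = numeric()))
}
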