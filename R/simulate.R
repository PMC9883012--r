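#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Declares the ground-truth generative model for a two-sample MR simulation:
#' LD-blocked variants, true per-variant exposure effects, a causal effect of
#' the exposure on the outcome, optional invalid (pleiotropic) instruments,
#' palindromic and strand-discordant allele encodings, and multi-exposure
#' designs with a known effect correlation.
#'
#' True exposure effects are drawn from a zero-centred Gaussian with standard
#' deviation `effect_sd`; with the default sample sizes this yields per-variant
#' F-statistics spanning tens to hundreds, so the mean-F > 10 instrument
#' strength gate is exercised on both sides. Directional pleiotropy is
#' expressed per exposure-increasing allele (the direct outcome effect of an
#' invalid variant has mean `pleiotropy_mean` on the allele that increases the
#' exposure), the orientation in which MR-Egger estimates it. Correlated
#' pleiotropy acts through a latent confounder with loadings on both exposure
#' and outcome. Observed estimates are truth plus Gaussian noise with
#' `se = (2 n eaf (1 - eaf))^(-1/2)`, the standard error of a standardised
#' per-allele regression estimate; p-values come from the normal approximation
#' of beta / se.
#'
#' @param n_variants Number of variants to simulate.
#' @param n_blocks Number of LD blocks (variants are split evenly).
#' @param block_r2 Length-2 bounds; within-block pairwise r-squared is drawn
#'   uniformly between them.
#' @param n_exposure,n_outcome GWAS sample sizes of the two cohorts.
#' @param theta True causal effect(s); a scalar for [simulate_pair()], a
#'   length-K vector for [simulate_multi_exposure()].
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"correlated"`.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct (pleiotropic)
#'   outcome effect of invalid variants (mean applies to directional mode, on
#'   the exposure-increasing allele).
#' @param prop_invalid Fraction of variants given a pleiotropic direct effect.
#' @param prop_reverse Fraction of variants that are reverse-causal: primarily
#'   associated with the outcome, with an exposure association induced at
#'   `reverse_scale` times the outcome effect.
#' @param reverse_effect_sd SD of the direct outcome effect of reverse-causal
#'   variants.
#' @param reverse_scale Induced exposure effect per unit outcome effect for
#'   reverse-causal variants.
#' @param confounder_sd_x,confounder_sd_y Loadings of the latent confounder on
#'   exposure and outcome (correlated pleiotropy mode only).
#' @param prop_palindromic Fraction of variants given palindromic (A/T or G/C)
#'   alleles.
#' @param prop_palindromic_ambiguous Fraction of palindromic variants whose
#'   allele frequency is drawn inside the ambiguity zone (0.42, 0.58).
#' @param prop_strand_flipped Fraction of variants re-encoded on the opposite
#'   strand in the outcome file.
#' @param prop_allele_swap Fraction of outcome rows listing effect/other
#'   alleles in swapped order (with beta negated and EAF complemented — a pure
#'   re-encoding harmonisation must undo).
#' @param prop_missing_outcome Fraction of variants omitted from the outcome
#'   file (to exercise proxy substitution).
#' @param prop_missing_eaf Fraction of variants with missing allele frequency.
#' @param effect_sd SD of true per-variant exposure effects.
#' @param exposure_corr K x K correlation matrix of true effects across
#'   exposures (multi-exposure designs); `NULL` for a single exposure.
#' @param eaf_range Range from which non-palindromic allele frequencies are
#'   drawn.
#' @param seed Integer seed; identical config and seed give identical output.
#'
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_variants = 100,
                       n_blocks = 50,
                       block_r2 = c(0.1, 0.8),
                       n_exposure = 50000,
                       n_outcome = 50000,
                       theta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "correlated"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       prop_invalid = 0,
                       prop_reverse = 0,
                       reverse_effect_sd = 0.1,
                       reverse_scale = 0.3,
                       confounder_sd_x = 0.05,
                       confounder_sd_y = 0.05,
                       prop_palindromic = 0,
                       prop_palindromic_ambiguous = 0.5,
                       prop_strand_flipped = 0,
                       prop_allele_swap = 0.3,
                       prop_missing_outcome = 0,
                       prop_missing_eaf = 0,
                       effect_sd = 0.05,
                       exposure_corr = NULL,
                       eaf_range = c(0.05, 0.95),
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  fracs <- c(prop_invalid = prop_invalid, prop_reverse = prop_reverse,
             prop_palindromic = prop_palindromic,
             prop_palindromic_ambiguous = prop_palindromic_ambiguous,
             prop_strand_flipped = prop_strand_flipped,
             prop_allele_swap = prop_allele_swap,
             prop_missing_outcome = prop_missing_outcome,
             prop_missing_eaf = prop_missing_eaf)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all proportions must lie in [0, 1]", class = "mrscreen_config")
  }
  if (!is.null(exposure_corr)) {
    exposure_corr <- as.matrix(exposure_corr)
    check_psd(exposure_corr, "exposure_corr")
    if (any(abs(diag(exposure_corr) - 1) > 1e-8)) {
      abort("exposure_corr must have unit diagonal", class = "mrscreen_config")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# Assign variants to blocks, chromosomes and positions. Blocks are placed 20 Mb
# apart so the clumping window never spans two blocks.
sim_variant_frame <- function(cfg) {
  m <- cfg$n_variants
  block <- sort(rep_len(seq_len(cfg$n_blocks), m))
  block_chrom <- ((seq_len(cfg$n_blocks) - 1) %% 22) + 1
  per_chrom_idx <- stats::ave(seq_len(cfg$n_blocks), block_chrom,
                              FUN = seq_along)
  tibble(
    variant_id = sprintf("rs%06d", seq_len(m)),
    block = block,
    chrom = as.character(block_chrom[block]),
    pos = as.integer(per_chrom_idx[block] * 2e7 +
                       stats::ave(seq_len(m), block, FUN = seq_along) * 1000L)
  )
}

sim_alleles <- function(m, palindromic) {
  npairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                     "G","A", "G","T", "T","C", "T","G"),
                   ncol = 2, byrow = TRUE)
  ppairs <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                   ncol = 2, byrow = TRUE)
  idx_n <- sample.int(nrow(npairs), m, replace = TRUE)
  idx_p <- sample.int(nrow(ppairs), m, replace = TRUE)
  ea <- ifelse(palindromic, ppairs[idx_p, 1], npairs[idx_n, 1])
  oa <- ifelse(palindromic, ppairs[idx_p, 2], npairs[idx_n, 2])
  list(ea = ea, oa = oa)
}

# Correlate true effects within LD blocks: each non-lead variant's marginal
# effect is sqrt(r2) times the block lead's (sign set by allele phase) plus an
# independent residual, so proxies genuinely tag their index variant's signal.
block_correlate <- function(b_x, vf, pairs, ea) {
  if (nrow(pairs) == 0) return(b_x)
  idx <- setNames(seq_along(b_x), vf$variant_id)
  for (bl in unique(vf$block[duplicated(vf$block)])) {
    members <- vf$variant_id[vf$block == bl]
    lead <- members[1]
    pr <- pairs[pairs$variant_a == lead & pairs$variant_b %in% members, ]
    if (nrow(pr) == 0) next
    j <- idx[pr$variant_b]
    s <- ifelse(pr$allele_b == ea[j], 1, -1)
    b_x[j] <- s * sqrt(pr$r2) * b_x[idx[lead]] +
      sqrt(1 - pr$r2) * b_x[j]
  }
  b_x
}

# Core single-exposure truth draw shared by simulate_pair and the screen panel.
sim_truth_draw <- function(cfg, m, b_x = rnorm(m, 0, cfg$effect_sd)) {
  invalid <- runif(m) < cfg$prop_invalid
  alpha <- numeric(m)
  n_inv <- sum(invalid)
  if (n_inv > 0) {
    alpha[invalid] <- switch(cfg$pleiotropy_mode,
      none = 0,
      balanced = rnorm(n_inv, 0, cfg$pleiotropy_sd),
      # directional pleiotropy acts on the exposure-increasing allele
      directional = sign(b_x[invalid]) *
        rnorm(n_inv, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      correlated = {
        u <- rnorm(n_inv)
        b_x[invalid] <- b_x[invalid] + cfg$confounder_sd_x * u
        cfg$confounder_sd_y * u
      }
    )
  }
  reverse <- runif(m) < cfg$prop_reverse
  if (any(reverse)) {
    g <- rnorm(sum(reverse), 0, cfg$reverse_effect_sd)
    alpha[reverse] <- alpha[reverse] + g
    b_x[reverse] <- cfg$reverse_scale * g
  }
  list(b_x = b_x, alpha = alpha, invalid = invalid, reverse = reverse)
}

sim_eaf <- function(cfg, m, palindromic) {
  eaf <- runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
  amb <- palindromic & runif(m) < cfg$prop_palindromic_ambiguous
  eaf[amb] <- runif(sum(amb), 0.44, 0.56)
  # unambiguous palindromes stay clear of the (0.42, 0.58) zone
  clear <- palindromic & !amb
  if (any(clear)) {
    lo <- runif(sum(clear)) < 0.5
    eaf[clear] <- ifelse(lo, runif(sum(clear), cfg$eaf_range[1], 0.40),
                         runif(sum(clear), 0.60, cfg$eaf_range[2]))
  }
  eaf
}

sim_ld_pairs <- function(cfg, vf, ea, oa) {
  by_block <- split(seq_len(nrow(vf)), vf$block)
  # per-variant haplotype orientation: whether the effect allele sits on the
  # block's reference haplotype; pairwise phase is then transitively
  # consistent within a block
  orient <- runif(nrow(vf)) < 0.5
  pairs <- list()
  for (idx in by_block) {
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    r2 <- runif(ncol(cmb), cfg$block_r2[1], cfg$block_r2[2])
    same <- orient[cmb[1, ]] == orient[cmb[2, ]]
    pairs[[length(pairs) + 1]] <- tibble(
      variant_a = vf$variant_id[cmb[1, ]],
      allele_a = ea[cmb[1, ]],
      variant_b = vf$variant_id[cmb[2, ]],
      allele_b = ifelse(same, ea[cmb[2, ]], oa[cmb[2, ]]),
      r2 = r2
    )
  }
  if (length(pairs) == 0) {
    tibble(variant_a = character(), allele_a = character(),
           variant_b = character(), allele_b = character(), r2 = numeric())
  } else {
    bind_rows(pairs)
  }
}

# Re-encode outcome rows: allele swaps (labels reversed, beta negated, EAF
# complemented — same physical association) and strand flips (labels
# complemented, beta and EAF unchanged).
sim_encode_outcome <- function(out, cfg) {
  m <- nrow(out)
  swap <- runif(m) < cfg$prop_allele_swap
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  tmp <- out$ea[swap]; out$ea[swap] <- out$oa[swap]; out$oa[swap] <- tmp
  flip <- runif(m) < cfg$prop_strand_flipped
  out$ea[flip] <- allele_complement(out$ea[flip])
  out$oa[flip] <- allele_complement(out$oa[flip])
  out$swapped <- swap
  out$strand_flipped <- flip
  out
}

observed_stats <- function(truth, se) {
  beta_hat <- truth + rnorm(length(truth), 0, se)
  tibble(beta = beta_hat, se = se, pvalue = p_from_z(beta_hat / se))
}

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Generates one exposure and one outcome summary-statistics table under the
#' generative model declared in a [sim_config()]: outcome effects are
#' `theta * b_X + alpha` with `alpha = 0` for valid variants and drawn per the
#' pleiotropy mode for invalid ones; observed estimates add Gaussian noise at
#' the frequency- and sample-size-derived standard error. A fraction of
#' variants is palindromic, a fraction is re-encoded on the opposite strand or
#' with swapped alleles in the outcome file, and a fraction may be dropped from
#' the outcome to exercise proxy lookup.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (`mr_sumstats`),
#'   `ld` ([ld_reference()]) and `truth` (a list with `theta`, the per-variant
#'   truth table, and the invalid/reverse variant id sets).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  m <- cfg$n_variants
  vf <- sim_variant_frame(cfg)
  palindromic <- runif(m) < cfg$prop_palindromic
  al <- sim_alleles(m, palindromic)
  eaf <- sim_eaf(cfg, m, palindromic)
  ld_pairs <- sim_ld_pairs(cfg, vf, al$ea, al$oa)
  b_x_raw <- block_correlate(rnorm(m, 0, cfg$effect_sd), vf, ld_pairs, al$ea)
  tr <- sim_truth_draw(cfg, m, b_x = b_x_raw)
  theta <- cfg$theta[1]
  b_y <- theta * tr$b_x + tr$alpha

  se_x <- 1 / sqrt(2 * cfg$n_exposure * eaf * (1 - eaf))
  se_y <- 1 / sqrt(2 * cfg$n_outcome * eaf * (1 - eaf))
  obs_x <- observed_stats(tr$b_x, se_x)
  obs_y <- observed_stats(b_y, se_y)

  miss_eaf <- runif(m) < cfg$prop_missing_eaf

  exp_df <- bind_cols(vf[c("variant_id", "chrom", "pos")],
                      tibble(ea = al$ea, oa = al$oa,
                             eaf = ifelse(miss_eaf, NA_real_, eaf)),
                      obs_x, tibble(n = cfg$n_exposure))
  out_df <- bind_cols(vf[c("variant_id", "chrom", "pos")],
                      tibble(ea = al$ea, oa = al$oa,
                             eaf = ifelse(miss_eaf, NA_real_, eaf)),
                      obs_y, tibble(n = cfg$n_outcome))
  out_df <- sim_encode_outcome(out_df, cfg)
  missing_out <- runif(m) < cfg$prop_missing_outcome
  truth_tab <- tibble(
    variant_id = vf$variant_id, block = vf$block,
    b_x_true = tr$b_x, alpha = tr$alpha,
    invalid = tr$invalid, reverse = tr$reverse,
    palindromic = palindromic,
    swapped = out_df$swapped, strand_flipped = out_df$strand_flipped,
    missing_outcome = missing_out
  )
  out_df <- out_df[!missing_out, !(names(out_df) %in%
                                     c("swapped", "strand_flipped"))]

  ld <- ld_reference(vf[c("variant_id", "block")], ld_pairs)
  exposure <- summary_stats(exp_df, trait_meta(
    "sim-exp-1", "simulated exposure", cfg$n_exposure, "continuous"))
  outcome <- summary_stats(out_df, trait_meta(
    "sim-out-1", "simulated outcome", cfg$n_outcome, "binary"))
  list(
    exposure = exposure, outcome = outcome, ld = ld,
    truth = list(
      theta = theta,
      variants = truth_tab,
      invalid_variant_ids = truth_tab$variant_id[truth_tab$invalid],
      reverse_variant_ids = truth_tab$variant_id[truth_tab$reverse]
    )
  )
}

#' Simulate a multi-exposure panel with correlated instrument effects
#'
#' Draws per-variant true effect vectors across K exposures from a
#' multivariate Gaussian with correlation `exposure_corr`, generates the
#' outcome from the linear combination `theta' b_X` plus optional pleiotropy,
#' and returns one summary-statistics table per exposure plus the shared
#' outcome. Used by the multivariable-MR and MR-BMA test scenarios.
#'
#' @param cfg A [sim_config()] with `theta` of length K >= 2 and
#'   `exposure_corr` a K x K correlation matrix (identity if `NULL`).
#' @return A list with `exposures` (list of `mr_sumstats`), `outcome`, `ld`
#'   and `truth` (including `causal`, the logical vector `theta != 0`).
#' @export
simulate_multi_exposure <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- length(cfg$theta)
  if (K < 2) {
    abort("multi-exposure simulation needs theta of length >= 2",
          class = "mrscreen_config")
  }
  corr <- cfg$exposure_corr %||% diag(K)
  if (!all(dim(corr) == c(K, K))) {
    abort("exposure_corr must be K x K", class = "mrscreen_config")
  }
  check_psd(corr, "exposure_corr")
  withr::local_seed(cfg$seed)
  m <- cfg$n_variants
  vf <- sim_variant_frame(cfg)
  palindromic <- runif(m) < cfg$prop_palindromic
  al <- sim_alleles(m, palindromic)
  eaf <- sim_eaf(cfg, m, palindromic)

  bX <- rmvnorm_chol(m, cfg$effect_sd^2 * corr)  # m x K true effects
  invalid <- runif(m) < cfg$prop_invalid
  alpha <- numeric(m)
  if (any(invalid)) {
    alpha[invalid] <- switch(cfg$pleiotropy_mode,
      none = 0,
      balanced = rnorm(sum(invalid), 0, cfg$pleiotropy_sd),
      directional = sign(bX[invalid, 1]) *
        rnorm(sum(invalid), cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      correlated = rnorm(sum(invalid), 0, cfg$confounder_sd_y)
    )
  }
  b_y <- drop(bX %*% cfg$theta) + alpha

  se_x <- 1 / sqrt(2 * cfg$n_exposure * eaf * (1 - eaf))
  se_y <- 1 / sqrt(2 * cfg$n_outcome * eaf * (1 - eaf))
  exposures <- vector("list", K)
  for (k in seq_len(K)) {
    obs <- observed_stats(bX[, k], se_x)
    df <- bind_cols(vf[c("variant_id", "chrom", "pos")],
                    tibble(ea = al$ea, oa = al$oa, eaf = eaf),
                    obs, tibble(n = cfg$n_exposure))
    exposures[[k]] <- summary_stats(df, trait_meta(
      sprintf("sim-exp-%d", k), sprintf("simulated exposure %d", k),
      cfg$n_exposure, "continuous"))
  }
  obs_y <- observed_stats(b_y, se_y)
  out_df <- bind_cols(vf[c("variant_id", "chrom", "pos")],
                      tibble(ea = al$ea, oa = al$oa, eaf = eaf),
                      obs_y, tibble(n = cfg$n_outcome))
  out_df <- sim_encode_outcome(out_df, cfg)
  out_df <- out_df[!(names(out_df) %in% c("swapped", "strand_flipped"))]
  outcome <- summary_stats(out_df, trait_meta(
    "sim-out-1", "simulated outcome", cfg$n_outcome, "binary"))
  ld <- ld_reference(vf[c("variant_id", "block")],
                     sim_ld_pairs(cfg, vf, al$ea, al$oa))
  list(
    exposures = exposures, outcome = outcome, ld = ld,
    truth = list(
      theta = cfg$theta,
      causal = cfg$theta != 0,
      b_x_true = bX,
      alpha = alpha,
      variant_id = vf$variant_id,
      invalid_variant_ids = vf$variant_id[invalid]
    )
  )
}

#' Simulate a phenome-style screen panel
#'
#' Builds a panel of independent exposure traits (each on its own variant set)
#' and a single outcome containing every variant, with per-trait causal
#' effects given by `theta`. This is the input shape [run_screen()] consumes.
#'
#' @param theta Numeric vector of per-trait causal effects (length = number of
#'   exposure traits).
#' @param cfg A [sim_config()] describing each trait's variant panel (the
#'   per-trait settings; `theta` in `cfg` is ignored).
#' @param batches Optional character vector of batch tags per trait.
#' @return A list with `exposures`, `outcome`, `ld`, `truth`.
#' @export
simulate_screen_panel <- function(theta, cfg = sim_config(), batches = NULL) {
  n_traits <- length(theta)
  withr::local_seed(cfg$seed)
  trait_seeds <- sample.int(2^30, n_traits)
  exposures <- vector("list", n_traits)
  out_parts <- vector("list", n_traits)
  ld_blocks <- vector("list", n_traits)
  ld_pairs <- vector("list", n_traits)
  for (t in seq_len(n_traits)) {
    cfg_t <- cfg
    cfg_t$theta <- theta[t]
    cfg_t$seed <- trait_seeds[t]
    sim <- simulate_pair(cfg_t)
    tag <- function(ids) sprintf("t%02d_%s", t, ids)
    exp_t <- sim$exposure
    exp_t$variant_id <- tag(exp_t$variant_id)
    attr(exp_t, "meta") <- trait_meta(
      sprintf("sim-trait-%02d", t), sprintf("simulated trait %02d", t),
      cfg$n_exposure, "continuous",
      batch = if (is.null(batches)) "synthetic" else batches[t])
    exposures[[t]] <- exp_t
    out_t <- as_tibble(sim$outcome)
    out_t$variant_id <- tag(out_t$variant_id)
    out_t$chrom <- sprintf("%s_%02d", out_t$chrom, t)
    out_parts[[t]] <- out_t
    exposures[[t]]$chrom <- sprintf("%s_%02d", exposures[[t]]$chrom, t)
    bl <- sim$ld$blocks
    bl$variant_id <- tag(bl$variant_id)
    bl$block <- sprintf("t%02d_%s", t, bl$block)
    ld_blocks[[t]] <- bl
    pr <- sim$ld$pairs
    if (nrow(pr) > 0) {
      pr$variant_a <- tag(pr$variant_a)
      pr$variant_b <- tag(pr$variant_b)
    }
    ld_pairs[[t]] <- pr
  }
  outcome_df <- bind_rows(out_parts)
  outcome <- summary_stats(outcome_df, trait_meta(
    "sim-out-1", "simulated outcome", cfg$n_outcome, "binary"))
  ld <- ld_reference(bind_rows(ld_blocks), bind_rows(ld_pairs))
  list(
    exposures = exposures, outcome = outcome, ld = ld,
    truth = list(theta = theta, causal = theta != 0,
                 trait_ids = map_chr(exposures, ~ meta_of(.x)$trait_id))
  )
}
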