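test_that("selection ladder stops at the first sufficient rung", {
  # 10 independent genome-wide-significant variants
  ss <- make_sumstats(beta = rep(0.1, 10), se = rep(0.01, 10),
                      pvalue = rep(1e-9, 10))
  sel <- select_instruments(ss, empty_ld(ss$variant_id))
  expect_equal(sel$threshold_used, 5e-8)
  expect_equal(sel$n_selected, 10)
  expect_true(sel$sufficient)
  expect_equal(nrow(sel$ladder_log), 1)

  # 3 at p < 5e-8, 4 more at ~1e-6: threshold relaxes to 5e-6
  ss2 <- make_sumstats(beta = rep(0.1, 7), se = rep(0.01, 7),
                       pvalue = c(rep(1e-9, 3), rep(1e-6, 4)))
  sel2 <- select_instruments(ss2, empty_ld(ss2$variant_id))
  expect_equal(sel2$threshold_used, 5e-6)
  expect_equal(sel2$n_selected, 7)
  expect_equal(sel2$ladder_log$threshold, c(5e-8, 5e-7, 5e-6))
  expect_equal(sel2$ladder_log$count, c(3, 3, 7))

  # nothing below 5e-5: flagged insufficient
  ss3 <- make_sumstats(beta = rep(0.01, 4), se = rep(0.01, 4),
                       pvalue = rep(0.3, 4))
  sel3 <- select_instruments(ss3, empty_ld(ss3$variant_id))
  expect_false(sel3$sufficient)
  expect_equal(sel3$n_selected, 0)
  expect_equal(sel3$threshold_used, 5e-5)
})

test_that("clumping keeps the lowest-p index and drops correlated neighbours", {
  ss <- make_sumstats(beta = c(0.1, 0.09), se = c(0.01, 0.01),
                      pvalue = c(1e-10, 1e-8), pos = c(1e6, 2e6))
  ld_cor <- ld_reference(
    tibble::tibble(variant_id = ss$variant_id, block = 1),
    tibble::tibble(variant_a = "v001", allele_a = "A", variant_b = "v002",
                   allele_b = "A", r2 = 0.5))
  expect_equal(clump(ss$variant_id, ss, ld_cor), "v001")

  ld_weak <- ld_reference(ld_cor$blocks,
                          dplyr::mutate(ld_cor$pairs, r2 = 0.0005))
  expect_setequal(clump(ss$variant_id, ss, ld_weak), c("v001", "v002"))

  # variants outside the window are retained regardless of r2
  ss_far <- make_sumstats(beta = c(0.1, 0.09), se = c(0.01, 0.01),
                          pvalue = c(1e-10, 1e-8), pos = c(1e6, 2e7))
  expect_setequal(clump(ss_far$variant_id, ss_far, ld_cor),
                  c("v001", "v002"))
})

test_that("clumping matches the brute-force oracle on random instances", {
  for (i in 1:25) {
    set.seed(2000 + i)
    m <- sample(10:30, 1)
    n_blocks <- sample(2:6, 1)
    block <- sort(sample(n_blocks, m, replace = TRUE))
    ss <- make_sumstats(beta = rnorm(m, 0, 0.1), se = rep(0.01, m),
                        chrom = as.character(block),
                        pos = as.integer(1e6 + seq_len(m) * 1000))
    pairs <- list()
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) < 2) next
      cmb <- utils::combn(idx, 2)
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        variant_a = ss$variant_id[cmb[1, ]], allele_a = "A",
        variant_b = ss$variant_id[cmb[2, ]], allele_b = "A",
        r2 = sample(c(0, 0.0005, 0.01, 0.5, 0.99), ncol(cmb),
                    replace = TRUE))
    }
    ld <- ld_reference(tibble::tibble(variant_id = ss$variant_id,
                                      block = block),
                       dplyr::bind_rows(pairs))
    expect_identical(clump(ss$variant_id, ss, ld),
                     oracle_clump(ss$variant_id, ss, ld))
  }
})

test_that("clumped sets are pairwise independent within the window", {
  sim <- simulate_pair(sim_config(seed = 77, n_variants = 60, n_blocks = 10,
                                  block_r2 = c(0.3, 0.9)))
  kept <- clump(sim$exposure$variant_id, sim$exposure, sim$ld)
  if (length(kept) >= 2) {
    cmb <- utils::combn(kept, 2)
    r2 <- mrscreen:::ld_r2(sim$ld, cmb[1, ], cmb[2, ])
    expect_true(all(r2 <= 0.001))
  }
})

test_that("proxy search honours the r2 floor and the max-r2 rule", {
  out <- make_sumstats(beta = c(0.02, 0.03, 0.01), se = rep(0.01, 3),
                       ids = c("p1", "p2", "p3"))
  mk_ld <- function(r2s) {
    ld_reference(
      tibble::tibble(variant_id = c("idx", "p1", "p2", "p3"), block = 1),
      tibble::tibble(variant_a = "idx", allele_a = "A",
                     variant_b = c("p1", "p2", "p3"), allele_b = "A",
                     r2 = r2s))
  }
  hit <- find_proxy("idx", out, mk_ld(c(0.91, 0.99, 0.2)))
  expect_equal(hit$proxy_id, "p2")
  expect_equal(hit$r2, 0.99)
  expect_null(find_proxy("idx", out, mk_ld(c(0.85, 0.5, 0.2))))
})

test_that("allele alignment handles swaps, strand flips and palindromes", {
  exp <- make_sumstats(beta = 0.1, se = 0.01, ids = "v1", ea = "A", oa = "G",
                       eaf = 0.3)
  mk_out <- function(ea, oa, beta = 0.05, eaf = 0.3) {
    make_sumstats(beta = beta, se = 0.01, ids = "v1", ea = ea, oa = oa,
                  eaf = eaf, trait_id = "out")
  }
  ld <- empty_ld("v1")

  # swapped allele order flips the outcome beta
  h <- harmonise(exp, mk_out("G", "A", eaf = 0.7), "v1", ld)
  expect_equal(h$b_y, -0.05)
  # strand complement, same order: sign unchanged
  h2 <- harmonise(exp, mk_out("T", "C"), "v1", ld)
  expect_equal(h2$b_y, 0.05)
  # strand complement, swapped: flipped
  h3 <- harmonise(exp, mk_out("C", "T", eaf = 0.7), "v1", ld)
  expect_equal(h3$b_y, -0.05)
  # irreconcilable pair is dropped with reason
  h4 <- harmonise(exp, mk_out("A", "C"), "v1", ld)
  expect_equal(nrow(h4), 0)
  expect_equal(attr(h4, "drop_log")$reason, "irreconcilable")
})

test_that("palindromic variants resolve by frequency or drop when ambiguous", {
  exp_pal <- make_sumstats(beta = 0.1, se = 0.01, ids = "v1", ea = "A",
                           oa = "T", eaf = 0.2)
  mk_out <- function(ea, oa, eaf, beta = 0.05) {
    make_sumstats(beta = beta, se = 0.01, ids = "v1", ea = ea, oa = oa,
                  eaf = eaf, trait_id = "out")
  }
  ld <- empty_ld("v1")

  # same labels, concordant frequency: kept as-is
  h <- harmonise(exp_pal, mk_out("A", "T", eaf = 0.22), "v1", ld)
  expect_equal(h$b_y, 0.05)
  # same labels, discordant frequency: strand flip inferred, sign flipped
  h2 <- harmonise(exp_pal, mk_out("A", "T", eaf = 0.78), "v1", ld)
  expect_equal(h2$b_y, -0.05)
  # ambiguous frequency (MAF > 0.42): dropped
  exp_amb <- make_sumstats(beta = 0.1, se = 0.01, ids = "v1", ea = "A",
                           oa = "T", eaf = 0.50)
  h3 <- harmonise(exp_amb, mk_out("A", "T", eaf = 0.50), "v1", ld)
  expect_equal(nrow(h3), 0)
  expect_equal(attr(h3, "drop_log")$reason, "palindromic_ambiguous")
  # missing frequency on a palindrome: dropped
  exp_na <- make_sumstats(beta = 0.1, se = 0.01, ids = "v1", ea = "A",
                          oa = "T", eaf = NA_real_)
  h4 <- harmonise(exp_na, mk_out("A", "T", eaf = 0.2), "v1", ld)
  expect_equal(attr(h4, "drop_log")$reason, "missing_eaf")
})

test_that("harmonisation is idempotent and allele-flip equivariant", {
  sim <- simulate_pair(sim_config(seed = 91, n_variants = 50, n_blocks = 25,
                                  theta = 0.2, prop_palindromic = 0.2,
                                  prop_strand_flipped = 0.3))
  ids <- sim$exposure$variant_id
  h1 <- harmonise(sim$exposure, sim$outcome, ids, sim$ld)

  # idempotence: re-harmonising the harmonised set against itself-as-outcome
  # leaves outcome betas unchanged
  re_out <- summary_stats(
    tibble::tibble(variant_id = h1$variant_id, chrom = "1",
                   pos = seq_len(nrow(h1)), ea = h1$ea, oa = h1$oa,
                   eaf = h1$eaf_y, beta = h1$b_y, se = h1$se_y,
                   pvalue = h1$p_y, n = 1000L),
    trait_meta("out2"))
  h2 <- harmonise(sim$exposure, re_out, h1$variant_id, sim$ld)
  expect_equal(h2$b_y, h1$b_y, tolerance = 1e-12)

  # flipping EA/OA and beta sign of exposure rows yields mirrored b_x and b_y
  flipped <- as_tibble(sim$exposure)
  tmp <- flipped$ea; flipped$ea <- flipped$oa; flipped$oa <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  exp_flip <- summary_stats(flipped, meta_of(sim$exposure))
  h3 <- harmonise(exp_flip, sim$outcome, ids, sim$ld)
  common <- intersect(h1$variant_id, h3$variant_id)
  expect_gt(length(common), 0)
  i1 <- match(common, h1$variant_id)
  i3 <- match(common, h3$variant_id)
  expect_equal(h3$b_x[i3], -h1$b_x[i1], tolerance = 1e-12)
  expect_equal(h3$b_y[i3], -h1$b_y[i1], tolerance = 1e-12)
})

test_that("proxy substitution recovers the association of a missing variant", {
  sim <- simulate_pair(sim_config(seed = 95, n_variants = 40, n_blocks = 8,
                                  theta = 0.2, block_r2 = c(0.92, 0.99),
                                  prop_missing_outcome = 0.3))
  miss <- sim$truth$variants$variant_id[sim$truth$variants$missing_outcome]
  h <- harmonise(sim$exposure, sim$outcome, sim$exposure$variant_id, sim$ld)
  used <- h[!is.na(h$proxy_id), ]
  expect_gt(nrow(used), 0)
  expect_true(all(used$variant_id %in% miss))
  expect_true(all(used$proxy_r2 >= 0.9))
  # proxied outcome betas still carry the causal signal (attenuated by the
  # imperfect LD between proxy and index): right sign, right magnitude range
  if (nrow(used) >= 3) {
    est <- mr_ivw(used)$estimate
    expect_gt(est, 0.08)
    expect_lt(est, 0.32)
  }
})

test_that("outcome-significance filter removes and only removes p_y < p_x", {
  h <- harmonised_set(
    b_x = c(0.1, 0.1, 0.1), se_x = rep(0.01, 3),
    b_y = c(0.02, 0.2, 0.02), se_y = rep(0.004, 3),
    p_x = c(1e-9, 1e-9, 1e-9), p_y = c(1e-12, 0.3, 1e-8))
  f <- filter_outcome_significance(h)
  expect_equal(f$variant_id, c("rs000002", "rs000003"))
  expect_true(all(attr(f, "drop_log")$reason == "outcome_more_significant"))
  # idempotent
  expect_equal(nrow(filter_outcome_significance(f)), nrow(f))
})

test_that("radial filter removes a planted outlier and preserves Q additivity", {
  set.seed(6)
  J <- 20
  b_x <- rnorm(J, 0.1, 0.02)
  se_x <- rep(0.005, J)
  se_y <- rep(0.004, J)
  b_y <- 0.2 * b_x
  b_y[7] <- 0.2 * b_x[7] + 10 * se_y[7]   # 10-SD outlier
  h <- harmonised_set(b_x, se_x, b_y, se_y)

  fit <- mrscreen:::radial_fit(h)
  expect_equal(which.max(fit$q_j), 7L)
  expect_equal(sum(fit$q_j),
               sum(fit$weights * (b_y / b_x - fit$theta)^2),
               tolerance = 1e-12)

  res <- radial_outlier_filter(h)
  expect_true("rs000007" %in% res$removed$variant_id)
  expect_false("rs000007" %in% res$hset$variant_id)

  # homogeneous set: all q_j = 0, nothing removed
  h0 <- harmonised_set(b_x, se_x, 0.5 * b_x, se_y)
  res0 <- radial_outlier_filter(h0)
  expect_equal(nrow(res0$removed), 0)
  expect_lt(max(res0$q_contributions), 1e-20)

  # fewer than 3 instruments: returned unchanged with a warning
  h2 <- harmonised_set(b_x[1:2], se_x[1:2], b_y[1:2], se_y[1:2])
  expect_warning(res2 <- radial_outlier_filter(h2))
  expect_equal(nrow(res2$hset), 2)
})
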