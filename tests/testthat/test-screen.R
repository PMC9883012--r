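fast_cfg <- function(...) {
  screen_config(n_boot = 100, seed = 1, ...)
}

test_that("duplicate traits resolve by sample size, then F, then id", {
  traits <- tibble::tibble(
    trait_id = c("a1", "a2", "b1", "b2", "c1"),
    trait_name = c("LDL cholesterol", "ldl  cholesterol",
                   "HDL cholesterol", "HDL cholesterol", "unique trait"),
    sample_size = c(10000, 50000, 20000, 20000, 5000),
    mean_f = c(30, 40, 30, 80, 10))
  kept <- dedup_traits(traits)
  expect_setequal(kept$trait_id, c("a2", "b2", "c1"))
  expect_setequal(attr(kept, "removed"), c("a1", "b1"))

  # same name, same n, same F: lexicographic id
  tie <- tibble::tibble(trait_id = c("z9", "a1"), trait_name = "same",
                        sample_size = 1000, mean_f = 50)
  expect_equal(dedup_traits(tie)$trait_id, "a1")

  # unique names: identity
  uniq <- traits[c(1, 3, 5), ]
  expect_equal(nrow(dedup_traits(uniq)), 3)
})

test_that("BH adjustment matches the brute-force oracle and base R", {
  set.seed(20)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
  # worked example: step-up adjustment
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(oracle_bh(p), c(0.004, 0.02, 0.8 / 30, 0.8),
               tolerance = 1e-12)
})

test_that("a strong clean causal trait reaches a significant verdict", {
  panel <- simulate_screen_panel(
    theta = c(0.3, 0, 0),
    cfg = sim_config(seed = 33, n_variants = 40, n_blocks = 40,
                     prop_palindromic = 0.1))
  scr <- run_screen(panel$exposures, panel$outcome, panel$ld, fast_cfg())
  expect_s3_class(scr, "mr_screen")
  expect_equal(nrow(scr), 3)
  expect_equal(scr$verdict[1], "significant")
  expect_true(all(scr$verdict[2:3] != "significant"))
  expect_equal(glance(scr)$n_significant, 1)
  # effect estimate near truth, OR on the exp scale
  expect_lt(abs(scr$estimate[1] - 0.3), 0.05)
  expect_equal(scr$or[1], exp(scr$estimate[1]))
})

test_that("excluded batches and insufficient traits are flagged not analysed", {
  panel <- simulate_screen_panel(
    theta = c(0.2, 0),
    cfg = sim_config(seed = 34, n_variants = 30, n_blocks = 30),
    batches = c("ukb", "synthetic"))
  scr <- run_screen(panel$exposures, panel$outcome, panel$ld, fast_cfg())
  expect_equal(scr$status[1], "excluded")
  expect_equal(scr$exclusion_reason[1], "batch")
  expect_true(is.na(scr$fdr_p[1]))

  # a trait with no selectable instruments is excluded with a reason
  weak <- make_sumstats(beta = rep(0.001, 10), se = rep(0.01, 10),
                        trait_id = "weak-1")
  scr2 <- run_screen(list(weak), panel$outcome, panel$ld, fast_cfg())
  expect_equal(scr2$status, "excluded")
  expect_equal(scr2$exclusion_reason, "insufficient_instruments")
  # excluded + analysed = input count
  expect_equal(sum(scr$status == "analysed") +
                 sum(scr$status == "excluded"), 2)
})

test_that("verdicts are invariant to exposure order", {
  panel <- simulate_screen_panel(
    theta = c(0.3, 0, 0.25),
    cfg = sim_config(seed = 35, n_variants = 30, n_blocks = 30))
  scr_a <- run_screen(panel$exposures, panel$outcome, panel$ld, fast_cfg())
  scr_b <- run_screen(rev(panel$exposures), panel$outcome, panel$ld,
                      fast_cfg())
  a <- scr_a[order(scr_a$trait_id), c("trait_id", "verdict")]
  b <- scr_b[order(scr_b$trait_id), c("trait_id", "verdict")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("replication stores second-outcome results without changing verdicts", {
  panel <- simulate_screen_panel(
    theta = c(0.3, 0),
    cfg = sim_config(seed = 36, n_variants = 40, n_blocks = 40))
  scr <- run_screen(panel$exposures, panel$outcome, panel$ld, fast_cfg())
  v0 <- scr$verdict

  # self-replication: identical outcome reproduces the primary estimates
  rep_same <- replicate_screen(scr, panel$exposures, panel$outcome, panel$ld)
  expect_equal(rep_same$verdict, v0)
  i <- which(rep_same$verdict == "significant")
  expect_equal(rep_same$rep_estimate[i], scr$estimate[i], tolerance = 1e-10)

  # null second outcome: replication p not significant, verdict unchanged
  null_out <- summary_stats(
    dplyr::mutate(as_tibble(panel$outcome),
                  beta = withr::with_seed(1, rnorm(nrow(panel$outcome), 0,
                                                   se)),
                  pvalue = 2 * pnorm(-abs(beta / se))),
    trait_meta("null-out", "null outcome", 50000, "binary"))
  rep_null <- replicate_screen(scr, panel$exposures, null_out, panel$ld)
  expect_equal(rep_null$verdict, v0)
  expect_gt(min(rep_null$rep_pvalue[i]), 0.05)

  # no significant records: a no-op
  scr_none <- scr
  scr_none$verdict <- "not_significant"
  rep_none <- replicate_screen(scr_none, panel$exposures, panel$outcome,
                               panel$ld)
  expect_true(all(is.na(rep_none$rep_estimate)))
})

test_that("reverse MR attenuates a forward-causal signal", {
  # balanced pleiotropic variants double as outcome-specific loci, giving
  # the reverse analysis instruments of its own
  sim <- simulate_pair(sim_config(seed = 37, theta = 0.4, n_variants = 80,
                                  n_blocks = 80, prop_invalid = 0.4,
                                  pleiotropy_mode = "balanced",
                                  pleiotropy_sd = 0.08))
  fwd <- run_screen(list(sim$exposure), sim$outcome, sim$ld, fast_cfg())
  rev <- reverse_mr(sim$exposure, sim$outcome, sim$ld, fast_cfg())
  # reverse estimate shrunk towards zero relative to the forward one
  expect_lt(abs(rev$estimate), abs(fwd$estimate[1]) / 2)

  # degenerate self-regression is flagged
  self <- reverse_mr(sim$exposure, sim$exposure, sim$ld, fast_cfg())
  expect_true(attr(self, "degenerate"))
  expect_equal(self$estimate, 1, tolerance = 1e-6)
})

test_that("under a global null the screen finds essentially nothing", {
  panel <- simulate_screen_panel(
    theta = rep(0, 15),
    cfg = sim_config(seed = 38, n_variants = 30, n_blocks = 30))
  scr <- run_screen(panel$exposures, panel$outcome, panel$ld, fast_cfg())
  expect_lte(sum(scr$verdict == "significant"), 1)
})

test_that("estimator failure downgrades a trait instead of aborting", {
  # outcome with constant exposure betas among selected instruments makes
  # Egger degenerate, but the screen must still complete
  ss <- make_sumstats(beta = rep(0.1, 8), se = rep(0.01, 8),
                      pvalue = rep(1e-10, 8), trait_id = "degenerate")
  out <- make_sumstats(beta = rep(0.02, 8), se = rep(0.01, 8),
                       pvalue = rep(0.02, 8), trait_id = "out")
  scr <- run_screen(list(ss), out, empty_ld(ss$variant_id), fast_cfg())
  expect_equal(nrow(scr), 1)
  expect_true(scr$status %in% c("analysed", "excluded"))
})
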