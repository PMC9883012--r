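# Deterministic fixtures: exact proportionality and hand-checkable ratios.

test_that("exact proportionality gives the slope with zero heterogeneity", {
  h <- harmonised_set(
    b_x = c(0.05, 0.1, 0.15, 0.2), se_x = rep(0.01, 4),
    b_y = 0.5 * c(0.05, 0.1, 0.15, 0.2), se_y = rep(0.01, 4))
  fe <- mr_ivw(h, "fixed")
  mre <- mr_ivw(h)
  expect_equal(fe$estimate, 0.5, tolerance = 1e-12)
  expect_equal(attr(fe, "q"), 0, tolerance = 1e-20)
  # with Q = 0 the MRE SE equals the FE SE
  expect_equal(mre$se, fe$se, tolerance = 1e-12)
})

test_that("wald ratio matches the closed form and IVW refuses J = 1", {
  h <- harmonised_set(b_x = 0.1, se_x = 0.01, b_y = 0.02, se_y = 0.004)
  wr <- mr_wald_ratio(h)
  expect_equal(wr$estimate, 0.2, tolerance = 1e-12)
  expect_equal(wr$se, 0.04, tolerance = 1e-12)
  expect_error(mr_ivw(h), class = "mrscreen_insufficient")
  expect_error(mr_egger(h), class = "mrscreen_insufficient")
  expect_error(mr_weighted_median(h), class = "mrscreen_insufficient")
})

test_that("IVW closed form equals weighted regression through the origin", {
  set.seed(4)
  h <- harmonised_set(b_x = rnorm(10, 0.1, 0.03), se_x = rep(0.01, 10),
                      b_y = rnorm(10, 0.02, 0.01),
                      se_y = runif(10, 0.003, 0.01))
  fit <- lm(b_y ~ b_x - 1, data = as.data.frame(h), weights = 1 / h$se_y^2)
  expect_equal(mr_ivw(h, "fixed")$estimate, unname(coef(fit)),
               tolerance = 1e-10)
})

test_that("MRE SE is never below FE SE; equality iff Q <= J - 1", {
  set.seed(5)
  for (i in 1:20) {
    J <- sample(3:15, 1)
    h <- harmonised_set(b_x = rnorm(J, 0.1, 0.03), se_x = rep(0.01, J),
                        b_y = rnorm(J, 0.02, 0.02),
                        se_y = runif(J, 0.002, 0.02))
    fe <- mr_ivw(h, "fixed")
    mre <- mr_ivw(h)
    expect_gte(mre$se, fe$se)
    q <- attr(mre, "q")
    if (q <= J - 1) expect_equal(mre$se, fe$se, tolerance = 1e-12)
    else expect_gt(mre$se, fe$se)
  }
})

test_that("estimates are sign- and scale-equivariant", {
  set.seed(6)
  J <- 12
  h <- harmonised_set(b_x = rnorm(J, 0.1, 0.03), se_x = rep(0.01, J),
                      b_y = rnorm(J, 0.02, 0.01), se_y = rep(0.005, J))
  neg <- harmonised_set(h$b_x, h$se_x, -h$b_y, h$se_y)
  scl <- harmonised_set(2 * h$b_x, 2 * h$se_x, h$b_y, h$se_y)
  for (f in list(function(x) mr_ivw(x)$estimate,
                 function(x) mr_weighted_median(x, n_boot = 10,
                                                seed = 1)$estimate,
                 function(x) mr_radial_ivw(x)$estimate)) {
    expect_equal(f(neg), -f(h), tolerance = 1e-9)
    expect_equal(f(scl), f(h) / 2, tolerance = 1e-9)
  }
})

test_that("weighted median interpolates cumulative weights correctly", {
  h <- harmonised_set(b_x = c(1, 1, 1), se_x = rep(0.01, 3),
                      b_y = c(0.1, 0.2, 0.9), se_y = rep(0.1, 3))
  # equal weights: middle order statistic
  est <- mr_weighted_median(h, n_boot = 10, seed = 1)$estimate
  expect_equal(est, 0.2, tolerance = 1e-12)
  # equal weights equals plain median on a larger set
  set.seed(7)
  r <- rnorm(11, 0.3, 0.1)
  h2 <- harmonised_set(b_x = rep(1, 11), se_x = rep(0.01, 11),
                       b_y = r, se_y = rep(0.05, 11))
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$estimate,
               median(r), tolerance = 1e-10)
})

test_that("bootstrap standard errors are seed-reproducible", {
  set.seed(8)
  h <- harmonised_set(b_x = rnorm(8, 0.1, 0.02), se_x = rep(0.01, 8),
                      b_y = rnorm(8, 0.02, 0.01), se_y = rep(0.005, 8))
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_mode(h, n_boot = 200, seed = 99)
  d <- mr_weighted_mode(h, n_boot = 200, seed = 99)
  expect_identical(c$se, d$se)
  expect_false(identical(a$se, mr_weighted_median(h, n_boot = 200,
                                                  seed = 100)$se))
})

test_that("weighted mode finds a point mass and the plurality cluster", {
  h <- harmonised_set(b_x = rep(0.1, 5), se_x = rep(0.01, 5),
                      b_y = rep(0.03, 5), se_y = rep(0.005, 5))
  expect_equal(mr_weighted_mode(h, n_boot = 10, seed = 1)$estimate, 0.3,
               tolerance = 1e-10)
  # plurality of instruments at ratio 0.2, minority at 0.8
  set.seed(9)
  J <- 30
  ratios <- c(rnorm(18, 0.2, 0.01), rnorm(12, 0.8, 0.01))
  h2 <- harmonised_set(b_x = rep(0.1, J), se_x = rep(0.005, J),
                       b_y = 0.1 * ratios, se_y = rep(0.002, J))
  expect_equal(mr_weighted_mode(h2, n_boot = 10, seed = 1)$estimate, 0.2,
               tolerance = 0.05)
})

test_that("egger detects rank deficiency and recovers on clean data", {
  # identical oriented exposure betas: degenerate design
  h <- harmonised_set(b_x = c(0.1, 0.1, 0.1), se_x = rep(0.01, 3),
                      b_y = c(0.02, 0.03, 0.04), se_y = rep(0.01, 3))
  expect_error(mr_egger(h), class = "mrscreen_collinear")

  set.seed(10)
  J <- 40
  b_x <- rnorm(J, 0, 0.08)
  b_y <- 0.25 * b_x + rnorm(J, 0, 0.002)
  h2 <- harmonised_set(b_x, rep(0.005, J), b_y, rep(0.002, J))
  eg <- mr_egger(h2)
  expect_equal(eg$slope$estimate, 0.25, tolerance = 0.05)
  expect_equal(eg$intercept$estimate, 0, tolerance = 0.01)
})

test_that("battery returns one row per method with consistent OR scale", {
  set.seed(11)
  h <- harmonised_set(b_x = rnorm(10, 0.1, 0.02), se_x = rep(0.01, 10),
                      b_y = rnorm(10, 0.02, 0.005), se_y = rep(0.005, 10))
  bat <- mr_battery(h, n_boot = 20, seed = 1)
  expect_setequal(bat$method,
                  c("ivw_fe", "ivw_mre", "egger_slope", "egger_intercept",
                    "weighted_median", "weighted_mode", "radial_ivw"))
  cont <- bat[bat$method == "ivw_mre", ]
  expect_equal(cont$or, exp(cont$estimate))
  expect_true(all(bat$ci_low < bat$estimate & bat$estimate < bat$ci_high))
})

test_that("QC battery computes F, Q, I2 and leave-one-out flags", {
  # b_x / se_x = 10 everywhere: mean F = 100, no weak flag
  h <- harmonised_set(b_x = rep(0.1, 6), se_x = rep(0.01, 6),
                      b_y = 0.5 * rep(0.1, 6), se_y = rep(0.01, 6))
  qc <- qc_battery(h)
  expect_equal(qc$mean_f, 100, tolerance = 1e-12)
  expect_equal(qc$cochran_q, 0, tolerance = 1e-18)
  expect_equal(qc$q_pvalue, 1)
  expect_false("weak_instruments" %in% qc$flags)
  expect_false("heterogeneous" %in% qc$flags)
  expect_equal(nrow(qc$loo), 6)

  # weak set: mean F below 10 raises the flag
  hw <- harmonised_set(b_x = rep(0.02, 6), se_x = rep(0.01, 6),
                       b_y = rep(0.01, 6), se_y = rep(0.01, 6))
  expect_true("weak_instruments" %in% qc_battery(hw)$flags)
})

test_that("a single variant carrying the signal trips the loo flag", {
  set.seed(12)
  J <- 8
  b_x <- rnorm(J, 0.1, 0.01)
  b_y <- 0.08 * b_x + rnorm(J, 0, 0.004)  # weak signal in most variants
  b_y[3] <- 0.35 * b_x[3]                 # one variant drives significance
  h <- harmonised_set(b_x, rep(0.01, J), b_y, rep(0.01, J))
  qc <- qc_battery(h)
  full_p <- qc$ivw$pvalue
  omit_p <- qc$loo$pvalue[qc$loo$left_out == h$variant_id[3]]
  expect_lt(full_p, 0.05)
  expect_gte(omit_p, 0.05)
  expect_true("loo_unstable" %in% qc$flags)
})

test_that("tidiers expose QC content as tibbles", {
  h <- harmonised_set(b_x = rep(0.1, 5), se_x = rep(0.01, 5),
                      b_y = 0.3 * rep(0.1, 5) + c(0, 1e-3, -1e-3, 0, 0),
                      se_y = rep(0.005, 5))
  qc <- qc_battery(h)
  expect_s3_class(tidy(qc), "tbl_df")
  g <- glance(qc)
  expect_equal(g$n_snv, 5)
  expect_true(is.numeric(g$i2_gx))
})
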