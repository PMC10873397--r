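test_that("Wald ratio arithmetic and delta-method SEs", {
  p <- harmonized_pair(0.1, 0.02, 0.05, 0.01)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)

  expect_equal(wald_ratio(harmonized_pair(0.1, 0.02, 0, 0.01))$beta, 0)

  w2 <- wald_ratio(p, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))

  expect_error(wald_ratio(harmonized_pair(0, 0.02, 0.05, 0.01)), "zero")
})

test_that("IVW equals the equal-weight mean and the Wald fallback", {
  p <- harmonized_pair(c(1, 1), c(0.1, 0.1), c(1, 3), c(0.2, 0.2))
  expect_equal(mr_ivw(p)$beta, 2)

  one <- harmonized_pair(0.2, 0.02, 0.1, 0.05)
  expect_warning(iv1 <- mr_ivw(one), "Wald")
  expect_equal(iv1$beta, wald_ratio(one)$beta)
  expect_equal(iv1$se, wald_ratio(one)$se)
})

test_that("IVW and Egger match independent oracles on random instances", {
  for (i in 1:25) {
    pair <- random_pair(J = sample(3:25, 1), seed = 700 + i)
    expect_equal(mr_ivw(pair)$beta, oracle_ivw(pair), tolerance = 1e-6)
    eg <- mr_egger(pair)
    or <- oracle_egger(pair)
    expect_equal(eg$beta[eg$method == "egger_slope"], or$slope,
                 tolerance = 1e-9)
    expect_equal(eg$beta[eg$method == "egger_intercept"], or$intercept,
                 tolerance = 1e-9)
    expect_equal(eg$se[eg$method == "egger_slope"], or$se_slope,
                 tolerance = 1e-9)
  }
})

test_that("Egger interpolates an exact linear relation and is orientation-invariant", {
  g <- c(0.1, 0.2, 0.4, 0.8)
  p <- harmonized_pair(g, rep(0.01, 4), 0.03 + 0.5 * g, rep(0.01, 4))
  eg <- mr_egger(p)
  expect_equal(eg$beta[eg$method == "egger_slope"], 0.5)
  expect_equal(eg$beta[eg$method == "egger_intercept"], 0.03)
  # zero residuals: the SE inflation floors at 1, leaving the fixed SE
  expect_equal(eg$se[eg$method == "egger_slope"],
               oracle_egger(p)$se_slope)

  flipped <- p
  flipped$beta_exposure[2] <- -flipped$beta_exposure[2]
  flipped$beta_outcome[2] <- -flipped$beta_outcome[2]
  expect_equal(mr_egger(flipped)$beta, eg$beta)

  expect_error(mr_egger(p[1:2, ]), "at least 3")
  same <- harmonized_pair(rep(0.2, 3), rep(0.01, 3), rnorm(3), rep(0.01, 3))
  expect_error(mr_egger(same), "unidentifiable")
})

test_that("weighted median: simple median, breakdown, and the worked interpolation", {
  p <- harmonized_pair(rep(1, 3), rep(0.1, 3), c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(p, n_boot = 0)$beta, 2)

  # heavy middle SNP (> 50% of weight) is returned exactly
  expect_equal(oracle_wmedian(c(1, 5, 9), c(0.1, 0.8, 0.1)), 5)
  heavy <- harmonized_pair(c(1, 1, 1), c(0.1, 0.1, 0.1), c(1, 5, 9),
                           c(sqrt(1 / 0.1), sqrt(1 / 0.8), sqrt(1 / 0.1)))
  expect_equal(mr_weighted_median(heavy, n_boot = 0)$beta, 5)

  # worked 4-SNP interpolation: ratios {1,2,10,11}, weights {.3,.3,.2,.2};
  # midpoints p = (.15,.45,.70,.90), so 0.5 falls between ratios 2 and 10:
  # 2 + (0.5 - 0.45)/(0.70 - 0.45) * (10 - 2) = 3.6
  expect_equal(oracle_wmedian(c(1, 2, 10, 11), c(0.3, 0.3, 0.2, 0.2)), 3.6)
  p4 <- harmonized_pair(rep(1, 4), rep(0.1, 4), c(1, 2, 10, 11),
                        1 / sqrt(c(0.3, 0.3, 0.2, 0.2)))
  expect_equal(mr_weighted_median(p4, n_boot = 0)$beta, 3.6)
})

test_that("weighted median matches its formula oracle on random instances", {
  for (i in 1:25) {
    pair <- random_pair(J = sample(3:25, 1), seed = 800 + i)
    r <- pair$beta_outcome / pair$beta_exposure
    w <- pair$beta_exposure^2 / pair$se_outcome^2
    expect_equal(mr_weighted_median(pair, n_boot = 0)$beta,
                 oracle_wmedian(r, w), tolerance = 1e-10)
  }
})

test_that("weighted mode finds the dominant cluster and ignores weight scale", {
  same <- harmonized_pair(rep(1, 4), rep(0.1, 4), rep(0.7, 4), rep(0.1, 4))
  expect_equal(mr_weighted_mode(same, n_boot = 0)$beta, 0.7)

  set.seed(90)
  ratios <- c(rnorm(7, 1, 0.05), rnorm(3, 5, 0.05))
  p <- harmonized_pair(rep(1, 10), rep(0.05, 10), ratios, rep(0.08, 10))
  est <- mr_weighted_mode(p, n_boot = 0)$beta
  or <- oracle_wmode(ratios, rep(1 / 0.08^2, 10))
  expect_lt(abs(est - or$mode), 2 * or$resolution)
  expect_gt(est, 0.8); expect_lt(est, 1.2)

  p_scaled <- p
  p_scaled$se_outcome <- p$se_outcome / 3   # weights scale by 9
  expect_equal(mr_weighted_mode(p_scaled, n_boot = 0)$beta, est,
               tolerance = 1e-6)
})

test_that("bootstrap SEs are seeded and reproducible", {
  pair <- random_pair(J = 12, seed = 901)
  a <- mr_weighted_median(pair, n_boot = 200, seed = 5)
  b <- mr_weighted_median(pair, n_boot = 200, seed = 5)
  expect_identical(a, b)
  c <- mr_weighted_median(pair, n_boot = 200, seed = 6)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
  m1 <- mr_weighted_mode(pair, n_boot = 100, seed = 5)
  m2 <- mr_weighted_mode(pair, n_boot = 100, seed = 5)
  expect_identical(m1, m2)
})

test_that("per-doubling scaling multiplies estimates by ln 2 exactly once", {
  r <- mr_ivw(random_pair(J = 8, seed = 902))
  s <- scale_to_doubling(r)
  expect_equal(s$beta, r$beta * log(2))
  expect_equal(s$beta / log(2), r$beta)
  expect_equal((s$ci_high - s$ci_low) / (r$ci_high - r$ci_low), log(2))
  expect_true(s$scaled_by_ln2)
  expect_error(scale_to_doubling(s), "already scaled")

  z <- wald_ratio(harmonized_pair(0.1, 0.01, 0, 0.01))
  expect_equal(scale_to_doubling(z)$beta, 0)
})

test_that("the MR panel runs both APOE variants deterministically", {
  spec <- generative_spec(n_samples = 2, seed = 903)
  ss <- simulate_summary_stats(spec, 2e4, 2e4, seed = 904)
  ins <- test_instrument()
  a <- run_mr_panel(ins, ss$outcome, n_boot = 100, seed = 7)
  b <- run_mr_panel(ins, ss$outcome, n_boot = 100, seed = 7)
  expect_identical(a, b)
  expect_setequal(unique(a$apoe), c("with", "without"))
  expect_true(all(a$scaled_by_ln2))
  expect_equal(sum(a$method == "ivw"), 2)

  # single-SNP input: ivw request degrades to a Wald ratio
  one <- ss$outcome[ss$outcome$snp == ins$snp[3], ]
  w <- run_mr_panel(ins, one, methods = "ivw", apoe_sets = "with",
                    n_boot = 0)
  expect_equal(w$method, "wald")
  expect_equal(w$J, 1L)
})
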