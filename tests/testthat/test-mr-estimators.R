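test_that("Wald ratios follow the first-order formulas and drop zero exposures", {
  p <- make_pairs(0.1, 0.01, 0.02, 0.005)
  rt <- wald_ratios(p)
  expect_equal(rt$ratio, 0.2)
  expect_equal(rt$se_ratio, 0.05)
  expect_equal(rt$weight, 400)
  expect_equal(wald_ratios(make_pairs(-0.1, 0.01, 0.02, 0.005))$ratio, -0.2)
  expect_warning(rt2 <- wald_ratios(make_pairs(c(0.1, 0), c(0.01, 0.01),
                                               c(0.02, 0.01), c(0.005, 0.005))),
                 "beta_exp")
  expect_equal(nrow(rt2), 1L)
  # second-order SE is never smaller than first-order
  rt3 <- wald_ratios(ivw_fixture(), second_order = TRUE)
  expect_true(all(rt3$se_ratio >= wald_ratios(ivw_fixture())$se_ratio))
})

test_that("IVW equals the closed-form weighted mean and its L=1/homogeneous limits", {
  # single pair reduces to the Wald ratio
  one <- mr_ivw(make_pairs(0.1, 0.01, 0.02, 0.005))
  expect_equal(one$beta, 0.2)
  expect_equal(one$se, 0.05)

  # all ratios equal: Q = 0, fixed and random coincide
  hom <- make_pairs(c(0.1, 0.2, 0.4), 0.01, c(0.03, 0.06, 0.12), 0.01)
  expect_equal(mr_ivw(hom, "fixed")$beta, 0.3)
  expect_equal(mr_ivw(hom, "fixed")$extras$Q, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(hom, "random")$se, mr_ivw(hom, "fixed")$se)

  # 3-variant fixture vs independent closed form
  fx <- ivw_fixture()
  est <- mr_ivw(fx, "fixed")
  o <- oracle_ivw(fx$beta_exp, fx$se_out, fx$beta_out)
  expect_equal(est$beta, o$beta, tolerance = 1e-10)
  expect_equal(est$beta, 0.21737, tolerance = 1e-4)
  expect_equal(est$se, o$se, tolerance = 1e-10)
})

test_that("the auto rule switches to random effects exactly when Q p < 0.05", {
  fx <- ivw_fixture() # mild heterogeneity, Q p ~ 0.72
  expect_equal(mr_ivw(fx, "auto")$extras$model_used, "fixed")
  het <- make_pairs(c(0.1, 0.1, 0.1), 0.001,
                    c(0.02, 0.05, 0.005), 0.002)
  est <- mr_ivw(het, "auto")
  expect_lt(est$extras$Q_pval, 0.05)
  expect_equal(est$extras$model_used, "random")
  expect_gt(est$se, mr_ivw(het, "fixed")$se)
  # random-effects SE floored at the fixed-effects SE
  expect_gte(mr_ivw(ivw_fixture(), "random")$se, mr_ivw(ivw_fixture(), "fixed")$se)
})

test_that("Egger recovers exact linear and affine fits and matches normal equations", {
  x <- c(0.1, 0.15, 0.2, 0.3, 0.12)
  p_line <- make_pairs(x, 0.01, 0.2 * x, 0.01)
  est <- mr_egger(p_line)
  expect_equal(est$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$extras$intercept, 0, tolerance = 1e-10)

  p_aff <- make_pairs(x, 0.01, 0.01 + 0.2 * x, 0.01)
  est <- mr_egger(p_aff)
  expect_equal(est$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$extras$intercept, 0.01, tolerance = 1e-10)

  set.seed(7)
  for (rep in 1:5) {
    bx <- runif(5, 0.05, 0.3) * sample(c(-1, 1), 5, replace = TRUE)
    by <- 0.02 + 0.25 * abs(bx) * sign(bx) + rnorm(5, 0, 0.02)
    so <- runif(5, 0.005, 0.02)
    p <- make_pairs(bx, 0.01, by, so)
    est <- mr_egger(p)
    o <- oracle_egger(bx, by, so)
    expect_equal(est$beta, o$slope, tolerance = 1e-10)
    expect_equal(est$se, o$slope_se, tolerance = 1e-10)
    expect_equal(est$extras$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(est$extras$intercept_se, o$intercept_se, tolerance = 1e-10)
  }
  expect_error(mr_egger(make_pairs(c(0.1, 0.2), 0.01, c(0.02, 0.04), 0.01)),
               "3 variants")
})

test_that("weighted median interpolates standardized cumulative weights", {
  # equal weights: plain median
  p <- make_pairs(c(0.1, 0.1, 0.1), 0.01, c(0.1, 0.2, 0.3), 0.01)
  est <- mr_weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)

  # hand-evaluated interpolation with weights {1,1,2}
  se_out <- 0.1 / sqrt(c(1, 1, 2))
  p2 <- make_pairs(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.3), se_out)
  est2 <- mr_weighted_median(p2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.2 + 0.1 * (0.5 - 0.375) / 0.375, tolerance = 1e-10)

  # determinism of the seeded bootstrap
  a <- mr_weighted_median(ivw_fixture(), n_boot = 200, seed = 99)
  b <- mr_weighted_median(ivw_fixture(), n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(make_pairs(0.1, 0.01, 0.02, 0.01),
                                  n_boot = 10, seed = 1), "3 variants")
})

test_that("mode estimators find the ratio cluster and are reproducible", {
  # point mass: all ratios equal
  hom <- make_pairs(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.1, 0.2), 0.01)
  expect_equal(mr_mode(hom, weighted = FALSE, n_boot = 20, seed = 1)$beta, 0.5)
  expect_equal(mr_mode(hom, weighted = TRUE, n_boot = 20, seed = 1)$beta, 0.5)

  # clustered ratios {0.2, 0.21, 0.19, 1.0}: mode inside the cluster,
  # cross-checked against a dense grid maximization
  bx <- c(1, 1, 1, 1)
  by <- c(0.2, 0.21, 0.19, 1.0)
  p <- make_pairs(bx, 0.01, by, 0.02)
  est <- mr_mode(p, weighted = FALSE, n_boot = 20, seed = 1)
  expect_gte(est$beta, 0.19)
  expect_lte(est$beta, 0.21)
  h <- est$extras$bandwidth
  dense <- seq(0, 1.2, length.out = 20001)
  dens <- vapply(dense, function(x) sum(dnorm((x - by) / h)), numeric(1))
  expect_equal(est$beta, dense[which.max(dens)], tolerance = 0.01)

  a <- mr_mode(ivw_fixture(), n_boot = 100, seed = 5)
  b <- mr_mode(ivw_fixture(), n_boot = 100, seed = 5)
  expect_identical(a$se, b$se)
})

test_that("all five estimators are sign-equivariant and IVW/Egger scale-equivariant", {
  set.seed(31)
  for (rep in 1:5) {
    L <- 8
    bx <- runif(L, 0.05, 0.2)
    by <- 0.3 * bx + rnorm(L, 0, 0.01)
    p <- make_pairs(bx, 0.01, by, runif(L, 0.005, 0.02))
    pneg <- p
    pneg$beta_out <- -pneg$beta_out
    expect_equal(mr_ivw(pneg)$beta, -mr_ivw(p)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(pneg)$beta, -mr_egger(p)$beta, tolerance = 1e-12)
    expect_equal(mr_weighted_median(pneg, 20, seed = 3)$beta,
                 -mr_weighted_median(p, 20, seed = 3)$beta, tolerance = 1e-9)
    expect_equal(mr_mode(pneg, FALSE, n_boot = 20, seed = 3)$beta,
                 -mr_mode(p, FALSE, n_boot = 20, seed = 3)$beta, tolerance = 1e-9)
    expect_equal(mr_mode(pneg, TRUE, n_boot = 20, seed = 3)$beta,
                 -mr_mode(p, TRUE, n_boot = 20, seed = 3)$beta, tolerance = 1e-9)

    k <- 2.5
    pscale <- p
    pscale$beta_exp <- k * pscale$beta_exp
    pscale$se_exp <- k * pscale$se_exp
    expect_equal(mr_ivw(pscale)$beta, mr_ivw(p)$beta / k, tolerance = 1e-12)
    expect_equal(mr_egger(pscale)$beta, mr_egger(p)$beta / k, tolerance = 1e-12)
  }
})

test_that("log-effects convert to odds ratios per SD", {
  expect_equal(unname(round(beta_to_or(-0.425)["or"], 3)), 0.654)
  expect_equal(unname(round(beta_to_or(-0.154)["or"], 3)), 0.857)
  expect_equal(unname(beta_to_or(0)["or"]), 1)
  or <- beta_to_or(new_est <- mr_ivw(ivw_fixture()))
  expect_equal(unname(or["or"]), exp(new_est$beta))
  expect_equal(unname(or["or_low"]), exp(new_est$ci_low))
})

test_that("with strong instruments and no pleiotropy all five estimators recover the effect", {
  sim <- simulate_chain(chain_sim_config(L = 80, n_med_loci = 0, seed = 21))
  cfg <- analysis_config(seed = 2, n_boot = 200)
  pairs <- suppressMessages(select_instruments(sim$exposure, sim$outcome, cfg))
  est <- mr_all_methods(pairs, n_boot = 200, seed = 2)
  for (i in seq_len(nrow(est))) {
    expect_lt(abs(est$beta[i] - sim$truth$theta_total), 3 * est$se[i])
  }
})

test_that("weighted median resists 40% invalid instruments better than IVW", {
  # 12 of 30 instruments carry a one-signed pleiotropic offset; valid
  # instruments still hold the majority of the weight, so the weighted
  # median should stay near the true effect while IVW drifts.
  set.seed(123)
  R <- 500
  L <- 30
  err_ivw <- err_wm <- numeric(R)
  for (i in seq_len(R)) {
    bx <- runif(L, 0.05, 0.2)
    by <- 0.3 * bx + rnorm(L, 0, 0.01)
    by[1:12] <- by[1:12] + 0.05
    p <- make_pairs(bx, 0.005, by, 0.01)
    err_ivw[i] <- mr_ivw(p, "fixed")$beta - 0.3
    err_wm[i] <- weighted_median_point_for_test(p) - 0.3
  }
  expect_lt(abs(mean(err_wm)), abs(mean(err_ivw)))
})

test_that("the Egger intercept recovers mean pleiotropy under InSIDE", {
  # pleiotropic effects independent of instrument strength, all exposure
  # effects oriented positive: the intercept estimates the mean pleiotropy
  set.seed(321)
  R <- 300
  mu <- 0.01
  intercepts <- numeric(R)
  for (i in seq_len(R)) {
    L <- 50
    bx <- runif(L, 0.05, 0.2)
    alpha <- rnorm(L, mu, 0.01)
    by <- 0.3 * bx + alpha + rnorm(L, 0, 0.005)
    p <- make_pairs(bx, 0.005, by, 0.005)
    intercepts[i] <- mr_egger(p)$extras$intercept
  }
  mc_se <- sd(intercepts) / sqrt(R)
  expect_lt(abs(mean(intercepts) - mu), 2 * mc_se + 1e-12)
})
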