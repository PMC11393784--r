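test_that("Cochran's Q matches hand arithmetic and its limits", {
  hom <- make_pairs(c(0.1, 0.2, 0.4), 0.01, c(0.03, 0.06, 0.12), 0.01)
  q <- cochran_q(hom)
  expect_equal(q$Q, 0, tolerance = 1e-18)
  expect_equal(q$pval, 1)

  fx <- ivw_fixture()
  q <- cochran_q(fx)
  o <- oracle_ivw(fx$beta_exp, fx$se_out, fx$beta_out)
  expect_equal(q$Q, o$Q, tolerance = 1e-10)
  expect_equal(q$Q, 0.6527, tolerance = 1e-3)
  expect_equal(q$df, 2L)

  two <- make_pairs(c(0.1, 0.2), 0.01, c(0.02, 0.05), 0.01)
  expect_equal(cochran_q(two)$df, 1L)
  expect_error(cochran_q(make_pairs(0.1, 0.01, 0.02, 0.01)), "2 variants")
})

test_that("the Egger intercept test mirrors the regression fit", {
  x <- c(0.1, 0.15, 0.2, 0.3, 0.12)
  through_origin <- make_pairs(x, 0.01, 0.2 * x, 0.01)
  it <- egger_intercept_test(through_origin)
  expect_equal(it$intercept, 0, tolerance = 1e-12)

  set.seed(8)
  offset <- make_pairs(x, 0.01, 0.01 + 0.2 * x + rnorm(5, 0, 1e-4), 0.01)
  it <- egger_intercept_test(offset)
  expect_lt(abs(it$intercept - 0.01), 1e-3)

  bx <- runif(6, 0.05, 0.3)
  by <- 0.015 + 0.2 * bx + rnorm(6, 0, 0.01)
  so <- runif(6, 0.005, 0.02)
  p <- make_pairs(bx, 0.01, by, so)
  o <- oracle_egger(bx, by, so)
  it <- egger_intercept_test(p)
  expect_equal(it$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(it$se, o$intercept_se, tolerance = 1e-10)
})

test_that("leave-one-out has L+1 rows, equal estimates under exchangeability, and flags outliers", {
  hom <- make_pairs(rep(0.1, 5), 0.01, rep(0.03, 5), rep(0.01, 5))
  loo <- leave_one_out(hom)
  expect_equal(nrow(loo), 6L)
  expect_equal(length(unique(round(loo$beta, 12))), 1L)
  expect_false(any(loo$flagged))

  # one extreme outlier among 10 concordant variants drags the pooled
  # estimate across zero; only its exclusion restores the sign, so only
  # that row is flagged
  bx <- rep(0.1, 11)
  by <- c(rep(0.005, 10), -0.1)
  out <- make_pairs(bx, 0.01, by, rep(0.005, 11))
  loo <- leave_one_out(out)
  expect_true(loo$flagged[11])
  expect_equal(sum(loo$flagged), 1L)
})

test_that("MR-PRESSO is quiet on homogeneous data and flags a planted outlier", {
  sim <- simulate_chain(chain_sim_config(L = 50, n_med_loci = 0, seed = 14))
  cfg <- analysis_config(seed = 5)
  pairs <- suppressMessages(select_instruments(sim$exposure, sim$outcome, cfg))
  pr <- mr_presso(pairs, n_sim = 300, seed = 6)
  expect_gt(pr$global_pval, 0.05)
  expect_length(pr$outlier_indices, 0)
  expect_true(is.na(pr$distortion_pval))

  # displace one variant's outcome effect by 10 combined SEs
  j <- 3
  shift <- 10 * sqrt(pairs$se_out[j]^2 +
                       (pairs$beta_out[j] / pairs$beta_exp[j])^2 * pairs$se_exp[j]^2)
  pairs2 <- pairs
  pairs2$beta_out[j] <- pairs2$beta_out[j] + shift
  pr2 <- mr_presso(pairs2, n_sim = 300, seed = 6)
  expect_true(j %in% pr2$outlier_indices)
  expect_lt(pr2$global_pval, 0.05)
  expect_false(is.na(pr2$distortion_pval))
  # removing the planted outlier moves the estimate back toward the truth
  expect_lt(abs(pr2$estimate_after$beta - sim$truth$theta_total),
            abs(pr2$estimate_before$beta - sim$truth$theta_total))
  # and never increases heterogeneity
  expect_lte(cochran_q(pairs2[-pr2$outlier_indices, ])$Q, cochran_q(pairs2)$Q)

  # determinism under a fixed seed
  pr3 <- mr_presso(pairs2, n_sim = 300, seed = 6)
  expect_identical(pr3$global_pval, pr2$global_pval)
  expect_error(mr_presso(pairs[1:3, ], n_sim = 300, seed = 1), "4 variants")
  expect_error(mr_presso(pairs, n_sim = 50, seed = 1), "n_sim")
})

test_that("the PRESSO global test holds its type-I error under the null", {
  cfg <- analysis_config(seed = 8)
  R <- 500
  rej <- logical(R)
  for (i in seq_len(R)) {
    sim <- simulate_chain(chain_sim_config(L = 50, n_med_loci = 0,
                                           n_out_loci = 0,
                                           palindrome_fraction = 0,
                                           seed = 50000 + i))
    pairs <- suppressMessages(select_instruments(sim$exposure, sim$outcome, cfg))
    if (nrow(pairs) < 4) next
    rej[i] <- mr_presso(pairs, n_sim = 300, seed = 50000 + i)$global_pval < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("diagnostics bundle collects Q, intercept and PRESSO columns", {
  sim <- simulate_chain(chain_sim_config(L = 30, n_med_loci = 0, seed = 15))
  cfg <- analysis_config(seed = 5)
  pairs <- suppressMessages(select_instruments(sim$exposure, sim$outcome, cfg))
  d <- mr_diagnostics(pairs, n_sim = 200, seed = 7)
  expect_named(d, c("Q", "Q_df", "Q_pval", "egger_intercept", "intercept_se",
                    "intercept_pval", "presso_global_pval", "presso_outliers"))
  expect_equal(d$Q, cochran_q(pairs)$Q)
})
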