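test_that("indirect effect follows the first-order delta formula", {
  # null path through the mediator
  z <- indirect_effect(0, 0.01, 0.5, 0.02)
  expect_equal(z$indirect, 0)
  expect_equal(z$se_indirect, 0.5 * 0.01)

  # arithmetic oracle evaluated independently
  ie <- indirect_effect(-0.130, 0.0306, 0.514, 0.0569)
  expect_equal(ie$indirect, -0.130 * 0.514)
  se_expected <- sqrt((-0.130)^2 * 0.0569^2 + 0.514^2 * 0.0306^2)
  expect_equal(ie$se_indirect, se_expected, tolerance = 1e-12)
  expect_equal(round(ie$se_indirect, 4), 0.0174)
  expect_equal(ie$ci, c(-0.101, -0.033), tolerance = 2e-2)

  # symmetric in the two coefficient pairs
  a <- indirect_effect(-0.130, 0.0306, 0.514, 0.0569)
  b <- indirect_effect(0.514, 0.0569, -0.130, 0.0306)
  expect_equal(a$indirect, b$indirect)
  expect_equal(a$se_indirect, b$se_indirect)

  # second-order variant adds the se1^2 se2^2 term
  c2 <- indirect_effect(-0.130, 0.0306, 0.514, 0.0569, second_order = TRUE)
  expect_equal(c2$se_indirect^2 - ie$se_indirect^2, 0.0306^2 * 0.0569^2)
})

test_that("mediated proportion divides by the total effect, CI by its bounds", {
  mp <- mediated_proportion(-0.188, -0.067, c(-0.103, -0.035))
  expect_equal(round(mp$proportion_pct, 2), 35.64)
  expect_equal(round(mp$proportion_ci_pct, 2), c(18.62, 54.79))

  expect_equal(mediated_proportion(-0.2, 0, c(-0.01, 0.01))$proportion_pct, 0)
  expect_error(mediated_proportion(0, 0.1, c(0, 0.2)), "zero")

  # inconsistent mediation (opposing paths) is flagged, not an error
  flag <- mediated_proportion(0.1, -0.05, c(-0.08, -0.02))
  expect_true(isTRUE(attr(flag, "inconsistent")))

  # simultaneous sign flips of (beta0, beta1) leave the proportion unchanged
  ie1 <- indirect_effect(-0.130, 0.0306, 0.514, 0.0569)
  ie2 <- indirect_effect(0.130, 0.0306, 0.514, 0.0569)
  p1 <- mediated_proportion(-0.188, ie1$indirect, ie1$ci)
  p2 <- mediated_proportion(0.188, ie2$indirect, ie2$ci)
  expect_equal(p1$proportion_pct, p2$proportion_pct)
  expect_equal(p1$proportion_ci_pct, p2$proportion_ci_pct)
})

test_that("reporting rounds the indirect effect before deriving the displayed proportion", {
  rows <- list(
    list(b = c(-0.188, -0.130, 0.514), ind = "-0.067", prop = "35.64"),
    list(b = c(-0.154, -0.1096, 0.514), ind = "-0.056", prop = "36.36"),
    list(b = c(-0.425, -0.304, 0.200), ind = "-0.061", prop = "14.35"))
  for (r in rows) {
    res <- mediation_from_betas(r$b[1], 0.05, r$b[2], 0.03, r$b[3], 0.05)
    rep_row <- report_mediation(res)
    expect_equal(rep_row$indirect, r$ind)
    expect_equal(rep_row$proportion_pct, r$prop)
    # full-precision values are carried alongside, unrounded
    expect_equal(rep_row$indirect_full, r$b[2] * r$b[3])
  }
})

test_that("the shipped reference coefficients reproduce their published proportions", {
  ref <- reference_mediation_table()
  tab <- mediation_table(ref)
  expect_equal(as.numeric(tab$proportion_pct), ref$prop)
  expect_equal(as.numeric(tab$indirect), ref$ind)
})

test_that("two-step mediation recovers the chain's mediated proportion", {
  cfg <- analysis_config(seed = 2)
  sim <- simulate_chain(chain_sim_config(seed = 77))
  res <- suppressMessages(two_step_mediation(sim$exposure, sim$mediator,
                                             sim$outcome, cfg))
  expect_false(res$screened)
  expect_equal(res$indirect, res$beta1 * res$beta2)
  # single-replicate check at the generous end; replicate-level calibration
  # lives in the acceptance suite
  expect_lt(abs(res$proportion_pct - 100 * sim$truth$proportion_true), 10)
})

test_that("null and full mediation limits behave", {
  cfg <- analysis_config(seed = 3)
  # no exposure -> mediator path: proportion ~ 0
  sim0 <- simulate_chain(chain_sim_config(kappa = 0, theta_dir = 0.3, seed = 41))
  res0 <- suppressMessages(two_step_mediation(sim0$exposure, sim0$mediator,
                                              sim0$outcome, cfg))
  expect_lt(abs(res0$proportion_pct), 5)

  # no direct path: proportion ~ 100%
  sim1 <- simulate_chain(chain_sim_config(theta_dir = 0, seed = 42))
  res1 <- suppressMessages(two_step_mediation(sim1$exposure, sim1$mediator,
                                              sim1$outcome, cfg))
  expect_lt(abs(res1$proportion_pct - 100), 10)
})

test_that("a mediator without outcome effect is screened out", {
  cfg <- analysis_config(seed = 4)
  sim <- simulate_chain(chain_sim_config(theta_M = 0, theta_dir = 0.3, seed = 43))
  res <- suppressMessages(two_step_mediation(sim$exposure, sim$mediator,
                                             sim$outcome, cfg))
  expect_true(res$screened)
  expect_gte(res$screen_pval, 0.05)
  expect_error(report_mediation(res), "screened")
})
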