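#' Indirect effect of an exposure through a mediator
#'
#' Product-of-coefficients indirect effect `beta1 * beta2`, where `beta1`
#' is the exposure-to-mediator causal effect and `beta2` the
#' mediator-to-outcome effect, with a first-order delta-method standard
#' error `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`. The cross-covariance is
#' taken as zero, appropriate for non-overlapping two-sample GWAS;
#' `second_order = TRUE` adds the `se1^2 se2^2` term of the exact variance
#' of a product of independent normals.
#'
#' @param beta1,se1 exposure-to-mediator effect and SE (`se1 > 0`).
#' @param beta2,se2 mediator-to-outcome effect and SE (`se2 > 0`).
#' @param second_order include the `se1^2 se2^2` variance term.
#' @return list with `indirect`, `se_indirect`, `ci` (95%, normal).
#' @examples
#' indirect_effect(-0.130, 0.0306, 0.514, 0.0569)
#' @export
indirect_effect <- function(beta1, se1, beta2, se2, second_order = FALSE) {
  stopifnot(se1 > 0, se2 > 0)
  indirect <- beta1 * beta2
  v <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) v <- v + se1^2 * se2^2
  se_indirect <- sqrt(v)
  list(indirect = indirect, se_indirect = se_indirect,
       ci = indirect + c(-1, 1) * Z95 * se_indirect)
}

#' Mediated proportion of a total effect
#'
#' The share of the total effect `beta0` transmitted through the mediator:
#' `100 * indirect / beta0` (percent). The confidence interval divides the
#' indirect-effect CI bounds by `beta0` and orders them - the convention
#' under which the interval endpoints remain consistent with the reported
#' indirect-effect interval. A delta-method interval on the ratio itself is
#' available via `method = "delta"`, which additionally propagates the
#' uncertainty in `beta0` assuming independence.
#'
#' Proportions outside \[0, 100\] (an "inconsistent" mediation pattern,
#' where direct and indirect paths oppose each other) are returned with
#' attribute `inconsistent = TRUE` rather than raising an error.
#'
#' @param beta0 total exposure-to-outcome effect (nonzero).
#' @param indirect indirect effect (`beta1 * beta2`).
#' @param indirect_ci length-2 indirect-effect confidence bounds.
#' @param method `"bounds"` (divide CI bounds, default) or `"delta"`.
#' @param se0,se_indirect needed for `method = "delta"`.
#' @return list with `proportion_pct` and `proportion_ci_pct` (ascending).
#' @examples
#' mediated_proportion(-0.188, -0.067, c(-0.103, -0.035))
#' @export
mediated_proportion <- function(beta0, indirect, indirect_ci,
                                method = c("bounds", "delta"),
                                se0 = NULL, se_indirect = NULL) {
  method <- match.arg(method)
  if (beta0 == 0) stopf("mediated proportion undefined: total effect is zero")
  proportion <- 100 * indirect / beta0
  if (method == "bounds") {
    ci <- sort(100 * indirect_ci / beta0)
  } else {
    stopifnot(!is.null(se0), !is.null(se_indirect))
    ratio <- indirect / beta0
    se_ratio <- abs(ratio) * sqrt((se_indirect / indirect)^2 + (se0 / beta0)^2)
    ci <- sort(100 * (ratio + c(-1, 1) * Z95 * se_ratio))
  }
  out <- list(proportion_pct = proportion, proportion_ci_pct = ci)
  if (proportion < 0 || proportion > 100) attr(out, "inconsistent") <- TRUE
  out
}

new_mediation_result <- function(exposure, mediator, outcome,
                                 beta0, se0, beta1, se1, beta2, se2,
                                 screened = FALSE, screen_pval = NA_real_) {
  res <- list(exposure = exposure, mediator = mediator, outcome = outcome,
              beta0 = beta0, se0 = se0, beta1 = beta1, se1 = se1,
              beta2 = beta2, se2 = se2, screened = screened,
              screen_pval = screen_pval)
  if (!screened) {
    ie <- indirect_effect(beta1, se1, beta2, se2)
    mp <- mediated_proportion(beta0, ie$indirect, ie$ci)
    res <- c(res, list(indirect = ie$indirect, se_indirect = ie$se_indirect,
                       indirect_ci = ie$ci,
                       proportion_pct = mp$proportion_pct,
                       proportion_ci_pct = mp$proportion_ci_pct,
                       inconsistent = isTRUE(attr(mp, "inconsistent"))))
  }
  structure(res, class = "mediation_result")
}

#' Assemble a mediation result from the three step estimates
#'
#' Composes [indirect_effect()] and [mediated_proportion()] from
#' already-estimated coefficients: `beta0` (total exposure-to-outcome
#' effect), `beta1` (exposure-to-mediator) and `beta2`
#' (mediator-to-outcome), with their standard errors. Used both by the
#' full pipeline ([two_step_mediation()]) and to recompute mediation
#' arithmetic from published coefficient tables.
#'
#' @param beta0,se0,beta1,se1,beta2,se2 step estimates and SEs.
#' @param exposure,mediator,outcome trait labels.
#' @return A `mediation_result`.
#' @export
mediation_from_betas <- function(beta0, se0, beta1, se1, beta2, se2,
                                 exposure = "exposure", mediator = "mediator",
                                 outcome = "outcome") {
  new_mediation_result(exposure, mediator, outcome,
                       beta0, se0, beta1, se1, beta2, se2)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  if (x$screened) {
    cat(sprintf("  mediator screened out: mediator-outcome p = %.3g (>= 0.05)\n",
                x$screen_pval))
    return(invisible(x))
  }
  row <- report_mediation(x)
  cat(sprintf("  indirect %.3f (%s); mediated proportion %s%% (%s)\n",
              x$indirect, row$indirect_ci, row$proportion_pct, row$proportion_ci_pct))
  invisible(x)
}

#' Two-step Mendelian randomization mediation analysis
#'
#' Runs the full instrument-selection / harmonization / IVW pipeline three
#' times - exposure on outcome (total effect `beta0`), exposure on mediator
#' (`beta1`) and mediator on outcome (`beta2`), each with the IVW
#' fixed/random switching rule as the primary estimator - then combines
#' them into the indirect effect `beta1 * beta2` and the mediated
#' proportion `(beta1 * beta2) / beta0`. The mediator is screened out
#' (flagged, not computed) when the mediator-to-outcome IVW p-value is
#' >= 0.05: a trait with no credible effect on the outcome cannot mediate.
#'
#' `beta2` is estimated by univariable MR of the mediator on the outcome;
#' results therefore carry the usual caveat that the mediator-outcome
#' effect is not adjusted for the exposure.
#'
#' @param exposure,mediator,outcome [sumstats] objects.
#' @param config an [analysis_config()] list (thresholds, clumping, LD,
#'   seed, ...).
#' @param ld optional `ld_info` used for clumping both instrument sets
#'   (default: independence).
#' @return A `mediation_result`.
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               config = analysis_config(), ld = ld_independent()) {
  e0 <- fit_ivw_pipeline(exposure, outcome, config, ld)
  e1 <- fit_ivw_pipeline(exposure, mediator, config, ld)
  e2 <- fit_ivw_pipeline(mediator, outcome, config, ld,
                         threshold = config$p_threshold_mediator %||% config$p_threshold)
  if (e2$pval >= 0.05) {
    return(new_mediation_result(trait_label(exposure), trait_label(mediator),
                                trait_label(outcome),
                                beta0 = e0$beta, se0 = e0$se,
                                beta1 = e1$beta, se1 = e1$se,
                                beta2 = e2$beta, se2 = e2$se,
                                screened = TRUE, screen_pval = e2$pval))
  }
  new_mediation_result(trait_label(exposure), trait_label(mediator),
                       trait_label(outcome),
                       beta0 = e0$beta, se0 = e0$se,
                       beta1 = e1$beta, se1 = e1$se,
                       beta2 = e2$beta, se2 = e2$se)
}

#' Format a mediation result the way published mediation tables report it
#'
#' Reporting convention: the indirect effect and its CI bounds are rounded
#' to 3 decimals first, and the displayed proportion (to 2 decimals) is
#' then computed from those rounded values - the convention under which
#' the displayed proportion, its CI and the displayed indirect effect are
#' mutually consistent to the printed digits. Full-precision values remain
#' available on the `mediation_result` itself and in the numeric columns.
#'
#' @param result a `mediation_result` (not screened).
#' @return one-row data.frame with display columns (`indirect`,
#'   `indirect_ci`, `proportion_pct`, `proportion_ci_pct` as formatted
#'   strings) and full-precision numeric columns (`*_full`).
#' @export
report_mediation <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  if (isTRUE(result$screened)) stopf("mediator was screened out; nothing to report")
  ind_r <- round(result$indirect, 3)
  ci_r <- round(result$indirect_ci, 3)
  prop_disp <- round(100 * ind_r / result$beta0, 2)
  prop_ci_disp <- sort(round(100 * ci_r / result$beta0, 2))
  data.frame(
    exposure = result$exposure, mediator = result$mediator,
    outcome = result$outcome,
    beta0 = result$beta0, beta1 = result$beta1, beta2 = result$beta2,
    indirect = sprintf("%.3f", ind_r),
    indirect_ci = sprintf("(%.3f,%.3f)", ci_r[1], ci_r[2]),
    proportion_pct = sprintf("%.2f", prop_disp),
    proportion_ci_pct = sprintf("(%.2f,%.2f)", prop_ci_disp[1], prop_ci_disp[2]),
    indirect_full = result$indirect,
    se_indirect_full = result$se_indirect,
    proportion_pct_full = result$proportion_pct,
    proportion_lo_full = result$proportion_ci_pct[1],
    proportion_hi_full = result$proportion_ci_pct[2],
    stringsAsFactors = FALSE
  )
}
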