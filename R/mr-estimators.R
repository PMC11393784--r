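#' Per-variant Wald ratios
#'
#' The building block of every summary-data causal estimator: for variant j
#' the ratio estimate is `r_j = beta_out / beta_exp` with first-order
#' standard error `se_r = se_out / |beta_exp|` and inverse-variance weight
#' `w_j = 1 / se_r^2`. The first-order SE ignores the uncertainty in the
#' exposure association, which is negligible in the F > 10 regime enforced
#' upstream; `second_order = TRUE` adds the `beta_out^2 se_exp^2 /
#' beta_exp^4` term.
#'
#' @param pairs a `harmonized_pairs` object (see [harmonize()]).
#' @param second_order include the exposure-uncertainty term in the ratio SE.
#' @return data.frame with columns `rsid, ratio, se_ratio, weight`; pairs
#'   with `beta_exp == 0` are dropped with a warning.
#' @export
wald_ratios <- function(pairs, second_order = FALSE) {
  stopifnot(inherits(pairs, "harmonized_pairs") || is.data.frame(pairs))
  zero <- pairs$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("dropping %d pair(s) with beta_exp == 0", sum(zero)),
            call. = FALSE)
    pairs <- pairs[!zero, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stopf("no usable pairs: all exposure betas are zero")
  ratio <- pairs$beta_out / pairs$beta_exp
  se_ratio <- if (second_order) {
    sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
           pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  } else {
    pairs$se_out / abs(pairs$beta_exp)
  }
  data.frame(rsid = pairs$rsid, ratio = ratio, se_ratio = se_ratio,
             weight = 1 / se_ratio^2, stringsAsFactors = FALSE)
}

new_mr_estimate <- function(method, beta, se, pval, n_snp, extras = list(),
                            df = Inf) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else Z95
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, n_snp = n_snp, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- beta_to_or(x)
  cat(sprintf("<mr_estimate> %s: beta %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  cat(sprintf("  OR %.3f (95%% CI %.3f - %.3f)\n", or["or"], or["or_low"], or["or_high"]))
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' The primary causal estimator: the inverse-variance weighted average of
#' per-variant Wald ratios, `beta = sum(w r) / sum(w)`. Under the
#' fixed-effects model `se = (sum w)^(-1/2)`; the multiplicative
#' random-effects model scales that SE by `sqrt(max(Q/(L-1), 1))` where Q is
#' Cochran's heterogeneity statistic, so it can never be smaller than the
#' fixed-effects SE. `effects_model = "auto"` applies the conventional
#' switching rule: random effects if the Q test has p < 0.05, fixed
#' otherwise. Inference uses the normal reference.
#'
#' The `ratio_se` argument controls the variance attached to the pooled
#' estimate: `"first"` keeps the first-order ratio variances (exposure
#' uncertainty ignored; the textbook formula `se = (sum w)^(-1/2)`), while
#' `"second"` keeps the same first-order weights for the point estimate but
#' propagates the second-order ratio variances into the pooled SE,
#' `Var(b) = sum(w^2 v2) / (sum w)^2`. The second-order SE matters when the
#' exposure and outcome samples are of comparable size, where the neglected
#' term is about `beta^2` of the total variance; re-weighting by the
#' second-order variances themselves is deliberately avoided because
#' outcome-dependent weights bias the estimate toward zero.
#'
#' @param pairs a `harmonized_pairs` object.
#' @param effects_model `"auto"` (default), `"fixed"` or `"random"`.
#' @param ratio_se `"first"` (default) or `"second"`; see Details.
#' @return An `mr_estimate`; `extras` carries `Q`, `Q_df`, `Q_pval` (when
#'   L >= 2) and `model_used`.
#' @export
mr_ivw <- function(pairs, effects_model = c("auto", "fixed", "random"),
                   ratio_se = c("first", "second")) {
  effects_model <- match.arg(effects_model)
  ratio_se <- match.arg(ratio_se)
  rt <- wald_ratios(pairs)
  L <- nrow(rt)
  w <- rt$weight
  beta <- sum(w * rt$ratio) / sum(w)
  se_fixed <- if (ratio_se == "second") {
    v2 <- suppressWarnings(wald_ratios(pairs, second_order = TRUE)$se_ratio^2)
    sqrt(sum(w^2 * v2) / sum(w)^2)
  } else {
    1 / sqrt(sum(w))
  }
  extras <- list(model_used = "fixed")
  se <- se_fixed
  if (L >= 2) {
    Q <- sum(w * (rt$ratio - beta)^2)
    Q_pval <- stats::pchisq(Q, df = L - 1, lower.tail = FALSE)
    extras <- list(Q = Q, Q_df = L - 1, Q_pval = Q_pval, model_used = "fixed")
    use_random <- switch(effects_model,
                         fixed = FALSE,
                         random = TRUE,
                         auto = Q_pval < 0.05)
    if (use_random) {
      se <- se_fixed * sqrt(max(Q / (L - 1), 1))
      extras$model_used <- "random"
    }
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("ivw", beta, se, pval, L, extras)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an unconstrained intercept, weights `1/se_out^2`, after orienting
#' every pair so the exposure effect is positive. The slope is a
#' pleiotropy-robust causal estimate (valid under the InSIDE assumption);
#' the intercept estimates the average directional pleiotropic effect and
#' its deviation from zero is the Egger pleiotropy test. Inference uses the
#' t distribution with L - 2 degrees of freedom.
#'
#' @param pairs a `harmonized_pairs` object with at least 3 variants.
#' @return An `mr_estimate` with `extras` `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(pairs) {
  if (nrow(pairs) < 3) stopf("MR-Egger needs at least 3 variants")
  sgn <- sign(pairs$beta_exp)
  sgn[sgn == 0] <- 1
  x <- pairs$beta_exp * sgn
  y <- pairs$beta_out * sgn
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  L <- nrow(pairs)
  est <- new_mr_estimate("egger", cf["x", 1], cf["x", 2],
                         2 * stats::pt(-abs(cf["x", 3]), df = L - 2),
                         L,
                         extras = list(intercept = cf["(Intercept)", 1],
                                       intercept_se = cf["(Intercept)", 2],
                                       intercept_pval = 2 * stats::pt(-abs(cf["(Intercept)", 3]),
                                                                      df = L - 2)),
                         df = L - 2)
  est
}

# Weighted median of ratio estimates via the standardized cumulative-weight
# interpolation rule.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The 50th percentile of the inverse-variance-weight-standardized
#' distribution of Wald ratios: order the ratios, form standardized
#' cumulative weights `p_j = (S_j - w_j/2) / S_L`, and linearly interpolate
#' the ratio at p = 0.5. Consistent as long as valid instruments contribute
#' at least half the total weight. The SE comes from a seeded parametric
#' bootstrap: each ratio is redrawn from `Normal(r_j, se_r_j)` and the
#' weighted median recomputed.
#'
#' @param pairs a `harmonized_pairs` object with at least 3 variants.
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap (required; no global RNG
#'   state is consumed).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed) {
  if (nrow(pairs) < 3) stopf("weighted median needs at least 3 variants")
  stopifnot(n_boot >= 1)
  rt <- wald_ratios(pairs)
  beta <- weighted_median_point(rt$ratio, rt$weight)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      r_star <- stats::rnorm(nrow(rt), rt$ratio, rt$se_ratio)
      weighted_median_point(r_star, rt$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, pval, nrow(rt))
}

# Default kernel bandwidth: robust (MAD-based) spread of the ratios with
# the usual n^(-1/5) rate; falls back to the SD when the MAD degenerates.
mode_bandwidth <- function(ratio, bandwidth_factor) {
  s <- stats::mad(ratio)
  if (s == 0) s <- stats::sd(ratio)
  bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
}

mode_point <- function(ratio, weight, h, grid_n = 512) {
  if (h <= 0 || !is.finite(h)) return(stats::median(ratio)) # degenerate spread
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) {
    sum(weight * stats::dnorm((x - ratio) / h))
  }, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the kernel-smoothed empirical density of Wald ratios: a
#' normal kernel with bandwidth `bandwidth_factor` times a MAD-based
#' default is evaluated on a 512-point grid spanning the ratio range plus
#' three bandwidths; the estimate is the grid argmax. The simple mode
#' weights every ratio equally; the weighted mode weights each ratio by its
#' inverse-variance weight. Consistent when the largest group of
#' instruments sharing the same ratio is valid. SE by seeded parametric
#' bootstrap as in [mr_weighted_median()].
#'
#' @param pairs a `harmonized_pairs` object with at least 3 variants.
#' @param weighted use inverse-variance weights in the density (weighted
#'   mode) instead of equal weights (simple mode).
#' @param bandwidth_factor multiplier on the default bandwidth (default 1).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_mode"` or
#'   `"simple_mode"`; `extras$bandwidth` records the bandwidth used.
#' @export
mr_mode <- function(pairs, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed) {
  if (nrow(pairs) < 3) stopf("mode estimator needs at least 3 variants")
  rt <- wald_ratios(pairs)
  w <- if (weighted) rt$weight / sum(rt$weight) else rep(1 / nrow(rt), nrow(rt))
  h <- mode_bandwidth(rt$ratio, bandwidth_factor)
  beta <- mode_point(rt$ratio, w, h)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      r_star <- stats::rnorm(nrow(rt), rt$ratio, rt$se_ratio)
      mode_point(r_star, w, mode_bandwidth(r_star, bandwidth_factor))
    }, numeric(1))
  })
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, pval, nrow(rt),
                  extras = list(bandwidth = h))
}

#' Convert a log-scale estimate to an odds ratio with 95% CI
#'
#' Exponentiates the causal log-effect and its confidence bounds, giving
#' the odds ratio per standard deviation of the exposure (for binary
#' outcomes analysed on the log-odds scale). Rounding to 3 decimals is left
#' to the reporting layer.
#'
#' @param estimate an `mr_estimate`, or a bare numeric log-effect.
#' @param ci_low,ci_high confidence bounds when `estimate` is numeric.
#' @return Named numeric vector `or, or_low, or_high`.
#' @examples
#' beta_to_or(-0.425, -0.658, -0.192)  # OR 0.654
#' @export
beta_to_or <- function(estimate, ci_low = NULL, ci_high = NULL) {
  if (inherits(estimate, "mr_estimate")) {
    ci_low <- estimate$ci_low
    ci_high <- estimate$ci_high
    estimate <- estimate$beta
  }
  c(or = exp(estimate),
    or_low = if (is.null(ci_low)) NA_real_ else exp(ci_low),
    or_high = if (is.null(ci_high)) NA_real_ else exp(ci_high))
}

#' Run the full five-estimator suite
#'
#' Applies the inverse-variance weighted (with the fixed/random switching
#' rule), MR-Egger, weighted-median, simple-mode and weighted-mode
#' estimators to one harmonized instrument set and returns a tidy table,
#' one row per method, with odds-ratio columns for reporting.
#'
#' @param pairs a `harmonized_pairs` object.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param ratio_se IVW ratio-variance order (see [mr_ivw()]).
#' @param n_boot bootstrap draws for median/mode SEs.
#' @param seed integer seed for all stochastic SEs.
#' @return data.frame with columns `method, n_snp, beta, se, ci_low,
#'   ci_high, pval, or, or_low, or_high`.
#' @export
mr_all_methods <- function(pairs, effects_model = "auto", ratio_se = "first",
                           n_boot = 1000, seed) {
  ests <- list(
    mr_ivw(pairs, effects_model = effects_model, ratio_se = ratio_se),
    mr_egger(pairs),
    mr_weighted_median(pairs, n_boot = n_boot, seed = seed),
    mr_mode(pairs, weighted = FALSE, n_boot = n_boot, seed = seed + 1L),
    mr_mode(pairs, weighted = TRUE, n_boot = n_boot, seed = seed + 2L)
  )
  do.call(rbind, lapply(ests, function(e) {
    or <- beta_to_or(e)
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               or = or["or"], or_low = or["or_low"], or_high = or["or_high"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
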