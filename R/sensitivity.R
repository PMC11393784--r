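#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (r_j - beta_ivw_fixed)^2` over the Wald ratios, referred
#' to a chi-square distribution with L - 1 degrees of freedom. Large Q
#' indicates that the per-variant ratio estimates disagree beyond sampling
#' noise, e.g. because of heterogeneous pleiotropy, and triggers the switch
#' to the random-effects IVW model in the primary analysis.
#'
#' @param pairs a `harmonized_pairs` object with at least 2 variants.
#' @return list with `Q`, `df` (= L - 1) and `pval`.
#' @export
cochran_q <- function(pairs) {
  rt <- wald_ratios(pairs)
  L <- nrow(rt)
  if (L < 2) stopf("Cochran's Q needs at least 2 variants")
  beta <- sum(rt$weight * rt$ratio) / sum(rt$weight)
  Q <- sum(rt$weight * (rt$ratio - beta)^2)
  list(Q = Q, df = L - 1L, pval = stats::pchisq(Q, df = L - 1, lower.tail = FALSE))
}

#' Egger intercept pleiotropy test
#'
#' Returns the intercept of the MR-Egger regression ([mr_egger()]) with its
#' standard error and t-test p-value (L - 2 degrees of freedom). A nonzero
#' intercept is evidence of directional horizontal pleiotropy.
#'
#' @param pairs a `harmonized_pairs` object with at least 3 variants.
#' @return list with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(pairs) {
  est <- mr_egger(pairs)
  list(intercept = est$extras$intercept,
       se = est$extras$intercept_se,
       pval = est$extras$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate (with the fixed/random switching rule, to
#' mirror the primary analysis) excluding each variant in turn, alongside
#' the all-variant estimate. An exclusion row is flagged when removing that
#' variant changes the sign of the causal estimate or moves it outside the
#' all-variant confidence interval - the signature of a single variant
#' driving the result.
#'
#' @param pairs a `harmonized_pairs` object with at least 3 variants.
#' @param ratio_se IVW ratio-variance order (see [mr_ivw()]).
#' @return data.frame with L + 1 rows (`excluded_rsid == "none"` for the
#'   full set) and columns `excluded_rsid, n_snp, beta, se, ci_low,
#'   ci_high, pval, flagged`.
#' @export
leave_one_out <- function(pairs, ratio_se = "first") {
  if (nrow(pairs) < 3) stopf("leave-one-out needs at least 3 variants")
  full <- mr_ivw(pairs, effects_model = "auto", ratio_se = ratio_se)
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    est <- mr_ivw(pairs[-j, , drop = FALSE], effects_model = "auto",
                  ratio_se = ratio_se)
    data.frame(excluded_rsid = pairs$rsid[j], n_snp = est$n_snp,
               beta = est$beta, se = est$se, ci_low = est$ci_low,
               ci_high = est$ci_high, pval = est$pval,
               flagged = sign(est$beta) != sign(full$beta) ||
                 est$beta < full$ci_low || est$beta > full$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out,
               data.frame(excluded_rsid = "none", n_snp = full$n_snp,
                          beta = full$beta, se = full$se, ci_low = full$ci_low,
                          ci_high = full$ci_high, pval = full$pval,
                          flagged = FALSE, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# Leave-one-out fixed-effects IVW betas in O(L) from the weight sums.
loo_ivw_beta <- function(ratio, weight) {
  W <- sum(weight)
  T <- sum(weight * ratio)
  (T - weight * ratio) / (W - weight)
}

#' MR-PRESSO: global pleiotropy, outlier and distortion tests
#'
#' Residual-sum-of-squares based pleiotropy diagnostics:
#'
#' * **Global test** - the observed RSS is `sum_j w_j (r_j - b^(-j))^2`,
#'   where `b^(-j)` is the fixed-effects IVW estimate excluding variant j.
#'   Its null distribution is built from `n_sim` parametric simulations
#'   that redraw each pair's exposure and outcome effects from normal
#'   distributions centred on the no-pleiotropy fit (`beta_exp_j` and
#'   `beta_exp_j * b^(-j)`) with the reported SEs; the p-value is the
#'   fraction of simulated RSS values at least as large as observed.
#' * **Outlier test** - each variant's observed weighted squared residual
#'   is compared with its own simulated distribution; variants with
#'   empirical p below `outlier_alpha / L` (Bonferroni) are declared
#'   outliers.
#' * **Distortion test** - compares the IVW estimate before and after
#'   outlier removal with a seeded permutation reference: random subsets of
#'   non-outlying variants of the same size as the outlier set are removed
#'   and the resulting shifts form the null for the observed shift.
#'
#' All randomness is drawn inside `withr::with_seed(seed, ...)`: a single
#' stream fills an L x n_sim matrix of exposure draws, then one of outcome
#' draws, then the distortion permutations, so results are reproducible
#' across platforms for a given seed.
#'
#' @param pairs a `harmonized_pairs` object with at least 4 variants.
#' @param n_sim number of parametric simulations (>= 100; default 1000).
#' @param outlier_alpha familywise outlier level before Bonferroni
#'   correction (default 0.05).
#' @param seed integer seed.
#' @return list of class `presso_result`: `global_rss_obs`, `global_pval`,
#'   `outlier_pvals` (per variant), `outlier_indices`, `outlier_rsids`,
#'   `distortion_pval` (`NA` when no outliers), `estimate_before`,
#'   `estimate_after` (IVW-auto on the retained subset).
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05, seed) {
  if (nrow(pairs) < 4) stopf("MR-PRESSO needs at least 4 variants")
  if (n_sim < 100) stopf("n_sim must be at least 100")
  pairs <- pairs[pairs$beta_exp != 0, , drop = FALSE]
  rt <- wald_ratios(pairs)
  L <- nrow(rt)
  b_loo <- loo_ivw_beta(rt$ratio, rt$weight)
  obs_res2 <- rt$weight * (rt$ratio - b_loo)^2
  rss_obs <- sum(obs_res2)

  pr <- withr::with_seed(seed, {
    bx_star <- matrix(stats::rnorm(L * n_sim, pairs$beta_exp, pairs$se_exp),
                      nrow = L)
    by_star <- matrix(stats::rnorm(L * n_sim, pairs$beta_exp * b_loo, pairs$se_out),
                      nrow = L)
    r_star <- by_star / bx_star
    w_star <- (bx_star / pairs$se_out)^2
    W <- colSums(w_star)
    T <- colSums(w_star * r_star)
    b_loo_star <- sweep(-(w_star * r_star), 2, T, `+`) /
      sweep(-w_star, 2, W, `+`)
    res2_star <- w_star * (r_star - b_loo_star)^2
    rss_star <- colSums(res2_star)
    global_pval <- mean(rss_star >= rss_obs)
    outlier_pvals <- rowMeans(res2_star >= obs_res2)
    outliers <- which(outlier_pvals < outlier_alpha / L)

    est_before <- mr_ivw(pairs, effects_model = "auto")
    distortion_pval <- NA_real_
    est_after <- est_before
    if (length(outliers) > 0 && L - length(outliers) >= 2) {
      est_after <- mr_ivw(pairs[-outliers, , drop = FALSE], effects_model = "auto")
      d_obs <- est_before$beta - est_after$beta
      inliers <- setdiff(seq_len(L), outliers)
      d_null <- vapply(seq_len(n_sim), function(k) {
        drop_k <- sample(inliers, length(outliers))
        est_before$beta - mr_ivw(pairs[-drop_k, , drop = FALSE],
                                 effects_model = "auto")$beta
      }, numeric(1))
      distortion_pval <- mean(abs(d_null) >= abs(d_obs))
    }
    list(global_rss_obs = rss_obs, global_pval = global_pval,
         outlier_pvals = outlier_pvals, outlier_indices = outliers,
         outlier_rsids = rt$rsid[outliers],
         distortion_pval = distortion_pval,
         estimate_before = est_before, estimate_after = est_after)
  })
  class(pr) <- "presso_result"
  pr
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS %.3f, p = %.4g; %d outlier(s)%s\n",
              x$global_rss_obs, x$global_pval, length(x$outlier_indices),
              if (length(x$outlier_indices))
                paste0(" [", paste(x$outlier_rsids, collapse = ", "), "]")
              else ""))
  if (!is.na(x$distortion_pval)) {
    cat(sprintf("  distortion p = %.4g; beta %.4f -> %.4f after removal\n",
                x$distortion_pval, x$estimate_before$beta, x$estimate_after$beta))
  }
  invisible(x)
}

#' Bundle the standard diagnostics for one instrument set
#'
#' Convenience wrapper returning Cochran's Q, the Egger intercept test and
#' (optionally) MR-PRESSO as one tidy row, matching the columns reported
#' alongside each causal estimate.
#'
#' @param pairs a `harmonized_pairs` object.
#' @param presso run MR-PRESSO (needs >= 4 variants).
#' @param n_sim,seed passed to [mr_presso()].
#' @return one-row data.frame `Q, Q_df, Q_pval, egger_intercept,
#'   intercept_se, intercept_pval, presso_global_pval, presso_outliers`.
#' @export
mr_diagnostics <- function(pairs, presso = TRUE, n_sim = 1000, seed = 1L) {
  q <- cochran_q(pairs)
  eg <- if (nrow(pairs) >= 3) egger_intercept_test(pairs) else
    list(intercept = NA_real_, se = NA_real_, pval = NA_real_)
  pg <- NA_real_
  po <- ""
  if (presso && nrow(pairs) >= 4) {
    pr <- mr_presso(pairs, n_sim = n_sim, seed = seed)
    pg <- pr$global_pval
    po <- paste(pr$outlier_rsids, collapse = ",")
  }
  data.frame(Q = q$Q, Q_df = q$df, Q_pval = q$pval,
             egger_intercept = eg$intercept, intercept_se = eg$se,
             intercept_pval = eg$pval, presso_global_pval = pg,
             presso_outliers = po, stringsAsFactors = FALSE)
}
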