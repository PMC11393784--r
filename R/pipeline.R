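#' Analysis configuration
#'
#' One bag of parameters shared by the pipeline stages, with the
#' conventional defaults: forward instrument threshold `5e-8` (relaxed
#' presets `5e-7` for sparse exposures and `5e-6` for reverse analyses),
#' clumping at `r2 <= 0.001` within 10,000 kb, weak instruments excluded
#' below F = 10, palindrome frequency band (0.42, 0.58), IVW with the
#' fixed/random switching rule, 1000 bootstrap draws and 1000 MR-PRESSO
#' simulations.
#'
#' @param p_threshold forward instrument p-value threshold.
#' @param p_threshold_reverse threshold for reverse-direction analyses.
#' @param p_threshold_mediator threshold when instrumenting mediators
#'   (defaults to `p_threshold`).
#' @param clump_r2,clump_kb clumping parameters.
#' @param f_min minimum instrument F-statistic.
#' @param palindrome_band frequency band for ambiguous palindromes.
#' @param effects_model IVW effects model (`"auto"`, `"fixed"`, `"random"`).
#' @param ratio_se ratio-variance order for the primary IVW standard error
#'   (`"second"` by default; see [mr_ivw()]).
#' @param n_boot bootstrap draws for median/mode SEs.
#' @param n_sim MR-PRESSO simulations.
#' @param seed integer seed for all stochastic steps.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(p_threshold = 5e-8, p_threshold_reverse = 5e-6,
                            p_threshold_mediator = NULL,
                            clump_r2 = 0.001, clump_kb = 10000, f_min = 10,
                            palindrome_band = c(0.42, 0.58),
                            effects_model = "auto", ratio_se = "second",
                            n_boot = 1000, n_sim = 1000, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            p_threshold_reverse > 0, p_threshold_reverse < 1,
            clump_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold,
                 p_threshold_reverse = p_threshold_reverse,
                 p_threshold_mediator = p_threshold_mediator,
                 clump_r2 = clump_r2, clump_kb = clump_kb, f_min = f_min,
                 palindrome_band = palindrome_band,
                 effects_model = effects_model, ratio_se = ratio_se,
                 n_boot = n_boot,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = c("analysis_config", "list"))
}

#' Select and harmonize instruments for one exposure-outcome pair
#'
#' The instrument-selection chain: p-value thresholding on the exposure,
#' greedy LD clumping, F-statistic filtering, then harmonization of
#' exposure and outcome onto a common allele frame.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param config an [analysis_config()].
#' @param ld `ld_info` for clumping (default: independence).
#' @param threshold instrument p-value threshold (default
#'   `config$p_threshold`).
#' @return A `harmonized_pairs` object.
#' @export
select_instruments <- function(exposure, outcome, config = analysis_config(),
                               ld = ld_independent(),
                               threshold = config$p_threshold) {
  iv <- select_by_pvalue(exposure, threshold)
  if (nrow(iv) == 0L) stopf("no instruments for %s at p < %g",
                            trait_label(exposure), threshold)
  iv <- ld_clump(iv, ld, r2_max = config$clump_r2, window_kb = config$clump_kb)
  iv <- filter_weak_instruments(iv, config$f_min)
  if (nrow(iv) == 0L) stopf("no instruments for %s after F filter",
                            trait_label(exposure))
  harmonize(iv, outcome, palindrome_eaf_band = config$palindrome_band)
}

# IVW-only pipeline used as the primary estimate inside mediation.
fit_ivw_pipeline <- function(exposure, outcome, config, ld = ld_independent(),
                             threshold = config$p_threshold) {
  pairs <- select_instruments(exposure, outcome, config, ld, threshold)
  mr_ivw(pairs, effects_model = config$effects_model,
         ratio_se = config$ratio_se %||% "first")
}

#' Full MR analysis of one exposure-outcome pair
#'
#' Instrument selection and harmonization followed by the five-estimator
#' suite, heterogeneity/pleiotropy diagnostics and a leave-one-out scan.
#'
#' @inheritParams select_instruments
#' @param diagnostics also run Cochran's Q, the Egger intercept test and
#'   MR-PRESSO.
#' @return list of class `mr_report`: `exposure`, `outcome`, `n_snp`,
#'   `estimates` (tidy data.frame from [mr_all_methods()]), `diagnostics`
#'   (one-row data.frame or `NULL`), `loo` (leave-one-out table or
#'   `NULL`), `pairs`.
#' @export
run_mr <- function(exposure, outcome, config = analysis_config(),
                   ld = ld_independent(), threshold = config$p_threshold,
                   diagnostics = TRUE) {
  pairs <- select_instruments(exposure, outcome, config, ld, threshold)
  estimates <- mr_all_methods(pairs, effects_model = config$effects_model,
                              ratio_se = config$ratio_se %||% "first",
                              n_boot = config$n_boot, seed = config$seed)
  diag_row <- NULL
  loo <- NULL
  if (diagnostics && nrow(pairs) >= 2) {
    diag_row <- mr_diagnostics(pairs, presso = nrow(pairs) >= 4,
                               n_sim = config$n_sim, seed = config$seed + 10L)
    if (nrow(pairs) >= 3) loo <- leave_one_out(pairs)
  }
  structure(list(exposure = trait_label(exposure),
                 outcome = trait_label(outcome), n_snp = nrow(pairs),
                 estimates = estimates, diagnostics = diag_row, loo = loo,
                 pairs = pairs),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s -> %s (%d instruments)\n", x$exposure, x$outcome,
              x$n_snp))
  print(x$estimates, digits = 4)
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g); Egger intercept %.4g (p = %.3g)\n",
                x$diagnostics$Q, x$diagnostics$Q_df, x$diagnostics$Q_pval,
                x$diagnostics$egger_intercept, x$diagnostics$intercept_pval))
  }
  invisible(x)
}

# A direction is "supported" when the primary IVW estimate is significant
# at 0.05 and the weighted median agrees in sign.
direction_supported <- function(estimates) {
  ivw <- estimates[estimates$method == "ivw", ]
  wm <- estimates[estimates$method == "weighted_median", ]
  isTRUE(ivw$pval < 0.05 && sign(ivw$beta) == sign(wm$beta))
}

#' Bidirectional MR between two traits
#'
#' Runs the full analysis in both directions: `trait_a -> trait_b` with
#' the forward instrument threshold and `trait_b -> trait_a` with the
#' relaxed reverse threshold. Each direction is flagged as supported when
#' the IVW p-value is below 0.05 and the weighted median agrees in sign.
#'
#' @param config an [analysis_config()].
#' @param trait_a,trait_b [sumstats] objects.
#' @param ld_a,ld_b `ld_info` for clumping instruments of each trait.
#' @return list of class `bidirectional_report` with elements `forward`,
#'   `reverse` (each an `mr_report`) and `forward_supported`,
#'   `reverse_supported` flags.
#' @export
run_bidirectional <- function(config, trait_a, trait_b,
                              ld_a = ld_independent(), ld_b = ld_independent()) {
  fwd <- run_mr(trait_a, trait_b, config, ld_a,
                threshold = config$p_threshold)
  rev <- run_mr(trait_b, trait_a, config, ld_b,
                threshold = config$p_threshold_reverse)
  structure(list(forward = fwd, reverse = rev,
                 forward_supported = direction_supported(fwd$estimates),
                 reverse_supported = direction_supported(rev$estimates)),
            class = "bidirectional_report")
}

#' @export
print.bidirectional_report <- function(x, ...) {
  cat(sprintf("<bidirectional_report> forward %s, reverse %s\n",
              if (x$forward_supported) "supported" else "not supported",
              if (x$reverse_supported) "supported" else "not supported"))
  print(x$forward)
  print(x$reverse)
  invisible(x)
}

#' Mediation suite over several exposures and candidate mediators
#'
#' For each exposure whose total effect on the outcome is supported (IVW
#' p < 0.05, weighted-median sign-consistent), evaluates every candidate
#' mediator by two-step MR. Mediators whose own effect on the outcome is
#' not significant are screened out and appear in the screening log but
#' not in the mediation table.
#'
#' @param config an [analysis_config()].
#' @param exposures named list of [sumstats] objects.
#' @param mediators named list of [sumstats] objects.
#' @param outcome a [sumstats] object.
#' @param ld `ld_info` shared by all clumping steps.
#' @return list of class `mediation_suite`: `table` (rows from
#'   [report_mediation()]), `screened` (data.frame of screened or skipped
#'   combinations with reasons), `results` (the `mediation_result`
#'   objects).
#' @export
run_mediation_suite <- function(config, exposures, mediators, outcome,
                                ld = ld_independent()) {
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(mediators)) == length(mediators))
  rows <- list()
  screened <- list()
  results <- list()
  for (ex_name in names(exposures)) {
    total <- run_mr(exposures[[ex_name]], outcome, config, ld,
                    diagnostics = FALSE)
    if (!direction_supported(total$estimates)) {
      screened[[length(screened) + 1L]] <-
        data.frame(exposure = ex_name, mediator = NA_character_,
                   reason = "total effect not supported",
                   stringsAsFactors = FALSE)
      next
    }
    for (md_name in names(mediators)) {
      res <- two_step_mediation(exposures[[ex_name]], mediators[[md_name]],
                                outcome, config, ld)
      res$exposure <- ex_name
      res$mediator <- md_name
      results[[paste(ex_name, md_name, sep = ".")]] <- res
      if (res$screened) {
        screened[[length(screened) + 1L]] <-
          data.frame(exposure = ex_name, mediator = md_name,
                     reason = sprintf("mediator-outcome p = %.3g", res$screen_pval),
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- report_mediation(res)
      }
    }
  }
  structure(list(table = if (length(rows)) do.call(rbind, rows) else NULL,
                 screened = if (length(screened)) do.call(rbind, screened) else NULL,
                 results = results),
            class = "mediation_suite")
}

#' Recompute a mediation table from published step coefficients
#'
#' Applies [mediation_from_betas()] and [report_mediation()] row-wise to a
#' table of step estimates - for instance a published mediation table
#' whose `beta0`, `beta1`, `beta2` and interval columns are re-derived
#' rather than re-estimated. SEs may be given directly (`se0,se1,se2`) or
#' recovered from 95% CI bounds (`b1_lo/b1_hi`, etc., as
#' `(hi - lo) / (2 * 1.96)`).
#'
#' @param df data.frame with columns `exposure, mediator, outcome, beta0,
#'   beta1, beta2` plus either SE or CI columns.
#' @return data.frame of [report_mediation()] rows.
#' @export
mediation_table <- function(df) {
  se_from_ci <- function(lo, hi) (hi - lo) / (2 * Z95)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    se0 <- r$se0 %||% se_from_ci(r$b0_lo, r$b0_hi)
    se1 <- r$se1 %||% se_from_ci(r$b1_lo, r$b1_hi)
    se2 <- r$se2 %||% se_from_ci(r$b2_lo, r$b2_hi)
    report_mediation(mediation_from_betas(r$beta0, se0, r$beta1, se1,
                                          r$beta2, se2,
                                          exposure = r$exposure,
                                          mediator = r$mediator,
                                          outcome = r$outcome))
  })
  do.call(rbind, rows)
}

#' Write the report tables of an analysis
#'
#' Writes the tidy estimate table, diagnostics and leave-one-out scan of
#' an `mr_report` (or each direction of a `bidirectional_report`) as TSVs
#' under `dir`.
#'
#' @param report an `mr_report` or `bidirectional_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(report, dir, prefix = "mr") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report, "bidirectional_report")) {
    write_mr_report(report$forward, dir, paste0(prefix, "_forward"))
    write_mr_report(report$reverse, dir, paste0(prefix, "_reverse"))
    return(invisible(dir))
  }
  est <- cbind(exposure = report$exposure, outcome = report$outcome,
               report$estimates)
  data.table::fwrite(est, file.path(dir, paste0(prefix, "_estimates.tsv")),
                     sep = "\t", quote = FALSE)
  if (!is.null(report$diagnostics)) {
    data.table::fwrite(report$diagnostics,
                       file.path(dir, paste0(prefix, "_diagnostics.tsv")),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(report$loo)) {
    data.table::fwrite(report$loo,
                       file.path(dir, paste0(prefix, "_leave_one_out.tsv")),
                       sep = "\t", quote = FALSE)
  }
  invisible(dir)
}
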