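#' Configuration for the exposure-mediator-outcome chain simulator
#'
#' Generative parameters for synthetic GWAS summary statistics under a
#' known causal chain. Two disjoint sets of loci are simulated, mirroring
#' the architecture that makes two-step mediation identifiable in real
#' data:
#'
#' * `L` exposure loci with per-allele effects
#'   `gamma_j ~ Normal(0, gamma_sd^2)` on the exposure; they affect the
#'   mediator through the causal path (`kappa * gamma_j`) and the outcome
#'   through both paths (`(theta_dir + kappa * theta_M) * gamma_j`) plus
#'   any horizontal pleiotropy `alpha_j`;
#' * `n_med_loci` mediator-specific loci with effects
#'   `delta_j ~ Normal(0, med_effect_sd^2)` on the mediator and
#'   `theta_M * delta_j` on the outcome, and no effect on the exposure;
#' * `n_out_loci` outcome-specific loci with effects
#'   `eta_j ~ Normal(0, out_effect_sd^2)` on the outcome only - the
#'   disease's own susceptibility loci, which are what a reverse-direction
#'   analysis instruments.
#'
#' The total exposure-outcome effect is `theta_total = theta_dir +
#' kappa * theta_M` and the true mediated proportion is
#' `kappa * theta_M / theta_total`. Pleiotropy
#' `alpha_j ~ Normal(pleio_mean, pleio_sd^2)` acts on a random fraction
#' `pleio_fraction` of the exposure loci: `pleio_mean = 0` gives balanced
#' pleiotropy (InSIDE holds), nonzero gives directional pleiotropy.
#'
#' Observed effects add finite-sample noise with standard error
#' `1 / sqrt(2 n maf (1 - maf))`, the standard approximation for a
#' standardized trait; the three samples are non-overlapping (independent
#' noise draws), matching the two-sample assumption of the delta method.
#'
#' The defaults (L = 100 exposure loci of SD 0.06, 100 mediator loci of
#' SD 0.15, samples of 100,000, kappa = 0.4, theta_M = 0.5, theta_dir =
#' 0.1, no pleiotropy, 20% palindromic variants) describe a well-powered
#' two-sample design whose true mediated proportion is 2/3.
#'
#' @param L number of exposure loci (>= 1).
#' @param gamma_sd SD of per-variant effects on the exposure.
#' @param kappa causal effect exposure -> mediator.
#' @param theta_M causal effect mediator -> outcome.
#' @param theta_dir direct exposure -> outcome effect.
#' @param pleio_mean,pleio_sd mean and SD of per-variant pleiotropic
#'   effects on the outcome.
#' @param pleio_fraction fraction of exposure loci receiving a pleiotropic
#'   effect (default 1).
#' @param n_med_loci number of mediator-specific loci (default `L`; 0
#'   removes them).
#' @param med_effect_sd SD of mediator-specific per-allele effects.
#' @param n_out_loci number of outcome-specific loci (default `L`).
#' @param out_effect_sd SD of outcome-specific per-allele effects.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param maf_range interval in (0, 0.5] for simulated minor-allele
#'   frequencies.
#' @param palindrome_fraction fraction of variants given A/T or G/C
#'   allele pairs.
#' @param noise_scale multiplier on the observation noise (0 gives the
#'   noiseless limit; reported SEs are unchanged).
#' @param seed integer seed.
#' @return list of class `chain_sim_config`.
#' @export
chain_sim_config <- function(L = 100, gamma_sd = 0.06, kappa = 0.4,
                             theta_M = 0.5, theta_dir = 0.1,
                             pleio_mean = 0, pleio_sd = 0, pleio_fraction = 1,
                             n_med_loci = L, med_effect_sd = 0.15,
                             n_out_loci = L, out_effect_sd = 0.1,
                             n_exp = 1e5, n_med = 1e5, n_out = 1e5,
                             maf_range = c(0.05, 0.5),
                             palindrome_fraction = 0.2,
                             noise_scale = 1, seed = 1L) {
  stopifnot(L >= 1, gamma_sd >= 0, pleio_sd >= 0,
            pleio_fraction >= 0, pleio_fraction <= 1,
            n_med_loci >= 0, med_effect_sd >= 0,
            n_out_loci >= 0, out_effect_sd >= 0,
            n_exp > 0, n_med > 0, n_out > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            noise_scale >= 0)
  structure(list(L = as.integer(L), gamma_sd = gamma_sd, kappa = kappa,
                 theta_M = theta_M, theta_dir = theta_dir,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 pleio_fraction = pleio_fraction,
                 n_med_loci = as.integer(n_med_loci),
                 med_effect_sd = med_effect_sd,
                 n_out_loci = as.integer(n_out_loci),
                 out_effect_sd = out_effect_sd,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 maf_range = maf_range,
                 palindrome_fraction = palindrome_fraction,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "chain_sim_config")
}

# Non-palindromic ordered allele pairs (effect, other).
NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

sim_trait_table <- function(rsid, chrom, pos, ea, oa, maf, true_beta, n,
                            noise_scale, trait) {
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  beta <- true_beta + stats::rnorm(length(maf), 0, noise_scale * se)
  eaf <- pmin(pmax(maf + stats::rnorm(length(maf), 0, sqrt(maf * (1 - maf) / (2 * n))),
                   1e-4), 1 - 1e-4)
  pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  sumstats(data.frame(rsid = rsid, chrom = chrom, pos = pos,
                      effect_allele = ea, other_allele = oa,
                      eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                      stringsAsFactors = FALSE),
           trait_label = trait, provenance = "simulated chain")
}

#' Simulate GWAS summary statistics under a known causal chain
#'
#' Draws one realisation of the model described in [chain_sim_config()]
#' and returns the three summary-statistics tables (exposure, mediator,
#' outcome) over the same `L + n_med_loci + n_out_loci` variants, plus the
#' generative truth. Variant positions are spaced 20 Mb apart along chromosomes
#' 1-22, so default clumping windows treat them as independent loci;
#' allele pairs include the configured fraction of palindromic variants,
#' and effect-allele frequencies are consistent across the three tables
#' up to sampling noise.
#'
#' @param config a [chain_sim_config()].
#' @return list with elements `exposure`, `mediator`, `outcome` (each a
#'   [sumstats]) and `truth` (list: `gamma`, `delta`, `eta`, `alpha`, `maf`,
#'   `theta_total`, `kappa`, `theta_M`, `theta_dir`, `proportion_true`).
#' @export
simulate_chain <- function(config) {
  stopifnot(inherits(config, "chain_sim_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    n_var <- cf$L + cf$n_med_loci + cf$n_out_loci
    rsid <- paste0("rs", seq_len(n_var))
    chrom <- as.character(rep_len(1:22, n_var))
    pos <- 1e6 + 2e7 * (ceiling(seq_len(n_var) / 22) - 1)
    maf <- stats::runif(n_var, cf$maf_range[1], cf$maf_range[2])

    gamma <- c(stats::rnorm(cf$L, 0, cf$gamma_sd),
               rep(0, cf$n_med_loci + cf$n_out_loci))
    delta <- c(rep(0, cf$L), stats::rnorm(cf$n_med_loci, 0, cf$med_effect_sd),
               rep(0, cf$n_out_loci))
    eta <- c(rep(0, cf$L + cf$n_med_loci),
             stats::rnorm(cf$n_out_loci, 0, cf$out_effect_sd))
    alpha <- rep(0, n_var)
    n_pleio <- round(cf$pleio_fraction * cf$L)
    if (n_pleio > 0 && (cf$pleio_sd > 0 || cf$pleio_mean != 0)) {
      which_pleio <- sample.int(cf$L, n_pleio)
      alpha[which_pleio] <- stats::rnorm(n_pleio, cf$pleio_mean, cf$pleio_sd)
    }

    n_pal <- round(cf$palindrome_fraction * n_var)
    is_pal <- sample(c(rep(TRUE, n_pal), rep(FALSE, n_var - n_pal)))
    ea <- oa <- character(n_var)
    pal_idx <- sample.int(nrow(PAL_PAIRS), n_pal, replace = TRUE)
    np_idx <- sample.int(nrow(NONPAL_PAIRS), n_var - n_pal, replace = TRUE)
    ea[is_pal] <- PAL_PAIRS[pal_idx, 1]
    oa[is_pal] <- PAL_PAIRS[pal_idx, 2]
    ea[!is_pal] <- NONPAL_PAIRS[np_idx, 1]
    oa[!is_pal] <- NONPAL_PAIRS[np_idx, 2]

    theta_total <- cf$theta_dir + cf$kappa * cf$theta_M
    beta_exp_true <- gamma
    beta_med_true <- cf$kappa * gamma + delta
    beta_out_true <- theta_total * gamma + cf$theta_M * delta + eta + alpha

    exposure <- sim_trait_table(rsid, chrom, pos, ea, oa, maf,
                                beta_exp_true, cf$n_exp, cf$noise_scale,
                                "exposure")
    mediator <- sim_trait_table(rsid, chrom, pos, ea, oa, maf,
                                beta_med_true, cf$n_med, cf$noise_scale,
                                "mediator")
    outcome <- sim_trait_table(rsid, chrom, pos, ea, oa, maf,
                               beta_out_true, cf$n_out, cf$noise_scale,
                               "outcome")
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = list(gamma = gamma, delta = delta, eta = eta, alpha = alpha,
                      maf = maf,
                      theta_total = theta_total, kappa = cf$kappa,
                      theta_M = cf$theta_M, theta_dir = cf$theta_dir,
                      proportion_true = if (theta_total != 0)
                        cf$kappa * cf$theta_M / theta_total else NA_real_))
  })
}

#' Simulate block-diagonal LD over the chain's variants
#'
#' Builds an r-squared matrix in which consecutive variants form blocks of
#' `block_size` with pairwise r-squared `within_r2` inside a block and 0
#' between blocks, together with a position table that places each block
#' within a single clumping window (1 kb spacing within blocks, blocks
#' 20 Mb apart along chromosomes 1-22). Apply the positions to simulated
#' tables with [set_variant_positions()] before clumping against this LD.
#'
#' @param config a [chain_sim_config()] (supplies the variant set).
#' @param block_size variants per block (>= 1).
#' @param within_r2 r-squared between distinct variants of a block, in
#'   \[0, 1\].
#' @return list with `ld` (an `ld_info` matrix) and `positions`
#'   (data.frame `rsid, chrom, pos`).
#' @export
simulate_ld_blocks <- function(config, block_size = 1, within_r2 = 0.9) {
  stopifnot(inherits(config, "chain_sim_config"),
            block_size >= 1, within_r2 >= 0, within_r2 <= 1)
  n_var <- config$L + config$n_med_loci + config$n_out_loci
  rsid <- paste0("rs", seq_len(n_var))
  block <- ceiling(seq_len(n_var) / block_size)
  r2 <- outer(block, block, function(a, b) ifelse(a == b, within_r2, 0))
  diag(r2) <- 1
  dimnames(r2) <- list(rsid, rsid)
  n_block <- max(block)
  block_chrom <- as.character(rep_len(1:22, n_block))
  block_start <- 1e6 + 2e7 * (ceiling(seq_len(n_block) / 22) - 1)
  within <- stats::ave(seq_len(n_var), block, FUN = seq_along)
  positions <- data.frame(rsid = rsid,
                          chrom = block_chrom[block],
                          pos = block_start[block] + 1000 * (within - 1),
                          stringsAsFactors = FALSE)
  list(ld = ld_matrix(r2), positions = positions)
}

#' @rdname simulate_ld_blocks
#' @param stats a [sumstats] object whose `chrom`/`pos` should be replaced.
#' @param positions data.frame `rsid, chrom, pos` covering all variants.
#' @export
set_variant_positions <- function(stats, positions) {
  stopifnot(inherits(stats, "sumstats"))
  idx <- match(stats$rsid, positions$rsid)
  if (anyNA(idx)) stopf("positions table lacks %d variant(s)", sum(is.na(idx)))
  stats$chrom <- positions$chrom[idx]
  stats$pos <- positions$pos[idx]
  stats
}

#' Write one simulated chain to disk
#'
#' Writes the three summary-statistics TSVs, an optional LD matrix TSV and
#' a truth table under `dir` - the on-disk layout consumed by the analysis
#' drivers.
#'
#' @param sim result of [simulate_chain()].
#' @param dir output directory (created if needed).
#' @param ld optional `ld_info` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_chain <- function(sim, dir, ld = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(ld)) write_ld_info(ld, file.path(dir, "ld.tsv"))
  truth <- sim$truth
  scalars <- truth[c("theta_total", "kappa", "theta_M", "theta_dir",
                     "proportion_true")]
  writeLines(paste(names(scalars), unlist(scalars), sep = "\t"),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}
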