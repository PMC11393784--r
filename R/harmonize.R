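#' Harmonize exposure and outcome associations onto a common allele frame
#'
#' Inner-joins exposure and outcome tables on rsid and re-expresses every
#' outcome association relative to the exposure's effect allele. For each
#' shared variant:
#'
#' * same allele pair, same orientation: kept unchanged;
#' * same pair, swapped orientation: outcome beta sign flipped and
#'   `eaf_out` replaced by `1 - eaf_out`;
#' * pair reported on the complementary strand (e.g. A/G vs T/C): alleles
#'   re-complemented, then treated as above;
#' * palindromic pair (A/T or G/C, where complementing equals swapping):
#'   orientation is resolved by comparing allele frequencies, provided both
#'   `eaf` values are present and lie outside `palindrome_eaf_band`;
#'   otherwise the variant is dropped as ambiguous;
#' * any other allele configuration: dropped as incompatible.
#'
#' For palindromic variants the label-based orientation is taken at face
#' value and then toggled when the two frequencies disagree about which
#' allele is the minor one; frequencies inside the band are too close to
#' 0.5 for that comparison to be trustworthy.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param palindrome_eaf_band numeric length-2: open interval around 0.5
#'   within which a palindromic variant's frequency is considered
#'   uninformative (default `c(0.42, 0.58)`).
#' @return A `harmonized_pairs` data.frame with columns `rsid, chrom, pos,
#'   effect_allele, other_allele, beta_exp, se_exp, eaf_exp, pval_exp,
#'   beta_out, se_out, eaf_out, action` (`action` is `"unchanged"` or
#'   `"flipped"` for surviving rows). The full per-variant action report,
#'   including `dropped_palindromic` and `dropped_incompatible` rows, is
#'   attached as attribute `"report"` and returned by
#'   [harmonization_report()].
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  band <- sort(palindrome_eaf_band)
  stopifnot(length(band) == 2, band[1] > 0, band[2] < 1)

  shared <- intersect(exposure$rsid, outcome$rsid)
  n_only_exp <- length(setdiff(exposure$rsid, shared))
  if (n_only_exp > 0) {
    ts_log("harmonize: %d exposure variant(s) absent from outcome, dropped", n_only_exp)
  }
  if (length(shared) == 0L) stopf("harmonize: no shared variants between tables")

  ex <- as.data.frame(exposure)[match(shared, exposure$rsid), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$rsid), ]

  e1 <- ex$effect_allele; o1 <- ex$other_allele
  e2 <- ou$effect_allele; o2 <- ou$other_allele
  pal <- is_palindromic(e1, o1)

  same <- e2 == e1 & o2 == o1
  swapped <- e2 == o1 & o2 == e1
  comp_same <- complement_alleles(e2) == e1 & complement_alleles(o2) == o1
  comp_swapped <- complement_alleles(e2) == o1 & complement_alleles(o2) == e1

  action <- rep("dropped_incompatible", length(shared))
  flip <- rep(NA, length(shared))

  # non-palindromic: allele labels identify orientation, complement is safe
  np <- !pal
  flip[np & (same | comp_same)] <- FALSE
  flip[np & !(same | comp_same) & (swapped | comp_swapped)] <- TRUE

  # palindromic: labels alone cannot distinguish strand; same/swapped and
  # complement coincide, so use the frequency signal
  if (any(pal)) {
    idx <- which(pal & (same | swapped))
    f_nominal <- ifelse(same[idx], ou$eaf[idx], 1 - ou$eaf[idx])
    informative <- !is.na(ex$eaf[idx]) & !is.na(ou$eaf[idx]) &
      (ex$eaf[idx] <= band[1] | ex$eaf[idx] >= band[2]) &
      (f_nominal <= band[1] | f_nominal >= band[2])
    freq_disagree <- (ex$eaf[idx] < 0.5) != (f_nominal < 0.5)
    nominal_flip <- swapped[idx]
    flip[idx[informative]] <- xor(nominal_flip, freq_disagree)[informative]
    action[idx[!informative]] <- "dropped_palindromic"
  }

  action[!is.na(flip) & !flip] <- "unchanged"
  action[!is.na(flip) & flip] <- "flipped"

  report <- data.frame(rsid = shared, action = action,
                       stringsAsFactors = FALSE)
  by_action <- table(action)
  ts_log("harmonize: %s", paste(sprintf("%s=%d", names(by_action),
                                        as.integer(by_action)), collapse = ", "))

  keep <- !is.na(flip)
  fl <- flip[keep]
  out <- data.frame(
    rsid = shared[keep],
    chrom = ex$chrom[keep],
    pos = ex$pos[keep],
    effect_allele = e1[keep],
    other_allele = o1[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    eaf_exp = ex$eaf[keep],
    pval_exp = ex$pval[keep],
    beta_out = ifelse(fl, -ou$beta[keep], ou$beta[keep]),
    se_out = ou$se[keep],
    eaf_out = ifelse(fl, 1 - ou$eaf[keep], ou$eaf[keep]),
    pval_out = ou$pval[keep],
    action = action[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("harmonized_pairs", "data.frame"),
            report = report,
            exposure_label = trait_label(exposure),
            outcome_label = trait_label(outcome))
}

#' @rdname harmonize
#' @param pairs a `harmonized_pairs` object.
#' @export
harmonization_report <- function(pairs) attr(pairs, "report")

#' @export
print.harmonized_pairs <- function(x, ...) {
  cat(sprintf("<harmonized_pairs> %s -> %s, %d variants\n",
              attr(x, "exposure_label") %||% "exposure",
              attr(x, "outcome_label") %||% "outcome", nrow(x)))
  NextMethod()
}

#' Rebuild one trait's summary-statistics view of a harmonized set
#'
#' Extracts the exposure or outcome side of a `harmonized_pairs` object as
#' a [sumstats] table on the common allele frame (useful for chaining
#' analyses or re-checking harmonization).
#'
#' @param pairs a `harmonized_pairs` object.
#' @param side `"exposure"` or `"outcome"`.
#' @return A [sumstats] object.
#' @export
pairs_as_sumstats <- function(pairs, side = c("exposure", "outcome")) {
  side <- match.arg(side)
  df <- data.frame(
    rsid = pairs$rsid, chrom = pairs$chrom, pos = pairs$pos,
    effect_allele = pairs$effect_allele, other_allele = pairs$other_allele,
    eaf = if (side == "exposure") pairs$eaf_exp else pairs$eaf_out,
    beta = if (side == "exposure") pairs$beta_exp else pairs$beta_out,
    se = if (side == "exposure") pairs$se_exp else pairs$se_out,
    pval = if (side == "exposure") pairs$pval_exp else pairs$pval_out,
    stringsAsFactors = FALSE
  )
  sumstats(df, trait_label = attr(pairs, paste0(side, "_label")) %||% side)
}
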