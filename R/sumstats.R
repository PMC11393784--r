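#' GWAS summary-statistics tables
#'
#' A `sumstats` object is a validated `data.frame` of per-variant summary
#' associations for one trait, with canonical columns
#' `rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' `beta` is the per-allele effect on the trait: log-odds for binary traits,
#' standard-deviation units for continuous traits, so that downstream causal
#' estimates are reported per SD of the exposure.
#'
#' Validation drops rows that violate the variant-level invariants
#' (`se > 0`, `pval` in (0,1], alleles over A/C/G/T with
#' `effect_allele != other_allele`, `eaf` in \[0,1\] when present) and
#' resolves duplicate rsids by keeping the row with the smallest p-value.
#' Counts of dropped rows are reported on the message stream. Rows with
#' missing `eaf` or `n` are retained: `eaf` is only needed to resolve
#' palindromic variants during harmonization and `n` only for reporting.
#'
#' @param x data.frame with at least `rsid, effect_allele, other_allele,
#'   beta, se, pval`; `chrom, pos, eaf, n` are optional and filled with `NA`.
#' @param trait_label character scalar naming the trait.
#' @param provenance free-text metadata (source, genome build, ...).
#' @return A `sumstats` object (data.frame subclass) with attributes
#'   `trait_label` and `provenance`.
#' @examples
#' ss <- sumstats(data.frame(
#'   rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.1, -0.05),
#'   se = c(0.01, 0.02), pval = c(1e-12, 1e-4)), trait_label = "exposure")
#' nrow(ss)
#' @export
sumstats <- function(x, trait_label = "trait", provenance = "") {
  stopifnot(is.data.frame(x))
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  optional <- c("chrom", "pos", "eaf", "n")
  for (col in optional) if (is.null(x[[col]])) x[[col]] <- NA
  x <- x[, c("rsid", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pval", "n")]
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$pos <- suppressWarnings(as.numeric(x$pos))
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  drop <- list(
    missing_fields = is.na(x$rsid) | !nzchar(x$rsid) |
      is.na(x$beta) | is.na(x$se) | is.na(x$pval),
    bad_allele = !valid_allele(x$effect_allele) | !valid_allele(x$other_allele) |
      x$effect_allele == x$other_allele,
    nonpositive_se = !is.na(x$se) & x$se <= 0,
    bad_pval = !is.na(x$pval) & (x$pval <= 0 | x$pval > 1),
    bad_eaf = !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  )
  bad <- Reduce(`|`, drop)
  bad[is.na(bad)] <- TRUE
  for (reason in names(drop)) {
    k <- sum(drop[[reason]], na.rm = TRUE)
    if (k > 0) ts_log("sumstats[%s]: dropped %d row(s): %s", trait_label, k, reason)
  }
  x <- x[!bad, , drop = FALSE]

  if (anyDuplicated(x$rsid)) {
    # deterministic resolution: keep the smallest p-value per rsid
    ord <- order(x$pval, seq_len(nrow(x)))
    x <- x[ord, , drop = FALSE]
    dup <- duplicated(x$rsid)
    ts_log("sumstats[%s]: dropped %d duplicate rsid row(s), kept smallest p",
           trait_label, sum(dup))
    x <- x[!dup, , drop = FALSE]
    x <- x[order(match(x$rsid, unique(x$rsid))), , drop = FALSE]
  }
  if (nrow(x) == 0L) stopf("sumstats[%s]: no valid rows after validation", trait_label)
  rownames(x) <- NULL
  structure(x, class = c("sumstats", "data.frame"),
            trait_label = trait_label, provenance = provenance)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait: %s, %d variants\n",
              attr(x, "trait_label"), nrow(x)))
  NextMethod()
}

#' @rdname sumstats
#' @param stats a `sumstats` object.
#' @export
trait_label <- function(stats) attr(stats, "trait_label") %||% "trait"

#' Column-name presets for common summary-statistics dialects
#'
#' Returns a named character vector mapping canonical field names to the
#' headers used by a given source dialect, suitable for the `column_map`
#' argument of [read_sumstats()].
#'
#' @param dialect one of `"canonical"`, `"ieu"` (IEU OpenGWAS exports) or
#'   `"gwas_catalog"`.
#' @return named character vector `canonical_field = file_header`.
#' @export
sumstats_column_preset <- function(dialect = c("canonical", "ieu", "gwas_catalog")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    canonical = c(rsid = "rsid", chrom = "chrom", pos = "pos",
                  effect_allele = "effect_allele", other_allele = "other_allele",
                  eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"),
    ieu = c(rsid = "SNP", chrom = "chr", pos = "position",
            effect_allele = "effect_allele", other_allele = "other_allele",
            eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "samplesize"),
    gwas_catalog = c(rsid = "variant_id", chrom = "chromosome", pos = "base_pair_location",
                     effect_allele = "effect_allele", other_allele = "other_allele",
                     eaf = "effect_allele_frequency", beta = "beta",
                     se = "standard_error", pval = "p_value", n = "n"))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated text file, renames columns to the
#' canonical schema via `column_map`, and validates the result (see
#' [sumstats()] for the invariants enforced and the dropped-row log).
#'
#' @param path file path.
#' @param column_map named character vector `canonical_field = file_header`,
#'   e.g. from [sumstats_column_preset()]; `NULL` assumes canonical headers.
#' @param trait_label trait name recorded on the object; defaults to the
#'   file name without extension.
#' @param provenance free-text metadata.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL,
                          provenance = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  map <- column_map %||% sumstats_column_preset("canonical")
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_req <- required[!required %in% names(map)]
  if (length(missing_req)) {
    stopf("column_map lacks required field(s): %s", paste(missing_req, collapse = ", "))
  }
  absent <- map[required][!map[required] %in% names(dt)]
  if (length(absent)) {
    stopf("input lacks mapped column(s): %s", paste(absent, collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(dt)))
  for (field in names(map)) {
    if (map[[field]] %in% names(dt)) out[[field]] <- dt[[map[[field]]]]
  }
  sumstats(out,
           trait_label = trait_label %||% sub("\\.[^.]*$", "", basename(path)),
           provenance = provenance %||% path)
}

#' Write a summary-statistics table as canonical TSV
#'
#' Writes the canonical header order
#' `rsid, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`
#' at full numeric precision, so that `read_sumstats(write_sumstats(x))`
#' is the identity on every field.
#'
#' @param stats a [sumstats] object (non-empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats) == 0L) stopf("refusing to write empty summary statistics")
  df <- as.data.frame(stats)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Instrument-strength F-statistic
#'
#' The single-variant instrument-strength statistic `beta^2 / se^2`
#' (the squared Wald z on the exposure association). Values below 10
#' conventionally flag weak instruments.
#'
#' @param beta numeric vector of effect estimates (or a [sumstats] object,
#'   in which case `se` is taken from it).
#' @param se numeric vector of standard errors, all `> 0`.
#' @return numeric vector of F-statistics, `>= 0`.
#' @examples
#' compute_f_statistic(0.1, 0.01)   # 100
#' compute_f_statistic(-0.05, 0.025) # 4: sign-invariant
#' @export
compute_f_statistic <- function(beta, se) {
  if (inherits(beta, "sumstats")) {
    se <- beta$se
    beta <- beta$beta
  }
  if (any(!is.finite(se)) || any(se <= 0)) stopf("se must be positive")
  (beta / se)^2
}
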