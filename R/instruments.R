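#' Select genome-wide-significant variants
#'
#' Keeps exactly the variants with `pval < threshold`, preserving the input
#' order. The conventional forward threshold is `5e-8`; relaxed presets
#' `5e-7` and `5e-6` are used when an exposure yields too few instruments or
#' for reverse-direction analyses.
#'
#' @param stats a [sumstats] object.
#' @param threshold p-value threshold in (0, 1\].
#' @return A [sumstats] object (possibly empty selection is flagged on the
#'   message stream but not an error).
#' @export
select_by_pvalue <- function(stats, threshold = 5e-8) {
  stopifnot(inherits(stats, "sumstats"))
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold > 1) {
    stopf("threshold must be a number in (0, 1]")
  }
  keep <- stats$pval < threshold
  if (!any(keep)) {
    ts_log("select_by_pvalue[%s]: no variant passes p < %g", trait_label(stats), threshold)
  }
  subset_sumstats(stats, keep)
}

#' Drop weak instruments by F-statistic
#'
#' Retains variants whose instrument-strength F-statistic
#' ([compute_f_statistic]) is at least `f_min`; variants strictly below the
#' cutoff are excluded, so `F == f_min` is kept.
#'
#' @param stats a [sumstats] object.
#' @param f_min minimum F-statistic, `>= 0` (default 10).
#' @return A [sumstats] object.
#' @export
filter_weak_instruments <- function(stats, f_min = 10) {
  stopifnot(inherits(stats, "sumstats"), is_scalar_number(f_min), f_min >= 0)
  f <- compute_f_statistic(stats$beta, stats$se)
  dropped <- sum(f < f_min)
  if (dropped > 0) {
    ts_log("filter_weak_instruments[%s]: dropped %d variant(s) with F < %g",
           trait_label(stats), dropped, f_min)
  }
  subset_sumstats(stats, f >= f_min)
}

# Subset preserving class and attributes.
subset_sumstats <- function(stats, keep) {
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            trait_label = attr(stats, "trait_label"),
            provenance = attr(stats, "provenance"))
}

#' Linkage-disequilibrium information for a variant set
#'
#' Clumping needs pairwise r-squared between candidate instruments. Rather
#' than querying a reference panel, the package takes LD as an explicit
#' input: either a symmetric r-squared matrix with unit diagonal
#' (`ld_matrix()`) or a declaration that all variants are pairwise
#' independent (`ld_independent()`), under which clumping removes nothing.
#'
#' @param r2 square numeric matrix with rsid dimnames, values in \[0,1\],
#'   symmetric with unit diagonal.
#' @return An `ld_info` object.
#' @export
ld_matrix <- function(r2) {
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2))
  if (is.null(rownames(r2)) || is.null(colnames(r2))) {
    stopf("r2 matrix needs rsid dimnames")
  }
  if (!isTRUE(all.equal(r2, t(r2), tolerance = 1e-8))) stopf("r2 matrix must be symmetric")
  if (any(r2 < 0 | r2 > 1)) stopf("r2 values must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stopf("r2 diagonal must be 1")
  structure(list(type = "matrix", r2 = r2), class = "ld_info")
}

#' @rdname ld_matrix
#' @export
ld_independent <- function() {
  structure(list(type = "independent"), class = "ld_info")
}

#' @export
print.ld_info <- function(x, ...) {
  if (x$type == "independent") {
    cat("<ld_info> pairwise independence declared\n")
  } else {
    cat(sprintf("<ld_info> r2 matrix over %d variants\n", nrow(x$r2)))
  }
  invisible(x)
}

#' @rdname ld_matrix
#' @param path TSV file: square r-squared matrix with rsid row and column
#'   names, or the literal single token `independent`.
#' @export
read_ld_info <- function(path) {
  first <- readLines(path, n = 1L)
  if (identical(trimws(first), "independent")) return(ld_independent())
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  ld_matrix(m)
}

#' @rdname ld_matrix
#' @param ld an `ld_info` object to write.
#' @export
write_ld_info <- function(ld, path) {
  stopifnot(inherits(ld, "ld_info"))
  if (ld$type == "independent") {
    writeLines("independent", path)
  } else {
    df <- data.frame(rsid = rownames(ld$r2), ld$r2, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

r2_lookup <- function(ld, rsids) {
  if (ld$type == "independent") {
    m <- diag(length(rsids))
    dimnames(m) <- list(rsids, rsids)
    return(m)
  }
  missing <- setdiff(rsids, rownames(ld$r2))
  if (length(missing)) {
    stopf("LD matrix lacks %d required variant(s), e.g. %s",
          length(missing), missing[1])
  }
  ld$r2[rsids, rsids, drop = FALSE]
}

#' Greedy LD clumping
#'
#' Iteratively keeps the remaining variant with the smallest p-value and
#' removes every other remaining variant on the same chromosome within
#' `window_kb` kilobases whose r-squared with it exceeds `r2_max`. With the
#' conventional settings (`r2_max = 0.001`, `window_kb = 10000`) the
#' retained instruments are approximately independent. Output is sorted by
#' chromosome and position.
#'
#' @param stats a [sumstats] object with `chrom` and `pos` available.
#' @param ld an `ld_info` object covering all variants (or declaring
#'   independence).
#' @param r2_max r-squared above which two variants are clumped together.
#' @param window_kb window in kilobases around the index variant.
#' @return A [sumstats] object, a subset of `stats`.
#' @export
ld_clump <- function(stats, ld = ld_independent(), r2_max = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(stats, "sumstats"), inherits(ld, "ld_info"))
  if (nrow(stats) == 0L) return(stats)
  if (ld$type == "matrix" && any(is.na(stats$pos) | is.na(stats$chrom))) {
    stopf("ld_clump requires chrom and pos for all variants")
  }
  r2 <- r2_lookup(ld, stats$rsid)
  remaining <- seq_len(nrow(stats))
  kept <- integer(0)
  while (length(remaining)) {
    idx <- remaining[which.min(stats$pval[remaining])]
    kept <- c(kept, idx)
    same_chr <- !is.na(stats$chrom[remaining]) &
      stats$chrom[remaining] == stats$chrom[idx]
    near <- same_chr & abs(stats$pos[remaining] - stats$pos[idx]) <= window_kb * 1000
    near[is.na(near)] <- FALSE
    linked <- near & r2[stats$rsid[remaining], stats$rsid[idx]] > r2_max
    remaining <- remaining[!(linked | remaining == idx)]
  }
  out <- subset_sumstats(stats, sort(kept))
  ord <- order(out$chrom, out$pos, na.last = TRUE)
  subset_sumstats(out, ord)
}
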