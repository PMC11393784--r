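# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
ts_log <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

# 95% two-sided normal quantile used for every Wald-type interval.
Z95 <- stats::qnorm(0.975)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Watson-Crick complement of allele strings (vectorized, A/C/G/T only).
complement_alleles <- function(a) chartr("ACGT", "TGCA", a)

# A/T and G/C pairs: the allele pair equals its own complement, so strand
# cannot be inferred from the labels alone.
is_palindromic <- function(ea, oa) complement_alleles(ea) == oa

valid_allele <- function(a) {
  !is.na(a) & nzchar(a) & !grepl("[^ACGT]", a)
}
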