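# Fixture builders and independent oracles used across the suite.

make_sumstats <- function(rsid, beta, se, pval,
                          effect_allele = rep("A", length(rsid)),
                          other_allele = rep("G", length(rsid)),
                          chrom = rep("1", length(rsid)),
                          pos = seq_along(rsid) * 1e6,
                          eaf = rep(0.3, length(rsid)),
                          n = rep(1e5, length(rsid)),
                          trait = "trait") {
  suppressMessages(sumstats(data.frame(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE), trait_label = trait))
}

# Hand-built harmonized pairs, bypassing harmonize(), for estimator tests.
make_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                       rsid = paste0("rs", seq_along(beta_exp))) {
  structure(data.frame(
    rsid = rsid, chrom = "1", pos = seq_along(beta_exp) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = 0.3, pval_exp = 1e-10,
    beta_out = beta_out, se_out = se_out, eaf_out = 0.3, pval_out = 0.01,
    action = "unchanged", stringsAsFactors = FALSE),
    class = c("harmonized_pairs", "data.frame"))
}

# The 3-variant fixture used for the closed-form IVW / Q oracles.
ivw_fixture <- function() {
  make_pairs(beta_exp = c(0.1, 0.2, 0.15),
             se_exp = c(0.01, 0.01, 0.01),
             beta_out = c(0.02, 0.05, 0.03),
             se_out = c(0.005, 0.01, 0.008))
}

# Independent closed-form IVW oracle (weighted mean of ratios).
oracle_ivw <- function(beta_exp, se_out, beta_out) {
  r <- beta_out / beta_exp
  w <- (beta_exp / se_out)^2
  b <- sum(w * r) / sum(w)
  list(beta = b, se = 1 / sqrt(sum(w)), Q = sum(w * (r - b)^2))
}

# Independent normal-equations oracle for the weighted Egger regression.
oracle_egger <- function(beta_exp, beta_out, se_out) {
  s <- sign(beta_exp); s[s == 0] <- 1
  x <- beta_exp * s; y <- beta_out * s
  w <- 1 / se_out^2
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% coef
  df <- length(y) - 2
  sigma2 <- sum(w * resid^2) / df
  se <- unname(sqrt(diag(solve(XtWX)) * sigma2))
  list(intercept = unname(coef[1]), slope = unname(coef[2]),
       intercept_se = se[1], slope_se = se[2])
}

weighted_median_point_for_test <- function(pairs) {
  rt <- wald_ratios(pairs)
  twostepmr:::weighted_median_point(rt$ratio, rt$weight)
}

# Brute-force greedy clumping over a small instance: re-derives the kept
# set directly from the rule definition without the package's loop.
oracle_clump <- function(pval, chrom, pos, r2, window_kb, r2_max) {
  remaining <- seq_along(pval)
  kept <- integer(0)
  while (length(remaining)) {
    i <- remaining[order(pval[remaining])][1]
    kept <- c(kept, i)
    drop <- vapply(remaining, function(j) {
      j == i || (chrom[j] == chrom[i] &&
                   abs(pos[j] - pos[i]) <= window_kb * 1000 &&
                   r2[i, j] > r2_max)
    }, logical(1))
    remaining <- remaining[!drop]
  }
  sort(kept)
}
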