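# Independent brute-force oracles, deliberately coded apart from the package
# implementations they check.

# textbook Pearson chi-squared: sum over cells of (O - E)^2 / E
oracle_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  total <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / total
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# exhaustive threshold scan for the Youden-J operating point; candidate set is
# every real number strictly between adjacent order statistics plus the two
# outer sentinels, represented by scanning thresholds just below/above each
# observed value
oracle_best_youden <- function(values, labels) {
  probes <- sort(unique(c(values - 1e-9, values + 1e-9,
                          min(values) - 1, max(values) + 1)))
  best <- -Inf
  for (th in probes) {
    sens <- sum(values[labels] > th) / sum(labels)
    spec <- sum(values[!labels] <= th) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# restricted argmax over the four intrinsic TNBC subtypes
oracle_tnbc4_label <- function(scores) {
  intr <- scores[c("BL1", "BL2", "M", "LAR")]
  names(intr)[order(-intr, names(intr))][1L]
}

# vote rule by direct enumeration of exceedance pattern
oracle_vote <- function(rq, cutoffs, min_positive) {
  n <- 0L
  for (g in names(cutoffs)) if (rq[[g]] > cutoffs[[g]]) n <- n + 1L
  if (n >= min_positive) "MABC_LAR" else "negative"
}
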