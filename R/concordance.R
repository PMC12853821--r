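#' Percentage with one-decimal half-up rounding
#'
#' All printed proportions in the package use half-up rounding to one decimal
#' (e.g. 56/83 -> 67.5, 15/16 -> 93.8), matching the convention of published
#' count ratios.
#'
#' @param k numerator count, 0 <= k <= n.
#' @param n denominator count, > 0.
#' @return percentage rounded half-up to one decimal.
#' @export
proportion_pct <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop("k and n must be scalar counts", call. = FALSE)
  }
  if (n <= 0) stop("denominator must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  round_half_up(100 * k / n, 1L)
}

#' Overlap partition between two subtype classifications
#'
#' Partitions a denominator population (e.g. the TNBC subset) by joint
#' positivity under two schemes: `mabc_lar` (positive under both),
#' `mabc_nonlar` (MABC-side only), `lar_nonmabc` (LAR-side only), `neither`.
#' The four sets are pairwise disjoint and their union is the denominator.
#'
#' @param calls_mabc `subtype_calls` for the MABC-defining scheme (e.g. CIT6).
#' @param positive_mabc label counted as positive on that side (e.g. "mApo").
#' @param calls_lar `subtype_calls` for the LAR-defining scheme (e.g. TNBC4).
#' @param positive_lar label counted as positive on that side (e.g. "LAR").
#' @param denominator character vector of sample ids forming the population.
#' @param restricted_to free-text description of the denominator.
#' @return object of class `overlap_groups`: the four id sets, their counts,
#'   and `restricted_to`.
#' @export
compute_overlap <- function(calls_mabc, positive_mabc, calls_lar, positive_lar,
                            denominator, restricted_to = "denominator") {
  denominator <- unique(as.character(denominator))
  for (nm in c("calls_mabc", "calls_lar")) {
    calls <- get(nm)
    miss <- setdiff(denominator, calls$sample_id)
    if (length(miss)) stop(nm, " missing denominator sample(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
  }
  a_pos <- intersect(denominator,
                     calls_mabc$sample_id[calls_mabc$label == positive_mabc])
  b_pos <- intersect(denominator,
                     calls_lar$sample_id[calls_lar$label == positive_lar])
  out <- list(mabc_lar = intersect(a_pos, b_pos),
              mabc_nonlar = setdiff(a_pos, b_pos),
              lar_nonmabc = setdiff(b_pos, a_pos),
              neither = setdiff(denominator, union(a_pos, b_pos)),
              restricted_to = restricted_to)
  out$counts <- vapply(out[1:4], length, integer(1L))
  class(out) <- "overlap_groups"
  out
}

#' @export
print.overlap_groups <- function(x, ...) {
  cat(sprintf("<overlap_groups> (%s): MABC-LAR %d | MABC-nonLAR %d | LAR-nonMABC %d | neither %d\n",
              x$restricted_to, x$counts[["mabc_lar"]], x$counts[["mabc_nonlar"]],
              x$counts[["lar_nonmabc"]], x$counts[["neither"]]))
  invisible(x)
}

#' Cross-tabulate two call tables
#'
#' Contingency table of labels under two schemes over the same sample
#' universe, plus a long-format (Sankey-ready) table of flow counts.
#'
#' @param calls_a,calls_b `subtype_calls` covering the same samples.
#' @return list with `table` (labels_a x labels_b counts) and `long`
#'   (data.frame label_a, label_b, n with n > 0).
#' @export
crosstab <- function(calls_a, calls_b) {
  if (!setequal(calls_a$sample_id, calls_b$sample_id)) {
    stop("call tables cover different sample universes", call. = FALSE)
  }
  b <- calls_b$label[match(calls_a$sample_id, calls_b$sample_id)]
  tab <- table(label_a = calls_a$label, label_b = b)
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(long) <- c("label_a", "label_b", "n")
  list(table = unclass(tab), long = long[long$n > 0, , drop = FALSE])
}

#' Pearson chi-squared test on a contingency table
#'
#' Thin wrapper around the standard chi-squared machinery; Yates continuity
#' correction is applied by default for 2x2 tables (and has no effect on
#' larger tables).  A table with a zero row or column marginal is rejected
#' rather than yielding NaN.
#'
#' @param table matrix of non-negative counts (2x2 or r x c).
#' @param continuity_correction apply Yates correction for 2x2 (default TRUE).
#' @return list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi2_proportions <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be non-negative",
                                           call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row/column marginal", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = continuity_correction))
  list(statistic = unname(res$statistic),
       p_value = unname(res$p.value),
       df = unname(res$parameter),
       expected = res$expected)
}

#' Confusion-matrix diagnostics against a gold-standard classification
#'
#' Samples the gold standard could not classify (label UNCLASSIFIED) are
#' excluded before counting; a predicted UNCLASSIFIED counts as negative.
#' Sensitivity/specificity are reported as half-up one-decimal percentages;
#' when a margin is empty (no gold positives or no gold negatives) the
#' corresponding rate is `NA` (explicitly undefined, never 0).
#'
#' @param pred `subtype_calls` of predictions.
#' @param gold `subtype_calls` of the gold standard (same sample universe or a
#'   superset of it in `pred`).
#' @param positive_pred predicted label counted positive.
#' @param positive_gold gold label counted positive.
#' @return object of class `confusion_summary` with tp/fp/tn/fn,
#'   `sensitivity_pct`, `specificity_pct`, `excluded` (gold-unclassifiable ids).
#' @export
evaluate_confusion <- function(pred, gold, positive_pred, positive_gold) {
  miss <- setdiff(gold$sample_id, pred$sample_id)
  if (length(miss)) stop("prediction missing gold sample(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "),
                         call. = FALSE)
  excluded <- gold$sample_id[gold$label == "UNCLASSIFIED"]
  counted <- setdiff(gold$sample_id, excluded)
  gpos <- gold$label[match(counted, gold$sample_id)] == positive_gold
  ppos <- pred$label[match(counted, pred$sample_id)] == positive_pred
  tp <- sum(gpos & ppos); fn <- sum(gpos & !ppos)
  fp <- sum(!gpos & ppos); tn <- sum(!gpos & !ppos)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity_pct = if (tp + fn > 0) proportion_pct(tp, tp + fn) else NA_real_,
              specificity_pct = if (tn + fp > 0) proportion_pct(tn, tn + fp) else NA_real_,
              excluded = excluded)
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> tp=%d fp=%d tn=%d fn=%d | sensitivity %s%% specificity %s%% | %d excluded\n",
              x$tp, x$fp, x$tn, x$fn,
              format(x$sensitivity_pct), format(x$specificity_pct),
              length(x$excluded)))
  invisible(x)
}
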