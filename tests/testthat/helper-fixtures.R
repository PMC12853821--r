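# In-code fixtures shared across test files.

toy_expr <- function(values, genes, samples, platform = "rnaseq") {
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  attr(m, "platform_tag") <- platform
  m
}

# label-only call table under an ad hoc scheme
label_calls <- function(labels, scheme = "GOLD") {
  subtype_calls(names(labels), scheme, unname(labels))
}

# pred/gold call pair realizing given confusion counts (plus gold-unclassifiable)
confusion_fixture <- function(tp, fn, fp, tn, n_excluded = 0L,
                              positive = "MABC") {
  n <- tp + fn + fp + tn + n_excluded
  ids <- sprintf("P%03d", seq_len(n))
  gold <- rep(c(positive, positive, "negative", "negative", "UNCLASSIFIED"),
              c(tp, fn, fp, tn, n_excluded))
  pred <- rep(c(positive, "negative", positive, "negative", "negative"),
              c(tp, fn, fp, tn, n_excluded))
  list(pred = label_calls(stats::setNames(pred, ids), "PRED"),
       gold = label_calls(stats::setNames(gold, ids), "GOLD"))
}

# two binary call tables over a common denominator with planted joint counts
overlap_fixture <- function(n_both, n_a_only, n_b_only, n_neither,
                            pos_a = "mApo", pos_b = "LAR") {
  n <- n_both + n_a_only + n_b_only + n_neither
  ids <- sprintf("S%03d", seq_len(n))
  a <- rep(c(pos_a, pos_a, "other", "other"),
           c(n_both, n_a_only, n_b_only, n_neither))
  b <- rep(c(pos_b, "other", pos_b, "other"),
           c(n_both, n_a_only, n_b_only, n_neither))
  list(calls_a = label_calls(stats::setNames(a, ids), "A"),
       calls_b = label_calls(stats::setNames(b, ids), "B"),
       denominator = ids)
}

# CT table builder: reps is a named list gene -> numeric vector of replicate CTs,
# replicated for each sample in `samples`
ct_fixture <- function(samples, reps, reference_gene = "RPL37A") {
  rows <- do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(names(reps), function(g) {
      data.frame(sample_id = s, gene = g,
                 replicate = seq_along(reps[[g]]), ct = reps[[g]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "reference_gene") <- reference_gene
  rows
}

# small cohort config used by recovery tests (per-class n overridable)
test_config <- function(n = c(MABC_core = 20, MABC_HER2 = 20, LAR_immune = 20,
                              MABC_stromal = 20, basal = 20,
                              luminalC_like = 20), ...) {
  cohort_config(n_per_class = n, ...)
}
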