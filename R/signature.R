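#' Relative quantities from CT measurements (2^-dCT)
#'
#' Replicate CTs are averaged per (sample, gene); the relative quantity is
#' rq = 2^-(meanCT_gene - meanCT_reference).  A gene with every replicate
#' Undetermined is treated as unexpressed: rq = 0 by default, or computed at a
#' substituted maximum CT (`undetermined = "max_ct"`).  An Undetermined
#' reference gene is an error for that sample — no quantity is defined.
#' Replicate spread (max - min CT) above `spread_flag_cycles` is flagged but
#' not rejected.  rq is invariant to adding a constant to every CT of a
#' sample (a global pipetting/loading shift cancels in the difference).
#'
#' @param ct CT table from [read_ct_table()] (or equivalent data.frame with
#'   attribute `reference_gene`).
#' @param undetermined handling of all-Undetermined genes: "zero" (default) or
#'   "max_ct".
#' @param max_ct CT substituted under `undetermined = "max_ct"` (default 40).
#' @param spread_flag_cycles duplicate-discordance flag threshold in cycles
#'   (default 0.5).
#' @return data.frame with columns sample_id, gene, rq, replicate_spread,
#'   flagged (reference gene excluded).
#' @export
relative_quantity <- function(ct, undetermined = c("zero", "max_ct"),
                              max_ct = 40, spread_flag_cycles = 0.5) {
  undetermined <- match.arg(undetermined)
  validate_ct_table(ct)
  ref <- attr(ct, "reference_gene") %||% "RPL37A"
  key <- interaction(ct$sample_id, ct$gene, drop = TRUE)
  mean_ct <- tapply(ct$ct, key, function(v) mean(v[!is.na(v)]))
  spread <- tapply(ct$ct, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L) max(v) - min(v) else NA_real_
  })
  info <- unique(ct[, c("sample_id", "gene")])
  k <- interaction(info$sample_id, info$gene, drop = TRUE)
  info$mean_ct <- as.numeric(mean_ct[as.character(k)])
  info$spread <- as.numeric(spread[as.character(k)])

  ref_rows <- info[info$gene == ref, ]
  bad_ref <- ref_rows$sample_id[is.nan(ref_rows$mean_ct)]
  if (length(bad_ref)) {
    stop("reference gene ", ref, " undetermined for sample(s): ",
         paste(bad_ref, collapse = ", "), call. = FALSE)
  }
  ref_ct <- stats::setNames(ref_rows$mean_ct, ref_rows$sample_id)

  tgt <- info[info$gene != ref, , drop = FALSE]
  all_undet <- is.nan(tgt$mean_ct)
  if (undetermined == "max_ct") tgt$mean_ct[all_undet] <- max_ct
  rq <- 2^(-(tgt$mean_ct - ref_ct[tgt$sample_id]))
  if (undetermined == "zero") rq[all_undet] <- 0
  out <- data.frame(sample_id = tgt$sample_id,
                    gene = tgt$gene,
                    rq = unname(rq),
                    replicate_spread = tgt$spread,
                    stringsAsFactors = FALSE)
  out$flagged <- !is.na(out$replicate_spread) &
    out$replicate_spread > spread_flag_cycles
  rownames(out) <- NULL
  out
}

#' ROC-based cut-off selection (Youden J)
#'
#' Candidate cut-offs are the midpoints between consecutive sorted unique
#' values, plus a below-minimum and an above-maximum sentinel; positivity is
#' value > cutoff (strict).  The returned cut-off maximises Youden
#' J = sensitivity + specificity - 1; among ties the largest cut-off wins
#' (favouring specificity).
#'
#' @param values numeric per-sample quantities for one gene.
#' @param labels logical (TRUE = gold positive) or a factor/character vector
#'   with `positive` naming the positive level.
#' @param positive positive label when `labels` is not logical.
#' @return list with `cutoff`, `sensitivity`, `specificity` (fractions in
#'   0..1) and `youden_j`.
#' @export
select_cutoff_roc <- function(values, labels, positive = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("supply 'positive' for non-logical labels",
                                call. = FALSE)
    labels <- labels == positive
  }
  if (length(values) != length(labels) || anyNA(values) || anyNA(labels)) {
    stop("values/labels must be complete and of equal length", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present",
                                       call. = FALSE)
  if (n_pos < 3L || n_neg < 3L) stop("need >= 3 samples per class", call. = FALSE)
  u <- sort(unique(values))
  candidates <- c(u[1L] - 1, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
                  u[length(u)] + 1)
  sens <- vapply(candidates, function(cc) mean(values[labels] > cc), numeric(1L))
  spec <- vapply(candidates, function(cc) mean(values[!labels] <= cc), numeric(1L))
  j <- sens + spec - 1
  best_j <- max(j)
  best <- max(candidates[j >= best_j - 1e-12])  # tie -> largest cutoff
  i <- which(candidates == best)[1L]
  list(cutoff = best, sensitivity = sens[i], specificity = spec[i],
       youden_j = j[i])
}

#' The RT-qPCR four-gene vote classifier model
#'
#' Per-gene relative-quantity cut-offs plus a vote threshold: a sample is
#' called MABC/LAR when at least `min_positive` of the target genes strictly
#' exceed their cut-offs.  Defaults are the validated assay values
#' (AR > 5.0, FOXA1 > 24, SPDEF > 3, TFF3 > 1.0; >= 3 of 4).
#'
#' @param cutoffs named numeric vector of strictly positive rq cut-offs.
#' @param min_positive vote threshold, 1 <= min_positive <= number of genes.
#' @param reference_gene reference gene of the dCT normalisation.
#' @return object of class `qpcr_signature_model`.
#' @export
qpcr_signature_model <- function(cutoffs = c(AR = 5.0, FOXA1 = 24, SPDEF = 3,
                                             TFF3 = 1.0),
                                 min_positive = 3L,
                                 reference_gene = "RPL37A") {
  if (is.null(names(cutoffs)) || any(names(cutoffs) == "")) {
    stop("cutoffs must be named by gene", call. = FALSE)
  }
  names(cutoffs) <- toupper(names(cutoffs))
  if (any(cutoffs <= 0)) stop("cutoffs must be strictly positive", call. = FALSE)
  min_positive <- as.integer(min_positive)
  if (min_positive < 1L || min_positive > length(cutoffs)) {
    stop("min_positive must lie in 1..", length(cutoffs), call. = FALSE)
  }
  structure(list(cutoffs = cutoffs, min_positive = min_positive,
                 reference_gene = toupper(reference_gene)),
            class = "qpcr_signature_model")
}

#' Apply the qPCR vote classifier
#'
#' A sample is MABC_LAR when at least `min_positive` of the model's genes have
#' rq strictly above their cut-offs; boundary values (rq equal to the cut-off)
#' do not count.  Scores store the exceedance count for MABC_LAR against the
#' vote threshold minus one half for negative, so the label always attains
#' the score maximum; per-gene margins (rq - cutoff) are kept in
#' `margin_<gene>` columns.
#'
#' @param rqs output of [relative_quantity()] (columns sample_id, gene, rq).
#' @param model a [qpcr_signature_model()].
#' @return `subtype_calls` under scheme QPCR4 with labels MABC_LAR/negative.
#' @export
classify_qpcr <- function(rqs, model = qpcr_signature_model()) {
  stopifnot(inherits(model, "qpcr_signature_model"))
  genes <- names(model$cutoffs)
  samples <- unique(rqs$sample_id)
  rqm <- matrix(NA_real_, length(samples), length(genes),
                dimnames = list(samples, genes))
  hit <- rqs$gene %in% genes
  rqm[cbind(match(rqs$sample_id[hit], samples), match(rqs$gene[hit], genes))] <-
    rqs$rq[hit]
  if (anyNA(rqm)) {
    bad <- which(is.na(rqm), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing relative quantity for gene '%s' in sample '%s'",
                 genes[bad[2L]], samples[bad[1L]]), call. = FALSE)
  }
  exceed <- sweep(rqm, 2L, model$cutoffs, `>`)
  n_exceed <- rowSums(exceed)
  labels <- ifelse(n_exceed >= model$min_positive, "MABC_LAR", "negative")
  scores <- cbind(MABC_LAR = n_exceed,
                  negative = rep(model$min_positive - 0.5, length(samples)))
  calls <- subtype_calls(samples, "QPCR4", labels, scores)
  margins <- sweep(rqm, 2L, model$cutoffs)
  for (j in seq_along(genes)) calls[[paste0("margin_", genes[j])]] <- margins[, j]
  calls
}

#' Fit qPCR cut-offs from a labelled discovery cohort
#'
#' Runs [select_cutoff_roc()] per signature gene against a gold-standard
#' positive/negative labelling and assembles the resulting
#' [qpcr_signature_model()].
#'
#' @param rqs output of [relative_quantity()].
#' @param gold_positive named logical vector sample id -> gold MABC/LAR truth.
#' @param genes signature genes (default AR, FOXA1, SPDEF, TFF3).
#' @param min_positive vote threshold (default 3).
#' @param reference_gene reference gene recorded in the model.
#' @return list with `model` and `roc` (per-gene data.frame of cutoff,
#'   sensitivity, specificity, youden_j).
#' @export
fit_qpcr_cutoffs <- function(rqs, gold_positive,
                             genes = c("AR", "FOXA1", "SPDEF", "TFF3"),
                             min_positive = 3L, reference_gene = "RPL37A") {
  genes <- toupper(genes)
  fits <- lapply(genes, function(g) {
    sub <- rqs[rqs$gene == g, , drop = FALSE]
    miss <- setdiff(names(gold_positive), sub$sample_id)
    if (length(miss)) stop("gene ", g, " not quantified for sample(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
    v <- sub$rq[match(names(gold_positive), sub$sample_id)]
    select_cutoff_roc(v, gold_positive)
  })
  roc <- do.call(rbind, lapply(fits, as.data.frame))
  roc <- cbind(gene = genes, roc)
  model <- qpcr_signature_model(stats::setNames(roc$cutoff, genes),
                                min_positive = min_positive,
                                reference_gene = reference_gene)
  list(model = model, roc = roc)
}

#' Serialize / deserialize a qPCR signature model as JSON
#' @param model `qpcr_signature_model`.
#' @param path JSON path.
#' @export
write_qpcr_model <- function(model, path) {
  stopifnot(inherits(model, "qpcr_signature_model"))
  obj <- unclass(model)
  obj$cutoffs <- as.list(obj$cutoffs)  # keep gene names in the JSON object
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_qpcr_model
#' @export
read_qpcr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qpcr_signature_model(cutoffs = unlist(obj$cutoffs),
                       min_positive = obj$min_positive,
                       reference_gene = obj$reference_gene)
}

#' Housekeeping-normalised RNA-seq features for the four-gene signature
#'
#' feature_g = log2((expr_g + eps) / (expr_TBP + eps)) with eps = 0.01 by
#' default, guarding zero FPKM; features are invariant to per-sample scaling
#' (library size) since the normaliser cancels.
#'
#' @param expr genes x samples expression matrix (linear scale).
#' @param genes signature genes (default AR, FOXA1, SPDEF, TFF3).
#' @param normalizer_gene housekeeping normaliser (default TBP).
#' @param eps pseudo-quantity; set to 0 to require strictly positive
#'   normaliser values.
#' @return numeric matrix samples x genes of log2 ratios.
#' @export
make_rnaseq_features <- function(expr, genes = c("AR", "FOXA1", "SPDEF", "TFF3"),
                                 normalizer_gene = "TBP", eps = 0.01) {
  validate_expression_matrix(expr)
  genes <- toupper(genes); normalizer_gene <- toupper(normalizer_gene)
  missing <- setdiff(c(genes, normalizer_gene), rownames(expr))
  if (length(missing)) stop("gene(s) absent from matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  norm <- expr[normalizer_gene, ]
  if (eps == 0 && any(norm == 0)) {
    stop("normaliser ", normalizer_gene, " is 0 for sample(s): ",
         paste(colnames(expr)[norm == 0], collapse = ", "), call. = FALSE)
  }
  feats <- t(log2(sweep(expr[genes, , drop = FALSE] + eps, 2L, norm + eps, `/`)))
  colnames(feats) <- genes
  feats
}

#' Train / apply the RNA-seq random-forest signature classifier
#'
#' Bootstrap-aggregated decision trees (majority vote) on the four
#' TBP-normalised log-ratio features; fully deterministic given the seed.
#'
#' @param features samples x genes feature matrix from
#'   [make_rnaseq_features()].
#' @param labels character/factor of two classes (conventionally MABC_LAR /
#'   negative), aligned with feature rows.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed frozen into the model.
#' @return object of class `rnaseq_signature_model`.
#' @export
train_forest <- function(features, labels, n_trees = 500L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) stop("labels/features mismatch",
                                             call. = FALSE)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("training labels contain a single class",
                             call. = FALSE)
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(x = features,
                                       y = factor(labels, levels = lev),
                                       ntree = n_trees)
  structure(list(forest = forest, genes = colnames(features), levels = lev,
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "rnaseq_signature_model")
}

#' @rdname train_forest
#' @param model trained `rnaseq_signature_model`.
#' @return `predict_forest()`: `subtype_calls` under scheme RF4 with vote
#'   fractions as scores (label = majority vote, lexicographic tie-break).
#' @export
predict_forest <- function(model, features) {
  stopifnot(inherits(model, "rnaseq_signature_model"))
  features <- as.matrix(features)[, model$genes, drop = FALSE]
  votes <- stats::predict(model$forest, features, type = "vote")
  votes <- votes[, model$levels, drop = FALSE]
  labels <- vapply(seq_len(nrow(votes)), function(i) which_max_lex(votes[i, ]),
                   character(1L))
  ids <- rownames(features) %||% paste0("sample_", seq_len(nrow(features)))
  scheme <- if (all(model$levels %in% .scheme_labels$RF4)) "RF4" else "RF"
  subtype_calls(ids, scheme, labels, votes)
}
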