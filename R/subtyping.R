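.scheme_labels <- list(
  CIT6  = c("lumA", "lumB", "lumC", "mApo", "basL", "normL"),
  TNBC6 = c("BL1", "BL2", "M", "LAR", "IM", "MSL"),
  TNBC4 = c("BL1", "BL2", "M", "LAR"),
  QPCR4 = c("MABC_LAR", "negative"),
  RF4   = c("MABC_LAR", "negative")
)

#' Label set of a classification scheme
#'
#' Known schemes: CIT6 (lumA/lumB/lumC/mApo/basL/normL), TNBC6
#' (BL1/BL2/M/LAR/IM/MSL), TNBC4 (the intrinsic four), QPCR4 and RF4
#' (MABC_LAR/negative).  Unknown scheme names return `NULL` (ad hoc schemes are
#' allowed, in which case the label set is the score column set).
#'
#' @param scheme scheme name.
#' @return character vector of labels, or `NULL`.
#' @export
scheme_labels <- function(scheme) .scheme_labels[[scheme]]

#' Construct a table of per-sample subtype calls
#'
#' A `subtype_calls` object is a data.frame with columns `sample_id`,
#' `scheme`, `label` and one numeric score column per subtype (correlation to
#' centroid, vote fraction, or exceedance count depending on the scheme).  The
#' label is either `UNCLASSIFIED` or the subtype attaining the maximum score
#' after restriction to the scheme's label set (ties broken lexicographically
#' by subtype name).
#'
#' @param sample_id character vector of sample ids (unique).
#' @param scheme scheme name (one per table).
#' @param label character vector of labels.
#' @param scores numeric matrix, samples x subtypes, with column names; may be
#'   `NULL` for label-only tables read from file.
#' @param check validate the label/argmax invariant (default TRUE).
#' @return data.frame of class `subtype_calls`.
#' @export
subtype_calls <- function(sample_id, scheme, label, scores = NULL, check = TRUE) {
  stopifnot(length(scheme) == 1L, length(label) == length(sample_id))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in calls", call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id),
                   scheme = scheme,
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores))) stop("scores must have subtype column names",
                                        call. = FALSE)
    if (nrow(scores) != length(sample_id)) stop("scores/sample length mismatch",
                                                call. = FALSE)
    df <- cbind(df, as.data.frame(scores))
  }
  class(df) <- c("subtype_calls", "data.frame")
  if (check) validate_subtype_calls(df)
  df
}

#' @rdname subtype_calls
#' @param calls a `subtype_calls` data.frame.
#' @export
validate_subtype_calls <- function(calls) {
  stopifnot(all(c("sample_id", "scheme", "label") %in% colnames(calls)))
  sc <- call_scores(calls)
  known <- scheme_labels(calls$scheme[1L])
  ok_labels <- known %||% colnames(sc)
  if (is.null(known) && ncol(sc) == 0L) ok_labels <- unique(calls$label)
  bad <- setdiff(unique(calls$label), c(ok_labels, "UNCLASSIFIED"))
  if (length(bad)) stop("label(s) outside scheme '", calls$scheme[1L], "': ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(sc) && ncol(sc)) {
    restrict <- intersect(ok_labels, colnames(sc))
    if (length(restrict)) {
      for (i in seq_len(nrow(calls))) {
        lab <- calls$label[i]
        if (lab == "UNCLASSIFIED" || !(lab %in% restrict)) next
        if (sc[i, lab] < max(sc[i, restrict]) - 1e-9) {
          stop(sprintf("sample '%s': label '%s' does not attain the maximum score",
                       calls$sample_id[i], lab), call. = FALSE)
        }
      }
    }
  }
  invisible(calls)
}

#' Extract the score matrix from a calls table
#' @param calls `subtype_calls` data.frame.
#' @return numeric matrix samples x subtypes (possibly 0 columns), rownames =
#'   sample ids.
#' @export
call_scores <- function(calls) {
  num <- setdiff(colnames(calls), c("sample_id", "scheme", "label"))
  num <- num[vapply(calls[num], is.numeric, logical(1L))]
  m <- as.matrix(calls[, num, drop = FALSE])
  rownames(m) <- calls$sample_id
  m
}

#' Train a correlation-to-centroid subtype classifier
#'
#' Generic machinery behind both the CIT-style six-class and TNBCtype-style
#' classifiers: signature genes are z-scored over the training samples
#' (per-gene mean/sd frozen into the model), each subtype's centroid is the
#' mean standardized profile of its training samples, column-centred so that
#' centroids live in a zero-mean space (Pearson correlation is invariant to
#' this centring).
#'
#' @param expr genes x samples expression matrix (linear scale; standardized
#'   internally on log2(x+1)).
#' @param labels named character vector, sample id -> subtype; every class
#'   needs >= 2 samples.
#' @param signature_genes genes used by the classifier (>= 5 must survive
#'   zero-variance filtering).
#' @param scheme scheme name stored in resulting calls (e.g. "CIT6", "TNBC6").
#' @param correlation_kind "pearson" (default) or "spearman".
#' @param unclassified_threshold samples whose best centroid correlation falls
#'   below this are labelled UNCLASSIFIED (default 0.15).
#' @return object of class `centroid_model`.
#' @export
train_centroids <- function(expr, labels, signature_genes, scheme = "CIT6",
                            correlation_kind = c("pearson", "spearman"),
                            unclassified_threshold = 0.15) {
  correlation_kind <- match.arg(correlation_kind)
  validate_expression_matrix(expr)
  signature_genes <- unique(toupper(signature_genes))
  if (!all(names(labels) %in% colnames(expr))) {
    stop("labelled sample(s) absent from expression matrix", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 subtype classes to train", call. = FALSE)
  if (any(tab < 2L)) stop("every class needs >= 2 training samples; short: ",
                          paste(names(tab)[tab < 2L], collapse = ", "),
                          call. = FALSE)
  missing <- setdiff(signature_genes, rownames(expr))
  if (length(missing)) stop("signature gene(s) absent: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  x <- log2(expr[signature_genes, names(labels), drop = FALSE] + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    warning("dropping zero-variance gene(s): ",
            paste(signature_genes[!keep], collapse = ", "), call. = FALSE)
  }
  if (sum(keep) < 5L) stop("fewer than 5 signature genes with variance",
                           call. = FALSE)
  x <- x[keep, , drop = FALSE]
  mu <- mu[keep]; sdv <- sdv[keep]
  z <- (x - mu) / sdv
  classes <- sort(unique(labels))
  centroids <- vapply(classes,
                      function(cl) rowMeans(z[, names(labels)[labels == cl], drop = FALSE]),
                      numeric(nrow(z)))
  centroids <- sweep(centroids, 2L, colMeans(centroids))  # zero-mean columns
  model <- list(scheme = scheme,
                signature_genes = rownames(z),
                centroids = centroids,
                gene_means = mu,
                gene_sds = sdv,
                correlation_kind = correlation_kind,
                unclassified_threshold = unclassified_threshold)
  class(model) <- "centroid_model"
  model
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> scheme %s: %d genes, %d subtypes (%s), UNS threshold %.2f\n",
              x$scheme, length(x$signature_genes), ncol(x$centroids),
              paste(colnames(x$centroids), collapse = "/"),
              x$unclassified_threshold))
  invisible(x)
}

#' Classify samples against trained centroids
#'
#' Each sample's signature vector is standardized with the training statistics
#' frozen in the model and correlated with every centroid; the call is the
#' best-correlated subtype, or UNCLASSIFIED when the best correlation falls
#' below the model threshold.  Ties break lexicographically by subtype name.
#' At least 5 of the model's signature genes must be present (the intersection
#' is used).
#'
#' @param expr genes x samples expression matrix (linear scale).
#' @param model a `centroid_model`.
#' @return `subtype_calls` with one score column per subtype.
#' @export
classify_to_centroids <- function(expr, model) {
  stopifnot(inherits(model, "centroid_model"))
  validate_expression_matrix(expr)
  common <- intersect(model$signature_genes, rownames(expr))
  if (length(common) < 5L) {
    stop("fewer than 5 model signature genes present in expression matrix",
         call. = FALSE)
  }
  x <- log2(expr[common, , drop = FALSE] + 1)
  z <- (x - model$gene_means[common]) / model$gene_sds[common]
  scores <- stats::cor(z, model$centroids[common, , drop = FALSE],
                       method = model$correlation_kind)
  labels <- vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    if (max(s) < model$unclassified_threshold) "UNCLASSIFIED" else which_max_lex(s)
  }, character(1L))
  subtype_calls(colnames(expr), model$scheme, labels, scores)
}

#' Convert TNBCtype-6 calls to TNBCtype-4
#'
#' The IM and MSL subtypes reflect infiltrating immune and stromal signal
#' rather than tumour-intrinsic biology; the four-subtype classification
#' retains, for every sample, the intrinsic subtype (BL1, BL2, M or LAR) with
#' the highest coefficient.  UNCLASSIFIED propagates unchanged.
#'
#' @param calls `subtype_calls` under scheme TNBC6 with all six score columns.
#' @return `subtype_calls` under scheme TNBC4 (scores restricted to the
#'   intrinsic four).
#' @export
convert_tnbc6_to_4 <- function(calls) {
  stopifnot(inherits(calls, "subtype_calls"))
  sc <- call_scores(calls)
  missing <- setdiff(.scheme_labels$TNBC6, colnames(sc))
  if (length(missing)) stop("TNBC6 score(s) missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  intrinsic <- .scheme_labels$TNBC4
  labels <- vapply(seq_len(nrow(sc)), function(i) {
    if (calls$label[i] == "UNCLASSIFIED") return("UNCLASSIFIED")
    which_max_lex(sc[i, intrinsic])
  }, character(1L))
  subtype_calls(calls$sample_id, "TNBC4", labels, sc[, intrinsic, drop = FALSE])
}

#' Second-best subtype per sample
#'
#' Returns, for every call, the subtype with the second-largest score (ties
#' broken lexicographically) — used to show that discordant MABC tumours have
#' the LAR centroid as runner-up.
#'
#' @param calls `subtype_calls` with >= 2 score columns.
#' @return named character vector, sample id -> second-best subtype.
#' @export
second_best_subtype <- function(calls) {
  stopifnot(inherits(calls, "subtype_calls"))
  sc <- call_scores(calls)
  if (ncol(sc) < 2L) stop("need >= 2 scored subtypes", call. = FALSE)
  out <- vapply(seq_len(nrow(sc)), function(i) {
    s <- sc[i, ]
    ord <- order(-s, colnames(sc))
    colnames(sc)[ord][2L]
  }, character(1L))
  names(out) <- calls$sample_id
  out
}

#' Serialize / deserialize a centroid model as JSON
#' @param model `centroid_model`.
#' @param path JSON path.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  obj <- model
  obj$centroids <- list(genes = rownames(model$centroids),
                        subtypes = colnames(model$centroids),
                        values = unclass(model$centroids))
  class(obj) <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- matrix(as.numeric(obj$centroids$values),
                 nrow = length(obj$centroids$genes),
                 ncol = length(obj$centroids$subtypes),
                 byrow = FALSE,
                 dimnames = list(obj$centroids$genes, obj$centroids$subtypes))
  if (is.matrix(obj$centroids$values)) {
    cent[] <- obj$centroids$values
  }
  model <- list(scheme = obj$scheme,
                signature_genes = obj$signature_genes,
                centroids = cent,
                gene_means = stats::setNames(obj$gene_means, obj$signature_genes),
                gene_sds = stats::setNames(obj$gene_sds, obj$signature_genes),
                correlation_kind = obj$correlation_kind,
                unclassified_threshold = obj$unclassified_threshold)
  class(model) <- "centroid_model"
  model
}
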