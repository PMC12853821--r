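#' Marker gene set for a cell population
#'
#' Minimal MCPcounter-style abstraction: a named population scored by the mean
#' log2 expression of >= 3 marker genes.  Marker sets used together must be
#' disjoint in gene membership.
#'
#' @param population population name (e.g. "fibroblasts", "T_cells").
#' @param genes character vector of >= 3 HGNC symbols.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(population, genes) {
  genes <- unique(toupper(genes))
  if (length(genes) < 3L) stop("a marker set needs >= 3 genes", call. = FALSE)
  structure(list(population = population, genes = genes), class = "marker_set")
}

#' Check pairwise disjointness of a list of marker sets
#' @param sets list of [marker_set()] objects.
#' @return `sets` invisibly.
#' @export
validate_marker_sets <- function(sets) {
  genes <- unlist(lapply(sets, `[[`, "genes"))
  if (anyDuplicated(genes)) {
    stop("marker sets share gene(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  invisible(sets)
}

#' Marker-mean abundance score for one cell population
#'
#' Score = arithmetic mean of log2(value + 1) over the marker genes present in
#' the matrix (>= 3 required).  Monotone in every marker and invariant to
#' marker order; comparable between samples, not between populations.
#'
#' @param expr genes x samples expression matrix (linear scale).
#' @param markers a [marker_set()].
#' @return named numeric vector of per-sample scores.
#' @export
population_score <- function(expr, markers) {
  stopifnot(inherits(markers, "marker_set"))
  validate_expression_matrix(expr)
  present <- intersect(markers$genes, rownames(expr))
  if (length(present) < 3L) {
    stop("fewer than 3 marker genes of population '", markers$population,
         "' present", call. = FALSE)
  }
  colMeans(log2(expr[present, , drop = FALSE] + 1))
}

#' Two-sample t-test between score groups
#'
#' Welch's unequal-variance test is the default; the pooled-variance Student
#' variant is available for strict replication of classic workflows.
#'
#' @param scores_a,scores_b numeric score vectors, each of length >= 2.
#' @param variant "welch" (default) or "pooled".
#' @return list with `mean_a`, `mean_b`, `t`, `p_value`, `variant`.
#' @export
compare_groups_ttest <- function(scores_a, scores_b,
                                 variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  res <- stats::t.test(scores_a, scores_b, var.equal = (variant == "pooled"))
  list(mean_a = mean(scores_a), mean_b = mean(scores_b),
       t = unname(res$statistic), p_value = res$p.value, variant = variant)
}

#' High-cellularity enrichment per sample group
#'
#' For each group, the proportion of samples with `cellularity_class == "high"`
#' (tumour cellularity > 70%) among those with known cellularity; unknowns are
#' excluded and reported.  Pairwise chi-squared p-values compare the high
#' vs not-high 2x2 tables between groups.
#'
#' @param groups named list of sample-id vectors (non-empty).
#' @param annotations validated sample annotation data.frame.
#' @param continuity_correction Yates correction for the 2x2 tests.
#' @return list with `summary` (data.frame group, n_known, n_high, n_unknown,
#'   high_pct) and `pairwise_p` (matrix of chi-squared p-values).
#' @export
cellularity_enrichment <- function(groups, annotations,
                                   continuity_correction = TRUE) {
  validate_sample_annotation(annotations)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list", call. = FALSE)
  }
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 0L) stop("empty group: ", g, call. = FALSE)
    miss <- setdiff(ids, annotations$sample_id)
    if (length(miss)) stop("group '", g, "' has unannotated sample(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
    cl <- annotations$cellularity_class[match(ids, annotations$sample_id)]
    known <- cl != "unknown"
    if (!any(known)) stop("group '", g, "' has no known cellularity", call. = FALSE)
    data.frame(group = g,
               n_known = sum(known),
               n_high = sum(cl[known] == "high"),
               n_unknown = sum(!known),
               high_pct = proportion_pct(sum(cl[known] == "high"), sum(known)),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  g <- summary$group
  pw <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  if (length(g) > 1L) {
    for (i in seq_along(g)) for (j in seq_along(g)) {
      if (i >= j) next
      tab <- matrix(c(summary$n_high[i], summary$n_known[i] - summary$n_high[i],
                      summary$n_high[j], summary$n_known[j] - summary$n_high[j]),
                    nrow = 2L, byrow = TRUE)
      p <- tryCatch(chi2_proportions(tab, continuity_correction)$p_value,
                    error = function(e) NA_real_)
      pw[i, j] <- pw[j, i] <- p
    }
  }
  list(summary = summary, pairwise_p = pw)
}
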