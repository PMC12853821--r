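#' Validate a genes-by-samples expression matrix
#'
#' Expression matrices are plain numeric matrices on the linear scale (FPKM for
#' RNA-seq, normalised intensities for microarray) with HGNC symbols as row
#' names and sample identifiers as column names.  Validation enforces the
#' container invariants relied on by every downstream classifier: no negative
#' or missing values, unique uppercased gene symbols, unique sample ids.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene row names and sample column names",
         call. = FALSE)
  }
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(x < 0)) stop("expression matrix contains negative values", call. = FALSE)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene symbols: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(rownames(x) != toupper(rownames(x)))) {
    stop("gene symbols must be uppercase (readers uppercase on load)",
         call. = FALSE)
  }
  invisible(x)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' The expected layout is one gene per row: first column holds the gene symbol,
#' the header row holds sample identifiers.  Gene symbols are uppercased on
#' load so that symbol matching is case-insensitive everywhere.
#'
#' @param path path to a tab-delimited UTF-8 file.
#' @param platform_tag `"rnaseq"` or `"microarray"`; stored as an attribute.
#' @return numeric matrix (genes x samples) with attribute `platform_tag`.
#' @export
read_expression_matrix <- function(path, platform_tag = c("rnaseq", "microarray")) {
  platform_tag <- match.arg(platform_tag)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("expression TSV needs a gene column plus >= 1 sample column",
                           call. = FALSE)
  genes <- toupper(trimws(raw[[1L]]))
  if (anyDuplicated(genes)) {
    stop("duplicate gene rows in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !(trimws(raw[[j + 1L]]) %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("malformed numeric cell at gene '%s', sample '%s': '%s'",
                   genes[bad[1L]], samples[j], raw[[j + 1L]][bad[1L]]),
           call. = FALSE)
    }
    vals[, j] <- col
  }
  attr(vals, "platform_tag") <- platform_tag
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; round-trips exactly (up to numeric
#' print precision of 15 significant digits).
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.ihc_levels <- c("positive", "negative", "unknown")
.cellularity_levels <- c("low", "moderate", "high", "unknown")

#' Validate a sample annotation table
#'
#' Columns: `sample_id`, IHC statuses `er`, `pr`, `her2`, `ar_ihc` (each
#' positive/negative/unknown; AR positivity uses the >10% staining cut-off),
#' `cellularity_class` (low/moderate/high/unknown, high meaning tumour
#' cellularity > 70%), and a free-text `cohort` label.
#'
#' @param ann data.frame of annotations.
#' @return `ann` invisibly.
#' @export
validate_sample_annotation <- function(ann) {
  need <- c("sample_id", "er", "pr", "her2", "ar_ihc", "cellularity_class", "cohort")
  missing <- setdiff(need, colnames(ann))
  if (length(missing)) stop("annotation missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation",
                                         call. = FALSE)
  for (col in c("er", "pr", "her2", "ar_ihc")) {
    bad <- setdiff(unique(ann[[col]]), .ihc_levels)
    if (length(bad)) stop(sprintf("invalid %s value(s): %s", col,
                                  paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(ann$cellularity_class), .cellularity_levels)
  if (length(bad)) stop("invalid cellularity_class value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  invisible(ann)
}

#' Read / write sample annotations (CSV)
#' @param path CSV path with the fixed header described in
#'   [validate_sample_annotation()].
#' @return data.frame of validated annotations.
#' @export
read_sample_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_annotation(ann)
  ann
}

#' @rdname read_sample_annotation
#' @param ann annotation data.frame.
#' @export
write_sample_annotation <- function(ann, path) {
  validate_sample_annotation(ann)
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.alteration_classes <- c("oncogenic_mutation", "lof_mutation", "amplification",
                         "gain", "homozygous_deletion", "other")

#' Validate a genomic alteration table
#'
#' Long-format records of per-sample alterations: `sample_id`, `gene` (HGNC,
#' uppercased), `alteration_class` (one of oncogenic_mutation, lof_mutation,
#' amplification, gain, homozygous_deletion, other) and a logical `pathogenic`
#' flag (the pathogenicity call, e.g. from OncoKB, is an input here, never
#' looked up).  (sample, gene, class) triplets must be unique.
#'
#' @param alt data.frame of alteration records.
#' @return `alt` invisibly.
#' @export
validate_alteration_table <- function(alt) {
  need <- c("sample_id", "gene", "alteration_class", "pathogenic")
  missing <- setdiff(need, colnames(alt))
  if (length(missing)) stop("alteration table missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(alt$alteration_class), .alteration_classes)
  if (length(bad)) stop("unknown alteration_class: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.logical(alt$pathogenic) || anyNA(alt$pathogenic)) {
    stop("pathogenic must be TRUE/FALSE with no missing values", call. = FALSE)
  }
  key <- paste(alt$sample_id, alt$gene, alt$alteration_class, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (sample, gene, alteration_class) records",
                               call. = FALSE)
  invisible(alt)
}

#' Read / write alteration tables (CSV)
#' @param path CSV with columns sample_id, gene, alteration_class, pathogenic.
#' @return validated data.frame; gene symbols uppercased.
#' @export
read_alteration_table <- function(path) {
  alt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("gene" %in% colnames(alt)) alt$gene <- toupper(alt$gene)
  if ("pathogenic" %in% colnames(alt) && is.character(alt$pathogenic)) {
    alt$pathogenic <- as.logical(alt$pathogenic)
  }
  validate_alteration_table(alt)
  alt
}

#' @rdname read_alteration_table
#' @param alt alteration data.frame.
#' @export
write_alteration_table <- function(alt, path) {
  validate_alteration_table(alt)
  utils::write.csv(alt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an RT-qPCR CT table
#'
#' Long format: `sample_id`, `gene`, `replicate`, `ct` (quantification cycles,
#' `NA` encodes an Undetermined well — never silently zero).  The reference
#' gene (attribute `reference_gene`, default RPL37A) must be measured for
#' every sample.
#'
#' @param ct data.frame with attribute `reference_gene`.
#' @return `ct` invisibly.
#' @export
validate_ct_table <- function(ct) {
  need <- c("sample_id", "gene", "replicate", "ct")
  missing <- setdiff(need, colnames(ct))
  if (length(missing)) stop("CT table missing columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  ref <- attr(ct, "reference_gene") %||% "RPL37A"
  if (!is.numeric(ct$ct)) stop("ct column must be numeric (NA = Undetermined)",
                               call. = FALSE)
  if (any(ct$ct < 0, na.rm = TRUE)) stop("negative CT values", call. = FALSE)
  no_ref <- setdiff(unique(ct$sample_id), ct$sample_id[ct$gene == ref])
  if (length(no_ref)) {
    stop("reference gene ", ref, " not measured for sample(s): ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  }
  invisible(ct)
}

#' Read / write RT-qPCR CT tables (CSV)
#'
#' CSV columns `sample,gene,replicate,ct`; the literal value `Undetermined`
#' (any case) is preserved as an `NA` sentinel, never coerced to 0.
#'
#' @param path CSV path.
#' @param reference_gene reference (housekeeping) gene symbol; default RPL37A.
#' @return data.frame (`sample_id`, `gene`, `replicate`, `ct`) with attribute
#'   `reference_gene`.
#' @export
read_ct_table <- function(path, reference_gene = "RPL37A") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cn <- colnames(raw)
  if ("sample" %in% cn && !("sample_id" %in% cn)) {
    colnames(raw)[cn == "sample"] <- "sample_id"
  }
  ctv <- trimws(raw$ct)
  undet <- toupper(ctv) == "UNDETERMINED"
  num <- suppressWarnings(as.numeric(ctv))
  bad <- which(is.na(num) & !undet)
  if (length(bad)) {
    stop(sprintf("malformed CT value '%s' (sample '%s', gene '%s')",
                 ctv[bad[1L]], raw$sample_id[bad[1L]], raw$gene[bad[1L]]),
         call. = FALSE)
  }
  out <- data.frame(sample_id = raw$sample_id,
                    gene = toupper(trimws(raw$gene)),
                    replicate = as.integer(raw$replicate),
                    ct = ifelse(undet, NA_real_, num),
                    stringsAsFactors = FALSE)
  attr(out, "reference_gene") <- toupper(reference_gene)
  validate_ct_table(out)
  out
}

#' @rdname read_ct_table
#' @param ct CT table data.frame.
#' @export
write_ct_table <- function(ct, path) {
  validate_ct_table(ct)
  out <- ct
  out$ct <- ifelse(is.na(ct$ct), "Undetermined",
                   format(ct$ct, digits = 15, trim = TRUE, scientific = FALSE))
  colnames(out)[colnames(out) == "sample_id"] <- "sample"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
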