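.latent_classes <- c("MABC_core", "MABC_HER2", "LAR_immune", "MABC_stromal",
                     "basal", "luminalC_like")
.mabc_lar_classes <- c("MABC_core", "MABC_HER2", "LAR_immune", "MABC_stromal")

#' Default gene panels of the synthetic cohort generator
#'
#' The panels define which genes carry class effects (ar_targets in the
#' MABC/LAR classes, basal_markers in basal tumours, erbb2_amplicon in the
#' HER2-amplified class, esr1_module at intermediate level in the
#' luminal-C-like boundary class) and which genes mark the admixed
#' non-tumour compartments (immune_markers, fibroblast_markers).
#' Housekeeping genes (TBP, RPL37A) never receive a class effect.
#'
#' @return named list of character vectors; pairwise disjoint.
#' @export
default_gene_panels <- function() {
  list(ar_targets = c("AR", "FOXA1", "SPDEF", "TFF3", "PIP", "DHRS2", "AGR2",
                      "CLDN8"),
       basal_markers = c("KRT5", "KRT14", "KRT17", "EGFR", "CDH3", "ELF5"),
       immune_markers = c("PTPRC", "CD3D", "CD8A", "CD2", "CD52", "GZMB",
                          "IL7R"),
       fibroblast_markers = c("COL1A1", "COL1A2", "COL3A1", "DCN", "FAP",
                              "PDGFRB", "THY1"),
       esr1_module = c("ESR1", "PGR", "GREB1", "TFF1", "GATA3"),
       erbb2_amplicon = c("ERBB2", "GRB7", "STARD3"),
       housekeeping = c("TBP", "RPL37A"))
}

#' Default per-class log2 effects on the tumour profile
#' @return named list class -> named numeric vector panel -> log2 shift.
#' @export
default_effects <- function() {
  list(MABC_core = c(ar_targets = 3),
       MABC_HER2 = c(ar_targets = 3, erbb2_amplicon = 2.5),
       LAR_immune = c(ar_targets = 3),
       MABC_stromal = c(ar_targets = 3),
       basal = c(basal_markers = 2.5),
       luminalC_like = c(ar_targets = 1, esr1_module = 1.5))
}

#' Default per-class per-event alteration planting rates
#'
#' Bernoulli rates for pathogenic ERBB2 amplification, PIK3CA/AKT1 oncogenic
#' mutation and PTEN loss-of-function mutation; ERBB2 amplification is
#' near-certain (0.95) in the HER2-amplified class and uncommon elsewhere
#' (e.g. 0.10 of immune-rich LAR tumours despite triple-negative IHC).
#'
#' @return data.frame with columns gene, alteration_class, latent_class, rate.
#' @export
default_alteration_rates <- function() {
  grid <- function(gene, cls, rates) {
    data.frame(gene = gene, alteration_class = cls,
               latent_class = .latent_classes, rate = rates,
               stringsAsFactors = FALSE)
  }
  rbind(
    grid("ERBB2", "amplification",      c(0.05, 0.95, 0.10, 0.05, 0.02, 0.20)),
    grid("PIK3CA", "oncogenic_mutation", c(0.25, 0.25, 0.25, 0.25, 0.10, 0.30)),
    grid("AKT1", "oncogenic_mutation",  c(0.05, 0.05, 0.05, 0.05, 0.02, 0.02)),
    grid("PTEN", "lof_mutation",        c(0.08, 0.08, 0.08, 0.08, 0.10, 0.05)))
}

#' Configuration of the synthetic ER-negative cohort generator
#'
#' The generator emulates the latent structure the convergence analysis
#' assumes: four MABC/LAR classes (a high-purity core, an ERBB2-amplified
#' class, an immune-infiltrated class and a fibroblast-rich class), basal-like
#' tumours, and a luminal-C-like boundary class with intermediate ESR1-module
#' expression.  Per sample, log2 expression is a purity-weighted mixture of
#' the class tumour profile with immune and fibroblast profiles plus Gaussian
#' noise, exponentiated to the linear scale.
#'
#' @param n_per_class named integer vector of class sizes over
#'   MABC_core, MABC_HER2, LAR_immune, MABC_stromal, basal, luminalC_like;
#'   the default mix keeps LAR-truth prevalence near one quarter of the
#'   TNBC-like subset.
#' @param gene_panels see [default_gene_panels()]; pairwise disjoint,
#'   housekeeping excluded from every effect panel.
#' @param effect_log2fc see [default_effects()].
#' @param purity_beta named list class -> Beta(shape1, shape2) parameters of
#'   the tumour fraction, or a single number for a fixed purity.
#' @param admixture_split named numeric vector: immune share of the non-tumour
#'   fraction per class (fibroblasts take the rest).
#' @param admixture_log2fc log2 shift of immune/fibroblast markers in their
#'   compartment profiles (default 4).
#' @param noise_sd_log2 per-gene Gaussian noise sd in log2 space (default 0.5).
#' @param baseline_log2_mean,baseline_log2_sd per-cohort baseline log2
#'   expression is drawn once per gene from this Normal (defaults 5, 1).
#' @param n_background unaffected background genes added to the panel genes.
#' @param alteration_rates see [default_alteration_rates()]; all rates in
#'   0..1.
#' @param qpcr list: ct_ref_base (cycles at which the reference gene
#'   amplifies, default 26), ct_noise_sd (default 0.25 cycles),
#'   efficiency_range (default 1.01..1.07, used only in strict-efficiency
#'   mode), n_replicates (default 2).
#' @param seed default seed used by [generate_cohort()].
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(MABC_core = 30, MABC_HER2 = 30,
                                          LAR_immune = 10, MABC_stromal = 10,
                                          basal = 150, luminalC_like = 20),
                          gene_panels = default_gene_panels(),
                          effect_log2fc = default_effects(),
                          purity_beta = list(MABC_core = c(18, 3),
                                             MABC_HER2 = c(18, 3),
                                             LAR_immune = c(8, 6),
                                             MABC_stromal = c(8, 6),
                                             basal = c(12, 4),
                                             luminalC_like = c(12, 4)),
                          admixture_split = c(MABC_core = 0.5, MABC_HER2 = 0.5,
                                              LAR_immune = 0.85,
                                              MABC_stromal = 0.15,
                                              basal = 0.5,
                                              luminalC_like = 0.5),
                          admixture_log2fc = 4,
                          noise_sd_log2 = 0.5,
                          baseline_log2_mean = 5,
                          baseline_log2_sd = 1,
                          n_background = 40L,
                          alteration_rates = default_alteration_rates(),
                          qpcr = list(ct_ref_base = 26, ct_noise_sd = 0.25,
                                      efficiency_range = c(1.01, 1.07),
                                      n_replicates = 2L),
                          seed = NULL) {
  missing_cls <- setdiff(.latent_classes, names(n_per_class))
  if (length(missing_cls)) stop("n_per_class missing class(es): ",
                                paste(missing_cls, collapse = ", "),
                                call. = FALSE)
  if (any(n_per_class < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (!all(c("housekeeping") %in% names(gene_panels))) {
    stop("gene_panels must include a housekeeping panel", call. = FALSE)
  }
  gene_panels <- lapply(gene_panels, toupper)
  all_panel_genes <- unlist(gene_panels)
  if (anyDuplicated(all_panel_genes)) {
    stop("gene panels must be pairwise disjoint; shared: ",
         paste(unique(all_panel_genes[duplicated(all_panel_genes)]),
               collapse = ", "), call. = FALSE)
  }
  for (cls in names(effect_log2fc)) {
    bad <- setdiff(names(effect_log2fc[[cls]]), names(gene_panels))
    if (length(bad)) stop("unknown effect panel(s) for ", cls, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if ("housekeeping" %in% names(effect_log2fc[[cls]])) {
      stop("housekeeping genes must receive no class effect", call. = FALSE)
    }
  }
  if (any(admixture_split < 0 | admixture_split > 1)) {
    stop("admixture_split values must lie in [0, 1]", call. = FALSE)
  }
  if (any(alteration_rates$rate < 0 | alteration_rates$rate > 1)) {
    stop("alteration rates must lie in [0, 1]", call. = FALSE)
  }
  er <- qpcr$efficiency_range
  if (length(er) != 2L || er[1L] <= 0.9 || er[2L] > 1.2 || er[1L] > er[2L]) {
    stop("efficiency_range must lie within (0.9, 1.2]", call. = FALSE)
  }
  if (noise_sd_log2 < 0 || qpcr$ct_noise_sd < 0) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  cfg <- list(n_per_class = n_per_class[.latent_classes],
              gene_panels = gene_panels,
              effect_log2fc = effect_log2fc,
              purity_beta = purity_beta,
              admixture_split = admixture_split,
              admixture_log2fc = admixture_log2fc,
              noise_sd_log2 = noise_sd_log2,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              n_background = as.integer(n_background),
              alteration_rates = alteration_rates,
              qpcr = qpcr,
              seed = seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a cohort configuration from YAML
#'
#' Any field of [cohort_config()] may be overridden from a YAML file; omitted
#' fields keep their defaults.
#'
#' @param path YAML file.
#' @return `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in intersect(names(y), names(formals(cohort_config)))) {
    v <- y[[nm]]
    if (nm %in% c("n_per_class", "admixture_split")) v <- unlist(v)
    if (nm == "effect_log2fc") v <- lapply(v, unlist)
    if (nm == "alteration_rates") v <- as.data.frame(do.call(rbind, v))
    args[[nm]] <- v
  }
  do.call(cohort_config, args)
}

.draw_purity <- function(spec, n) {
  if (length(spec) == 1L) return(rep(as.numeric(spec), n))
  stats::rbeta(n, spec[1L], spec[2L])
}

#' Generate a synthetic ER-negative cohort
#'
#' Draws per-gene baselines, per-sample purity and admixture fractions, mixes
#' tumour/immune/fibroblast log2 profiles by those weights, adds Gaussian
#' noise and exponentiates to the linear scale.  Alterations are planted with
#' [plant_alterations()]; HER2 IHC is positive exactly when an ERBB2
#' amplification was planted, AR IHC is positive for the MABC/LAR classes,
#' ER/PR are negative throughout, and the cellularity class is derived from
#' the drawn purity (> 0.7 high, 0.4-0.7 moderate, otherwise low).
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed (defaults to `config$seed`); same config + seed gives
#'   bitwise-identical output.
#' @return list of class `synthetic_cohort`: `expression` (genes x samples
#'   linear matrix), `annotations`, `alterations`, `truth` (sample_id,
#'   latent_class, purity, immune_fraction, fibroblast_fraction,
#'   is_mabc_lar_truth), and `config`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$n_per_class)
  if (n_total == 0L) stop("empty cohort: all class counts are 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  panels <- config$gene_panels
  genes <- c(unlist(panels, use.names = FALSE),
             if (config$n_background > 0L)
               sprintf("BG%03d", seq_len(config$n_background)))
  baseline <- stats::rnorm(length(genes), config$baseline_log2_mean,
                           config$baseline_log2_sd)
  names(baseline) <- genes

  classes <- rep(names(config$n_per_class), config$n_per_class)
  ids <- sprintf("SYN%04d", seq_len(n_total))

  tumour <- vapply(.latent_classes, function(cls) {
    prof <- baseline
    eff <- config$effect_log2fc[[cls]]
    for (panel in names(eff)) prof[panels[[panel]]] <- prof[panels[[panel]]] + eff[[panel]]
    prof
  }, numeric(length(genes)))
  immune_prof <- baseline
  immune_prof[panels$immune_markers] <-
    immune_prof[panels$immune_markers] + config$admixture_log2fc
  fibro_prof <- baseline
  fibro_prof[panels$fibroblast_markers] <-
    fibro_prof[panels$fibroblast_markers] + config$admixture_log2fc

  purity <- numeric(n_total)
  for (cls in .latent_classes) {
    idx <- which(classes == cls)
    purity[idx] <- .draw_purity(config$purity_beta[[cls]], length(idx))
  }
  immune_fraction <- (1 - purity) * config$admixture_split[classes]
  fibroblast_fraction <- 1 - purity - immune_fraction

  log2expr <- sweep(tumour[, classes, drop = FALSE], 2L, purity, `*`) +
    outer(immune_prof, immune_fraction) +
    outer(fibro_prof, fibroblast_fraction)
  if (config$noise_sd_log2 > 0) {
    log2expr <- log2expr + matrix(stats::rnorm(length(log2expr), 0,
                                               config$noise_sd_log2),
                                  nrow = nrow(log2expr))
  }
  expr <- 2^log2expr
  dimnames(expr) <- list(genes, ids)
  attr(expr, "platform_tag") <- "rnaseq"
  validate_expression_matrix(expr)

  truth <- data.frame(sample_id = ids,
                      latent_class = classes,
                      purity = purity,
                      immune_fraction = immune_fraction,
                      fibroblast_fraction = fibroblast_fraction,
                      is_mabc_lar_truth = classes %in% .mabc_lar_classes,
                      stringsAsFactors = FALSE)

  alterations <- plant_alterations(truth, config)

  erbb2_amp <- truth$sample_id %in%
    alterations$sample_id[alterations$gene == "ERBB2" &
                            alterations$alteration_class == "amplification"]
  annotations <- data.frame(
    sample_id = ids,
    er = "negative", pr = "negative",
    her2 = ifelse(erbb2_amp, "positive", "negative"),
    ar_ihc = ifelse(truth$is_mabc_lar_truth, "positive", "negative"),
    cellularity_class = ifelse(purity > 0.7, "high",
                        ifelse(purity >= 0.4, "moderate", "low")),
    cohort = "synthetic",
    stringsAsFactors = FALSE)
  validate_sample_annotation(annotations)

  structure(list(expression = expr, annotations = annotations,
                 alterations = alterations, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Plant pathogenic alterations by class-specific Bernoulli rates
#'
#' Each (gene, alteration_class, latent_class) rate row triggers independent
#' per-sample Bernoulli draws; planted records carry `pathogenic = TRUE`.
#'
#' @param truth truth data.frame with sample_id and latent_class columns.
#' @param config a [cohort_config()] supplying `alteration_rates`.
#' @param seed optional seed (omit to continue the current RNG stream, as
#'   [generate_cohort()] does).
#' @return validated alteration table (possibly 0 rows).
#' @export
plant_alterations <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  rates <- config$alteration_rates
  if (any(rates$rate < 0 | rates$rate > 1)) {
    stop("alteration rates must lie in [0, 1]", call. = FALSE)
  }
  recs <- list()
  for (i in seq_len(nrow(rates))) {
    idx <- which(truth$latent_class == rates$latent_class[i])
    if (!length(idx)) next
    hit <- stats::rbinom(length(idx), 1L, rates$rate[i]) == 1L
    if (any(hit)) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = truth$sample_id[idx][hit],
        gene = rates$gene[i],
        alteration_class = rates$alteration_class[i],
        pathogenic = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample_id = character(), gene = character(),
               alteration_class = character(), pathogenic = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_alteration_table(out)
  out
}

#' Simulate RT-qPCR CT values from an expression matrix
#'
#' Inverts the 2^-dCT relation: for gene g in sample s,
#' ct = ct_ref_base - log2(expr_g / expr_ref) + Normal(0, ct_noise_sd) per
#' replicate, so that with zero noise the downstream 2^-dCT quantity equals
#' the expression ratio exactly.  Near-unit PCR efficiencies (validated on
#' standard curves in the assay this emulates) justify the plain factor-2
#' model; `strict_efficiency = TRUE` instead jitters a per-gene amplification
#' factor 1 + e with e drawn uniformly from `efficiency_range`.
#'
#' @param expr genes x samples expression matrix containing the signature
#'   genes and the reference gene.
#' @param config a [cohort_config()] (uses its `qpcr` block).
#' @param genes target genes (default AR, FOXA1, SPDEF, TFF3).
#' @param reference_gene default RPL37A.
#' @param strict_efficiency use per-gene jittered efficiencies (default
#'   FALSE).
#' @param seed optional RNG seed.
#' @return CT table data.frame with attribute `reference_gene`.
#' @export
simulate_qpcr <- function(expr, config, genes = c("AR", "FOXA1", "SPDEF", "TFF3"),
                          reference_gene = "RPL37A", strict_efficiency = FALSE,
                          seed = NULL) {
  validate_expression_matrix(expr)
  if (!is.null(seed)) set.seed(as.integer(seed))
  genes <- toupper(genes); reference_gene <- toupper(reference_gene)
  missing <- setdiff(c(genes, reference_gene), rownames(expr))
  if (length(missing)) stop("gene(s) absent from expression matrix: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  qp <- config$qpcr
  all_genes <- c(genes, reference_gene)
  eff <- if (strict_efficiency) {
    stats::setNames(1 + stats::runif(length(all_genes), qp$efficiency_range[1L] - 1,
                                     qp$efficiency_range[2L] - 1), all_genes)
  } else {
    stats::setNames(rep(2, length(all_genes)), all_genes)
  }
  samples <- colnames(expr)
  ref_vals <- expr[reference_gene, ]
  rows <- vector("list", length(all_genes))
  for (k in seq_along(all_genes)) {
    g <- all_genes[k]
    true_ct <- qp$ct_ref_base - log(expr[g, ] / ref_vals) / log(eff[[g]])
    rep_rows <- lapply(seq_len(qp$n_replicates), function(r) {
      noise <- if (qp$ct_noise_sd > 0)
        stats::rnorm(length(samples), 0, qp$ct_noise_sd) else 0
      data.frame(sample_id = samples, gene = g, replicate = r,
                 ct = pmax(true_ct + noise, 0), stringsAsFactors = FALSE)
    })
    rows[[k]] <- do.call(rbind, rep_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  validate_ct_table(out)
  out
}

#' Write a synthetic cohort to a directory
#'
#' Emits expression.tsv, annotations.csv, alterations.csv, ct.csv and
#' truth.csv using the package writers (all round-trip through the matching
#' readers).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @param seed seed for the qPCR simulation step.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_sample_annotation(cohort$annotations, file.path(dir, "annotations.csv"))
  write_alteration_table(cohort$alterations, file.path(dir, "alterations.csv"))
  ct <- simulate_qpcr(cohort$expression, cohort$config, seed = seed)
  write_ct_table(ct, file.path(dir, "ct.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
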