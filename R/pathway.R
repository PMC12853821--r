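#' Configuration for PI3K/AKT/mTOR pathway-activation calling
#'
#' Qualifying events: oncogenic mutations or amplifications of the mutation
#' genes (PIK3CA, AKT1), loss-of-function mutations or homozygous deletions of
#' the loss genes (PTEN; heterozygous loss never qualifies), and amplification
#' — never gain — of the amplification genes (ERBB2).  By default only records
#' flagged pathogenic (e.g. by OncoKB, supplied as an input column) count.
#'
#' @param mutation_genes genes whose oncogenic mutation/amplification activates
#'   the pathway.
#' @param loss_genes tumour suppressors whose loss activates the pathway.
#' @param amp_genes genes whose high-level amplification activates the pathway.
#' @param require_pathogenic drop records with `pathogenic = FALSE` (default
#'   TRUE).
#' @return object of class `pathway_call_config`.
#' @export
pathway_call_config <- function(mutation_genes = c("PIK3CA", "AKT1"),
                                loss_genes = "PTEN",
                                amp_genes = "ERBB2",
                                require_pathogenic = TRUE) {
  mutation_genes <- toupper(mutation_genes)
  loss_genes <- toupper(loss_genes)
  amp_genes <- toupper(amp_genes)
  all_genes <- c(mutation_genes, loss_genes, amp_genes)
  if (anyDuplicated(all_genes)) stop("pathway gene sets must be disjoint",
                                     call. = FALSE)
  stop_if_not_scalar_flag(require_pathogenic, "require_pathogenic")
  structure(list(mutation_genes = mutation_genes, loss_genes = loss_genes,
                 amp_genes = amp_genes, require_pathogenic = require_pathogenic),
            class = "pathway_call_config")
}

#' Flag PI3K/AKT/mTOR pathway activation per sample
#'
#' Each sample is flagged for `erbb2_amp` (high-level amplification of an
#' amp gene; gains are explicitly non-qualifying), `pi3k_mut` (oncogenic
#' mutation/amplification of a mutation gene or loss of a loss gene), overall
#' `active = erbb2_amp | pi3k_mut`, and a four-way `category`
#' (erbb2_only / pi3k_only / both / none) supporting mutually-exclusive vs
#' co-occurring tabulation.
#'
#' @param alterations validated alteration table (see
#'   [validate_alteration_table()]).
#' @param samples character vector: the sample universe to flag (records for
#'   other samples are ignored).
#' @param config a [pathway_call_config()].
#' @return data.frame with columns sample_id, erbb2_amp, pi3k_mut, active,
#'   category.
#' @export
flag_pathway_activation <- function(alterations, samples,
                                    config = pathway_call_config()) {
  validate_alteration_table(alterations)
  stopifnot(inherits(config, "pathway_call_config"))
  samples <- unique(as.character(samples))
  alt <- alterations[alterations$sample_id %in% samples, , drop = FALSE]
  if (config$require_pathogenic) alt <- alt[alt$pathogenic, , drop = FALSE]
  amp_hit <- alt$gene %in% config$amp_genes & alt$alteration_class == "amplification"
  mut_hit <- (alt$gene %in% config$mutation_genes &
                alt$alteration_class %in% c("oncogenic_mutation", "amplification")) |
             (alt$gene %in% config$loss_genes &
                alt$alteration_class %in% c("lof_mutation", "homozygous_deletion"))
  erbb2_amp <- samples %in% alt$sample_id[amp_hit]
  pi3k_mut <- samples %in% alt$sample_id[mut_hit]
  category <- ifelse(erbb2_amp & pi3k_mut, "both",
              ifelse(erbb2_amp, "erbb2_only",
              ifelse(pi3k_mut, "pi3k_only", "none")))
  data.frame(sample_id = samples,
             erbb2_amp = erbb2_amp,
             pi3k_mut = pi3k_mut,
             active = erbb2_amp | pi3k_mut,
             category = category,
             stringsAsFactors = FALSE)
}

#' Compare alteration frequencies between two sample groups
#'
#' Rates are half-up one-decimal percentages ([proportion_pct()]); the p-value
#' comes from a chi-squared test on the 2x2 count table
#' ([chi2_proportions()]).
#'
#' @param flags_a,flags_b outputs of [flag_pathway_activation()] for two
#'   disjoint, non-empty groups.
#' @param field which flag to compare: "erbb2_amp", "pi3k_mut" or "active".
#' @param continuity_correction Yates correction for the 2x2 test (default
#'   TRUE).
#' @return list with `rate_a_pct`, `rate_b_pct`, `statistic`, `p_value`,
#'   `counts` (the 2x2 table).
#' @export
compare_alteration_rates <- function(flags_a, flags_b,
                                     field = c("erbb2_amp", "pi3k_mut", "active"),
                                     continuity_correction = TRUE) {
  field <- match.arg(field)
  if (nrow(flags_a) == 0L || nrow(flags_b) == 0L) stop("empty group", call. = FALSE)
  if (length(intersect(flags_a$sample_id, flags_b$sample_id))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  ka <- sum(flags_a[[field]]); na <- nrow(flags_a)
  kb <- sum(flags_b[[field]]); nb <- nrow(flags_b)
  tab <- matrix(c(ka, na - ka, kb, nb - kb), nrow = 2L, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                flag = c("altered", "wildtype")))
  chi <- chi2_proportions(tab, continuity_correction = continuity_correction)
  list(rate_a_pct = proportion_pct(ka, na),
       rate_b_pct = proportion_pct(kb, nb),
       statistic = chi$statistic,
       p_value = chi$p_value,
       counts = tab)
}
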