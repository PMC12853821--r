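test_that("zero-noise full-purity cohorts are deterministic in closed form", {
  cfg <- test_config(noise_sd_log2 = 0,
                     purity_beta = list(MABC_core = 1, MABC_HER2 = 1,
                                        LAR_immune = 1, MABC_stromal = 1,
                                        basal = 1, luminalC_like = 1))
  coh <- generate_cohort(cfg, seed = 11)
  core <- coh$truth$sample_id[coh$truth$latent_class == "MABC_core"]
  ar <- coh$expression["AR", core]
  # every MABC_core sample's AR value is exactly baseline * 2^effect
  expect_true(all(ar == ar[1]))
  basal <- coh$truth$sample_id[coh$truth$latent_class == "basal"]
  expect_equal(unname(ar[1] / coh$expression["AR", basal[1]]), 2^3,
               tolerance = 1e-12)
  # housekeeping genes carry no effect anywhere
  expect_true(all(coh$expression["TBP", ] == coh$expression["TBP", 1]))
})

test_that("same config and seed reproduce the cohort bitwise", {
  cfg <- test_config()
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$expression, b$expression)
  expect_identical(a$alterations, b$alterations)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$expression, c$expression))
})

test_that("mixing weights sum to one and expression is strictly positive", {
  coh <- generate_cohort(test_config(), seed = 21)
  tot <- coh$truth$purity + coh$truth$immune_fraction +
    coh$truth$fibroblast_fraction
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(coh$expression > 0))
  expect_identical(coh$truth$is_mabc_lar_truth,
                   coh$truth$latent_class %in%
                     c("MABC_core", "MABC_HER2", "LAR_immune", "MABC_stromal"))
  # HER2 IHC is positive exactly where an ERBB2 amplification was planted
  amp <- coh$alterations$sample_id[coh$alterations$gene == "ERBB2" &
                                     coh$alterations$alteration_class == "amplification"]
  expect_setequal(coh$annotations$sample_id[coh$annotations$her2 == "positive"],
                  amp)
})

test_that("planted AR effect is recovered at its analytic expectation", {
  # E[log2 AR | class] - E[log2 AR | basal] = effect * E[purity_class]
  # (AR sits in no admixture profile, so only the purity-scaled tumour
  # profile contributes); with purity fixed at 1 the bare effect (3.0)
  # must be recovered.
  n <- c(MABC_core = 200, MABC_HER2 = 0, LAR_immune = 0, MABC_stromal = 0,
         basal = 200, luminalC_like = 0)
  cfg1 <- test_config(n, purity_beta = list(MABC_core = 1, MABC_HER2 = 1,
                                            LAR_immune = 1, MABC_stromal = 1,
                                            basal = 1, luminalC_like = 1))
  coh1 <- generate_cohort(cfg1, seed = 33)
  lg <- log2(coh1$expression["AR", ])
  cls <- coh1$truth$latent_class
  expect_lt(abs(mean(lg[cls == "MABC_core"]) - mean(lg[cls == "basal"]) - 3.0),
            0.15)

  cfg2 <- test_config(n)  # default Beta purity
  coh2 <- generate_cohort(cfg2, seed = 34)
  lg2 <- log2(coh2$expression["AR", ])
  cls2 <- coh2$truth$latent_class
  pb <- cfg2$purity_beta
  expected <- 3.0 * pb$MABC_core[1] / sum(pb$MABC_core)
  expect_lt(abs(mean(lg2[cls2 == "MABC_core"]) - mean(lg2[cls2 == "basal"]) -
                  expected), 0.15)
})

test_that("housekeeping log2 means are class-independent at n = 200", {
  n <- stats::setNames(rep(200L, 6), names(test_config()$n_per_class))
  coh <- generate_cohort(test_config(n), seed = 55)
  for (g in c("TBP", "RPL37A")) {
    means <- tapply(log2(coh$expression[g, ]), coh$truth$latent_class, mean)
    expect_lt(max(means) - min(means), 0.1)
  }
})

test_that("simulated CT values invert 2^-dCT exactly at zero noise", {
  cfg <- test_config(qpcr = list(ct_ref_base = 26, ct_noise_sd = 0,
                                 efficiency_range = c(1.01, 1.07),
                                 n_replicates = 2L))
  genes <- c("AR", "FOXA1", "SPDEF", "TFF3", "RPL37A")
  expr <- toy_expr(c(8, 2, 1, 0.5, 4,
                     4, 4, 4, 4, 4), genes, c("s1", "s2"))
  ct <- simulate_qpcr(expr, cfg)
  rq <- relative_quantity(ct)
  for (g in setdiff(genes, "RPL37A")) {
    expect_equal(rq$rq[rq$gene == g & rq$sample_id == "s1"],
                 unname(expr[g, "s1"] / expr["RPL37A", "s1"]),
                 tolerance = 1e-12)
  }
  # expr_g == reference -> dCT 0 -> quantity exactly 1
  expect_true(all(abs(rq$rq[rq$sample_id == "s2"] - 1) < 1e-12))
  expect_error(simulate_qpcr(expr[-1, ], cfg), "AR")
})

test_that("replicate-mean dCT noise matches the analytic variance", {
  # dCT = mean of n gene replicates - mean of n reference replicates;
  # with iid Normal(0, s) noise its sd is s * sqrt(2 / n)
  s <- 0.25; n_rep <- 2L
  cfg <- test_config(qpcr = list(ct_ref_base = 26, ct_noise_sd = s,
                                 efficiency_range = c(1.01, 1.07),
                                 n_replicates = n_rep))
  genes <- c("AR", "FOXA1", "SPDEF", "TFF3", "RPL37A")
  expr <- toy_expr(rep(16, 5 * 400), genes, sprintf("s%03d", 1:400))
  set.seed(99)
  ct <- simulate_qpcr(expr, cfg)
  rq <- relative_quantity(ct)
  dct <- -log2(rq$rq[rq$gene == "AR"])
  expect_lt(abs(stats::sd(dct) - s * sqrt(2 / n_rep)), 0.2 * s * sqrt(2 / n_rep))
})

test_that("alteration planting follows its Bernoulli rates", {
  truth <- data.frame(sample_id = sprintf("x%04d", 1:1000),
                      latent_class = "MABC_HER2", stringsAsFactors = FALSE)
  rates <- data.frame(gene = "ERBB2", alteration_class = "amplification",
                      latent_class = "MABC_HER2", rate = 1.0,
                      stringsAsFactors = FALSE)
  cfg <- test_config(alteration_rates = rates)
  alt <- plant_alterations(truth, cfg, seed = 1)
  expect_setequal(alt$sample_id, truth$sample_id)  # degenerate rate 1

  rates$rate <- 0
  expect_identical(nrow(plant_alterations(truth, test_config(alteration_rates = rates),
                                          seed = 1)), 0L)

  rates$rate <- 0.3
  alt <- plant_alterations(truth, test_config(alteration_rates = rates), seed = 2)
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(nrow(alt) / 1000 - 0.3), 3 * se)

  rates$rate <- 1.4
  expect_error(cohort_config(alteration_rates = rates), "\\[0, 1\\]")
})

test_that("degenerate and invalid configs are rejected", {
  expect_error(generate_cohort(test_config(stats::setNames(rep(0L, 6),
    names(test_config()$n_per_class)))), "empty cohort")
  expect_error(cohort_config(qpcr = list(ct_ref_base = 26, ct_noise_sd = 0.25,
                                         efficiency_range = c(0.5, 1.0),
                                         n_replicates = 2L)),
               "efficiency_range")
  panels <- default_gene_panels()
  panels$basal_markers <- c(panels$basal_markers, "AR")
  expect_error(cohort_config(gene_panels = panels), "disjoint")
})

test_that("written cohorts round-trip through the package readers", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(test_config(), seed = 77)
  write_cohort(coh, dir, seed = 78)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(unclass(expr)[, ], unclass(coh$expression)[, ], tolerance = 1e-9)
  ann <- read_sample_annotation(file.path(dir, "annotations.csv"))
  expect_identical(ann, coh$annotations)
  alt <- read_alteration_table(file.path(dir, "alterations.csv"))
  expect_identical(alt$sample_id, coh$alterations$sample_id)
  ct <- read_ct_table(file.path(dir, "ct.csv"))
  expect_identical(sort(unique(ct$gene)),
                   sort(c("AR", "FOXA1", "SPDEF", "TFF3", "RPL37A")))
})
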