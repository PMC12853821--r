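test_that("relative quantities implement 2^-dCT with replicate averaging", {
  ct <- ct_fixture("s1", list(AR = c(26, 26), RPL37A = c(26, 26)))
  expect_equal(relative_quantity(ct)$rq, 1, tolerance = 1e-12)

  ct <- ct_fixture("s1", list(AR = c(24, 24), RPL37A = c(26, 26)))
  expect_equal(relative_quantity(ct)$rq, 4, tolerance = 1e-12)

  # duplicates (25.0, 25.4) vs reference (27.0, 27.0): dCT = -1.8
  ct <- ct_fixture("s1", list(AR = c(25.0, 25.4), RPL37A = c(27.0, 27.0)))
  rq <- relative_quantity(ct)
  expect_equal(rq$rq, 2^1.8, tolerance = 1e-12)
  expect_equal(rq$replicate_spread, 0.4, tolerance = 1e-12)
  expect_false(rq$flagged)
  # discordant duplicates are flagged, not rejected
  ct <- ct_fixture("s1", list(AR = c(24.0, 25.0), RPL37A = c(26, 26)))
  expect_true(relative_quantity(ct)$flagged)

  # global pipetting shift: adding a constant to every CT of a sample cancels
  ct1 <- ct_fixture("s1", list(AR = c(24.1, 24.3), TFF3 = c(28, 28.2),
                               RPL37A = c(26, 26.4)))
  ct2 <- ct1; ct2$ct <- ct1$ct + 1.7
  expect_equal(relative_quantity(ct2)$rq, relative_quantity(ct1)$rq,
               tolerance = 1e-12)

  # all-Undetermined target gene: rq 0 by default, max-CT substitution optional
  ct <- ct_fixture("s1", list(AR = c(NA_real_, NA_real_), RPL37A = c(26, 26)))
  expect_identical(relative_quantity(ct)$rq, 0)
  expect_equal(relative_quantity(ct, undetermined = "max_ct", max_ct = 40)$rq,
               2^-14, tolerance = 1e-12)
  # Undetermined reference is an error for that sample
  ct <- ct_fixture("s1", list(AR = c(26, 26), RPL37A = c(NA_real_, NA_real_)))
  expect_error(relative_quantity(ct), "undetermined for sample")
})

test_that("ROC cut-off selection maximizes Youden J over midpoint candidates", {
  res <- select_cutoff_roc(c(2, 3, 4, 0, 1, 0.5),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$cutoff, 1.5, tolerance = 1e-12)
  expect_equal(res$youden_j, 1, tolerance = 1e-12)
  expect_equal(res$sensitivity, 1, tolerance = 1e-12)
  expect_equal(res$specificity, 1, tolerance = 1e-12)

  # perfectly interleaved values cannot beat J = 0
  v <- c(1, 2, 3, 4, 5, 6)
  l <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- select_cutoff_roc(v, l)
  expect_equal(res$youden_j, oracle_best_youden(v, l), tolerance = 1e-12)

  # label inversion symmetry: same J with sens/spec roles mirrored
  set.seed(31)
  v <- round(stats::rnorm(20, 5), 1)
  l <- rep(c(TRUE, FALSE), 10)
  a <- select_cutoff_roc(v, l)
  b <- select_cutoff_roc(-v, !l)
  expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)

  expect_error(select_cutoff_roc(1:6, rep(TRUE, 6)), "both classes")
  expect_error(select_cutoff_roc(1:6, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)),
               ">= 3 samples")
})

test_that("ROC cut-offs agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (i in 1:20) {
    v <- round(stats::rnorm(30, 5, 2), 1)
    l <- stats::runif(30) < 0.5
    if (sum(l) < 3 || sum(!l) < 3) next
    mine <- select_cutoff_roc(v, l)
    roc <- pROC::roc(response = l, predictor = v, quiet = TRUE,
                     direction = "<")
    best_j <- max(roc$sensitivities + roc$specificities - 1)
    expect_equal(mine$youden_j, best_j, tolerance = 1e-9)
  }
})

test_that("the vote classifier applies strict cut-offs and the >= 3 rule", {
  model <- qpcr_signature_model()
  rqs <- data.frame(sample_id = "s1",
                    gene = c("AR", "FOXA1", "SPDEF", "TFF3"),
                    rq = c(6, 30, 4, 0.5), stringsAsFactors = FALSE)
  expect_identical(classify_qpcr(rqs, model)$label, "MABC_LAR")

  # boundary values do not exceed strict cut-offs
  rqs$rq <- c(5.0, 24, 3, 1.0)
  expect_identical(classify_qpcr(rqs, model)$label, "negative")

  # all 16 exceed/not patterns equal the brute-force count rule
  for (mask in 0:15) {
    bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    rqs$rq <- ifelse(bits, model$cutoffs * 2, model$cutoffs / 2)
    got <- classify_qpcr(rqs, model)$label
    want <- oracle_vote(stats::setNames(rqs$rq, rqs$gene), model$cutoffs, 3L)
    expect_identical(got, want)
  }

  # monotone: raising any gene's quantity never flips positive to negative
  set.seed(43)
  for (i in 1:50) {
    rqs$rq <- stats::runif(4, 0, 2) * model$cutoffs
    before <- classify_qpcr(rqs, model)$label
    j <- sample(4, 1)
    rqs2 <- rqs; rqs2$rq[j] <- rqs2$rq[j] * 10
    after <- classify_qpcr(rqs2, model)$label
    expect_false(before == "MABC_LAR" && after == "negative")
  }

  expect_error(classify_qpcr(rqs[-1, ], model), "AR")
  expect_error(qpcr_signature_model(cutoffs = c(AR = -1, FOXA1 = 2, SPDEF = 1,
                                                TFF3 = 1)), "positive")
})

test_that("RNA-seq features are TBP-normalised log ratios", {
  genes <- c("AR", "FOXA1", "SPDEF", "TFF3", "TBP")
  expr <- toy_expr(c(4, 4, 4, 4, 4,
                     8, 2, 1, 16, 4), genes, c("s1", "s2"))
  f <- make_rnaseq_features(expr)
  expect_equal(unname(f["s1", ]), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(f["s2", "AR"]), log2(8.01 / 4.01), tolerance = 1e-12)

  # doubling every gene of a sample leaves the features unchanged (eps = 0)
  expr2 <- expr; expr2[, "s2"] <- expr[, "s2"] * 2
  f0 <- make_rnaseq_features(expr, eps = 0)
  f2 <- make_rnaseq_features(expr2, eps = 0)
  expect_equal(f2["s2", ], f0["s2", ], tolerance = 1e-12)

  expr3 <- expr; expr3["TBP", "s1"] <- 0
  expect_error(make_rnaseq_features(expr3, eps = 0), "TBP")
  expect_silent(make_rnaseq_features(expr3))
})

test_that("the forest classifier is seeded, memorizes, and recovers planted margins", {
  set.seed(47)
  n <- 400
  lab <- rep(c("MABC_LAR", "negative"), each = n / 2)
  # linearly separable planted features: margin >= 2 log2 units on every gene
  f <- matrix(stats::rnorm(n * 4, ifelse(lab == "MABC_LAR", 2, -1), 0.5),
              nrow = n, dimnames = list(sprintf("f%03d", 1:n),
                                        c("AR", "FOXA1", "SPDEF", "TFF3")))
  train <- seq(1, n, by = 2); test <- seq(2, n, by = 2)
  model <- train_forest(f[train, ], lab[train], n_trees = 200, seed = 7)
  calls <- predict_forest(model, f[test, ])
  cs <- evaluate_confusion(calls,
                           label_calls(stats::setNames(lab[test],
                                                       rownames(f)[test]), "GOLD"),
                           "MABC_LAR", "MABC_LAR")
  expect_gte(cs$sensitivity_pct, 95)
  expect_gte(cs$specificity_pct, 95)

  # determinism: same seed twice gives identical predictions
  model2 <- train_forest(f[train, ], lab[train], n_trees = 200, seed = 7)
  expect_identical(predict_forest(model2, f[test, ])$label, calls$label)

  # a single unlimited-depth tree memorizes its training set
  one <- train_forest(f[train, ], lab[train], n_trees = 1, seed = 9)
  expect_identical(predict_forest(one, f[train, ])$label, lab[train])

  expect_error(train_forest(f, rep("MABC_LAR", n)), "single class")
})

test_that("qPCR models round-trip through JSON and cut-off fitting drives the vote", {
  path <- withr::local_tempfile(fileext = ".json")
  model <- qpcr_signature_model(c(AR = 5, FOXA1 = 24, SPDEF = 3, TFF3 = 1),
                                min_positive = 3)
  write_qpcr_model(model, path)
  model2 <- read_qpcr_model(path)
  expect_equal(model2$cutoffs, model$cutoffs, tolerance = 1e-12)
  expect_identical(model2$min_positive, model$min_positive)

  # fit on cleanly separated rq values: fitted model classifies perfectly
  set.seed(53)
  n <- 40
  ids <- sprintf("q%02d", 1:n)
  truth <- stats::setNames(rep(c(TRUE, FALSE), each = n / 2), ids)
  rqs <- do.call(rbind, lapply(c("AR", "FOXA1", "SPDEF", "TFF3"), function(g) {
    data.frame(sample_id = ids, gene = g,
               rq = 2^stats::rnorm(n, ifelse(truth, 4, 0), 0.5),
               stringsAsFactors = FALSE)
  }))
  fit <- fit_qpcr_cutoffs(rqs, truth)
  expect_identical(nrow(fit$roc), 4L)
  calls <- classify_qpcr(rqs, fit$model)
  expect_identical(calls$label[match(ids, calls$sample_id)],
                   unname(ifelse(truth, "MABC_LAR", "negative")))
})
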