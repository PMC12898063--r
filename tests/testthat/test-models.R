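projection_128 <- function() {
  cached("proj128", function() hash_projection(1088, 128, seed = 8))
}

test_that("logistic and SVM classifiers separate a separable motif task", {
  windows <- separable_windows(n_per_class = 500, seed = 1)
  # independent check that the construction is separable: exact-match
  # detection of the planted 10-mer splits the classes perfectly
  motif_hits <- as.integer(grepl("TTTTCCGGAA", windows$sequence, fixed = TRUE))
  expect_equal(auroc(motif_hits, windows$label), 1)

  proj <- projection_128()
  logistic <- fit_rbp_logistic(windows, proj)
  acc_log <- mean((predict(logistic, windows) > 0.5) == (windows$label == 1))
  expect_gte(acc_log, 0.99)

  svm <- fit_rbp_svm(windows, proj)
  acc_svm <- mean((predict(svm, windows) > 0.5) == (windows$label == 1))
  expect_gte(acc_svm, 0.99)
})

test_that("label-permuted training gives chance-level held-out AUROC", {
  withr::with_seed(3, {
    windows <- separable_windows(n_per_class = 1000, seed = 30)
    windows$label <- sample(windows$label)
    train_idx <- sample(nrow(windows), 1500)
    model <- fit_rbp_logistic(windows[train_idx, ], projection_128())
    held_out <- evaluate_model(model, windows[-train_idx, ])
    expect_gte(held_out$auroc, 0.4)
    expect_lte(held_out$auroc, 0.6)
  })
})

test_that("uniform duplication of examples leaves the fit unchanged", {
  windows <- separable_windows(n_per_class = 100, seed = 2)
  single <- fit_rbp_logistic(windows, projection_128())
  doubled <- fit_rbp_logistic(
    dplyr::bind_rows(windows, windows), projection_128()
  )
  expect_equal(doubled$weights, single$weights, tolerance = 1e-6)
  expect_equal(doubled$bias, single$bias, tolerance = 1e-6)
})

test_that("single-class input is rejected", {
  windows <- separable_windows(n_per_class = 20, seed = 4)
  expect_error(
    fit_rbp_logistic(windows[windows$label == 1, ], projection_128()),
    "both classes"
  )
})

test_that("predict_window matches its definition and alphabet contract", {
  windows <- separable_windows(n_per_class = 50, width = 60, seed = 5)
  model <- fit_rbp_logistic(windows, projection_128())

  sequence <- windows$sequence[1]
  manual <- plogis(
    sum(hash_features(
      kmer_feature_vector(sequence), model$projection
    ) * model$weights) + model$bias
  )
  expect_equal(predict_window(model, sequence), manual, tolerance = 1e-12)

  with_u <- chartr("T", "U", sequence)
  expect_identical(predict_window(model, with_u), predict_window(model, sequence))

  zero_model <- model
  zero_model$weights <- numeric(length(model$weights))
  zero_model$bias <- 0
  expect_equal(predict_window(zero_model, sequence), 0.5)

  expect_error(predict_window(model, "ACGT"), "scan_rna")
})

test_that("SVM margins are linear in the features", {
  windows <- separable_windows(n_per_class = 50, width = 60, seed = 6)
  model <- fit_rbp_svm(windows, projection_128())
  x <- hash_features(kmer_feature_vector(windows$sequence[1]), model$projection)
  margin <- sum(x * model$weights) + model$bias
  # doubling the features doubles the affine part of the margin
  expect_equal(
    sum(2 * x * model$weights) + model$bias,
    2 * margin - model$bias
  )
  expect_equal(sign(predict(model, windows$sequence[1]) - 0.5), sign(margin))
})

test_that("logistic weights recover a known generative model", {
  proj <- projection_128()
  withr::with_seed(11, {
    sequences <- vapply(
      seq_len(5000), function(i) random_sequence(60), character(1)
    )
    x <- featurize_windows(sequences, kmer_space(), proj)
    true_weights <- rnorm(128, sd = 60)
    logits <- as.numeric(x %*% true_weights)
    logits <- logits - mean(logits)
    labels <- rbinom(5000, 1, plogis(logits))
    examples <- tibble::tibble(sequence = sequences, label = labels)
    model <- fit_rbp_logistic(examples, proj, l2_lambda = 1e-5)
    expect_gte(cor(model$weights, true_weights), 0.9)
  })
})

test_that("AUROC equals the brute-force pairwise oracle, ties included", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      label <- rbinom(n, 1, 0.5)
      if (length(unique(label)) < 2) next
      score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      expect_equal(auroc(score, label), auroc_oracle(score, label))
    }
  })
  expect_equal(
    auroc(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0)), 0.75
  )
})

test_that("threshold metrics match closed-form arithmetic", {
  perfect <- binding_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mcc, 1)

  # confusion TP=40, TN=30, FP=20, FN=10
  score <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 20), rep(0.1, 30))
  label <- c(rep(1, 50), rep(0, 50))
  metrics <- binding_metrics(score, label)
  expect_equal(metrics$balanced_accuracy, (0.8 + 0.6) / 2)
  expect_equal(metrics$mcc, (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40))
})

test_that("rank metrics are invariant under strictly monotone transforms", {
  withr::with_seed(10, {
    score <- runif(100)
    label <- rbinom(100, 1, 0.5)
    transformed <- plogis(5 * score - 2)
    expect_equal(auroc(score, label), auroc(transformed, label))
    expect_equal(
      pr_curve(score, label)[c("recall", "precision")],
      pr_curve(transformed, label)[c("recall", "precision")]
    )
  })
})

test_that("PR curves have non-decreasing recall", {
  withr::with_seed(12, {
    curve <- pr_curve(runif(200), rbinom(200, 1, 0.3))
    expect_true(all(diff(curve$recall) >= 0))
    expect_true(all(curve$precision >= 0 & curve$precision <= 1))
  })
})

test_that("stratified evaluation skips single-class strata with a warning", {
  windows <- separable_windows(n_per_class = 40, width = 60, seed = 13)
  model <- fit_rbp_logistic(windows, projection_128())
  windows$biotype <- c(
    rep("protein_coding", 40), rep(c("protein_coding", "lncRNA"), each = 20)
  )
  expect_warning(
    report <- evaluate_model(model, windows, strata_by = "biotype"),
    "single class"
  )
  expect_equal(report$stratum, "protein_coding")
  full <- evaluate_model(model, windows)
  expect_equal(full$n_pos, 40)

  gc_report <- suppressWarnings(
    evaluate_model(model, windows, strata_by = "gc_quartile")
  )
  expect_lte(nrow(gc_report), 4)
})
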