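test_that("PWM files round-trip with labels, headers and normalization", {
  pwm <- simulate_pwm("TGCATG")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  expect_equal(read_pwm(path), pwm, tolerance = 1e-6)

  # header row, U label and slightly off-normalized columns are accepted
  writeLines(c(
    paste(c("pos", 1:3), collapse = "\t"),
    "A\t0.7\t0.1\t0.1001",
    "C\t0.1\t0.7\t0.1",
    "G\t0.1\t0.1\t0.7",
    "U\t0.1\t0.1\t0.1"
  ), path)
  parsed <- read_pwm(path)
  expect_equal(rownames(parsed), c("A", "C", "G", "T"))
  expect_equal(colSums(parsed), rep(1, 3), ignore_attr = TRUE)

  writeLines(c("A\t0.5", "C\t0.1", "G\t0.1", "T\t0.1"), path)
  expect_error(read_pwm(path), "sum to 1")
})

test_that("k-mer PWM scores average products over valid alignments", {
  uniform <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(score_kmer_against_pwm(uniform, "AAA"), 0.25^3)

  acg <- simulate_pwm("ACG", sharpness = 1)
  expect_equal(score_kmer_against_pwm(acg, "ACG"), 1.0)
  expect_equal(score_kmer_against_pwm(acg, "AAA"), 0.0)

  # uniform L=4 except column 1 = (1,0,0,0): offsets 0 and 1 for "AAA"
  mixed <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  mixed[, 1] <- c(1, 0, 0, 0)
  expect_equal(
    score_kmer_against_pwm(mixed, "AAA"),
    (1 * 0.25 * 0.25 + 0.25^3) / 2
  )
  expect_equal(score_kmer_against_pwm(mixed, "AAA"), 0.0390625)

  expect_error(score_kmer_against_pwm(acg, "ACGT"), "exceeds")
})

test_that("PWM scoring matches brute-force alignment enumeration", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      len <- sample(3:10, 1)
      raw <- matrix(rgamma(4 * len, 1), 4, len)
      pwm <- sweep(raw, 2, colSums(raw), "/")
      rownames(pwm) <- c("A", "C", "G", "T")
      k <- sample(2:min(len, 6), 1)
      kmer <- random_sequence(k)
      codes <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
      brute <- mean(vapply(0:(len - k), function(offset) {
        prod(vapply(seq_len(k), function(j) pwm[codes[j], offset + j], numeric(1)))
      }, numeric(1)))
      expect_equal(score_kmer_against_pwm(pwm, kmer), brute)
      expect_gte(score_kmer_against_pwm(pwm, kmer), 0)
      expect_lte(score_kmer_against_pwm(pwm, kmer), 1)
    }
  })
})

ranking_fixture <- function(weights3 = NULL, weights5 = NULL) {
  if (is.null(weights3)) weights3 <- numeric(64)
  if (is.null(weights5)) weights5 <- numeric(1024)
  tibble::tibble(
    kmer = c(all_kmers(3), all_kmers(5)),
    k = rep(c(3L, 5L), c(64L, 1024L)),
    bin = NA_integer_,
    weight = c(weights3, weights5)
  )
}

test_that("k-mer rankings honor tie-breaking and disjointness", {
  equal_weights <- ranking_fixture()
  ranking <- rank_kmers(equal_weights, n3 = 5, n5 = 50)
  top3 <- ranking$kmer[ranking$side == "top" & ranking$k == 3]
  expect_equal(top3, all_kmers(3)[1:5]) # lexicographic tie rule
  bottom3 <- ranking$kmer[ranking$side == "bottom" & ranking$k == 3]
  expect_length(intersect(top3, bottom3), 0)

  spiked <- ranking_fixture(weights3 = c(rep(0, 40), 10, rep(0, 23)))
  spiked_ranking <- rank_kmers(spiked, n3 = 1, n5 = 1)
  expect_equal(
    spiked_ranking$kmer[spiked_ranking$side == "top" & spiked_ranking$k == 3],
    all_kmers(3)[41]
  )

  expect_error(rank_kmers(equal_weights, n3 = 64), "2n")
})

test_that("rankings are stable under sub-gap perturbations", {
  weights3 <- seq(1, 64) # gaps of 1
  base <- rank_kmers(ranking_fixture(weights3 = weights3), n3 = 5, n5 = 50)
  perturbed <- rank_kmers(
    ranking_fixture(weights3 = weights3 + runif(64, -0.4, 0.4)), n3 = 5, n5 = 50
  )
  expect_equal(
    base$kmer[base$k == 3 & base$side == "top"],
    perturbed$kmer[perturbed$k == 3 & perturbed$side == "top"]
  )
})

test_that("top-vs-bottom PWM comparison separates and degenerates correctly", {
  pwm <- simulate_pwm("TGCATG")
  # construct a ranking whose top k-mers are the PWM's own best scorers
  scores3 <- vapply(all_kmers(3), score_kmer_against_pwm, numeric(1), pwm = pwm)
  scores5 <- vapply(all_kmers(5), score_kmer_against_pwm, numeric(1), pwm = pwm)
  ranking <- rank_kmers(
    ranking_fixture(weights3 = scores3, weights5 = scores5), n3 = 5, n5 = 50
  )
  result <- compare_top_bottom_pwm(ranking, pwm)
  expect_gt(result$statistic, 0)
  expect_lt(result$p_value, 0.05)

  flat <- compare_top_bottom_pwm(
    rank_kmers(ranking_fixture(), n3 = 5, n5 = 50), pwm
  )
  expect_gt(flat$p_value, 0.2) # no separation
})

test_that("7-mer projection averages the eight constituent weights", {
  constant <- ranking_fixture(
    weights3 = rep(0.3, 64), weights5 = rep(0.3, 1024)
  )
  projected <- project_to_7mers(constant)
  expect_equal(nrow(projected), 16384)
  expect_true(all(abs(projected$score - 0.3) < 1e-12))

  zero <- project_to_7mers(ranking_fixture())
  expect_true(all(zero$score == 0))

  aaa_only <- ranking_fixture(weights3 = c(0.8, rep(0, 63)))
  projected_aaa <- project_to_7mers(aaa_only)
  expect_equal(
    projected_aaa$score[projected_aaa$kmer == "AAAAAAA"], 5 * 0.8 / 8
  )

  # linearity: projecting alpha * w equals alpha * projection(w)
  withr::with_seed(52, {
    random_map <- ranking_fixture(
      weights3 = rnorm(64), weights5 = rnorm(1024)
    )
    scaled <- random_map
    scaled$weight <- 3.7 * scaled$weight
    expect_equal(
      project_to_7mers(scaled)$score,
      3.7 * project_to_7mers(random_map)$score
    )
  })
})

test_that("correlation with 7-mer profiles behaves at the extremes", {
  withr::with_seed(53, {
    profile <- tibble::tibble(kmer = all_kmers(7), zscore = rnorm(16384))
  })
  self <- correlate_with_rnacompete(
    tibble::tibble(kmer = profile$kmer, score = profile$zscore), profile
  )
  expect_equal(self$spearman_rho, 1)
  flipped <- correlate_with_rnacompete(
    tibble::tibble(kmer = profile$kmer, score = -profile$zscore), profile
  )
  expect_equal(flipped$spearman_rho, -1)
  expect_warning(
    constant <- correlate_with_rnacompete(
      tibble::tibble(kmer = profile$kmer, score = 0), profile
    ),
    "undefined"
  )
  expect_true(is.na(constant$spearman_rho))
})

test_that("expression-quartile enrichment counts transcripts over threshold", {
  ranking <- rank_kmers(
    ranking_fixture(weights3 = c(10, rep(0, 63))), n3 = 1, n5 = 1
  )
  # 8 transcripts across 4 quartiles; one is 300 A's: 298 AAA occurrences
  transcripts <- tibble::tibble(
    gene_id = sprintf("g%d", 1:8),
    sequence = c(
      strrep("A", 300),
      vapply(2:8, function(i) random_sequence(300, c("C", "G", "T")),
             character(1))
    )
  )
  expression <- tibble::tibble(gene_id = transcripts$gene_id, count = 8:1)
  enrichment <- expression_quartile_enrichment(
    ranking, transcripts, expression, threshold = 50
  )
  # g1 has the highest count -> quartile Q4; only its "top" row is above
  above <- enrichment[enrichment$above > 0, ]
  expect_equal(nrow(above), 1)
  expect_equal(above$quartile, "Q4")
  expect_equal(above$side, "top")
  expect_equal(sum(enrichment$above + enrichment$at_or_below), 16)

  infinite <- expression_quartile_enrichment(
    ranking, transcripts, expression, threshold = Inf
  )
  expect_true(all(infinite$above == 0))

  # equal-length transcripts: per-kb mode ranks identically to raw mode
  raw <- expression_quartile_enrichment(
    ranking, transcripts, expression, threshold = 50
  )
  per_kb <- expression_quartile_enrichment(
    ranking, transcripts, expression, threshold = 50 / 0.3, per_kb = TRUE
  )
  expect_equal(raw$above > 0, per_kb$above > 0)
})

test_that("a trained model's top k-mers are more PWM-compatible than its bottom", {
  run <- cached("small_run_77", function() {
    run_synthetic_benchmark(
      seed = 77, config = small_benchmark_config(77), holdout = FALSE
    )
  })
  pwm <- standard_benchmark_pwm()
  ranking <- rank_kmers(run$weight_map, n3 = 5, n5 = 50)
  scores <- vapply(ranking$kmer, score_kmer_against_pwm, numeric(1), pwm = pwm)
  expect_gt(
    mean(scores[ranking$side == "top"]),
    5 * mean(scores[ranking$side == "bottom"])
  )
})

test_that("trained-model 7-mer projections correlate positively with the motif", {
  run <- cached("small_run_77", function() {
    run_synthetic_benchmark(
      seed = 77, config = small_benchmark_config(77), holdout = FALSE
    )
  })
  concordance <- correlate_with_rnacompete(
    project_to_7mers(run$weight_map),
    simulate_rnacompete_profile(standard_benchmark_pwm(), noise_sd = 0)
  )
  expect_gt(concordance$spearman_rho, 0)
  expect_lt(concordance$p_value, 1e-3)
})
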