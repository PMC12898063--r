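test_that("peak-derived 7-mer profiles use max signal and standardize", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAACCCCCCCGGGGGGG"))
  single_peak <- tibble::tibble(
    protein = "X", chrom = "chr1", start = 0L, end = 7L, strand = "+",
    fold_change = 2, neglog10_p = 3
  )
  profile <- eclip_7mer_profile(single_peak, genome)
  expect_equal(nrow(profile), 16384)
  expect_identical(profile$kmer[which.max(profile$zscore)], "AAAAAAA")
  expect_equal(mean(profile$zscore), 0, tolerance = 1e-9)
  expect_equal(sd(profile$zscore), 1, tolerance = 1e-9)
  # expected z-scores from the raw signal vector (6 at AAAAAAA, 0 elsewhere)
  raw <- numeric(16384)
  raw[1] <- 6
  expect_equal(profile$zscore, (raw - mean(raw)) / sd(raw))

  # two peaks with the same 7-mer: the max (10), not the mean (8), wins
  two_peaks <- dplyr::bind_rows(
    single_peak,
    dplyr::mutate(single_peak, fold_change = 5, neglog10_p = 2) # signal 10
  )
  profile_two <- eclip_7mer_profile(two_peaks, genome)
  raw_max <- numeric(16384)
  raw_max[1] <- 10
  expect_equal(profile_two$zscore, (raw_max - mean(raw_max)) / sd(raw_max))

  expect_error(eclip_7mer_profile(single_peak[0, ], genome), "Empty")
})

test_that("minus-strand peaks contribute reverse-complement 7-mers", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAAAAAACCCCCCCGGGGGGG"))
  minus_peak <- tibble::tibble(
    protein = "X", chrom = "chr1", start = 0L, end = 7L, strand = "-",
    fold_change = 2, neglog10_p = 3
  )
  profile <- eclip_7mer_profile(minus_peak, genome)
  expect_identical(profile$kmer[which.max(profile$zscore)], "TTTTTTT")
})

test_that("joint matrices concatenate consistently", {
  withr::with_seed(61, {
    features <- tibble::tibble(
      protein = c("P1", "P2", "P3"),
      f1 = rnorm(3), f2 = rnorm(3)
    )
    profiles <- purrr::map_dfr(c("P1", "P2", "P3"), function(p) {
      tibble::tibble(protein = p, kmer = all_kmers(7), zscore = rnorm(16384))
    })
  })
  joint <- build_joint_matrix(features, profiles)
  expect_equal(dim(joint$combined), c(3L, 2L + 16384L))
  expect_equal(joint$proteins, c("P1", "P2", "P3"))

  # permuting input rows permutes output rows identically
  permuted <- build_joint_matrix(features[c(3, 1, 2), ], profiles)
  expect_equal(permuted$combined[permuted$proteins == "P2", ],
               joint$combined[joint$proteins == "P2", ])

  zero_profiles <- dplyr::mutate(profiles, zscore = 0)
  zero_r <- build_joint_matrix(features, zero_profiles)
  expect_equal(
    sqrt(sum(zero_r$combined^2)), sqrt(sum(as.matrix(features[, -1])^2))
  )

  expect_error(
    build_joint_matrix(features[1:2, ], profiles), "P3"
  )
})

test_that("explained-norm curves follow the squared singular value convention", {
  rank1 <- outer(1:4, 1:3)
  curve <- svd_explained_norm(rank1)
  expect_equal(curve$explained[1], 1.0)

  identity5 <- diag(5)
  expect_equal(svd_explained_norm(identity5)$explained, (1:5) / 5)

  diag34 <- diag(c(3, 4))
  expect_equal(svd_explained_norm(diag34)$explained[1], 16 / 25)
  expect_equal(svd_explained_norm(diag34, squared = FALSE)$explained[1], 4 / 7)

  expect_error(svd_explained_norm(matrix(0, 3, 3)), "Zero matrix")
})

test_that("explained norm matches brute-force eigendecomposition of M'M", {
  withr::with_seed(62, {
    for (rep in 1:10) {
      n <- sample(3:20, 1)
      m <- sample(3:20, 1)
      mat <- matrix(rnorm(n * m), n, m)
      curve <- svd_explained_norm(mat)$explained
      eigenvalues <- sort(eigen(crossprod(mat), symmetric = TRUE,
                                only.values = TRUE)$values, decreasing = TRUE)
      eigenvalues <- pmax(eigenvalues, 0)[seq_along(curve)]
      expect_equal(curve, cumsum(eigenvalues) / sum(eigenvalues),
                   tolerance = 1e-8)
      expect_true(all(diff(curve) >= -1e-12))
      expect_equal(curve[length(curve)], 1.0)
    }
  })
})

test_that("random baselines match the target norm and end at 1", {
  baseline <- random_matrix_baseline(6, 40, target_norm = 12.5, n_reps = 20,
                                     seed = 63)
  curves <- attr(baseline, "curves")
  expect_equal(ncol(curves), 6)
  expect_true(all(abs(curves[, 6] - 1) < 1e-12))
  # rescaling is exact
  withr::with_seed(63, {
    m <- matrix(rnorm(6 * 40), 6, 40)
    m <- m * (12.5 / sqrt(sum(m^2)))
    expect_equal(sqrt(sum(m^2)), 12.5, tolerance = 1e-9)
  })
})

test_that("a planted low-rank matrix beats the random baseline", {
  withr::with_seed(64, {
    n <- 24
    m <- 2000
    low_rank <- matrix(rnorm(n * 3), n, 3) %*% matrix(rnorm(3 * m), 3, m)
    noisy <- low_rank + 0.05 * matrix(rnorm(n * m), n, m)
  })
  curve <- svd_explained_norm(noisy)
  expect_gte(curve$explained[3], 0.9)
  baseline <- random_matrix_baseline(
    n, m, target_norm = sqrt(sum(noisy^2)), n_reps = 30, seed = 65
  )
  expect_lt(baseline$mean[3], 0.25) # ~3/24 for random data
  expect_gt(curve$explained[3], baseline$q95[3])
})

test_that("latent cosine distances cover the canonical geometries", {
  coords <- rbind(
    c(1, 0, 0),
    c(1, 0, 0),   # identical -> distance 0
    c(0, 1, 0),   # orthogonal -> distance 1
    c(-1, 0, 0)   # antipodal -> distance 2
  )
  latent <- latent_space(coords, proteins = c("P1", "P2", "P3", "P4"))
  distances <- latent_cosine_distances(latent, r = 3)
  lookup <- function(a, b) {
    distances$distance[
      (distances$protein_a == a & distances$protein_b == b) |
        (distances$protein_a == b & distances$protein_b == a)
    ]
  }
  expect_equal(lookup("P1", "P2"), 0)
  expect_equal(lookup("P1", "P3"), 1)
  expect_equal(lookup("P1", "P4"), 2)
  expect_equal(nrow(distances), 6)

  # global positive scaling leaves cosine distances unchanged
  scaled <- latent_cosine_distances(latent_space(5 * coords), r = 3)
  expect_equal(scaled$distance, distances$distance)
})

test_that("W1 matches the brute-force optimal pairing on tiny samples", {
  withr::with_seed(66, {
    for (rep in 1:15) {
      n <- sample(2:8, 1)
      x <- round(runif(n), 3)
      y <- round(runif(n), 3)
      expect_equal(wasserstein1(x, y), w1_oracle(x, y))
    }
  })
  # translation property and point masses
  withr::with_seed(67, {
    x <- runif(40)
  })
  expect_equal(wasserstein1(x, x + 0.3), 0.3)
  expect_equal(wasserstein1(c(0, 0), c(1, 1)), 1)
  # unequal sizes via the CDF integral
  expect_equal(wasserstein1(c(0, 1), c(0.5)), 0.5)
})

test_that("space comparison returns W1 and rank correlations", {
  withr::with_seed(68, {
    d_a <- runif(45)
  })
  self <- compare_spaces(d_a, d_a)
  expect_equal(self$w1, 0)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$spearman_rho, 1)

  shifted <- compare_spaces(d_a, d_a + 0.3)
  expect_equal(shifted$w1, 0.3)
  expect_equal(shifted$pearson_r, 1)

  expect_error(compare_spaces(runif(5), runif(6)), "same length")
})
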