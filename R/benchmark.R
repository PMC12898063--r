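#' Configuration of the standard synthetic benchmark
#'
#' One 500-kb chromosome carrying 200 genes, a single protein with a sharp
#' 6-nt motif (consensus `TGCATG`), and expression-biased peak emission
#' with `bias_strength = 2`. This is the fixed reference condition used by
#' the package's end-to-end quality checks.
#'
#' @param seed Master seed.
#' @return A [synthetic_config()].
#' @export
standard_benchmark_config <- function(seed = 11) {
  synthetic_config(
    n_chromosomes = 1, chrom_length = 500000, n_genes = 200,
    bias_strength = 2, seed = seed
  )
}

#' @rdname standard_benchmark_config
#' @export
standard_benchmark_pwm <- function() {
  simulate_pwm("TGCATG", sharpness = 0.85)
}

# assign each region to the split part of its host gene (by midpoint);
# regions outside genes (intergenic negatives) are assigned at random in
# the split proportions
assign_regions_to_parts <- function(regions, gene_parts, fractions, seed) {
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  part <- rep(NA_character_, nrow(regions))
  for (chrom in unique(regions$chrom)) {
    here <- regions$chrom == chrom
    genes_here <- gene_parts[gene_parts$chrom == chrom, ]
    if (nrow(genes_here) == 0) {
      next
    }
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(mid[here] + 1L, mid[here] + 1L),
      as_iranges(genes_here),
      select = "first"
    )
    part[here] <- genes_here$part[hit]
  }
  orphan <- is.na(part)
  if (any(orphan)) {
    part[orphan] <- with_seed_if(seed, sample(
      names(fractions), sum(orphan), replace = TRUE, prob = fractions
    ))
  }
  regions$part <- part
  regions
}

#' Run the standard synthetic single-protein benchmark
#'
#' Simulates the benchmark bundle, samples 1:1 negatives, holds out a
#' fraction of genes (regions follow their host gene; intergenic negatives
#' are allotted proportionally at random, which leaks no sequence), trains
#' the logistic classifier on centered windows of the training regions and
#' evaluates on the held-out regions. Optionally fits the linear SVM
#' baseline on exactly the same data.
#'
#' @param seed Master seed; all internal seeds derive from it.
#' @param config A [synthetic_config()]; defaults to
#'   [standard_benchmark_config()] at this seed.
#' @param pwm Planted motif PWM; defaults to [standard_benchmark_pwm()].
#' @param out_dim Hashed feature dimension.
#' @param train_fraction Fraction of genes used for training.
#' @param svm Also fit the SVM baseline.
#' @param holdout If `FALSE`, train on everything and report training
#'   metrics (used for small interpretation-only runs).
#' @param protein Protein ID used in the bundle.
#' @return List with `model`, optional `svm_model`, `metrics` (held-out
#'   evaluation for each fitted model), `weight_map`, `bundle` and
#'   `projection`.
#' @export
run_synthetic_benchmark <- function(seed = 11, config = NULL, pwm = NULL,
                                    out_dim = 128, train_fraction = 0.75,
                                    svm = FALSE, holdout = TRUE,
                                    protein = "RBP1") {
  config <- config %||% standard_benchmark_config(seed)
  pwm <- pwm %||% standard_benchmark_pwm()
  pwms <- setNames(list(pwm), protein)
  bundle <- simulate_bundle(config, pwms)
  peaks <- bundle$peaks
  scheme <- window_scheme()
  negatives <- sample_negatives(
    peaks, bundle$genes, bundle$genome, ratio = 1.0, seed = seed + 10L,
    scheme = scheme
  )
  if (holdout) {
    fractions <- c(train = train_fraction, test = 1 - train_fraction)
    counts <- largest_remainder(nrow(bundle$genes), fractions)
    gene_parts <- with_seed_if(seed + 11L, {
      shuffled <- bundle$genes[sample.int(nrow(bundle$genes)), ]
      shuffled$part <- rep(names(fractions), counts)
      shuffled
    })
    positives <- assign_regions_to_parts(peaks, gene_parts, fractions, seed + 12L)
    negatives <- assign_regions_to_parts(negatives, gene_parts, fractions, seed + 13L)
  } else {
    positives <- dplyr::mutate(peaks, part = "train")
    negatives <- dplyr::mutate(negatives, part = "train")
  }
  windows <- dplyr::bind_rows(
    extract_windows(positives, bundle$genome, 1L, scheme, augment = FALSE),
    extract_windows(negatives, bundle$genome, 0L, scheme, augment = FALSE)
  )
  projection <- hash_projection(kmer_space()$total_dim, out_dim, seed = seed + 14L)
  train <- windows[windows$part == "train", ]
  test <- if (holdout) windows[windows$part == "test", ] else train
  model <- fit_rbp_logistic(train, projection, protein = protein)
  metrics <- dplyr::mutate(
    evaluate_model(model, test), model = "logistic", .before = 1
  )
  svm_model <- NULL
  if (svm) {
    svm_model <- fit_rbp_svm(train, projection, protein = protein)
    metrics <- dplyr::bind_rows(
      metrics,
      dplyr::mutate(
        evaluate_model(svm_model, test), model = "svm", .before = 1
      )
    )
  }
  list(
    model = model,
    svm_model = svm_model,
    metrics = metrics,
    weight_map = kmer_weight_map(model),
    bundle = bundle,
    projection = projection,
    train_n = nrow(train),
    test_n = nrow(test)
  )
}

#' A reduced benchmark condition for repeated simulation studies
#'
#' Same generative mechanism as the standard benchmark on a 60-kb
#' chromosome with 40 genes, small enough to train in well under a second
#' per replicate.
#'
#' @param seed Master seed.
#' @return A [synthetic_config()].
#' @export
small_benchmark_config <- function(seed) {
  synthetic_config(
    n_chromosomes = 1, chrom_length = 60000, n_genes = 40,
    motif_rate = 4, bias_strength = 2, seed = seed
  )
}
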