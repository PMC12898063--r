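#' Configuration for the synthetic CLIP benchmark generator
#'
#' The generator emulates the expression bias of immunoprecipitation assays:
#' motif instances are planted into gene bodies, but a peak is emitted over
#' an instance with probability that increases with the expression rank of
#' its gene. With `bias_strength = 0` emission is uniform across expression
#' quantiles; larger values concentrate peaks on highly expressed genes while
#' lowly expressed genes keep their (unobserved) planted sites.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in nt (>= 400).
#' @param n_genes Total number of genes tiled across chromosomes.
#' @param gene_length Length-2 integer range from which gene lengths are
#'   drawn uniformly.
#' @param expression_meanlog,expression_sdlog Log-normal law for per-gene
#'   expression counts (`sdlog >= 0`).
#' @param motif_rate Expected planted motif instances per gene (Poisson).
#' @param peak_rate Baseline probability that a planted instance is emitted
#'   as a peak (at the median expression quantile).
#' @param bias_strength Dimensionless >= 0; log-odds slope of peak emission
#'   in the expression quantile. 0 means no expression bias.
#' @param peak_extend Peak half-extension around a motif instance, nt.
#' @param embedding_dim Dimension of the stand-in protein embeddings.
#' @param noise_sd Noise standard deviation for embeddings and 7-mer
#'   affinity profiles.
#' @param biotype_props Named proportions for gene biotypes
#'   (`protein_coding`, `lncRNA`, `other`).
#' @param seed Integer master seed; every sub-generator derives its stream
#'   from it, so a fixed seed yields a byte-identical bundle.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 3, chrom_length = 100000,
                             n_genes = 60, gene_length = c(600, 1500),
                             expression_meanlog = 3, expression_sdlog = 1.5,
                             motif_rate = 5, peak_rate = 0.5,
                             bias_strength = 2, peak_extend = 30,
                             embedding_dim = 32, noise_sd = 0.1,
                             biotype_props = c(
                               protein_coding = 0.6, lncRNA = 0.3, other = 0.1
                             ),
                             seed = 1) {
  config <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    motif_rate = motif_rate,
    peak_rate = peak_rate,
    bias_strength = bias_strength,
    peak_extend = as.integer(peak_extend),
    embedding_dim = as.integer(embedding_dim),
    noise_sd = noise_sd,
    biotype_props = biotype_props / sum(biotype_props),
    seed = as.integer(seed)
  )
  if (config$n_chromosomes < 1L || config$n_genes < 1L || config$embedding_dim < 1L) {
    abort("All counts in the configuration must be >= 1.")
  }
  if (config$chrom_length < 400L) {
    abort("`chrom_length` must be >= 400 nt.")
  }
  if (config$expression_sdlog < 0 || config$noise_sd < 0 || config$bias_strength < 0) {
    abort("`expression_sdlog`, `noise_sd` and `bias_strength` must be >= 0.")
  }
  if (length(config$gene_length) != 2L || config$gene_length[1] > config$gene_length[2]) {
    abort("`gene_length` must be an increasing length-2 range.")
  }
  structure(config, class = "synthetic_config")
}

#' Simulate a sharp position weight matrix
#'
#' Each column puts `sharpness` probability on the consensus base and splits
#' the remainder evenly. Used to define the planted binding motif of a
#' synthetic protein.
#'
#' @param consensus Consensus sequence, e.g. `"TGCATG"`; defines the PWM
#'   length.
#' @param sharpness Probability of the consensus base per column, in (0.25, 1].
#' @return A 4 x L probability matrix with rows `A,C,G,T`.
#' @export
simulate_pwm <- function(consensus, sharpness = 0.85) {
  codes <- encode_bases(consensus)
  if (anyNA(codes)) {
    abort("`consensus` must be an ACGT/U string.")
  }
  len <- length(codes)
  pwm <- matrix((1 - sharpness) / 3, nrow = 4, ncol = len,
                dimnames = list(DNA_BASES, NULL))
  pwm[cbind(codes + 1L, seq_len(len))] <- sharpness
  pwm
}

#' Simulate a genome with non-overlapping annotated genes
#'
#' Background sequence is iid uniform over ACGT (the simplest null that
#' keeps planted motifs detectable). Genes are tiled without overlap,
#' separated by random intergenic gaps, and assigned a strand and a biotype.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (a named `DNAStringSet`) and `genes`
#'   (a tibble with `chrom, start, end, gene_id, strand, biotype`;
#'   coordinates 0-based half-open).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed_if(config$seed, {
    per_chrom <- largest_remainder(
      config$n_genes, rep(1 / config$n_chromosomes, config$n_chromosomes)
    )
    chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
    sequences <- vapply(
      chrom_names,
      function(chrom) {
        paste(sample(DNA_BASES, config$chrom_length, replace = TRUE), collapse = "")
      },
      character(1)
    )
    gene_rows <- purrr::map2(chrom_names, per_chrom, function(chrom, n_here) {
      if (n_here == 0L) {
        return(NULL)
      }
      lengths <- sample(config$gene_length[1]:config$gene_length[2], n_here,
                        replace = TRUE)
      slack <- config$chrom_length - sum(lengths)
      if (slack < n_here + 1L) {
        abort(sprintf(
          "chromosome length %d cannot host %d genes of length up to %d",
          config$chrom_length, n_here, config$gene_length[2]
        ))
      }
      weights <- runif(n_here + 1L)
      gaps <- floor(slack * weights / sum(weights))
      starts <- cumsum(c(gaps[1], lengths[-n_here] + gaps[2:n_here]))
      tibble(
        chrom = chrom,
        start = as.integer(starts),
        end = as.integer(starts + lengths),
        strand = sample(c("+", "-"), n_here, replace = TRUE),
        biotype = sample(names(config$biotype_props), n_here,
                         replace = TRUE, prob = config$biotype_props)
      )
    })
    genes <- dplyr::bind_rows(gene_rows)
    genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
    genes <- dplyr::select(
      genes, "gene_id", "chrom", "start", "end", "strand", "biotype"
    )
    list(genome = Biostrings::DNAStringSet(sequences), genes = genes)
  })
}

#' Simulate log-normal expression counts per gene
#'
#' @param genes Gene tibble from [simulate_genome()].
#' @param config A [synthetic_config()].
#' @param seed Seed for this draw; defaults to `config$seed + 1`.
#' @return Tibble with `gene_id` and `count`.
#' @export
simulate_expression <- function(genes, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed_if(seed, {
    tibble(
      gene_id = genes$gene_id,
      count = round(rlnorm(
        nrow(genes), config$expression_meanlog, config$expression_sdlog
      ))
    )
  })
}

#' Plant PWM motifs into gene bodies and emit expression-biased peaks
#'
#' For each protein, motif instances are sampled from its PWM into gene
#' bodies (on the gene strand). Every instance is recorded as ground truth;
#' a peak over an instance is emitted with probability
#' `plogis(qlogis(peak_rate) + bias_strength * (q - 0.5))` where `q` is the
#' expression quantile of the host gene. Peaks carry a log-normal fold
#' change and `-log10(p)` drawn in `[2, 10]` (mimicking significance-
#' thresholded peaks without modelling the replication filter).
#'
#' @param genome Named `DNAStringSet` from [simulate_genome()].
#' @param genes Gene tibble.
#' @param expression Expression tibble (`gene_id`, `count`) covering every
#'   gene.
#' @param pwms Named list of PWMs, one per protein.
#' @param config A [synthetic_config()].
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return A list with the modified `genome`, `peaks` (tibble with
#'   `protein, chrom, start, end, strand, fold_change, neglog10_p, gene_id`)
#'   and `truth` (every planted instance, peaked or not, with an `emitted`
#'   flag).
#' @export
plant_motifs_and_peaks <- function(genome, genes, expression, pwms, config,
                                   seed = config$seed + 2L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(names(pwms)) || any(!nzchar(names(pwms)))) {
    abort("`pwms` must be a named list: one PWM per protein.")
  }
  bad <- names(pwms)[!vapply(pwms, is.matrix, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("No PWM provided for protein(s): ", paste(bad, collapse = ", ")))
  }
  missing_expr <- setdiff(genes$gene_id, expression$gene_id)
  if (length(missing_expr) > 0) {
    abort(paste0("Expression missing for gene(s): ",
                 paste(head(missing_expr, 5), collapse = ", ")))
  }
  genes <- dplyr::left_join(genes, expression, by = "gene_id")
  genes$quantile <- rank(genes$count, ties.method = "average") / nrow(genes)
  chars <- setNames(as.character(genome), names(genome))

  with_seed_if(seed, {
    all_truth <- list()
    all_peaks <- list()
    for (protein in names(pwms)) {
      pwm <- validate_pwm(pwms[[protein]])
      width <- ncol(pwm)
      n_inst <- rpois(nrow(genes), config$motif_rate)
      rows <- rep(seq_len(nrow(genes)), n_inst)
      if (length(rows) == 0L) {
        next
      }
      host <- genes[rows, ]
      start <- host$start +
        floor(runif(length(rows)) * (host$end - host$start - width + 1L))
      # draw each instance from the PWM, base by base
      draws <- matrix(0L, nrow = length(rows), ncol = width)
      for (j in seq_len(width)) {
        draws[, j] <- sample.int(4L, length(rows), replace = TRUE, prob = pwm[, j])
      }
      motif_seq <- apply(draws, 1L, function(d) paste(DNA_BASES[d], collapse = ""))
      planted <- ifelse(host$strand == "-", reverse_complement(motif_seq), motif_seq)
      for (i in seq_along(rows)) {
        substr(chars[[host$chrom[i]]], start[i] + 1L, start[i] + width) <- planted[i]
      }
      emit_p <- plogis(
        qlogis(config$peak_rate) + config$bias_strength * (host$quantile - 0.5)
      )
      emitted <- rbinom(length(rows), 1L, emit_p) == 1L
      truth <- tibble(
        protein = protein,
        chrom = host$chrom,
        start = as.integer(start),
        end = as.integer(start + width),
        strand = host$strand,
        gene_id = host$gene_id,
        motif = motif_seq,
        emitted = emitted
      )
      peaks <- truth[truth$emitted, ]
      if (nrow(peaks) > 0) {
        host_peaks <- host[truth$emitted, ]
        peaks$start <- pmax(host_peaks$start, peaks$start - config$peak_extend)
        peaks$end <- pmin(host_peaks$end, peaks$end + config$peak_extend)
        peaks$fold_change <- rlnorm(nrow(peaks), meanlog = 1, sdlog = 0.5)
        peaks$neglog10_p <- 2 + 8 * rbeta(nrow(peaks), 1, 3)
      } else {
        peaks$fold_change <- numeric(0)
        peaks$neglog10_p <- numeric(0)
      }
      all_truth[[protein]] <- truth
      all_peaks[[protein]] <- dplyr::select(
        peaks, "protein", "chrom", "start", "end", "strand",
        "fold_change", "neglog10_p", "gene_id"
      )
    }
    list(
      genome = Biostrings::DNAStringSet(chars),
      peaks = dplyr::bind_rows(all_peaks),
      truth = dplyr::bind_rows(all_truth)
    )
  })
}

#' Simulate stand-in protein embeddings with controlled similarity
#'
#' Generates Gaussian vectors whose pairwise cosine similarity increases
#' with the supplied motif similarity (proteins with similar binding motifs
#' share latent factors). These are synthetic placeholders for protein
#' language-model embeddings consumed as input tables.
#'
#' @param proteins Character vector of protein IDs.
#' @param motif_similarity Optional symmetric matrix with unit diagonal
#'   (defaults to the identity: unrelated proteins).
#' @param dim Embedding dimension.
#' @param noise_sd Independent noise added per coordinate.
#' @param seed Integer seed.
#' @return Tibble with `protein` and `e1..e<dim>` columns.
#' @export
simulate_protein_embeddings <- function(proteins, motif_similarity = NULL,
                                        dim = 32, noise_sd = 0.1, seed = 1) {
  n <- length(proteins)
  if (is.null(motif_similarity)) {
    motif_similarity <- diag(n)
  }
  if (!isTRUE(all.equal(motif_similarity, t(motif_similarity))) ||
      !isTRUE(all.equal(unname(diag(motif_similarity)), rep(1, n)))) {
    abort("`motif_similarity` must be symmetric with unit diagonal.")
  }
  eig <- eigen(motif_similarity, symmetric = TRUE)
  loadings <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  with_seed_if(seed, {
    latent <- matrix(rnorm(n * dim), nrow = n, ncol = dim)
    vectors <- loadings %*% latent +
      noise_sd * matrix(rnorm(n * dim), nrow = n, ncol = dim)
    out <- as_tibble(vectors, .name_repair = ~ sprintf("e%d", seq_len(dim)))
    dplyr::bind_cols(tibble(protein = proteins), out)
  })
}

#' Simulate an RNAcompete-style 7-mer z-score profile from a PWM
#'
#' Scores every 7-mer against the PWM (position-averaged product of column
#' probabilities, sliding the shorter of the two over the longer), adds
#' Gaussian noise, and standardizes over the 16,384 entries. A degenerate
#' profile with zero spread standardizes to all zeros.
#'
#' @param pwm A 4 x L probability matrix (rows `A,C,G,T`).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return Tibble with `kmer` (all 16,384 7-mers, lexicographic) and
#'   `zscore`.
#' @export
simulate_rnacompete_profile <- function(pwm, noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  raw <- pwm_score_7mers(validate_pwm(pwm))
  if (noise_sd > 0) {
    raw <- raw + with_seed_if(seed, rnorm(length(raw), sd = noise_sd))
  }
  tibble(kmer = all_kmers(7), zscore = standardize_profile(raw))
}

standardize_profile <- function(x) {
  spread <- sd(x)
  if (!is.finite(spread) || spread == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / spread
}

#' Simulate a complete benchmark bundle
#'
#' Orchestrates the sub-generators under seeds derived from the master seed:
#' genome and annotation, expression, planted motifs with expression-biased
#' peaks, clustered protein embeddings (similarity taken from correlations
#' between the PWMs' 7-mer affinity profiles, floored at zero), and 7-mer
#' z-score tables per protein. Optionally writes everything to disk as
#' plain-text files.
#'
#' @param config A [synthetic_config()].
#' @param pwms Named list of PWMs, one per protein.
#' @param dir Optional output directory; see [write_bundle()].
#' @return A list of class `synthetic_bundle` with elements `genome`,
#'   `genes`, `expression`, `peaks`, `truth`, `embeddings`, `rnacompete`
#'   and `config`.
#' @export
simulate_bundle <- function(config, pwms, dir = NULL) {
  base <- simulate_genome(config)
  expression <- simulate_expression(base$genes, config)
  planted <- plant_motifs_and_peaks(
    base$genome, base$genes, expression, pwms, config
  )
  proteins <- names(pwms)
  scores <- vapply(
    pwms, function(p) pwm_score_7mers(validate_pwm(p)), numeric(16384)
  )
  similarity <- pmax(cor(scores), 0)
  diag(similarity) <- 1
  embeddings <- simulate_protein_embeddings(
    proteins, similarity,
    dim = config$embedding_dim, noise_sd = config$noise_sd,
    seed = config$seed + 3L
  )
  rnacompete <- purrr::imap(pwms, function(pwm, protein) {
    i <- match(protein, proteins)
    profile <- simulate_rnacompete_profile(
      pwm, noise_sd = config$noise_sd, seed = config$seed + 4L + i
    )
    dplyr::mutate(profile, protein = protein, .before = 1)
  })
  bundle <- structure(
    list(
      genome = planted$genome,
      genes = base$genes,
      expression = expression,
      peaks = planted$peaks,
      truth = planted$truth,
      embeddings = embeddings,
      rnacompete = dplyr::bind_rows(rnacompete),
      pwms = pwms,
      config = config
    ),
    class = "synthetic_bundle"
  )
  if (!is.null(dir)) {
    write_bundle(bundle, dir)
  }
  bundle
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes `genome.fa` (wrapped at 60 columns), `annotation.tsv` (BED6 plus a
#' biotype column), `expression.tsv`, one `peaks_<protein>.narrowPeak` per
#' protein (signalValue = fold change, pValue = -log10 p, qValue = peak =
#' -1), `embeddings.tsv`, `rnacompete.tsv` and `truth.tsv`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    bundle$genome, file.path(dir, "genome.fa"), width = 60
  )
  annotation <- dplyr::mutate(
    bundle$genes,
    score = 0L,
    .after = "end"
  )[, c("chrom", "start", "end", "gene_id", "score", "strand", "biotype")]
  readr::write_tsv(annotation, file.path(dir, "annotation.tsv"),
                   col_names = FALSE)
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  for (protein in unique(bundle$peaks$protein)) {
    write_narrowpeak(
      dplyr::filter(bundle$peaks, .data$protein == !!protein),
      file.path(dir, sprintf("peaks_%s.narrowPeak", protein))
    )
  }
  readr::write_tsv(bundle$embeddings, file.path(dir, "embeddings.tsv"))
  readr::write_tsv(bundle$rnacompete, file.path(dir, "rnacompete.tsv"))
  readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
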