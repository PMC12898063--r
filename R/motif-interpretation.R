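validate_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4L) {
    abort("A PWM must be a 4 x L matrix with rows A, C, G, T.")
  }
  if (is.null(rownames(pwm))) {
    rownames(pwm) <- DNA_BASES
  } else {
    rownames(pwm) <- chartr("U", "T", toupper(rownames(pwm)))
    if (!setequal(rownames(pwm), DNA_BASES)) {
      abort("PWM row labels must be A, C, G, T (or U for T).")
    }
    pwm <- pwm[DNA_BASES, , drop = FALSE]
  }
  if (any(pwm < 0)) {
    abort("PWM entries must be non-negative.")
  }
  sums <- colSums(pwm)
  if (any(abs(sums - 1) > 1e-3)) {
    abort("PWM columns must sum to 1 (tolerance 1e-3).")
  }
  sweep(pwm, 2, sums, "/")
}

#' Read / write a PWM as tab-separated text
#'
#' Accepts 4 rows by L columns of probabilities, an optional header row and
#' optional row labels `A/C/G/U|T`. Columns are validated to sum to 1
#' within 1e-3 and renormalized.
#'
#' @param path File path.
#' @return A 4 x L probability matrix with rows `A,C,G,T`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parse_row <- function(line) {
    fields <- strsplit(trimws(line), "[\t ]+")[[1]]
    label <- NA_character_
    if (toupper(fields[1]) %in% c("A", "C", "G", "T", "U")) {
      label <- chartr("U", "T", toupper(fields[1]))
      fields <- fields[-1]
    }
    values <- suppressWarnings(as.numeric(fields))
    list(label = label, values = values, numeric = !anyNA(values))
  }
  rows <- lapply(lines, parse_row)
  rows <- rows[vapply(rows, `[[`, logical(1), "numeric")] # drop header lines
  if (length(rows) != 4L) {
    abort("Expected exactly 4 numeric PWM rows.")
  }
  pwm <- do.call(rbind, lapply(rows, `[[`, "values"))
  labels <- vapply(rows, `[[`, character(1), "label")
  rownames(pwm) <- if (anyNA(labels)) DNA_BASES else labels
  validate_pwm(pwm)
}

#' @rdname read_pwm
#' @param pwm A 4 x L probability matrix.
#' @export
write_pwm <- function(pwm, path) {
  pwm <- validate_pwm(pwm)
  writeLines(
    vapply(DNA_BASES, function(base) {
      paste(c(base, format(pwm[base, ], digits = 6)), collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

#' Position-averaged PWM compatibility score of a k-mer
#'
#' Slides a window of length k across the PWM, takes the probability of
#' the k-mer at each of the `L - k + 1` alignments as the product of
#' nucleotide probabilities, and averages over alignments. The result is a
#' typical binding-compatibility score in `[0, 1]`, not a total expected
#' abundance.
#'
#' @param pwm A 4 x L probability matrix.
#' @param kmer Nucleotide string with `nchar(kmer) <= L`.
#' @return Numeric score in `[0, 1]`.
#' @examples
#' score_kmer_against_pwm(matrix(0.25, 4, 4), "AAA") # 0.25^3
#' @export
score_kmer_against_pwm <- function(pwm, kmer) {
  pwm <- validate_pwm(pwm)
  codes <- encode_bases(kmer)
  k <- length(codes)
  len <- ncol(pwm)
  if (k > len) {
    abort(sprintf("k-mer length %d exceeds PWM length %d.", k, len))
  }
  alignments <- vapply(0:(len - k), function(offset) {
    prod(pwm[cbind(codes + 1L, offset + seq_len(k))])
  }, numeric(1))
  mean(alignments)
}

# base-4 digit t (1 = most significant) of all 7-mer indices 0..16383
seven_mer_digit <- function(t) {
  (0:16383 %/% 4L^(7L - t)) %% 4L
}

# score all 16,384 7-mers against a PWM, sliding the shorter of the two
# over the longer (vectorized version of the alignment average)
pwm_score_7mers <- function(pwm) {
  pwm <- validate_pwm(pwm)
  len <- ncol(pwm)
  digits <- vapply(1:7, seven_mer_digit, numeric(16384)) # 16384 x 7
  total <- numeric(16384)
  if (len <= 7L) {
    offsets <- 0:(7L - len)
    for (offset in offsets) {
      prob <- rep(1, 16384)
      for (j in seq_len(len)) {
        prob <- prob * pwm[, j][digits[, offset + j] + 1L]
      }
      total <- total + prob
    }
  } else {
    offsets <- 0:(len - 7L)
    for (offset in offsets) {
      prob <- rep(1, 16384)
      for (j in 1:7) {
        prob <- prob * pwm[, offset + j][digits[, j] + 1L]
      }
      total <- total + prob
    }
  }
  total / length(offsets)
}

#' Top k-mers of a PWM
#'
#' Ranks all k-mers by [score_kmer_against_pwm()]; used e.g. to define the
#' consensus 3-mers a trained model is expected to recover.
#'
#' @param pwm A 4 x L probability matrix.
#' @param k k-mer length.
#' @param n Number of top k-mers to return.
#' @return Character vector of length `n`.
#' @export
top_pwm_kmers <- function(pwm, k, n = 5) {
  kmers <- all_kmers(k)
  scores <- vapply(kmers, score_kmer_against_pwm, numeric(1), pwm = pwm)
  kmers[order(-scores, kmers)][seq_len(n)]
}

#' Extract the top and bottom k-mers of a model by weight
#'
#' Within each k block, k-mers are sorted by weight (descending, ties
#' broken lexicographically); the first `n` form the top slice and the last
#' `n` the bottom slice, which are disjoint as long as `2n` does not exceed
#' the block size. Defaults extract 5 of 64 3-mers and 50 of 1024 5-mers;
#' use `n3 = n5 = 20` for the enrichment-style variant.
#'
#' @param weight_map A [kmer_weight_map()].
#' @param n3,n5 Slice sizes for the 3-mer and 5-mer blocks.
#' @return Tibble of class `kmer_ranking` with `kmer, k, weight, side,
#'   rank`.
#' @export
rank_kmers <- function(weight_map, n3 = 5, n5 = 50) {
  sizes <- c("3" = n3, "5" = n5)
  slices <- purrr::map(unique(weight_map$k), function(k) {
    block <- weight_map[weight_map$k == k, ]
    n <- sizes[[as.character(k)]]
    if (is.null(n)) {
      return(NULL)
    }
    if (n < 1 || 2 * n > nrow(block)) {
      abort(sprintf(
        "Need 1 <= n and 2n <= %d for the %d-mer block (got n = %d).",
        nrow(block), k, n
      ))
    }
    ordering <- order(-block$weight, block$kmer)
    top <- block[ordering[seq_len(n)], ]
    bottom <- block[rev(ordering)[seq_len(n)], ]
    dplyr::bind_rows(
      dplyr::mutate(top, side = "top", rank = seq_len(n)),
      dplyr::mutate(bottom, side = "bottom", rank = seq_len(n))
    )
  })
  out <- dplyr::bind_rows(slices)
  class(out) <- c("kmer_ranking", class(out))
  out
}

#' Rank-sum comparison of top versus bottom k-mers on a PWM
#'
#' Scores the top and bottom k-mer slices against the PWM and runs a
#' one-sided Wilcoxon rank-sum test (top > bottom). The returned
#' `statistic` is the rank-sum statistic centered at its null expectation,
#' so positive values mean the top k-mers are more PWM-compatible.
#'
#' @param ranking A [rank_kmers()] result.
#' @param pwm A 4 x L probability matrix for the same protein.
#' @return One-row tibble with `statistic, p_value, n_top, n_bottom,
#'   median_top, median_bottom`.
#' @export
compare_top_bottom_pwm <- function(ranking, pwm) {
  usable <- ranking[ranking$k <= ncol(pwm), ]
  score <- vapply(usable$kmer, score_kmer_against_pwm, numeric(1), pwm = pwm)
  top <- score[usable$side == "top"]
  bottom <- score[usable$side == "bottom"]
  test <- suppressWarnings(
    wilcox.test(top, bottom, alternative = "greater", exact = FALSE)
  )
  tibble(
    statistic = unname(test$statistic) - length(top) * length(bottom) / 2,
    p_value = test$p.value,
    n_top = length(top),
    n_bottom = length(bottom),
    median_top = median(top),
    median_bottom = median(bottom)
  )
}

#' Project 3-/5-mer model weights onto all 7-mers
#'
#' Each 7-mer contains five constituent 3-mers (offsets 0-4) and three
#' constituent 5-mers (offsets 0-2). The default `"pooled"` method scores
#' the 7-mer as the mean of those eight weights; `"per_k"` first averages
#' within each k and then averages the two block means. The projection is
#' linear in the weight map either way.
#'
#' @param weight_map A [kmer_weight_map()] over the default 3/5 space.
#' @param method `"pooled"` (single 8-term mean) or `"per_k"`.
#' @return Tibble with `kmer` (all 16,384 7-mers) and `score`.
#' @export
project_to_7mers <- function(weight_map, method = c("pooled", "per_k")) {
  method <- match.arg(method)
  if (!all(c(3L, 5L) %in% weight_map$k)) {
    abort("The weight map must contain 3-mer and 5-mer blocks.")
  }
  w3 <- weight_map$weight[weight_map$k == 3L]
  w5 <- weight_map$weight[weight_map$k == 5L]
  idx <- 0:16383
  sum3 <- numeric(16384)
  for (offset in 0:4) {
    sum3 <- sum3 + w3[((idx %/% 4L^(4L - offset)) %% 64L) + 1L]
  }
  sum5 <- numeric(16384)
  for (offset in 0:2) {
    sum5 <- sum5 + w5[((idx %/% 4L^(2L - offset)) %% 1024L) + 1L]
  }
  score <- if (method == "pooled") {
    (sum3 + sum5) / 8
  } else {
    (sum3 / 5 + sum5 / 3) / 2
  }
  tibble(kmer = all_kmers(7), score = score)
}

#' Spearman correlation with an RNAcompete-style 7-mer profile
#'
#' Correlates projected model scores with 7-mer z-scores across all 16,384
#' 7-mers. A constant input leaves the correlation undefined and is
#' reported as `NA`.
#'
#' @param projected [project_to_7mers()] output (or a numeric vector in
#'   lexicographic 7-mer order).
#' @param zscores A 7-mer profile tibble (`kmer`, `zscore`) or numeric
#'   vector.
#' @return One-row tibble with `spearman_rho, p_value, n`.
#' @export
correlate_with_rnacompete <- function(projected, zscores) {
  as_profile_vector <- function(x, value_cols) {
    if (is.data.frame(x)) {
      col <- intersect(value_cols, names(x))[1]
      x[[col]][match(all_kmers(7), x$kmer)]
    } else {
      x
    }
  }
  a <- as_profile_vector(projected, c("score", "zscore"))
  b <- as_profile_vector(zscores, c("zscore", "score"))
  if (length(a) != length(b)) {
    abort("Profiles must have the same length.")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    warn("Constant profile: Spearman correlation undefined.")
    return(tibble(spearman_rho = NA_real_, p_value = NA_real_, n = length(a)))
  }
  test <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  tibble(
    spearman_rho = unname(test$estimate),
    p_value = test$p.value,
    n = length(a)
  )
}

#' Expression-quartile enrichment of top/bottom k-mers in transcripts
#'
#' For each expression quartile (Q1 lowest) and each ranking side, counts
#' transcripts whose total occurrence count of that side's k-mers
#' (overlapping occurrences) exceeds the threshold. With `per_kb = TRUE`
#' counts are divided by transcript length in kb before thresholding
#' (the gene-length-normalized variant).
#'
#' @param ranking A [rank_kmers()] result.
#' @param transcripts Tibble with `gene_id` and `sequence`.
#' @param expression Counts tibble (`gene_id`, `count`) covering every
#'   transcript.
#' @param threshold Occurrence-count threshold (default 50).
#' @param per_kb Normalize counts per kilobase of transcript.
#' @return Tibble with `quartile, side, above, at_or_below` (zero rows for
#'   empty quartiles are kept).
#' @export
expression_quartile_enrichment <- function(ranking, transcripts, expression,
                                           threshold = 50, per_kb = FALSE) {
  missing <- setdiff(transcripts$gene_id, expression$gene_id)
  if (length(missing) > 0) {
    abort(paste0("Expression missing for: ", paste(head(missing, 5), collapse = ", ")))
  }
  expr <- expression[match(transcripts$gene_id, expression$gene_id), ]
  quartile <- sprintf(
    "Q%d", dplyr::ntile(rank(expr$count, ties.method = "first"), 4)
  )
  sides <- unique(ranking$side)
  rows <- purrr::map(sides, function(side_name) {
    kmer_set <- ranking[ranking$side == side_name, ]
    hits <- vapply(transcripts$sequence, function(seq_i) {
      total <- 0
      for (k in unique(kmer_set$k)) {
        counts <- count_kmers(seq_i, k)
        total <- total + sum(counts[kmer_set$kmer[kmer_set$k == k]])
      }
      if (per_kb) total / (nchar(seq_i) / 1000) else total
    }, numeric(1), USE.NAMES = FALSE)
    tibble(
      quartile = quartile,
      side = side_name,
      above = hits > threshold
    )
  })
  counted <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$quartile, .data$side),
    n_above = sum(.data$above),
    at_or_below = dplyr::n() - .data$n_above,
    .groups = "drop"
  )
  counted <- dplyr::rename(counted, above = "n_above")
  tidyr::complete(
    counted,
    quartile = sprintf("Q%d", 1:4),
    side = sides,
    fill = list(above = 0L, at_or_below = 0L)
  )
}
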