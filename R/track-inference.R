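#' Sliding-window binding-probability track along an RNA
#'
#' Traverses the RNA with a fixed window (default 200 nt) and stride
#' (default 50 nt), predicting one binding probability per window. When the
#' last regular stride does not reach the 3' end, an extra right-anchored
#' window ending at the final nucleotide is appended so the whole molecule
#' is covered (disable with `tail_window = FALSE` for a strict stride).
#'
#' @param model A fitted single-protein model (`rbp_logistic` / `rbp_svm`).
#' @param sequence RNA sequence of length >= the model window.
#' @param step Stride in nt.
#' @param rna Optional RNA identifier stored on the track.
#' @param tail_window Append the right-anchored final window when needed.
#' @return Tibble of class `rbp_track` with `start, end, probability`
#'   (0-based half-open bins).
#' @export
scan_rna <- function(model, sequence, step = 50, rna = NULL,
                     tail_window = TRUE) {
  window <- model$window
  len <- nchar(sequence)
  if (len < window) {
    abort(sprintf(
      paste0(
        "Sequence length %d is below the %d-nt window; pad the RNA or call ",
        "predict_window() on a centered genomic slice instead."
      ),
      len, window
    ))
  }
  offsets <- seq.int(0L, len - window, by = step)
  if (tail_window && offsets[length(offsets)] != len - window) {
    offsets <- c(offsets, len - window)
  }
  windows <- substring(sequence, offsets + 1L, offsets + window)
  track <- tibble(
    start = as.integer(offsets),
    end = as.integer(offsets + window),
    probability = predict(model, windows)
  )
  attr(track, "rna") <- rna
  attr(track, "window") <- window
  attr(track, "step") <- as.integer(step)
  class(track) <- c("rbp_track", class(track))
  track
}

#' Aggregate an overlapping-window track to per-nucleotide values
#'
#' Each nucleotide receives the mean probability over all windows covering
#' it — the representation used for bedGraph-style export.
#'
#' @param track An `rbp_track`.
#' @return Tibble with `position` (0-based) and `probability`.
#' @export
track_per_nucleotide <- function(track) {
  len <- max(track$end)
  total <- numeric(len)
  cover <- numeric(len)
  for (i in seq_len(nrow(track))) {
    span <- (track$start[i] + 1L):track$end[i]
    total[span] <- total[span] + track$probability[i]
    cover[span] <- cover[span] + 1
  }
  tibble(
    position = 0:(len - 1L),
    probability = ifelse(cover > 0, total / cover, NA_real_)
  )
}

#' Map model weights back to k-mers
#'
#' Every k-mer inherits the weight of its hash bin, so k-mers colliding in
#' the same bin report equal weights (the price of hashing, recorded in the
#' `bin` column). With an identity/permutation projection the original
#' weights are recovered exactly.
#'
#' @param model A fitted `rbp_logistic` or `rbp_svm`.
#' @return Tibble of class `kmer_weight_map` with one row per k-mer of the
#'   model space (`kmer, k, bin, weight`; 1088 rows for the default space).
#' @export
kmer_weight_map <- function(model) {
  space <- model$space
  kmers <- unlist(lapply(space$ks, all_kmers))
  k <- rep(space$ks, space$block_dims)
  bins <- model$projection$bins
  out <- tibble(
    kmer = kmers,
    k = as.integer(k),
    bin = bins,
    weight = model$weights[bins]
  )
  class(out) <- c("kmer_weight_map", class(out))
  out
}

weight_lookup <- function(weight_map, k) {
  rows <- weight_map[weight_map$k == k, ]
  setNames(rows$weight, rows$kmer)
}

#' Score a region by its k-mer content
#'
#' The score of a region is the sum of model-inferred weights of the
#' k-mers present in it. By default presence is read as *distinct*
#' presence (set semantics); `mode = "occurrence"` weights each k-mer by
#' its occurrence count instead.
#'
#' @param weight_map A [kmer_weight_map()] (or any tibble with
#'   `kmer, k, weight`).
#' @param sequence Nucleotide string.
#' @param mode `"presence"` or `"occurrence"`.
#' @return A single numeric score.
#' @export
score_region <- function(weight_map, sequence,
                         mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  if (nrow(weight_map) == 0) {
    return(0)
  }
  total <- 0
  for (k in unique(weight_map$k)) {
    weights <- weight_lookup(weight_map, k)
    counts <- count_kmers(sequence, k)[names(weights)]
    counts[is.na(counts)] <- 0
    contribution <- if (mode == "presence") {
      sum(weights[counts > 0])
    } else {
      sum(weights * counts)
    }
    total <- total + contribution
  }
  total
}

#' Compare two peak sets by overlap class and model score
#'
#' Classifies peaks as `common` (>= 1 bp intersection with a peak of the
#' other set) or exclusive to their own set, scores every peak's sequence
#' with [score_region()], and summarizes the per-group score
#' distributions. Swapping the two sets swaps the exclusive labels and
#' preserves the common class.
#'
#' @param set_a,set_b Peak tibbles on the same genome coordinates.
#' @param weight_map A [kmer_weight_map()].
#' @param genome Named `DNAStringSet`.
#' @param names_ab Labels for the two sets (used in `source`).
#' @return List with `scores` (per-peak tibble with `source`) and
#'   `summary` (per-group n, mean, median, quartiles).
#' @export
compare_peak_sets <- function(set_a, set_b, weight_map, genome,
                              names_ab = c("a", "b")) {
  classify <- function(peaks, others, own, other_name) {
    hit <- logical(nrow(peaks))
    for (chrom in unique(peaks$chrom)) {
      here <- peaks$chrom == chrom
      there <- others$chrom == chrom
      if (!any(there)) {
        next
      }
      hit[here] <- IRanges::countOverlaps(
        as_iranges(peaks[here, ]), as_iranges(others[there, ])
      ) > 0
    }
    dplyr::mutate(
      peaks,
      set = own,
      source = ifelse(hit, "common", paste0(own, "-only"))
    )
  }
  labeled <- dplyr::bind_rows(
    classify(set_a, set_b, names_ab[1], names_ab[2]),
    classify(set_b, set_a, names_ab[2], names_ab[1])
  )
  labeled$score <- vapply(seq_len(nrow(labeled)), function(i) {
    seq_i <- extract_sequences(
      genome[[labeled$chrom[i]]],
      labeled$start[i], labeled$end[i], labeled$strand[i]
    )
    score_region(weight_map, seq_i)
  }, numeric(1))
  summary <- dplyr::summarise(
    dplyr::group_by(labeled, .data$source),
    n = dplyr::n(),
    mean = mean(.data$score),
    median = median(.data$score),
    q25 = quantile(.data$score, 0.25),
    q75 = quantile(.data$score, 0.75),
    .groups = "drop"
  )
  list(scores = labeled, summary = summary)
}
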