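#' Window and augmentation scheme
#'
#' Windows are 200 nt; inference scans with a 50-nt step. Training examples
#' are augmented by shifting the window around the region midpoint from -15
#' to +15 nt: in 1-nt increments for the positive class (31 windows per
#' region) and 5-nt increments for the negative class (7 windows per
#' region).
#'
#' @param window Window length, nt.
#' @param step_scan Scanning stride for track inference, nt.
#' @param shift_range Maximum window shift magnitude for augmentation, nt.
#' @param pos_shift_step,neg_shift_step Shift increments for the positive
#'   and negative classes, nt.
#' @return An object of class `window_scheme`.
#' @export
window_scheme <- function(window = 200, step_scan = 50, shift_range = 15,
                          pos_shift_step = 1, neg_shift_step = 5) {
  scheme <- list(
    window = as.integer(window),
    step_scan = as.integer(step_scan),
    shift_range = as.integer(shift_range),
    pos_shift_step = as.integer(pos_shift_step),
    neg_shift_step = as.integer(neg_shift_step)
  )
  if (scheme$window < 1L || scheme$step_scan < 1L || scheme$shift_range < 0L) {
    abort("window and step_scan must be positive; shift_range non-negative.")
  }
  structure(scheme, class = "window_scheme")
}

scheme_shifts <- function(scheme, label) {
  step <- if (label == 1L) scheme$pos_shift_step else scheme$neg_shift_step
  if (scheme$shift_range == 0L) {
    return(0L)
  }
  seq.int(-scheme$shift_range, scheme$shift_range, by = step)
}

#' Read peaks from a narrowPeak / BED6+ file
#'
#' Parses `chrom, start, end, name, score, strand` plus, when present,
#' `signalValue` (column 7, stored as `fold_change`) and `pValue`
#' (column 8, `-log10 p`, stored as `neglog10_p`). Missing extra columns
#' default to 1.0 / 0.0 with a warning. Records with `start >= end` are
#' rejected and counted; an unparseable line raises an error naming the
#' line number.
#'
#' @param path Path to a tab-separated narrowPeak or BED6+ file.
#' @param protein Optional protein ID attached to every peak; defaults to
#'   the name column of the file.
#' @return Tibble with `protein, chrom, start, end, strand, fold_change,
#'   neglog10_p` (0-based half-open coordinates).
#' @export
read_peaks <- function(path, protein = NULL) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_cols <- lengths(fields)
  if (any(n_cols < 6L)) {
    abort(sprintf("Line %d has fewer than 6 columns.", which(n_cols < 6L)[1]))
  }
  pull_col <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.integer(pull_col(2)))
  end <- suppressWarnings(as.integer(pull_col(3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf(
      "Line %d: start/end are not integers.", which(is.na(start) | is.na(end))[1]
    ))
  }
  has_signal <- all(n_cols >= 7L)
  has_pvalue <- all(n_cols >= 8L)
  if (!has_signal) {
    warn("No signalValue column; fold_change defaults to 1.0.")
  }
  if (!has_pvalue) {
    warn("No pValue column; neglog10_p defaults to 0.0.")
  }
  peaks <- tibble(
    protein = protein %||% pull_col(4),
    chrom = pull_col(1),
    start = start,
    end = end,
    strand = pull_col(6),
    fold_change = if (has_signal) as.numeric(pull_col(7)) else 1.0,
    neglog10_p = if (has_pvalue) as.numeric(pull_col(8)) else 0.0
  )
  invalid <- peaks$start >= peaks$end
  if (any(invalid)) {
    message(sprintf("Rejected %d record(s) with start >= end.", sum(invalid)))
  }
  peaks[!invalid, ]
}

#' Write peaks as a narrowPeak (BED6+4) file
#'
#' Columns: chrom, start, end, name (protein), score, strand,
#' signalValue (fold change), pValue (-log10 p), qValue = -1, peak = -1.
#'
#' @param peaks Peak tibble with `chrom, start, end, strand, fold_change,
#'   neglog10_p` and optionally `protein`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = peaks$protein %||% ".",
    score = 0L,
    strand = peaks$strand,
    signalValue = peaks$fold_change,
    pValue = peaks$neglog10_p,
    qValue = -1,
    peak = -1L
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (BED6 + biotype)
#'
#' @param path Tab-separated file with columns chrom, start, end, gene_id,
#'   score, strand, biotype and no header.
#' @return Tibble with `gene_id, chrom, start, end, strand, biotype`.
#' @export
read_annotation <- function(path) {
  cols <- c("chrom", "start", "end", "gene_id", "score", "strand", "biotype")
  genes <- readr::read_tsv(
    path,
    col_names = cols,
    col_types = readr::cols(
      chrom = "c", start = "i", end = "i", gene_id = "c",
      score = "i", strand = "c", biotype = "c"
    )
  )
  genes[, c("gene_id", "chrom", "start", "end", "strand", "biotype")]
}

# 0-based half-open tibble coordinates -> 1-based closed IRanges
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Sample negative regions for one protein
#'
#' Candidate negatives are 200-nt windows tiled over (a) intergenic space
#' and (b) bodies of peak-bearing genes outside any peak of the protein.
#' Every candidate keeps a `slack` (default: the augmentation shift range)
#' clearance from all peaks, so no augmented negative window can touch a
#' peak. Candidates are subsampled to `ratio` times the number of positive
#' regions under `seed`.
#'
#' @param peaks Peak tibble for a single protein.
#' @param genes Gene annotation tibble.
#' @param genome Named `DNAStringSet` (used for chromosome lengths).
#' @param ratio Negative:positive region ratio (default 1.0).
#' @param seed Integer seed for the subsample.
#' @param scheme A [window_scheme()]; provides window length and slack.
#' @param tile_step Stride between candidate windows, nt.
#' @return Tibble with `chrom, start, end, strand` (0-based half-open).
#' @export
sample_negatives <- function(peaks, genes, genome, ratio = 1.0, seed = 1,
                             scheme = window_scheme(), tile_step = 50L) {
  if (length(unique(peaks$protein)) > 1L) {
    abort("`peaks` must come from a single protein.")
  }
  window <- scheme$window
  slack <- scheme$shift_range
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  candidates <- purrr::map(names(genome), function(chrom) {
    len <- chrom_lengths[[chrom]]
    genes_here <- genes[genes$chrom == chrom, ]
    peaks_here <- peaks[peaks$chrom == chrom, ]
    peak_ranges <- as_iranges(peaks_here)
    grown_peaks <- if (length(peak_ranges) > 0) {
      IRanges::reduce(peak_ranges + slack)
    } else {
      IRanges::IRanges()
    }
    gene_ranges <- as_iranges(genes_here)
    intergenic <- IRanges::setdiff(
      IRanges::IRanges(1L, len),
      IRanges::reduce(c(gene_ranges, grown_peaks))
    )
    bearing <- IRanges::countOverlaps(gene_ranges, peak_ranges) > 0
    in_gene <- IRanges::setdiff(
      IRanges::reduce(gene_ranges[bearing]), grown_peaks
    )
    tile_runs <- function(runs, strand_of) {
      rows <- purrr::map(seq_along(runs), function(i) {
        run_start <- IRanges::start(runs)[i] - 1L # back to 0-based
        run_end <- IRanges::end(runs)[i]
        if (run_end - run_start < window) {
          return(NULL)
        }
        starts <- seq.int(run_start, run_end - window, by = tile_step)
        tibble(
          chrom = chrom, start = as.integer(starts),
          end = as.integer(starts + window),
          strand = strand_of(starts)
        )
      })
      dplyr::bind_rows(rows)
    }
    strand_plus <- function(starts) rep("+", length(starts))
    strand_gene <- function(starts) {
      mid <- starts + window %/% 2L
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(mid + 1L, mid + 1L), gene_ranges, select = "first"
      )
      ifelse(is.na(hit), "+", genes_here$strand[hit])
    }
    dplyr::bind_rows(
      tile_runs(intergenic, strand_plus),
      tile_runs(in_gene, strand_gene)
    )
  })
  candidates <- dplyr::bind_rows(candidates)
  n_needed <- round(ratio * nrow(peaks))
  if (nrow(candidates) < n_needed) {
    abort(sprintf(
      "Insufficient negative candidate space: need %d windows, found %d.",
      n_needed, nrow(candidates)
    ))
  }
  with_seed_if(seed, {
    candidates[sort(sample.int(nrow(candidates), n_needed)), ]
  })
}

#' Extract fixed-length windows around region midpoints
#'
#' The 200-nt window is centered on the region midpoint and shifted over
#' the augmentation range of the scheme: -15..+15 in 1-nt steps for
#' positives (31 windows) and 5-nt steps for negatives (7 windows). Shifts
#' that would leave the chromosome are dropped (never clamped), preserving
#' the window-length invariant. Minus-strand regions are
#' reverse-complemented.
#'
#' @param regions Tibble with `chrom, start, end, strand` and optionally
#'   `protein` / `gene_id` columns, carried through.
#' @param genome Named `DNAStringSet`.
#' @param label 1 (positive) or 0 (negative).
#' @param scheme A [window_scheme()].
#' @param augment If `FALSE`, only the centered (shift 0) window is
#'   extracted.
#' @return Tibble with `sequence, label, chrom, start, end, strand, shift`
#'   plus carried columns.
#' @export
extract_windows <- function(regions, genome, label, scheme = window_scheme(),
                            augment = TRUE) {
  label <- as.integer(label)
  stopifnot(label %in% c(0L, 1L))
  unknown <- setdiff(unique(regions$chrom), names(genome))
  if (length(unknown) > 0) {
    abort(paste0("Unknown chromosome(s): ", paste(unknown, collapse = ", ")))
  }
  shifts <- if (augment) scheme_shifts(scheme, label) else 0L
  window <- scheme$window
  half <- window %/% 2L
  carried <- intersect(c("protein", "gene_id", "biotype", "part"), names(regions))
  regions <- dplyr::mutate(
    regions,
    .center = .data$start + (.data$end - .data$start) %/% 2L,
    .region_id = dplyr::row_number()
  )
  expanded <- tidyr::expand_grid(regions, shift = as.integer(shifts))
  expanded <- dplyr::mutate(
    expanded,
    win_start = .data$.center - half + .data$shift,
    win_end = .data$win_start + window
  )
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  expanded <- dplyr::filter(
    expanded,
    .data$win_start >= 0L, .data$win_end <= chrom_lengths[.data$chrom]
  )
  parts <- dplyr::group_split(expanded, .data$chrom)
  sequences <- purrr::map(parts, function(part) {
    chrom_seq <- genome[[part$chrom[1]]]
    part$sequence <- extract_sequences(
      chrom_seq, part$win_start, part$win_end, part$strand
    )
    part
  })
  out <- dplyr::arrange(
    dplyr::bind_rows(sequences), .data$.region_id, .data$shift
  )
  tibble(
    sequence = out$sequence,
    label = label,
    chrom = out$chrom,
    start = as.integer(out$win_start),
    end = as.integer(out$win_end),
    strand = out$strand,
    shift = out$shift
  ) |>
    dplyr::bind_cols(out[, carried, drop = FALSE])
}

#' Leakage-safe chromosome and protein splits
#'
#' Chromosomes and proteins are shuffled under `seed` and assigned to
#' train/validation/test by deterministic largest-remainder allocation, so
#' 120 proteins at fractions (0.75, 0.125, 0.125) give exactly 90/15/15.
#' Each chromosome and each protein lands in exactly one part.
#'
#' @param chroms Character vector of chromosome names (needs at least as
#'   many as there are parts).
#' @param proteins Character vector of protein IDs.
#' @param fractions Numeric vector of length 3 summing to 1
#'   (train, validation, test).
#' @param seed Integer seed.
#' @return An object of class `split_assignment`: a list of tibbles
#'   `chromosomes` (`chrom`, `part`) and `proteins` (`protein`, `part`).
#' @export
make_splits <- function(chroms, proteins, fractions = c(0.75, 0.125, 0.125),
                        seed = 1) {
  parts <- c("train", "validation", "test")
  if (length(fractions) != length(parts) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be 3 values summing to 1.")
  }
  if (length(chroms) < length(parts)) {
    abort(sprintf(
      "Need at least %d chromosomes to form %d parts; got %d.",
      length(parts), length(parts), length(chroms)
    ))
  }
  allocate <- function(items, offset) {
    counts <- largest_remainder(length(items), fractions)
    shuffled <- with_seed_if(seed + offset, sample(items))
    tibble(
      item = shuffled,
      part = rep(parts, counts)
    )
  }
  chrom_split <- allocate(chroms, 0L)
  protein_split <- allocate(proteins, 1L)
  structure(
    list(
      chromosomes = dplyr::rename(chrom_split, chrom = "item"),
      proteins = dplyr::rename(protein_split, protein = "item"),
      fractions = fractions,
      seed = as.integer(seed)
    ),
    class = "split_assignment"
  )
}

#' Assign (protein, RNA) pairs to splits without leakage
#'
#' A pair enters part S only when both its protein and the chromosome of
#' its RNA are assigned to S; pairs whose protein and chromosome fall in
#' different parts are dropped (the price of the strict split).
#'
#' @param pairs Tibble with `protein` and `chrom` columns.
#' @param splits A [make_splits()] result.
#' @return `pairs` with a `part` column; cross-part pairs removed.
#' @export
assign_pairs <- function(pairs, splits) {
  stopifnot(inherits(splits, "split_assignment"))
  joined <- dplyr::left_join(
    pairs,
    dplyr::rename(splits$proteins, protein_part = "part"),
    by = "protein"
  )
  joined <- dplyr::left_join(
    joined,
    dplyr::rename(splits$chromosomes, chrom_part = "part"),
    by = "chrom"
  )
  kept <- dplyr::filter(
    joined,
    !is.na(.data$protein_part),
    .data$protein_part == .data$chrom_part
  )
  dplyr::select(
    dplyr::mutate(kept, part = .data$protein_part),
    -"protein_part", -"chrom_part"
  )
}

#' Build a labeled window dataset for one protein
#'
#' Positive regions are the protein's peaks; negative regions are sampled
#' at the configured ratio with [sample_negatives()]. Both are expanded
#' into augmented fixed-length windows with [extract_windows()].
#'
#' @param peaks Peak tibble for one protein.
#' @param genes Gene annotation tibble.
#' @param genome Named `DNAStringSet`.
#' @param scheme A [window_scheme()].
#' @param ratio Negative:positive region ratio.
#' @param seed Integer seed (negative subsampling).
#' @param augment Apply the +/-15 nt shift augmentation.
#' @return Tibble of labeled examples (see [extract_windows()]).
#' @export
build_dataset <- function(peaks, genes, genome, scheme = window_scheme(),
                          ratio = 1.0, seed = 1, augment = TRUE) {
  negatives <- sample_negatives(
    peaks, genes, genome, ratio = ratio, seed = seed, scheme = scheme
  )
  dplyr::bind_rows(
    extract_windows(peaks, genome, 1L, scheme, augment = augment),
    extract_windows(negatives, genome, 0L, scheme, augment = augment)
  )
}
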