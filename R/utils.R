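DNA_BASES <- c("A", "C", "G", "T")

# smallest prime strictly greater than n (trial division; n is small here)
next_prime <- function(n) {
  candidate <- n + 1L
  repeat {
    if (candidate >= 2L) {
      upper <- floor(sqrt(candidate))
      if (upper < 2L || all(candidate %% 2:upper != 0L)) {
        return(as.integer(candidate))
      }
    }
    candidate <- candidate + 1L
  }
}

#' All k-mers over the ACGT alphabet in lexicographic order
#'
#' Lexicographic order with `A < C < G < T` fixes the mapping between k-mer
#' strings and 0-based feature indices used throughout the package: the k-mer
#' at index `i` spells `i` in base 4 with the first character most
#' significant.
#'
#' @param k k-mer length, a positive integer.
#' @return Character vector of length `4^k`.
#' @examples
#' all_kmers(2)[1:5]
#' @export
all_kmers <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  cols <- rep(list(DNA_BASES), k)
  grid <- do.call(expand.grid, c(cols, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest (= least significant digit),
  # so paste columns in reverse to get the first character most significant
  do.call(paste0, rev(grid))
}

# nucleotide string -> integer codes A=0, C=1, G=2, T/U=3, anything else NA
encode_bases <- function(sequence) {
  chars <- strsplit(chartr("acgtuU", "ACGTTT", sequence), "", fixed = TRUE)[[1]]
  match(chars, DNA_BASES) - 1L
}

# 0-based indices of the valid (N-free) k-mers along a sequence, in order
kmer_indices <- function(codes, k) {
  n_win <- length(codes) - k + 1L
  if (n_win < 1L) {
    return(integer(0))
  }
  idx <- numeric(n_win)
  bad <- logical(n_win)
  for (offset in 0:(k - 1L)) {
    digit <- codes[(1L + offset):(n_win + offset)]
    bad <- bad | is.na(digit)
    digit[is.na(digit)] <- 0L
    idx <- idx * 4 + digit
  }
  as.integer(idx[!bad])
}

frobenius_norm <- function(m) sqrt(sum(m^2))

# run code under a fixed seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG alone
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# deterministic largest-remainder allocation of n items to parts
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

reverse_complement <- function(sequences) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequences)))
}

# extract [start, end) 0-based half-open slices from one chromosome,
# reverse-complementing minus-strand entries
extract_sequences <- function(chrom_seq, start, end, strand) {
  out <- as.character(Biostrings::extractAt(
    chrom_seq, IRanges::IRanges(start = start + 1L, end = end)
  ))
  minus <- strand == "-"
  if (any(minus)) {
    out[minus] <- reverse_complement(out[minus])
  }
  out
}

gc_content <- function(sequences) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(sequences))
  total <- rowSums(counts[, DNA_BASES, drop = FALSE])
  ifelse(total > 0, (counts[, "C"] + counts[, "G"]) / total, NA_real_)
}
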