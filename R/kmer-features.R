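#' Define a k-mer feature space
#'
#' The default space concatenates 3-mer and 5-mer blocks, giving a
#' `4^3 + 4^5 = 1088`-dimensional representation of an RNA window. Within
#' each block, k-mers are indexed lexicographically (`A < C < G < T`), so
#' model weights can always be mapped back to k-mer strings.
#'
#' @param ks Integer vector of k values, strictly increasing, each >= 1.
#' @return An object of class `kmer_space` with fields `ks`, `block_dims`
#'   and `total_dim`.
#' @examples
#' kmer_space()$total_dim # 1088
#' @export
kmer_space <- function(ks = c(3L, 5L)) {
  ks <- as.integer(ks)
  if (length(ks) < 1L || anyNA(ks) || any(ks < 1L)) {
    abort("`ks` must be a vector of integers >= 1.")
  }
  if (is.unsorted(ks, strictly = TRUE)) {
    abort("`ks` must be strictly increasing.")
  }
  block_dims <- as.integer(4L^ks)
  structure(
    list(ks = ks, block_dims = block_dims, total_dim = sum(block_dims)),
    class = "kmer_space"
  )
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(
    "<kmer_space> k =", paste(x$ks, collapse = ", "),
    "| dimension", paste(x$block_dims, collapse = " + "),
    "=", x$total_dim, "\n"
  )
  invisible(x)
}

#' Count overlapping k-mers in a nucleotide sequence
#'
#' Slides a window of length `k` with step 1 over the sequence. `U` is read
#' as `T`; windows containing `N` (or any other non-ACGT character) are
#' skipped. A sequence shorter than `k` yields an all-zero vector.
#'
#' @param sequence A single nucleotide string over `A,C,G,T,U,N`.
#' @param k k-mer length.
#' @return Named integer vector of length `4^k` (lexicographic k-mer order).
#' @examples
#' count_kmers("AAAA", 3)[["AAA"]] # 2
#' @export
count_kmers <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  idx <- kmer_indices(encode_bases(sequence), k)
  counts <- tabulate(idx + 1L, nbins = 4L^k)
  names(counts) <- all_kmers(k)
  counts
}

#' Build the concatenated k-mer feature vector of an RNA window
#'
#' Per-k blocks are concatenated in increasing k order. With
#' `normalization = "frequencies"` (the default) each block is divided by its
#' total number of valid k-mers, so a block sums to 1 whenever the window
#' contains at least one valid k-mer; `"counts"` keeps raw counts (used for
#' region scoring).
#'
#' @param sequence A single nucleotide string.
#' @param space A [kmer_space()].
#' @param normalization `"frequencies"` or `"counts"`.
#' @return Named numeric vector of length `space$total_dim`.
#' @export
kmer_feature_vector <- function(sequence, space = kmer_space(),
                                normalization = c("frequencies", "counts")) {
  normalization <- match.arg(normalization)
  blocks <- lapply(space$ks, function(k) {
    counts <- count_kmers(sequence, k)
    values <- as.numeric(counts)
    names(values) <- names(counts)
    if (normalization == "frequencies") {
      total <- sum(values)
      if (total > 0) values / total else values
    } else {
      values
    }
  })
  unlist(blocks)
}

#' Featurize a batch of fixed-length windows
#'
#' @param sequences Character vector of windows (or a data frame with a
#'   `sequence` column).
#' @param space A [kmer_space()].
#' @param projection Optional [hash_projection()]; when supplied, rows are
#'   hashed down to `projection$out_dim`.
#' @param normalization Passed to [kmer_feature_vector()].
#' @return Numeric matrix with one row per window.
#' @export
featurize_windows <- function(sequences, space = kmer_space(), projection = NULL,
                              normalization = c("frequencies", "counts")) {
  normalization <- match.arg(normalization)
  if (is.data.frame(sequences)) {
    sequences <- sequences$sequence
  }
  features <- t(vapply(
    sequences,
    kmer_feature_vector,
    numeric(space$total_dim),
    space = space,
    normalization = normalization,
    USE.NAMES = FALSE
  ))
  if (!is.null(projection)) {
    features <- hash_features(features, projection)
  }
  features
}

#' Create a universal-family hash projection
#'
#' Draws `(a, b)` from the linear universal hash family
#' `hash(i) = ((a * i + b) mod p) mod out_dim` with `p` the smallest prime
#' exceeding `in_dim` (1091 for the default 1088-dimensional space), and
#' materializes the projection as a 0/1 matrix with exactly one 1 per column
#' (column-stochastic), so hashing is the matrix-vector product and total
#' feature mass is conserved.
#'
#' @param in_dim Input dimension (number of k-mers).
#' @param out_dim Output dimension; must satisfy `1 <= out_dim <= in_dim`.
#' @param seed Integer seed used to draw `(a, b)`; required unless both `a`
#'   and `b` are given explicitly.
#' @param a,b Optional explicit family parameters (`1 <= a < p`,
#'   `0 <= b < p`). `a = 1, b = 0` with `out_dim = in_dim` induces the
#'   identity permutation.
#' @return An object of class `hash_projection` with fields `in_dim`,
#'   `out_dim`, `a`, `b`, `p`, `seed`, `bins` (1-based output bin per input
#'   index) and `matrix` (sparse `out_dim x in_dim`).
#' @examples
#' proj <- hash_projection(1088, 128, seed = 1)
#' all(Matrix::colSums(proj$matrix) == 1)
#' @export
hash_projection <- function(in_dim, out_dim, seed = NULL, a = NULL, b = NULL) {
  in_dim <- as.integer(in_dim)
  out_dim <- as.integer(out_dim)
  if (out_dim < 1L) {
    abort("`out_dim` must be >= 1.")
  }
  if (out_dim > in_dim) {
    abort("`out_dim` must not exceed `in_dim`: hashing reduces, never expands.")
  }
  p <- next_prime(in_dim)
  if (is.null(a) || is.null(b)) {
    if (is.null(seed)) {
      abort("Provide `seed` (or explicit `a` and `b`) so the projection is reproducible.")
    }
    drawn <- with_seed_if(seed, c(sample.int(p - 1L, 1L), sample.int(p, 1L) - 1L))
    a <- drawn[1]
    b <- drawn[2]
  }
  a <- as.integer(a)
  b <- as.integer(b)
  if (a < 1L || a >= p || b < 0L || b >= p) {
    abort(sprintf("Need 1 <= a < p and 0 <= b < p (p = %d).", p))
  }
  index <- as.numeric(0:(in_dim - 1L))
  bins <- as.integer(((a * index + b) %% p) %% out_dim) + 1L
  mat <- Matrix::sparseMatrix(
    i = bins, j = seq_len(in_dim), x = 1, dims = c(out_dim, in_dim)
  )
  structure(
    list(
      in_dim = in_dim, out_dim = out_dim, a = a, b = b, p = p,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      bins = bins, matrix = mat
    ),
    class = "hash_projection"
  )
}

#' @export
print.hash_projection <- function(x, ...) {
  cat(sprintf(
    "<hash_projection> %d -> %d | hash(i) = ((%d i + %d) mod %d) mod %d\n",
    x$in_dim, x$out_dim, x$a, x$b, x$p, x$out_dim
  ))
  invisible(x)
}

#' Apply a hash projection to feature vectors
#'
#' Computes the matrix-vector product with the column-stochastic 0/1
#' operator, which is identical to accumulating each input coordinate into
#' its hash bin (`out[hash(i)] += x[i]`). The total of the output always
#' equals the total of the input.
#'
#' @param x Numeric vector of length `in_dim`, or a matrix with `in_dim`
#'   columns (rows are hashed independently).
#' @param projection A [hash_projection()].
#' @return Vector of length `out_dim`, or matrix with `out_dim` columns.
#' @export
hash_features <- function(x, projection) {
  stopifnot(inherits(projection, "hash_projection"))
  if (is.matrix(x)) {
    if (ncol(x) != projection$in_dim) {
      abort(sprintf(
        "Feature dimension %d does not match projection in_dim %d.",
        ncol(x), projection$in_dim
      ))
    }
    return(as.matrix(x %*% Matrix::t(projection$matrix)))
  }
  if (length(x) != projection$in_dim) {
    abort(sprintf(
      "Feature dimension %d does not match projection in_dim %d.",
      length(x), projection$in_dim
    ))
  }
  as.numeric(projection$matrix %*% x)
}

#' Serialize / restore a hash projection
#'
#' The JSON header stores `(in_dim, out_dim, a, b, p, seed)`, which is
#' sufficient to rebuild the operator exactly, so a trained model remains
#' usable across sessions.
#'
#' @param projection A [hash_projection()].
#' @param path File path.
#' @return `read_hash_projection()` returns a `hash_projection`.
#' @export
write_hash_projection <- function(projection, path) {
  stopifnot(inherits(projection, "hash_projection"))
  jsonlite::write_json(
    projection[c("in_dim", "out_dim", "a", "b", "p", "seed")],
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_hash_projection
#' @export
read_hash_projection <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- hash_projection(
    in_dim = fields$in_dim, out_dim = fields$out_dim,
    a = fields$a, b = fields$b
  )
  if (proj$p != fields$p) {
    abort("Stored prime does not match the rebuilt projection; file corrupt?")
  }
  proj$seed <- fields$seed
  proj
}
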