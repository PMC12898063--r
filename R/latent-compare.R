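#' Derive a 7-mer interaction profile from CLIP peaks
#'
#' For each 7-mer, the binding signal is the maximum of
#' `fold_change * neglog10_p` across all peaks whose (strand-aware)
#' sequence contains that 7-mer — the maximum rather than the mean, so
#' strong specific interactions are not diluted by abundant weak ones.
#' 7-mers absent from every peak get 0 before standardization; the vector
#' is then centered and scaled over all 16,384 entries, yielding a proxy
#' z-score profile comparable to RNAcompete output.
#'
#' @param peaks Peak tibble from a single protein (`chrom, start, end,
#'   strand, fold_change, neglog10_p`).
#' @param genome Named `DNAStringSet`.
#' @return Tibble with `kmer` (all 16,384 7-mers) and `zscore`.
#' @export
eclip_7mer_profile <- function(peaks, genome) {
  if (nrow(peaks) == 0) {
    abort("Empty peak list: cannot derive a 7-mer profile.")
  }
  if ("protein" %in% names(peaks) && length(unique(peaks$protein)) > 1L) {
    abort("`peaks` must come from a single protein.")
  }
  raw <- numeric(16384)
  for (i in seq_len(nrow(peaks))) {
    seq_i <- extract_sequences(
      genome[[peaks$chrom[i]]], peaks$start[i], peaks$end[i], peaks$strand[i]
    )
    present <- unique(kmer_indices(encode_bases(seq_i), 7L)) + 1L
    if (length(present) > 0) {
      signal <- peaks$fold_change[i] * peaks$neglog10_p[i]
      raw[present] <- pmax(raw[present], signal)
    }
  }
  tibble(kmer = all_kmers(7), zscore = standardize_profile(raw))
}

#' Assemble the joint protein-RNA matrix
#'
#' Horizontally concatenates a protein feature block and the per-protein
#' 7-mer profiles into the `[P | R]` matrix whose SVD defines the joint
#' latent space. Row order is consistent across blocks; a protein present
#' in only one input is an error.
#'
#' @param protein_features Tibble with `protein` plus numeric feature
#'   columns (or a numeric matrix with protein rownames).
#' @param profiles Long tibble with `protein, kmer, zscore` (e.g. stacked
#'   [eclip_7mer_profile()] or [simulate_rnacompete_profile()] outputs).
#' @param normalize_blocks Scale each block to unit Frobenius norm before
#'   concatenation (off by default).
#' @return An object of class `joint_matrix` with `proteins`, `p_block`,
#'   `r_block` and `combined`.
#' @export
build_joint_matrix <- function(protein_features, profiles,
                               normalize_blocks = FALSE) {
  p_block <- embedding_matrix(protein_features)
  value_col <- intersect(c("zscore", "score"), names(profiles))[1]
  wide <- tidyr::pivot_wider(
    profiles, id_cols = "protein", names_from = "kmer",
    values_from = dplyr::all_of(value_col)
  )
  r_block <- as.matrix(wide[, -1])
  rownames(r_block) <- wide$protein
  only_p <- setdiff(rownames(p_block), rownames(r_block))
  only_r <- setdiff(rownames(r_block), rownames(p_block))
  if (length(only_p) + length(only_r) > 0) {
    abort(paste0(
      "Protein sets differ between blocks. Only in features: ",
      paste(only_p, collapse = ", "), "; only in profiles: ",
      paste(only_r, collapse = ", ")
    ))
  }
  proteins <- rownames(p_block)
  r_block <- r_block[proteins, , drop = FALSE]
  if (normalize_blocks) {
    p_block <- p_block / frobenius_norm(p_block)
    r_block <- r_block / frobenius_norm(r_block)
  }
  structure(
    list(
      proteins = proteins,
      p_block = p_block,
      r_block = r_block,
      combined = cbind(p_block, r_block)
    ),
    class = "joint_matrix"
  )
}

as_numeric_matrix <- function(matrix) {
  if (inherits(matrix, "joint_matrix")) matrix$combined else as.matrix(matrix)
}

#' Cumulative explained-norm curve of a matrix
#'
#' `curve[k]` is the share of the squared Frobenius norm captured by the
#' top k singular values, `sum(d[1:k]^2) / sum(d^2)` (the standard
#' variance-explained convention; `squared = FALSE` switches to the
#' unsquared `sum(d[1:k]) / sum(d)` reading). Curves are non-decreasing
#' and end at 1.
#'
#' @param matrix A numeric matrix or [build_joint_matrix()] result.
#' @param squared Use squared singular values (default).
#' @return Tibble of class `explained_norm_curve` with `rank` and
#'   `explained`.
#' @export
svd_explained_norm <- function(matrix, squared = TRUE) {
  m <- as_numeric_matrix(matrix)
  if (all(m == 0)) {
    abort("Zero matrix: explained norm undefined.")
  }
  d <- svd(m, nu = 0, nv = 0)$d
  mass <- if (squared) d^2 else d
  out <- tibble(
    rank = seq_along(d),
    explained = cumsum(mass) / sum(mass)
  )
  class(out) <- c("explained_norm_curve", class(out))
  out
}

#' Explained-norm baseline from random matrices of matched norm
#'
#' Generates `n_reps` iid standard-normal matrices rescaled to the target
#' Frobenius norm, computes each one's explained-norm curve, and returns
#' per-rank summaries. For strongly rectangular shapes the mean curve
#' concentrates near `k / min(n, m)`: random data are explained in
#' proportion to the number of components used, which is what a structured
#' matrix must beat.
#'
#' @param n_rows,n_cols Matrix shape.
#' @param target_norm Frobenius norm to match.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param squared Passed to [svd_explained_norm()].
#' @return Tibble with `rank, mean, median, q05, q25, q75, q95`; the full
#'   `n_reps x rank` curve matrix is attached as attribute `"curves"`.
#' @export
random_matrix_baseline <- function(n_rows, n_cols, target_norm,
                                   n_reps = 1000, seed = 1, squared = TRUE) {
  stopifnot(n_reps >= 1, target_norm > 0)
  n_ranks <- min(n_rows, n_cols)
  curves <- with_seed_if(seed, {
    t(vapply(seq_len(n_reps), function(rep) {
      m <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
      m <- m * (target_norm / frobenius_norm(m))
      svd_explained_norm(m, squared = squared)$explained
    }, numeric(n_ranks)))
  })
  out <- tibble(
    rank = seq_len(n_ranks),
    mean = colMeans(curves),
    median = apply(curves, 2, median),
    q05 = apply(curves, 2, quantile, probs = 0.05),
    q25 = apply(curves, 2, quantile, probs = 0.25),
    q75 = apply(curves, 2, quantile, probs = 0.75),
    q95 = apply(curves, 2, quantile, probs = 0.95)
  )
  attr(out, "curves") <- curves
  out
}

#' SVD latent space of a joint matrix
#'
#' @param matrix A numeric matrix or [build_joint_matrix()] result.
#' @param proteins Optional row (protein) IDs; taken from the joint matrix
#'   or rownames when available.
#' @return An object of class `latent_space` with `u`, `d`, `v`,
#'   `proteins` and the explained-norm `curve`.
#' @export
latent_space <- function(matrix, proteins = NULL) {
  m <- as_numeric_matrix(matrix)
  proteins <- proteins %||%
    (if (inherits(matrix, "joint_matrix")) matrix$proteins else rownames(m)) %||%
    sprintf("row%d", seq_len(nrow(m)))
  decomposition <- svd(m)
  structure(
    list(
      u = decomposition$u,
      d = decomposition$d,
      v = decomposition$v,
      proteins = proteins,
      curve = svd_explained_norm(m)
    ),
    class = "latent_space"
  )
}

#' Pairwise cosine distances between proteins in a latent space
#'
#' Protein i is represented by row i of `U[, 1:r] %*% diag(d[1:r])` (the
#' singular-value-scaled coordinates, which preserve the row-space
#' geometry). Distance is `1 - cosine similarity`. The default rank r is
#' the elbow where the explained-norm curve first reaches 0.9.
#'
#' @param latent A [latent_space()] (or a `joint_matrix` / matrix, which
#'   is decomposed first).
#' @param r Latent rank to use; `NULL` for the 0.9 elbow.
#' @param scale_by_singular_values Use `U %*% diag(d)` coordinates
#'   (default) rather than bare `U`.
#' @return Tibble with `protein_a, protein_b, distance`
#'   (`n (n - 1) / 2` rows).
#' @export
latent_cosine_distances <- function(latent, r = NULL,
                                    scale_by_singular_values = TRUE) {
  if (!inherits(latent, "latent_space")) {
    latent <- latent_space(latent)
  }
  if (is.null(r)) {
    r <- which(latent$curve$explained >= 0.9)[1]
  }
  if (r > length(latent$d)) {
    abort(sprintf("r = %d exceeds the available rank %d.", r, length(latent$d)))
  }
  coords <- latent$u[, seq_len(r), drop = FALSE]
  if (scale_by_singular_values) {
    coords <- coords %*% diag(latent$d[seq_len(r)], r)
  }
  norms <- sqrt(rowSums(coords^2))
  if (any(norms == 0)) {
    warn("Zero-vector latent row(s): distances to them are undefined (NA).")
  }
  unit <- coords / ifelse(norms == 0, NA_real_, norms)
  similarity <- tcrossprod(unit)
  pairs <- which(upper.tri(similarity), arr.ind = TRUE)
  tibble(
    protein_a = latent$proteins[pairs[, 1]],
    protein_b = latent$proteins[pairs[, 2]],
    distance = 1 - similarity[pairs]
  )
}

#' One-dimensional Wasserstein (earth mover's) distance
#'
#' For equal-size samples this is the mean absolute difference of sorted
#' order statistics (the optimal pairing); in general it integrates the
#' absolute difference of the empirical CDFs, which coincides with the
#' optimal-transport cost.
#'
#' @param x,y Numeric samples.
#' @return Non-negative scalar.
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(x) == length(y)) {
    return(mean(abs(sort(x) - sort(y))))
  }
  grid <- sort(c(x, y))
  steps <- diff(grid)
  cdf_x <- ecdf_at(x, grid[-length(grid)])
  cdf_y <- ecdf_at(y, grid[-length(grid)])
  sum(abs(cdf_x - cdf_y) * steps)
}

ecdf_at <- function(sample, points) {
  vapply(points, function(p) mean(sample <= p), numeric(1))
}

#' Compare two latent distance distributions
#'
#' Computes the 1-D Wasserstein W1 distance between the two distance
#' distributions plus Pearson and Spearman correlations on the paired
#' values (pairs matched by protein pair when tibbles are supplied).
#'
#' @param distances_a,distances_b [latent_cosine_distances()] tibbles or
#'   numeric vectors of equal length.
#' @return One-row tibble with `w1, pearson_r, spearman_rho, n_pairs`.
#' @export
compare_spaces <- function(distances_a, distances_b) {
  if (is.data.frame(distances_a) && is.data.frame(distances_b)) {
    joined <- dplyr::inner_join(
      distances_a, distances_b,
      by = c("protein_a", "protein_b"), suffix = c("_a", "_b")
    )
    if (nrow(joined) != nrow(distances_a) || nrow(joined) != nrow(distances_b)) {
      abort("Distance tibbles do not cover the same protein pairs.")
    }
    a <- joined$distance_a
    b <- joined$distance_b
  } else {
    a <- as.numeric(distances_a)
    b <- as.numeric(distances_b)
    if (length(a) != length(b)) {
      abort("Distance vectors must have the same length.")
    }
  }
  tibble(
    w1 = wasserstein1(a, b),
    pearson_r = cor(a, b),
    spearman_rho = cor(a, b, method = "spearman"),
    n_pairs = length(a)
  )
}
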