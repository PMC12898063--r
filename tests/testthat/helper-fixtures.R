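# shared fixtures, built in code and cached for the session

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- builder()
  }
  .fixtures[[key]]
}

# small two-protein bundle used across module tests
tiny_bundle <- function() {
  cached("tiny_bundle", function() {
    config <- synthetic_config(
      n_chromosomes = 3, chrom_length = 40000, n_genes = 30, seed = 42
    )
    simulate_bundle(
      config,
      list(RBP1 = simulate_pwm("TGCATG"), RBP2 = simulate_pwm("ACCTGA"))
    )
  })
}

random_sequence <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# windows with/without a planted exact motif, strongly separable
separable_windows <- function(n_per_class = 200, width = 100,
                              motif = "TTTTCCGGAA", copies = 3, seed = 1) {
  withr::with_seed(seed, {
    make_one <- function(plant) {
      s <- random_sequence(width)
      if (plant) {
        for (i in seq_len(copies)) {
          at <- sample.int(width - nchar(motif) + 1L, 1)
          substr(s, at, at + nchar(motif) - 1L) <- motif
        }
      }
      s
    }
    tibble::tibble(
      sequence = c(
        vapply(seq_len(n_per_class), function(i) make_one(TRUE), character(1)),
        vapply(seq_len(n_per_class), function(i) make_one(FALSE), character(1))
      ),
      label = rep(c(1L, 0L), each = n_per_class)
    )
  })
}

# brute-force k-mer counting oracle: substring enumeration
count_kmers_oracle <- function(sequence, k) {
  sequence <- chartr("u", "t", tolower(sequence))
  sequence <- chartr("acgt", "ACGT", sequence)
  kmers <- all_kmers(k)
  counts <- setNames(integer(length(kmers)), kmers)
  n <- nchar(sequence)
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      sub <- substr(sequence, i, i + k - 1L)
      if (sub %in% kmers) {
        counts[sub] <- counts[sub] + 1L
      }
    }
  }
  counts
}

# brute-force AUROC over all positive/negative pairs, ties get half credit
auroc_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# brute-force 1-D W1 for equal-size samples: best pairing over permutations
w1_oracle <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1L) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) {
        out[[length(out) + 1L]] <- c(v[i], rest)
      }
    }
    out
  }
  best <- Inf
  for (perm in perms(y)) {
    best <- min(best, mean(abs(x - perm)))
  }
  best
}
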