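# hashed design matrix + 0/1 labels from a labeled-example tibble
prepare_xy <- function(examples, space, projection, normalization) {
  widths <- unique(nchar(examples$sequence))
  if (length(widths) != 1L) {
    abort("All training windows must have the same length.")
  }
  y <- as.integer(examples$label)
  if (length(unique(y)) < 2L) {
    abort("Training data must contain both classes.")
  }
  x <- featurize_windows(
    examples$sequence, space, projection, normalization = normalization
  )
  list(x = x, y = y, window = widths)
}

#' Train a single-protein logistic classifier
#'
#' Fits an L2-regularized (ridge) logistic regression on hashed k-mer
#' feature vectors via `glmnet`. A fixed-size window representation makes
#' plain logistic regression sufficient for the single-protein task; the
#' model is fully described by a weight per hash bin plus a bias, so it
#' remains directly interpretable through [kmer_weight_map()].
#'
#' `l2_lambda` is the ridge penalty on the average-log-likelihood scale
#' (glmnet's native parameterization), which makes the fit exactly
#' invariant under uniform duplication of the training set. k-mer
#' frequencies are small (order 1/window), so useful penalties are small;
#' the default is 1e-3.
#'
#' @param examples Tibble of labeled windows (`sequence`, `label`), e.g.
#'   from [build_dataset()].
#' @param projection A [hash_projection()]; recorded in the model so
#'   inference is reproducible.
#' @param space A [kmer_space()].
#' @param normalization Feature normalization (see [kmer_feature_vector()]).
#' @param l2_lambda Ridge penalty (average-loss scale).
#' @param max_iter,tol Optimizer budget and convergence threshold.
#' @param protein Optional protein ID stored in the model.
#' @return An object of class `rbp_logistic` with `weights`, `bias`,
#'   `projection`, `space`, `window` and hyperparameters.
#' @export
fit_rbp_logistic <- function(examples, projection, space = kmer_space(),
                             normalization = c("frequencies", "counts"),
                             l2_lambda = 1e-3, max_iter = 1e5, tol = 1e-9,
                             protein = NULL) {
  normalization <- match.arg(normalization)
  data <- prepare_xy(examples, space, projection, normalization)
  fit <- glmnet::glmnet(
    data$x, factor(data$y, levels = c(0, 1)),
    family = "binomial", alpha = 0, lambda = l2_lambda,
    standardize = FALSE, maxit = max_iter, thresh = tol
  )
  if (fit$npasses >= max_iter) {
    message("glmnet reached max_iter without meeting `tol`.")
  }
  beta <- as.numeric(fit$beta)
  structure(
    list(
      protein = protein %||% unique(examples[["protein"]]) %||% NA_character_,
      weights = beta,
      bias = as.numeric(fit$a0),
      projection = projection,
      space = space,
      normalization = normalization,
      window = data$window,
      hyperparams = list(l2_lambda = l2_lambda, max_iter = max_iter, tol = tol),
      n_obs = nrow(data$x)
    ),
    class = "rbp_logistic"
  )
}

#' Train a linear SVM baseline on the same features
#'
#' Hinge-loss counterpart of [fit_rbp_logistic()], fitted with
#' `e1071::svm` (linear kernel, no feature scaling). The separating
#' hyperplane is extracted so the model exposes the same `weights`/`bias`
#' interface; scores are oriented so larger means more peak-like.
#'
#' @inheritParams fit_rbp_logistic
#' @param cost SVM cost parameter `C`.
#' @return An object of class `rbp_svm`.
#' @export
fit_rbp_svm <- function(examples, projection, space = kmer_space(),
                        normalization = c("frequencies", "counts"),
                        cost = 1, protein = NULL) {
  normalization <- match.arg(normalization)
  data <- prepare_xy(examples, space, projection, normalization)
  fit <- e1071::svm(
    x = data$x, y = factor(data$y, levels = c(0, 1)),
    kernel = "linear", cost = cost, scale = FALSE
  )
  weights <- as.numeric(t(fit$coefs) %*% fit$SV)
  bias <- -fit$rho
  # e1071 orients decision values toward the class of the first training
  # example; flip if needed so larger score = more peak-like
  margins <- as.numeric(data$x %*% weights + bias)
  if (auroc(margins, data$y) < 0.5) {
    weights <- -weights
    bias <- -bias
  }
  structure(
    list(
      protein = protein %||% unique(examples[["protein"]]) %||% NA_character_,
      weights = weights,
      bias = bias,
      projection = projection,
      space = space,
      normalization = normalization,
      window = data$window,
      hyperparams = list(cost = cost),
      n_obs = nrow(data$x)
    ),
    class = "rbp_svm"
  )
}

linear_scores <- function(model, sequences) {
  x <- featurize_windows(
    sequences, model$space, model$projection, normalization = model$normalization
  )
  as.numeric(x %*% model$weights + model$bias)
}

#' Predict the binding probability of a single fixed-length window
#'
#' Computes `sigmoid(w . hash(features) + b)`. `U` and `T` spellings give
#' identical results. Longer RNAs must be scanned with [scan_rna()];
#' sequences of the wrong length raise an error.
#'
#' @param model An `rbp_logistic` or `rbp_svm` model.
#' @param sequence A nucleotide string of the model's window length.
#' @return Probability in `[0, 1]` (for the SVM, a sigmoid-squashed margin).
#' @export
predict_window <- function(model, sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) != model$window) {
    abort(sprintf(
      "Sequence length %d does not match the model window %d; use scan_rna() for longer RNAs.",
      nchar(sequence), model$window
    ))
  }
  plogis(linear_scores(model, sequence))
}

#' @export
predict.rbp_logistic <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    newdata <- newdata$sequence
  }
  scores <- linear_scores(object, newdata)
  if (type == "response") plogis(scores) else scores
}

#' @export
predict.rbp_svm <- predict.rbp_logistic

#' Train the multi-protein concatenation network
#'
#' Concatenates the hashed RNA feature vector with a fixed-length protein
#' embedding and feeds the result to a fully connected network with a
#' sigmoid output (one hidden layer, `nnet`). When a
#' [make_splits()] assignment is supplied, a hard leakage guard verifies
#' that every training pair has both its protein and its chromosome in the
#' training part.
#'
#' @param pairs Tibble with `sequence`, `label`, `protein` and `chrom`.
#' @param embeddings Tibble with `protein` plus numeric embedding columns.
#' @param projection A [hash_projection()].
#' @param splits Optional [make_splits()] result; enforced, not assumed.
#' @param space A [kmer_space()].
#' @param normalization Feature normalization.
#' @param hidden Hidden layer width.
#' @param decay L2 weight decay.
#' @param maxit Optimizer iterations.
#' @param seed Integer seed (weight initialization).
#' @return An object of class `rbp_net`.
#' @export
fit_rbp_net <- function(pairs, embeddings, projection, splits = NULL,
                        space = kmer_space(),
                        normalization = c("frequencies", "counts"),
                        hidden = 32, decay = 1e-4, maxit = 300, seed = 1) {
  normalization <- match.arg(normalization)
  if (!is.null(splits)) {
    assigned <- assign_pairs(
      dplyr::distinct(pairs[, c("protein", "chrom")]), splits
    )
    train_ok <- dplyr::filter(assigned, .data$part == "train")
    offending <- dplyr::anti_join(
      dplyr::distinct(pairs[, c("protein", "chrom")]),
      train_ok,
      by = c("protein", "chrom")
    )
    if (nrow(offending) > 0) {
      abort(paste0(
        "Leakage guard: training pairs outside the train split: ",
        paste(sprintf("%s/%s", offending$protein, offending$chrom),
              collapse = ", ")
      ))
    }
  }
  emb <- embedding_matrix(embeddings)
  missing <- setdiff(unique(pairs$protein), rownames(emb))
  if (length(missing) > 0) {
    abort(paste0("No embedding for protein(s): ", paste(missing, collapse = ", ")))
  }
  data <- prepare_xy(pairs, space, projection, normalization)
  x <- cbind(data$x, emb[pairs$protein, , drop = FALSE])
  fit <- with_seed_if(seed, nnet::nnet(
    x = x, y = data$y, size = hidden, decay = decay, maxit = maxit,
    entropy = TRUE, trace = FALSE, MaxNWts = 1e6
  ))
  structure(
    list(
      fit = fit,
      embeddings = emb,
      projection = projection,
      space = space,
      normalization = normalization,
      window = data$window,
      hyperparams = list(hidden = hidden, decay = decay, maxit = maxit,
                         seed = seed),
      n_obs = nrow(x)
    ),
    class = "rbp_net"
  )
}

embedding_matrix <- function(embeddings) {
  if (is.matrix(embeddings)) {
    return(embeddings)
  }
  mat <- as.matrix(embeddings[, setdiff(names(embeddings), "protein")])
  rownames(mat) <- embeddings$protein
  mat
}

#' @export
predict.rbp_net <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  x <- featurize_windows(
    newdata$sequence, object$space, object$projection,
    normalization = object$normalization
  )
  missing <- setdiff(unique(newdata$protein), rownames(object$embeddings))
  if (length(missing) > 0) {
    abort(paste0("No embedding for protein(s): ", paste(missing, collapse = ", ")))
  }
  x <- cbind(x, object$embeddings[newdata$protein, , drop = FALSE])
  as.numeric(predict(object$fit, x))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation: tied scores receive half credit, which makes
#' the value identical to brute-force enumeration over all
#' positive/negative pairs.
#'
#' @param score Numeric scores (larger = more positive).
#' @param label 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  label <- as.integer(label)
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    return(NA_real_)
  }
  ranks <- rank(score)
  (sum(ranks[label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold metrics and AUROC for one set of scores
#'
#' Balanced accuracy and Matthews correlation are computed at the given
#' probability threshold (default 0.5); AUROC is threshold-free.
#'
#' @param score Numeric scores in `[0, 1]`.
#' @param label 0/1 labels.
#' @param threshold Classification threshold.
#' @return One-row tibble with `n_pos, n_neg, auroc, balanced_accuracy,
#'   mcc`.
#' @export
binding_metrics <- function(score, label, threshold = 0.5) {
  label <- as.integer(label)
  pred <- as.integer(score > threshold)
  tp <- sum(pred == 1L & label == 1L)
  tn <- sum(pred == 0L & label == 0L)
  fp <- sum(pred == 1L & label == 0L)
  fn <- sum(pred == 0L & label == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  tibble(
    n_pos = sum(label == 1L),
    n_neg = sum(label == 0L),
    auroc = auroc(score, label),
    balanced_accuracy = mean(c(sens, spec)),
    mcc = mcc
  )
}

#' Precision-recall curve over score thresholds
#'
#' @param score Numeric scores.
#' @param label 0/1 labels.
#' @return Tibble of class `pr_curve` with `threshold, recall, precision`,
#'   ordered by decreasing threshold (recall non-decreasing).
#' @export
pr_curve <- function(score, label) {
  label <- as.integer(label)
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]
  label <- label[ord]
  keep <- !duplicated(score, fromLast = TRUE) # last index of each threshold
  tp <- cumsum(label)[keep]
  n_called <- seq_along(label)[keep]
  out <- tibble(
    threshold = score[keep],
    recall = tp / sum(label),
    precision = tp / n_called
  )
  class(out) <- c("pr_curve", class(out))
  out
}

#' Evaluate a model with optional stratified reporting
#'
#' Computes AUROC (rank statistic), balanced accuracy and MCC at the 0.5
#' threshold, overall or per stratum. Strata with a single class are
#' skipped with a warning. GC quartiles are computed on the evaluated
#' windows; expression quartiles come from the supplied counts table over
#' the genes present in the evaluation set.
#'
#' @param model A fitted `rbp_logistic`, `rbp_svm` or `rbp_net`.
#' @param examples Tibble of labeled windows; needs `biotype` or `gene_id`
#'   columns for the corresponding strata.
#' @param strata_by One of `"none"`, `"biotype"`, `"gc_quartile"`,
#'   `"expression_quartile"`.
#' @param expression Counts tibble (`gene_id`, `count`), required for
#'   expression quartiles.
#' @param threshold Classification threshold for BA/MCC.
#' @return Tibble with one row per stratum.
#' @export
evaluate_model <- function(model, examples,
                           strata_by = c("none", "biotype", "gc_quartile",
                                         "expression_quartile"),
                           expression = NULL, threshold = 0.5) {
  strata_by <- match.arg(strata_by)
  score <- if (inherits(model, "rbp_net")) {
    predict(model, examples)
  } else {
    plogis(linear_scores(model, examples$sequence))
  }
  scored <- dplyr::mutate(examples, .score = score)
  scored$stratum <- switch(
    strata_by,
    none = "all",
    biotype = {
      if (is.null(scored$biotype)) abort("`examples` needs a `biotype` column.")
      scored$biotype
    },
    gc_quartile = sprintf("GC_Q%d", dplyr::ntile(gc_content(scored$sequence), 4)),
    expression_quartile = {
      if (is.null(expression)) abort("Provide `expression` for expression quartiles.")
      if (is.null(scored$gene_id)) abort("`examples` needs a `gene_id` column.")
      genes_here <- dplyr::filter(expression, .data$gene_id %in% scored$gene_id)
      genes_here$quartile <- sprintf(
        "expr_Q%d", dplyr::ntile(rank(genes_here$count, ties.method = "first"), 4)
      )
      joined <- dplyr::left_join(
        scored, genes_here[, c("gene_id", "quartile")], by = "gene_id"
      )
      joined$quartile
    }
  )
  groups <- split(scored, scored$stratum)
  rows <- purrr::imap(groups, function(group, name) {
    if (length(unique(group$label)) < 2L) {
      warn(sprintf("Stratum '%s' has a single class; skipped.", name))
      return(NULL)
    }
    dplyr::mutate(
      binding_metrics(group$.score, group$label, threshold),
      stratum = name, .before = 1
    )
  })
  dplyr::bind_rows(rows)
}
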