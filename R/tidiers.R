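#' Tidy a fitted single-protein model
#'
#' One row per hashed feature bin plus the intercept.
#'
#' @param x An `rbp_logistic` or `rbp_svm`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy rbp_logistic
#' @export
tidy.rbp_logistic <- function(x, ...) {
  tibble(
    term = c("(Intercept)", sprintf("bin%03d", seq_along(x$weights))),
    estimate = c(x$bias, x$weights)
  )
}

#' @rdname tidy.rbp_logistic
#' @method tidy rbp_svm
#' @export
tidy.rbp_svm <- tidy.rbp_logistic

#' One-row model summaries
#'
#' @param x A fitted model.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance rbp_logistic
#' @export
glance.rbp_logistic <- function(x, ...) {
  tibble(
    protein = x$protein,
    n_obs = x$n_obs,
    n_features = length(x$weights),
    window = x$window,
    l2_lambda = x$hyperparams$l2_lambda
  )
}

#' @rdname glance.rbp_logistic
#' @method glance rbp_svm
#' @export
glance.rbp_svm <- function(x, ...) {
  tibble(
    protein = x$protein,
    n_obs = x$n_obs,
    n_features = length(x$weights),
    window = x$window,
    cost = x$hyperparams$cost
  )
}

#' @rdname glance.rbp_logistic
#' @method glance rbp_net
#' @export
glance.rbp_net <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_weights = length(x$fit$wts),
    window = x$window,
    hidden = x$hyperparams$hidden,
    decay = x$hyperparams$decay
  )
}

#' Tidy a latent space
#'
#' @param x A [latent_space()].
#' @param ... Unused.
#' @return Tibble with `rank`, `singular_value` and cumulative
#'   `explained`.
#' @method tidy latent_space
#' @export
tidy.latent_space <- function(x, ...) {
  tibble(
    rank = seq_along(x$d),
    singular_value = x$d,
    explained = x$curve$explained
  )
}
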