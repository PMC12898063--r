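#' Plot a binding-probability track
#'
#' @param object An `rbp_track` from [scan_rna()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rbp_track
#' @export
autoplot.rbp_track <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = 0, ymax = .data$probability
    )
  ) +
    ggplot2::geom_rect(alpha = 0.35, fill = "steelblue") +
    ggplot2::geom_step(
      ggplot2::aes(x = .data$start, y = .data$probability),
      inherit.aes = FALSE, colour = "steelblue4"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "position (nt)", y = "binding probability",
      title = attr(object, "rna")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an explained-norm curve
#'
#' @param object An `explained_norm_curve` from [svd_explained_norm()].
#' @param baseline Optional [random_matrix_baseline()] summary drawn as a
#'   ribbon.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot explained_norm_curve
#' @export
autoplot.explained_norm_curve <- function(object, baseline = NULL, ...) {
  p <- ggplot2::ggplot(
    object, ggplot2::aes(x = .data$rank, y = .data$explained)
  )
  if (!is.null(baseline)) {
    p <- p +
      ggplot2::geom_ribbon(
        data = baseline,
        ggplot2::aes(x = .data$rank, ymin = .data$q05, ymax = .data$q95),
        inherit.aes = FALSE, fill = "grey80"
      ) +
      ggplot2::geom_line(
        data = baseline,
        ggplot2::aes(x = .data$rank, y = .data$mean),
        inherit.aes = FALSE, colour = "grey40", linetype = 2
      )
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "rank", y = "cumulative explained norm") +
    ggplot2::theme_minimal()
}

#' Plot top/bottom k-mer weights
#'
#' @param object A `kmer_ranking` from [rank_kmers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kmer_ranking
#' @export
autoplot.kmer_ranking <- function(object, ...) {
  object$kmer <- stats::reorder(object$kmer, object$weight)
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$kmer, y = .data$weight, fill = .data$side)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~k, scales = "free") +
    ggplot2::scale_fill_manual(values = c(top = "firebrick", bottom = "steelblue")) +
    ggplot2::labs(x = NULL, y = "model weight") +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(
    object, ggplot2::aes(x = .data$recall, y = .data$precision)
  ) +
    ggplot2::geom_path(colour = "steelblue4") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
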