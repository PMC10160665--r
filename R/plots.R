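# ggplot2 autoplot methods for the package's result types.

#' Plot a rating table
#'
#' Items ordered by rank with their n.mElo ratings, coloured by theme when
#' available.
#'
#' @param object A ranked `rating_table`.
#' @param top Show only the `top` highest-ranked items (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rating_table <- function(object, top = NULL, ...) {
  df <- tibble::as_tibble(unclass_tbl(object))
  if (is.null(df$rank)) abort("rank not filled: run rank_items() first")
  df <- dplyr::arrange(df, .data$rank)
  if (!is.null(top)) df <- head(df, top)
  df$item_id <- factor(df$item_id, levels = rev(df$item_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nmelo, y = .data$item_id))
  p <- if ("theme" %in% names(df) && !all(is.na(df$theme))) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$theme), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$nmelo,
                                       yend = .data$item_id),
                          linewidth = 0.2, colour = "grey60") +
    ggplot2::labs(x = "n.mElo rating", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-respondent response proportions
#'
#' Stacked proportions of FIRST / SECOND / SKIP selections per respondent.
#'
#' @param object A [summarize_responses()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.response_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_respondent, -"respondent_id",
                            names_to = "outcome", values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$respondent_id,
                                   y = .data$proportion,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "respondent", y = "proportion of responses") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a rater-inclusion plateau curve
#'
#' Median weighted consistency index against the number of raters included;
#' the plateau suggests the sample size needed for stable rankings.
#'
#' @param object A [plateau_curve()].
#' @param plateau Optional [detect_plateau()] result to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plateau_curve <- function(object, plateau = NULL, ...) {
  df <- tibble::as_tibble(unclass_tbl(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_count,
                                        y = .data$median_weighted_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "raters included",
                  y = "median weighted consistency index") +
    ggplot2::theme_minimal()
  if (!is.null(plateau)) {
    p <- p + ggplot2::geom_vline(xintercept = plateau$plateau_raters,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a random-response null distribution
#'
#' Histogram of the simulated metric with an optional observed value marked.
#'
#' @param object A [simulate_random_null()] result.
#' @param observed Optional observed metric value.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(sample = object$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = paste("simulated", object$metric), y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red",
                                 linewidth = 0.8)
  }
  p
}

#' Plot bootstrap intervals
#'
#' Point estimates with percentile confidence intervals per item; for
#' difference intervals a zero reference line is drawn.
#'
#' @param object A [bootstrap_ci()] or [difference_ci()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bootstrap_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass_tbl(object))
  df <- dplyr::arrange(df, .data$estimate)
  df$item_id <- factor(df$item_id, levels = df$item_id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$item_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::labs(x = "n.mElo", y = NULL) +
    ggplot2::theme_minimal()
  if ("excludes_zero" %in% names(df)) {
    p <- p + ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "n.mElo difference")
  }
  p
}

#' Plot a rank-stability curve
#'
#' Mean absolute rank change per added respondent.
#'
#' @param object A [rank_stability_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rank_stability <- function(object, ...) {
  df <- tibble::as_tibble(unclass_tbl(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater_count,
                                   y = .data$mean_abs_rank_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "raters included", y = "mean |rank change|") +
    ggplot2::theme_minimal()
}
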