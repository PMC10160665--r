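# Item-level content validity indices from expert relevance ratings.

#' Item-level content validity indices (CVI)
#'
#' The CVI of an item is the proportion of expert raters who judged it
#' "quite" or "very" relevant. An item has good evidence of content
#' validity when its CVI is strictly greater than the threshold (default
#' 0.78, the conventional cut-off for three or more experts).
#'
#' @param ratings A long tibble with columns `rater_id`, `item_id`,
#'   `rating` (`not` / `somewhat` / `quite` / `very`, case-insensitive,
#'   optionally suffixed " relevant"); see [read_relevance_ratings()].
#' @param threshold Validity cut-off (strict inequality; default 0.78).
#' @return A `validity_report` tibble: `item_id`, `n_raters`, `cvi`,
#'   `content_valid`. `glance()` summarises the number and share of valid
#'   items.
#' @export
#' @examples
#' ratings <- tidyr::expand_grid(rater_id = paste0("R", 1:6),
#'                               item_id = c("C1", "C2"))
#' ratings$rating <- c(rep("very", 6), rep(c("quite", "not"), 3))
#' content_validity(ratings)
content_validity <- function(ratings, threshold = 0.78) {
  ratings <- tibble::as_tibble(ratings)
  ratings$rating <- normalize_relevance(ratings$rating)
  n_raters <- dplyr::n_distinct(ratings$rater_id)
  if (n_raters < 3) {
    abort("content validity requires ratings from at least 3 raters")
  }
  missing <- ratings |>
    dplyr::count(.data$item_id) |>
    dplyr::filter(.data$n < n_raters)
  if (nrow(missing) > 0) {
    warn(paste0("item(s) not rated by every rater: ",
                paste(head(missing$item_id, 5), collapse = ", ")))
  }
  out <- ratings |>
    dplyr::summarise(
      n_raters = dplyr::n_distinct(.data$rater_id),
      cvi = mean(.data$rating %in% c("quite", "very")),
      .by = "item_id"
    ) |>
    dplyr::mutate(content_valid = .data$cvi > threshold)
  new_tbl_subclass(out, "validity_report", threshold = threshold)
}

#' @export
glance.validity_report <- function(x, ...) {
  tibble::tibble(n_items = nrow(x),
                 n_valid = sum(x$content_valid),
                 share_valid = mean(x$content_valid),
                 threshold = attr(x, "threshold"))
}

#' @export
tidy.validity_report <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @export
print.validity_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Content validity: %d of %d items valid (%.0f%%) at CVI > %.2f\n",
              g$n_valid, g$n_items, 100 * g$share_valid, g$threshold))
  NextMethod()
}
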