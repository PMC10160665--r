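# Running consistency indices and the rater-inclusion plateau curve.

#' Running consistency index of a comparison stream
#'
#' Processes the records sequentially while maintaining running Elo ratings.
#' A record whose two items have unequal standing ratings is *evaluated*; it
#' is an *upset* when the lower-rated item wins. The unweighted index is
#' `1 - n_upsets / n_evaluated`; the weighted index divides weighted upset
#' mass by weighted evaluated mass, so larger upsets (bigger standing rating
#' gaps) hurt more. Records whose items share a standing rating — including
#' every item's first appearance at the common start — enter neither count.
#'
#' @param records A SKIP-free comparison tibble (in respondent presentation
#'   order; the index is order-dependent by construction).
#' @param items Item tibble or id vector.
#' @param cfg An [elo_config()].
#' @param weighting `"rating_diff"` (default): weight = |standing rating
#'   difference|; `"margin"`: weight = `2 * |E_winner - 0.5|`.
#' @return A one-row `consistency_result` tibble: `unweighted_index`,
#'   `weighted_index`, `n_evaluated`, `n_upsets`.
#' @export
consistency_index <- function(records, items, cfg = elo_config(),
                              weighting = c("rating_diff", "margin")) {
  cfg <- as_elo_config(cfg)
  weighting <- match.arg(weighting)
  assert_skip_free(records)
  ids <- item_ids_of(items)
  wl <- winner_loser_idx(records, ids)
  res <- consistency_cpp(wl$winner, wl$loser, length(ids),
                         cfg$k_factor, cfg$scale, cfg$start_rating,
                         if (weighting == "rating_diff") 0L else 1L)
  if (res$n_evaluated == 0) {
    abort("no evaluated records: all comparisons met at equal standing ratings")
  }
  new_tbl_subclass(
    tibble::tibble(
      unweighted_index = 1 - res$n_upsets / res$n_evaluated,
      weighted_index = 1 - res$weight_upsets / res$weight_evaluated,
      n_evaluated = as.integer(res$n_evaluated),
      n_upsets = as.integer(res$n_upsets)
    ),
    "consistency_result", weighting = weighting
  )
}

#' Weighted consistency index versus number of raters included
#'
#' For each of `n_trials` randomized rater-inclusion orders, the weighted
#' consistency index is computed on the pooled records of the first
#' r = 1..R respondents (keeping each respondent's own record order). The
#' reported curve is the median across trials at each rater count; its
#' plateau indicates the sample size at which rankings stabilize.
#'
#' @inheritParams consistency_index
#' @param n_trials Number of randomized inclusion orders (default 10).
#' @param seed Integer seed.
#' @return A `plateau_curve` tibble: `rater_count`, `median_weighted_index`;
#'   per-trial values in `attr(, "trials")`.
#' @export
plateau_curve <- function(records, items, cfg = elo_config(), n_trials = 10,
                          seed = NULL) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  resp <- unique(records$respondent_id)
  if (length(resp) < 2) {
    abort("plateau_curve needs at least 2 respondents")
  }
  ids <- item_ids_of(items)
  wl <- winner_loser_idx(records, ids)
  resp_idx <- split(seq_len(nrow(records)), factor(records$respondent_id, resp))
  R <- length(resp)
  seed <- seed %||% cfg$seed
  trials <- with_seed(seed, {
    vapply(seq_len(n_trials), function(tr) {
      ord <- sample.int(R)
      vapply(seq_len(R), function(r) {
        rows <- unlist(resp_idx[ord[seq_len(r)]], use.names = FALSE)
        res <- consistency_cpp(wl$winner[rows], wl$loser[rows], length(ids),
                               cfg$k_factor, cfg$scale, cfg$start_rating, 0L)
        if (res$weight_evaluated == 0) NA_real_
        else 1 - res$weight_upsets / res$weight_evaluated
      }, numeric(1))
    }, numeric(R))
  })
  out <- tibble::tibble(
    rater_count = seq_len(R),
    median_weighted_index = apply(trials, 1, median, na.rm = TRUE)
  )
  new_tbl_subclass(out, "plateau_curve",
                   trials = trials, n_trials = n_trials, seed = seed)
}

#' Detect the plateau of a rater-inclusion curve
#'
#' Returns the smallest rater count r such that every median at r' >= r lies
#' within `tolerance` of the final median. When only the final point itself
#' qualifies, the curve never stabilized early and `stabilized` is `FALSE`
#' (with a warning).
#'
#' @param curve A [plateau_curve()].
#' @param tolerance Half-width of the stability band (default 0.01).
#' @return A one-row tibble: `plateau_raters`, `stabilized`, `tolerance`,
#'   `final_median`.
#' @export
detect_plateau <- function(curve, tolerance = 0.01) {
  if (nrow(curve) < 3) abort("plateau detection needs a curve with >= 3 points")
  med <- curve$median_weighted_index
  R <- length(med)
  final <- med[R]
  ok <- abs(med - final) < tolerance
  # smallest r whose whole suffix stays in the band
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  r <- which(suffix_ok)[1]
  stabilized <- r < R
  if (!stabilized) {
    warn("curve does not stabilize within tolerance before the final rater")
  }
  tibble::tibble(plateau_raters = curve$rater_count[r],
                 stabilized = stabilized,
                 tolerance = tolerance,
                 final_median = final)
}
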