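# Elo engine: sequential rating updates, mElo over randomized sequences,
# min-max normalization (n.mElo), ranks and theme medians.

#' Elo engine configuration
#'
#' Every item starts at the same arbitrary rating (`start_rating`, default 0).
#' After each comparison the winner gains `k_factor * (1 - E_winner)` and the
#' loser loses the same amount, where `E` is the logistic expected score with
#' base 10 and spread `scale` (default 400) — the configuration of the
#' comparative-judgement literature. Because the final ratings depend on the
#' order in which the pooled comparisons are processed, ratings are averaged
#' over `n_sequences` uniformly shuffled orders (mElo; default 500).
#'
#' @param start_rating Common starting rating (default 0).
#' @param k_factor Maximum rating change from one comparison (default 100).
#' @param scale Logistic spread constant (default 400).
#' @param n_sequences Number of randomized processing sequences for mElo
#'   (default 500).
#' @param seed Default integer seed used by seeded operations when they are
#'   not given one explicitly.
#' @return An `elo_config` list.
#' @export
elo_config <- function(start_rating = 0, k_factor = 100, scale = 400,
                       n_sequences = 500, seed = NULL) {
  stopifnot(k_factor > 0, scale > 0, n_sequences >= 1)
  structure(list(start_rating = start_rating, k_factor = k_factor,
                 scale = scale, n_sequences = as.integer(n_sequences),
                 seed = seed),
            class = "elo_config")
}

as_elo_config <- function(cfg) {
  if (inherits(cfg, "elo_config")) return(cfg)
  if (is.null(cfg)) return(elo_config())
  do.call(elo_config, cfg)
}

#' Expected score of the first item in a comparison
#'
#' `E_a = 1 / (1 + 10^((r_b - r_a) / scale))`; `E_a + E_b = 1`. Vectorized.
#'
#' @param r_a,r_b Ratings of the two items.
#' @param scale Logistic spread constant.
#' @return The probability that the first item "wins".
#' @export
#' @examples
#' expected_score(0, 0)        # 0.5
#' expected_score(400, 0, 400) # 10/11
expected_score <- function(r_a, r_b, scale = 400) {
  stopifnot(scale > 0)
  1 / (1 + 10^((r_b - r_a) / scale))
}

#' Apply a single comparison outcome to a rating vector
#'
#' The winner gains `k * (1 - E_winner)`; the loser loses the same amount
#' (a zero-sum update). All other ratings are untouched.
#'
#' @param ratings Named numeric vector of current ratings.
#' @param winner,loser Item ids present in `ratings`.
#' @param cfg An [elo_config()].
#' @return The updated rating vector.
#' @export
apply_comparison <- function(ratings, winner, loser, cfg = elo_config()) {
  cfg <- as_elo_config(cfg)
  if (winner == loser) abort("winner and loser must differ")
  if (!winner %in% names(ratings) || !loser %in% names(ratings)) {
    abort("winner and loser must both be present in the rating vector")
  }
  e <- expected_score(ratings[[winner]], ratings[[loser]], cfg$scale)
  d <- cfg$k_factor * (1 - e)
  ratings[[winner]] <- ratings[[winner]] + d
  ratings[[loser]] <- ratings[[loser]] - d
  ratings
}

#' Remove "I do not understand" responses
#'
#' Drops all SKIP-outcome records (preserving order) and reports how many
#' were removed via a message and the `n_skipped` attribute.
#'
#' @param records A comparison tibble.
#' @param quiet Suppress the message.
#' @return The SKIP-free tibble with attribute `n_skipped`.
#' @export
filter_skips <- function(records, quiet = FALSE) {
  n0 <- nrow(records)
  out <- records[records$outcome != "SKIP", ]
  removed <- n0 - nrow(out)
  if (!quiet) {
    inform(paste0("filter_skips: removed ", removed, " SKIP record(s) of ", n0))
  }
  attr(out, "n_skipped") <- removed
  out
}

#' Run one sequential Elo pass
#'
#' Starts every item at `start_rating` and applies the comparisons in the
#' given order. Items never compared retain the starting rating.
#'
#' @param records A SKIP-free comparison tibble.
#' @param items An item tibble or character vector of item ids.
#' @param cfg An [elo_config()].
#' @return A tibble with columns `item_id`, `rating`.
#' @export
run_sequence <- function(records, items, cfg = elo_config()) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  ids <- item_ids_of(items)
  if (nrow(records) == 0) {
    return(tibble::tibble(item_id = ids, rating = cfg$start_rating))
  }
  wl <- winner_loser_idx(records, ids)
  r <- elo_run_cpp(wl$winner, wl$loser, length(ids),
                   cfg$k_factor, cfg$scale, cfg$start_rating)
  tibble::tibble(item_id = ids, rating = as.numeric(r))
}

#' Mean Elo ratings over randomized sequences (mElo)
#'
#' Runs the sequential Elo pass over `cfg$n_sequences` uniformly shuffled
#' orders of the pooled records and averages the final ratings per item,
#' removing the order dependence of a single pass. Only the record order is
#' resampled — never the outcomes, never with replacement.
#'
#' @inheritParams run_sequence
#' @param seed Integer seed (falls back to `cfg$seed`); results are
#'   bit-reproducible given the seed.
#' @param keep_sequences Keep the per-sequence rating matrix in
#'   `attr(, "sequences")`.
#' @return A `rating_table` tibble with columns `item_id`, `melo` (plus
#'   `label`/`theme` when `items` is a tibble).
#' @export
mean_elo <- function(records, items, cfg = elo_config(), seed = NULL,
                     keep_sequences = FALSE) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  if (nrow(records) == 0) {
    abort("no records: mElo is undefined on an empty comparison set")
  }
  ids <- item_ids_of(items)
  wl <- winner_loser_idx(records, ids)
  seed <- seed %||% cfg$seed
  mat <- with_seed(seed, {
    elo_sequences_cpp(wl$winner, wl$loser, length(ids),
                      cfg$k_factor, cfg$scale, cfg$start_rating,
                      cfg$n_sequences)
  })
  out <- tibble::tibble(item_id = ids, melo = rowMeans(mat))
  if (is.data.frame(items)) {
    out <- dplyr::left_join(out, items, by = "item_id") |>
      dplyr::select("item_id", dplyr::any_of(c("label", "theme")), "melo")
  }
  out <- new_tbl_subclass(out, "rating_table",
                          cfg = cfg, seed = seed,
                          n_records = nrow(records))
  if (keep_sequences) attr(out, "sequences") <- mat
  out
}

#' Min-max normalize mElo ratings to n.mElo
#'
#' `nmelo = (melo - min) / (max - min)`: the least important item maps to 0,
#' the most important to 1, and rating distances stay proportional to the
#' original mElo differences (the transform is affine-invariant). A table in
#' which all mElo values are equal carries no usable signal and is a hard
#' error.
#'
#' @param rating_table A `rating_table` with `melo` filled.
#' @return The table with an `nmelo` column added.
#' @export
minmax_normalize <- function(rating_table) {
  m <- rating_table$melo
  if (length(m) < 2) abort("need at least 2 items to normalize")
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    abort("all mElo ratings are equal: normalization is degenerate (no signal)")
  }
  rating_table$nmelo <- (m - rng[1]) / (rng[2] - rng[1])
  rating_table
}

#' Rank items by n.mElo
#'
#' Rank 1 is the highest n.mElo. Exact ties are broken lexicographically by
#' `item_id` and flagged in a logical `tie` column.
#'
#' @param rating_table A `rating_table` with `nmelo` filled.
#' @return The table with `rank` and `tie` columns, sorted by rank.
#' @export
rank_items <- function(rating_table) {
  if (is.null(rating_table$nmelo)) {
    abort("nmelo not filled: run minmax_normalize() first")
  }
  ord <- order(-rating_table$nmelo, rating_table$item_id)
  out <- rating_table[ord, ]
  out$rank <- seq_len(nrow(out))
  dup <- duplicated(out$nmelo) | duplicated(out$nmelo, fromLast = TRUE)
  out$tie <- dup
  out
}

#' Theme-level medians of n.mElo ratings
#'
#' Median n.mElo of each theme's member items (midpoint of the two central
#' values for even counts), with themes ranked by median descending.
#'
#' @param rating_table A ranked `rating_table`.
#' @param items Item tibble supplying `theme` when the rating table lacks it.
#' @return A `theme_summary` tibble: `theme`, `n_items`, `median_nmelo`,
#'   `rank`.
#' @export
theme_medians <- function(rating_table, items = NULL) {
  tab <- rating_table
  if (!"theme" %in% names(tab) && !is.null(items)) {
    tab <- dplyr::left_join(tab, items[, c("item_id", "theme")], by = "item_id")
  }
  if (!"theme" %in% names(tab) || any(is.na(tab$theme))) {
    missing <- if ("theme" %in% names(tab)) {
      tab$item_id[is.na(tab$theme)]
    } else {
      tab$item_id
    }
    abort(paste0("item(s) without a theme: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out <- tab |>
    dplyr::summarise(n_items = dplyr::n(),
                     median_nmelo = median(.data$nmelo),
                     .by = "theme") |>
    dplyr::arrange(dplyr::desc(.data$median_nmelo), .data$theme)
  out$rank <- seq_len(nrow(out))
  new_tbl_subclass(out, "theme_summary")
}

#' Rate items from pooled comparisons (full pipeline)
#'
#' Convenience wrapper: [filter_skips()] then [mean_elo()],
#' [minmax_normalize()] and [rank_items()].
#'
#' @inheritParams mean_elo
#' @return A ranked `rating_table` (columns `item_id`, `melo`, `nmelo`,
#'   `rank`, `tie`).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_items = 8, n_respondents = 20,
#'                                            m_per_respondent = 10, seed = 1))
#' elo_rate(cohort$records, cohort$items,
#'          elo_config(n_sequences = 50), seed = 1)
elo_rate <- function(records, items, cfg = elo_config(), seed = NULL,
                     keep_sequences = FALSE) {
  records |>
    filter_skips(quiet = TRUE) |>
    mean_elo(items, cfg, seed = seed, keep_sequences = keep_sequences) |>
    minmax_normalize() |>
    rank_items()
}

#' @export
tidy.rating_table <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @export
glance.rating_table <- function(x, ...) {
  cfg <- attr(x, "cfg")
  tibble::tibble(
    n_items = nrow(x),
    n_records = attr(x, "n_records") %||% NA_integer_,
    n_sequences = cfg$n_sequences,
    k_factor = cfg$k_factor,
    scale = cfg$scale,
    melo_range = diff(range(x$melo)),
    top_item = if (!is.null(x$rank)) x$item_id[x$rank == 1] else NA_character_
  )
}

#' @export
print.rating_table <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat("Elo rating table:", nrow(x), "items,",
      attr(x, "n_records") %||% NA, "comparisons,",
      cfg$n_sequences, "sequences\n")
  NextMethod()
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  for (a in c("cfg", "seed", "n_records", "sequences", "triplets")) {
    attr(x, a) <- NULL
  }
  x
}
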