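# Survey design: pair bank, randomized question assignment, triplet test.

#' Build the bank of all possible item pairs
#'
#' All n(n-1)/2 unordered pairs, ordered lexicographically by
#' (min id, max id) for determinism.
#'
#' @param items An item tibble or a character vector of item ids.
#' @return A tibble with columns `item_a`, `item_b` (`item_a` < `item_b`).
#' @export
#' @examples
#' all_pairs(c("A", "B", "C"))
all_pairs <- function(items) {
  ids <- sort(item_ids_of(items))
  n <- length(ids)
  if (n < 2) {
    abort("need at least 2 items to form pairs")
  }
  idx <- utils::combn(n, 2)
  tibble::tibble(item_a = ids[idx[1, ]], item_b = ids[idx[2, ]])
}

#' Randomly assign question subsets to respondents
#'
#' Each respondent independently receives `m` distinct pairs sampled
#' uniformly without replacement from the bank (a pair may be seen by many
#' respondents), in shuffled order, with each pair's option order decided by
#' a fair coin.
#'
#' @param bank A pair bank from [all_pairs()].
#' @param respondent_ids Character vector of respondent ids.
#' @param m Questions per respondent; must not exceed the bank size.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A tibble with columns `respondent_id`, `presentation_index`,
#'   `first_item`, `second_item`.
#' @export
assign_questions <- function(bank, respondent_ids, m, seed = NULL) {
  if (m > nrow(bank)) {
    abort(paste0("m = ", m, " exceeds the pair bank size ", nrow(bank)))
  }
  with_seed(seed, {
    purrr::map_dfr(respondent_ids, function(rid) {
      rows <- sample.int(nrow(bank), m)
      flip <- runif(m) < 0.5
      tibble::tibble(
        respondent_id = rid,
        presentation_index = seq_len(m) - 1L,
        first_item = ifelse(flip, bank$item_b[rows], bank$item_a[rows]),
        second_item = ifelse(flip, bank$item_a[rows], bank$item_b[rows])
      )
    })
  })
}

#' Construct a triplet-based reliability test
#'
#' Selects `3 * n_triplets` distinct items uniformly at random, partitions
#' them into triplets (A, B, C) and emits four questions per triplet —
#' (A,B), (B,C), (A,C) and the symmetry probe (B,A) — in randomized order.
#'
#' @param items An item tibble or character vector of item ids.
#' @param n_triplets Number of triplets (13 gives the 39-item, 52-question
#'   test).
#' @param seed Integer seed.
#' @return A `triplet_test` tibble with columns `triplet_id`,
#'   `presentation_index`, `first_item`, `second_item`; the triplet
#'   memberships are in `attr(, "triplets")`.
#' @export
build_triplet_test <- function(items, n_triplets, seed = NULL) {
  ids <- item_ids_of(items)
  if (length(ids) < 3 * n_triplets) {
    abort(paste0("need at least ", 3 * n_triplets, " items for ",
                 n_triplets, " triplets"))
  }
  with_seed(seed, {
    chosen <- sample(ids, 3 * n_triplets)
    trip <- tibble::tibble(
      triplet_id = rep(seq_len(n_triplets), each = 3),
      member = rep(c("A", "B", "C"), n_triplets),
      item_id = chosen
    )
    wide <- tidyr::pivot_wider(trip, names_from = "member",
                               values_from = "item_id")
    q <- purrr::pmap_dfr(wide, function(triplet_id, A, B, C) {
      tibble::tibble(
        triplet_id = triplet_id,
        first_item = c(A, B, A, B),
        second_item = c(B, C, C, A)
      )
    })
    q <- q[sample.int(nrow(q)), ]
    q$presentation_index <- seq_len(nrow(q)) - 1L
    out <- q[, c("triplet_id", "presentation_index", "first_item", "second_item")]
    new_tbl_subclass(out, "triplet_test", triplets = wide)
  })
}

#' @export
print.triplet_test <- function(x, ...) {
  cat("Triplet reliability test:", nrow(attr(x, "triplets")), "triplets,",
      nrow(x), "questions\n")
  NextMethod()
}
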