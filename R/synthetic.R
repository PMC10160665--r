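# Synthetic respondents: latent item-importance scores driving probabilistic
# binary choices, with a small "I do not understand" (SKIP) probability.

#' Configuration for the synthetic respondent cohort
#'
#' The cohort emulates the generative structure the rating method assumes: a
#' group sharing latent item-importance scores `theta`, each respondent
#' answering a random subset of the pair bank. Item i is chosen over item j
#' with probability `plogis(beta * (theta_i - theta_j))` (a Bradley-Terry /
#' logistic choice model); with probability `epsilon` the respondent skips
#' the question instead.
#'
#' Defaults mirror the study conditions: 91 items in 7 themes, 901
#' respondents answering 50 comparisons each, and a SKIP probability of
#' 0.0034 (0.34% of answers).
#'
#' @param n_items Number of items (default 91).
#' @param n_themes Number of themes items are cycled into (default 7).
#' @param theta Optional vector of latent importance scores (length
#'   `n_items`); drawn standard normal when `NULL`.
#' @param beta Discrimination of the choice model (>= 0): 0 gives uniform
#'   random choice, large values near-deterministic choice (default 2).
#' @param epsilon SKIP probability per question (default 0.0034).
#' @param n_respondents Number of respondents (default 901).
#' @param m_per_respondent Questions per respondent (default 50).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_items = 91, n_themes = 7, theta = NULL,
                             beta = 2, epsilon = 0.0034, n_respondents = 901,
                             m_per_respondent = 50, seed = NULL) {
  stopifnot(n_items >= 2, beta >= 0, epsilon >= 0, epsilon <= 1,
            n_respondents >= 1,
            m_per_respondent <= n_items * (n_items - 1) / 2)
  if (!is.null(theta) && length(theta) != n_items) {
    abort("theta must have one entry per item")
  }
  structure(list(n_items = n_items, n_themes = n_themes, theta = theta,
                 beta = beta, epsilon = epsilon,
                 n_respondents = n_respondents,
                 m_per_respondent = m_per_respondent, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic survey cohort
#'
#' Builds the item set (ids `I01`, `I02`, ... cycled over themes), draws or
#' takes the latent scores, assigns each respondent a random question subset
#' via [assign_questions()] (randomized option order), and samples each
#' answer from the logistic choice model with SKIP probability `epsilon`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `items` (tibble), `theta` (tibble `item_id`, `theta`),
#'   `records` (validated comparison tibble).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_items = 6, n_respondents = 5,
#'                                            m_per_respondent = 4, seed = 42))
#' cohort$records
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    width <- max(2, nchar(as.character(cfg$n_items)))
    ids <- sprintf(paste0("I%0", width, "d"), seq_len(cfg$n_items))
    items <- tibble::tibble(
      item_id = ids,
      label = paste("Characteristic", seq_len(cfg$n_items)),
      theme = paste0("T", (seq_len(cfg$n_items) - 1) %% cfg$n_themes + 1)
    )
    theta <- cfg$theta %||% rnorm(cfg$n_items)
    names(theta) <- ids
    bank <- all_pairs(items)
    assign <- assign_questions(
      bank, sprintf("R%04d", seq_len(cfg$n_respondents)),
      cfg$m_per_respondent
    )
    th1 <- theta[assign$first_item]
    th2 <- theta[assign$second_item]
    p_first <- plogis(cfg$beta * (th1 - th2))
    u <- runif(nrow(assign))
    outcome <- ifelse(runif(nrow(assign)) < cfg$epsilon, "SKIP",
                      ifelse(u < p_first, "FIRST", "SECOND"))
    records <- as_comparisons(
      tibble::tibble(
        respondent_id = assign$respondent_id,
        group = "all",
        first_item = assign$first_item,
        second_item = assign$second_item,
        outcome = outcome,
        sitting = 1L,
        presentation_index = assign$presentation_index
      ),
      items = items
    )
    list(items = items,
         theta = tibble::tibble(item_id = ids, theta = unname(theta)),
         records = records)
  })
}

#' Parameter recovery between latent scores and recovered ratings
#'
#' Rank correlations (Spearman and Kendall) between the generative latent
#' importance scores and the n.mElo ratings recovered by the Elo pipeline.
#'
#' @param theta A tibble with `item_id`, `theta` (as from
#'   [generate_cohort()]) or a named numeric vector.
#' @param rating_table A `rating_table` with `nmelo` filled.
#' @return A one-row tibble: `spearman`, `kendall`, `n_items`.
#' @export
recovery <- function(theta, rating_table) {
  if (!is.data.frame(theta)) {
    theta <- tibble::tibble(item_id = names(theta), theta = unname(theta))
  }
  if (!setequal(theta$item_id, rating_table$item_id)) {
    abort("theta and rating table cover different item sets")
  }
  j <- dplyr::inner_join(theta, tibble::as_tibble(rating_table[, c("item_id", "nmelo")]),
                         by = "item_id")
  tibble::tibble(
    spearman = stats::cor(j$theta, j$nmelo, method = "spearman"),
    kendall = stats::cor(j$theta, j$nmelo, method = "kendall"),
    n_items = nrow(j)
  )
}

#' Simulate a reliability-test cohort with controllable consistency
#'
#' Each rater holds a fixed latent preference for every unordered item pair
#' and answers accordingly with probability `p_consistent` (else the answer
#' flips). The second sitting reuses the same latent preferences, so
#' `p_consistent = 1` gives perfect symmetry, transitivity and test-retest
#' stability while `p_consistent = 0.5` reproduces the uniform-random null.
#' Each rater's latent preferences derive from rater-specific latent item
#' values (so they are internally transitive); only the noise channel makes
#' answers inconsistent.
#'
#' @param test A [build_triplet_test()].
#' @param n_raters Number of raters.
#' @param p_consistent Probability of answering according to the latent
#'   preference, in \[0.5, 1\].
#' @param seed Integer seed.
#' @return A list of two response tibbles, `sitting1` and `sitting2`.
#' @export
simulate_reliability_cohort <- function(test, n_raters, p_consistent,
                                        seed = NULL) {
  if (p_consistent < 0.5 || p_consistent > 1) {
    abort("p_consistent must lie in [0.5, 1]")
  }
  test_items <- unique(c(test$first_item, test$second_item))
  with_seed(seed, {
    sittings <- lapply(1:2, function(s) vector("list", n_raters))
    for (r in seq_len(n_raters)) {
      # rater-specific latent item values fix a transitive preference over
      # every pair, reused in both sittings
      v <- setNames(runif(length(test_items)), test_items)
      for (s in 1:2) {
        latent_choice <- ifelse(v[test$first_item] > v[test$second_item],
                                test$first_item, test$second_item)
        follow <- runif(nrow(test)) < p_consistent
        chosen <- ifelse(follow, latent_choice,
                         ifelse(latent_choice == test$first_item,
                                test$second_item, test$first_item))
        sittings[[s]][[r]] <- tibble::tibble(
          respondent_id = sprintf("E%03d", r),
          triplet_id = test$triplet_id,
          first_item = test$first_item,
          second_item = test$second_item,
          outcome = ifelse(chosen == test$first_item, "FIRST", "SECOND"),
          sitting = s
        )
      }
    }
    list(sitting1 = dplyr::bind_rows(sittings[[1]]),
         sitting2 = dplyr::bind_rows(sittings[[2]]))
  })
}
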