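# Intra- and inter-rater reliability metrics for triplet-test and survey
# responses.

# Shared container for a per-respondent reliability metric.
new_reliability_metric <- function(metric, per_respondent, pooled_mean,
                                   pooled_count, n_units) {
  structure(list(metric = metric,
                 per_respondent = per_respondent,
                 pooled_mean = pooled_mean,
                 pooled_count = pooled_count,
                 n_units = n_units),
            class = "reliability_metric")
}

#' @export
print.reliability_metric <- function(x, ...) {
  cat(sprintf("%s: %.3f (respondent mean), %.3f (pooled counts), %d respondents\n",
              x$metric, x$pooled_mean, x$pooled_count, nrow(x$per_respondent)))
  invisible(x)
}

#' @export
tidy.reliability_metric <- function(x, ...) x$per_respondent

#' @export
glance.reliability_metric <- function(x, ...) {
  tibble::tibble(metric = x$metric, pooled_mean = x$pooled_mean,
                 pooled_count = x$pooled_count,
                 n_respondents = nrow(x$per_respondent))
}

prepare_responses <- function(responses) {
  resp <- tibble::as_tibble(responses)
  resp <- resp[resp$outcome != "SKIP", ]
  resp$chosen <- chosen_item(resp)
  resp$key <- pair_key(resp$first_item, resp$second_item)
  resp
}

#' Response-option symmetry consistency
#'
#' Proportion of symmetric question pairs — the same unordered item pair
#' asked in both orientations, (A,B) and (B,A) — answered with the same
#' underlying item, per respondent and pooled.
#'
#' @param responses Responses to a triplet test (columns `respondent_id`,
#'   `first_item`, `second_item`, `outcome`).
#' @param test The [build_triplet_test()] the responses answer.
#' @return A `reliability_metric`: per-respondent proportions, their mean
#'   (`pooled_mean`) and the pooled-count proportion (`pooled_count`).
#' @export
symmetry_consistency <- function(responses, test) {
  resp <- prepare_responses(responses)
  test_keys <- pair_key(test$first_item, test$second_item)
  sym_keys <- unique(test_keys[duplicated(test_keys)])
  df <- resp[resp$key %in% sym_keys, ] |>
    dplyr::summarise(n = dplyr::n(),
                     agree = dplyr::n_distinct(.data$chosen) == 1,
                     .by = c("respondent_id", "key"))
  incomplete <- df$n != 2
  if (any(incomplete)) {
    warn(paste0(sum(incomplete),
                " symmetric pair(s) missing an orientation were excluded"))
    df <- df[!incomplete, ]
  }
  if (nrow(df) == 0) abort("no complete symmetric pairs in the responses")
  per <- dplyr::summarise(df, proportion = mean(.data$agree),
                          n_pairs = dplyr::n(), .by = "respondent_id")
  new_reliability_metric("symmetry_consistency", per,
                         mean(per$proportion), mean(df$agree),
                         length(sym_keys))
}

#' Triplet transitivity
#'
#' A triplet (A, B, C) is transitive when the outcomes of (A,B), (B,C) and
#' (A,C) admit a strict total order — i.e. they are not one of the two cyclic
#' patterns among the 8 possible outcome combinations. Under uniform-random
#' responding the per-triplet transitive probability is exactly 6/8.
#'
#' @inheritParams symmetry_consistency
#' @return A `reliability_metric` of per-respondent transitive proportions.
#' @export
triplet_transitivity <- function(responses, test) {
  trips <- attr(test, "triplets")
  if (is.null(trips)) abort("test must be a triplet_test with triplet metadata")
  resp <- prepare_responses(responses)
  # transitivity reads the (A,B), (B,C), (A,C) questions in their canonical
  # orientation; the (B,A) symmetry probe is not part of the triplet logic
  long <- purrr::pmap_dfr(trips, function(triplet_id, A, B, C) {
    tibble::tibble(triplet_id = triplet_id,
                   role = c("ab", "bc", "ac"),
                   first_item = c(A, B, A),
                   second_item = c(B, C, C),
                   ref = c(A, B, A))
  })
  df <- resp[, c("respondent_id", "first_item", "second_item", "chosen")] |>
    dplyr::distinct(.data$respondent_id, .data$first_item, .data$second_item,
                    .keep_all = TRUE) |>
    dplyr::inner_join(long, by = c("first_item", "second_item")) |>
    dplyr::mutate(bit = .data$chosen == .data$ref) |>
    dplyr::select("respondent_id", "triplet_id", "role", "bit") |>
    tidyr::pivot_wider(names_from = "role", values_from = "bit")
  complete <- stats::complete.cases(df[, c("ab", "bc", "ac")])
  if (any(!complete)) {
    warn(paste0(sum(!complete), " incomplete triplet(s) were excluded"))
    df <- df[complete, ]
  }
  if (nrow(df) == 0) abort("no complete triplets in the responses")
  df$transitive <- !((df$ab & df$bc & !df$ac) | (!df$ab & !df$bc & df$ac))
  per <- dplyr::summarise(df, proportion = mean(.data$transitive),
                          n_triplets = dplyr::n(), .by = "respondent_id")
  new_reliability_metric("triplet_transitivity", per,
                         mean(per$proportion), mean(df$transitive),
                         nrow(trips))
}

#' Test-retest stability
#'
#' Proportion of questions answered with the same item in two sittings,
#' pooled over all respondent-question pairs, plus per-respondent
#' proportions and their min-max range.
#'
#' @param sitting1,sitting2 Response tibbles from the two sittings sharing
#'   question identities (respondent, first item, second item).
#' @return A `reliability_metric`; the per-respondent range is in
#'   `attr(, "range")`.
#' @export
test_retest <- function(sitting1, sitting2) {
  r1 <- prepare_responses(sitting1)
  r2 <- prepare_responses(sitting2)
  df <- dplyr::inner_join(
    r1[, c("respondent_id", "first_item", "second_item", "chosen")],
    r2[, c("respondent_id", "first_item", "second_item", "chosen")],
    by = c("respondent_id", "first_item", "second_item"),
    suffix = c("_1", "_2")
  )
  if (nrow(df) == 0) abort("the two sittings share no questions")
  df$same <- df$chosen_1 == df$chosen_2
  per <- dplyr::summarise(df, proportion = mean(.data$same),
                          n_questions = dplyr::n(), .by = "respondent_id")
  out <- new_reliability_metric("test_retest", per,
                                mean(per$proportion), mean(df$same),
                                dplyr::n_distinct(df$first_item, df$second_item))
  attr(out, "range") <- range(per$proportion)
  out
}

#' Consensus rates and the weighted mean consensus rate (WMCR)
#'
#' For every question (unordered item pair) answered by at least two
#' respondents, the consensus rate is the proportion choosing the modal
#' item. The WMCR averages the per-question rates weighted by how many
#' times each question was answered.
#'
#' @param records Comparison records or reliability-test responses (SKIPs
#'   are dropped).
#' @return A `consensus_result`: `$rates` (per-question tibble) and `$wmcr`.
#' @export
consensus_rates <- function(records) {
  resp <- prepare_responses(records)
  rates <- resp |>
    dplyr::summarise(n_answers = dplyr::n(),
                     modal = max(table(.data$chosen)),
                     .by = "key") |>
    dplyr::filter(.data$n_answers >= 2) |>
    dplyr::mutate(rate = .data$modal / .data$n_answers)
  if (nrow(rates) == 0) {
    abort("no question was answered by more than one respondent")
  }
  keys <- strsplit(rates$key, "\r", fixed = TRUE)
  rates$item_a <- vapply(keys, `[`, "", 1)
  rates$item_b <- vapply(keys, `[`, "", 2)
  structure(
    list(rates = rates[, c("item_a", "item_b", "n_answers", "rate")],
         wmcr = sum(rates$rate * rates$n_answers) / sum(rates$n_answers)),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus: %d multi-rater questions, WMCR = %.3f\n",
              nrow(x$rates), x$wmcr))
  invisible(x)
}

#' @export
tidy.consensus_result <- function(x, ...) x$rates

#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(wmcr = x$wmcr, n_questions = nrow(x$rates),
                 n_answers = sum(x$rates$n_answers))
}

#' Full reliability report for a triplet test
#'
#' Bundles symmetry consistency, triplet transitivity, consensus rates /
#' WMCR and (when a second sitting is supplied) test-retest stability.
#'
#' @inheritParams symmetry_consistency
#' @param retest Optional second-sitting responses.
#' @return A `reliability_report` list; `tidy()` gives one row per metric.
#' @export
reliability_report <- function(responses, test, retest = NULL) {
  rep <- list(
    symmetry = symmetry_consistency(responses, test),
    transitivity = triplet_transitivity(responses, test),
    consensus = consensus_rates(responses),
    test_retest = if (!is.null(retest)) test_retest(responses, retest)
  )
  structure(rep, class = "reliability_report")
}

#' @export
tidy.reliability_report <- function(x, ...) {
  rows <- list(
    glance(x$symmetry),
    glance(x$transitivity),
    tibble::tibble(metric = "wmcr", pooled_mean = x$consensus$wmcr,
                   pooled_count = x$consensus$wmcr,
                   n_respondents = NA_integer_)
  )
  if (!is.null(x$test_retest)) rows <- c(rows, list(glance(x$test_retest)))
  dplyr::bind_rows(rows)
}

#' @export
print.reliability_report <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}
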