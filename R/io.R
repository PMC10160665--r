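# CSV readers/writers and response summaries.
#
# All interchange is RFC-4180 CSV (UTF-8). Columns `group`, `sitting` and
# `presentation_index` are optional in comparison files: absent columns
# default to group = "all", sitting = 1 and within-respondent row order.

#' Read an item list
#'
#' Reads a CSV with columns `item_id`, `label` and optionally `theme`.
#' Input order is preserved so downstream iteration is deterministic.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `item_id`, `label`, `theme` (`NA` when the
#'   file has no theme column).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("item_id,label,theme", "C01,Time management,Self",
#'              "C02,Asking for help,Self"), f)
#' read_items(f)
read_items <- function(path) {
  items <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(items) == 0) {
    abort(paste0("item file is empty: ", path))
  }
  if (!all(c("item_id", "label") %in% names(items))) {
    abort("item file must have columns item_id,label[,theme]")
  }
  if (!"theme" %in% names(items)) {
    items$theme <- NA_character_
  }
  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate item_id in item file: ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(items$label) | items$label == "")) {
    abort("item labels must be non-empty")
  }
  tibble::as_tibble(items[, c("item_id", "label", "theme")])
}

#' Read comparison-response records
#'
#' Reads a CSV of pairwise-comparison answers with columns `respondent_id`,
#' `first_item`, `second_item`, `outcome` and optionally `group`, `sitting`,
#' `presentation_index`. Outcomes are `FIRST`, `SECOND` or `SKIP`
#' (case-insensitive); `SKIP` encodes the "I do not understand one or both
#' of the options" response. Every record is validated against `items`.
#'
#' @param path Path to a CSV file.
#' @param items An item tibble (from [read_items()]) or a character vector of
#'   item ids; when supplied, unknown ids are an error.
#' @return A tibble of validated records in file order.
#' @export
read_comparisons <- function(path, items = NULL) {
  rec <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("respondent_id", "first_item", "second_item", "outcome")
  if (!all(need %in% names(rec))) {
    abort(paste0("comparison file must have columns ",
                 paste(need, collapse = ","), "[,group,sitting,presentation_index]"))
  }
  rec <- as_comparisons(rec, items = items)
  rec
}

#' Coerce and validate a comparison data frame
#'
#' Normalises outcome tokens to upper case, fills optional columns
#' (`group = "all"`, `sitting = 1`, `presentation_index` = within-respondent
#' row order) and checks invariants: no self-pairs, known outcome tokens and
#' (when `items` is given) only known item ids.
#'
#' @param records A data frame of comparison records.
#' @inheritParams read_comparisons
#' @return A validated tibble with the full column set.
#' @export
as_comparisons <- function(records, items = NULL) {
  rec <- tibble::as_tibble(records)
  rec$outcome <- toupper(as.character(rec$outcome))
  bad_outcome <- which(!rec$outcome %in% outcome_levels)
  if (length(bad_outcome) > 0) {
    abort(paste0("unknown outcome token in row(s) ",
                 paste(head(bad_outcome, 5), collapse = ", "),
                 ": expected FIRST/SECOND/SKIP"))
  }
  if (!"group" %in% names(rec) || all(is.na(rec$group))) rec$group <- "all"
  if (!"sitting" %in% names(rec)) rec$sitting <- 1L
  rec$sitting <- as.integer(rec$sitting)
  if (!"presentation_index" %in% names(rec)) {
    rec <- rec |>
      dplyr::group_by(.data$respondent_id) |>
      dplyr::mutate(presentation_index = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
  }
  rec$presentation_index <- as.integer(rec$presentation_index)
  self <- which(rec$first_item == rec$second_item)
  if (length(self) > 0) {
    abort(paste0("first_item equals second_item in row(s) ",
                 paste(head(self, 5), collapse = ", ")))
  }
  if (!is.null(items)) {
    ids <- item_ids_of(items)
    unknown <- which(!(rec$first_item %in% ids) | !(rec$second_item %in% ids))
    if (length(unknown) > 0) {
      bad <- setdiff(unique(c(rec$first_item, rec$second_item)), ids)
      abort(paste0("unknown item id(s) ", paste(bad, collapse = ", "),
                   " in row(s) ", paste(head(unknown, 5), collapse = ", ")))
    }
  }
  rec[, c("respondent_id", "group", "first_item", "second_item",
          "outcome", "sitting", "presentation_index")]
}

#' Write comparison records
#'
#' @param records A comparison tibble.
#' @param path Output CSV path.
#' @return `records`, invisibly.
#' @export
write_comparisons <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(records)
}

#' Summarize response proportions
#'
#' Pooled and per-respondent proportions of FIRST / SECOND / SKIP selections.
#' With randomized option order and no position bias the FIRST and SECOND
#' proportions should each sit near 0.5.
#'
#' @param records A comparison tibble.
#' @return A `response_summary` object: `$pooled` (outcome, n, proportion)
#'   and `$by_respondent` (one row per respondent). `glance()` gives the
#'   pooled proportions as a single row.
#' @export
summarize_responses <- function(records) {
  if (nrow(records) == 0) {
    abort("no records to summarize")
  }
  pooled <- tibble::tibble(outcome = outcome_levels) |>
    dplyr::left_join(dplyr::count(records, .data$outcome), by = "outcome") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  proportion = .data$n / sum(.data$n))
  by_resp <- records |>
    dplyr::count(.data$respondent_id, .data$outcome) |>
    dplyr::group_by(.data$respondent_id) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "proportion",
                       values_fill = 0) |>
    dplyr::rename_with(tolower)
  for (col in c("first", "second", "skip")) {
    if (!col %in% names(by_resp)) by_resp[[col]] <- 0
  }
  structure(
    list(pooled = pooled,
         by_respondent = by_resp[, c("respondent_id", "first", "second", "skip")]),
    class = "response_summary"
  )
}

#' @export
glance.response_summary <- function(x, ...) {
  tibble::tibble(
    n_records = sum(x$pooled$n),
    n_respondents = nrow(x$by_respondent),
    p_first = x$pooled$proportion[x$pooled$outcome == "FIRST"],
    p_second = x$pooled$proportion[x$pooled$outcome == "SECOND"],
    p_skip = x$pooled$proportion[x$pooled$outcome == "SKIP"]
  )
}

#' @export
tidy.response_summary <- function(x, ...) x$by_respondent

#' @export
print.response_summary <- function(x, ...) {
  cat("Response summary:", sum(x$pooled$n), "records,",
      nrow(x$by_respondent), "respondents\n")
  print(x$pooled)
  invisible(x)
}

#' Read an expert relevance-rating matrix
#'
#' Long CSV with columns `rater_id`, `item_id`, `rating`, the input to
#' [content_validity()]. Ratings are `not`, `somewhat`, `quite` or `very`
#' (case-insensitive; a trailing " relevant" is tolerated).
#'
#' @param path Path to a CSV file.
#' @return A tibble with normalised rating tokens.
#' @export
read_relevance_ratings <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("rater_id", "item_id", "rating")
  if (!all(need %in% names(x))) {
    abort("relevance file must have columns rater_id,item_id,rating")
  }
  x$rating <- normalize_relevance(x$rating)
  tibble::as_tibble(x[, need])
}

normalize_relevance <- function(rating) {
  r <- tolower(trimws(as.character(rating)))
  r <- sub("[[:space:]]+relevant$", "", r)
  bad <- which(!r %in% c("not", "somewhat", "quite", "very"))
  if (length(bad) > 0) {
    abort(paste0("unknown relevance rating ", unique(rating[bad])[1],
                 " at row(s) ", paste(head(bad, 5), collapse = ", ")))
  }
  r
}

#' Read a run configuration file
#'
#' YAML key-value file overriding [elo_config()] defaults and replicate
#' counts (`n_boot`, `n_perm`, `n_sims`, `n_trials`, `seed`, ...).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
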