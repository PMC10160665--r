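# Shared fixtures and an independent pure-R Elo oracle for cross-checks.

make_items <- function(n, themes = NULL) {
  tibble::tibble(
    item_id = sprintf("I%02d", seq_len(n)),
    label = paste("item", seq_len(n)),
    theme = if (is.null(themes)) NA_character_ else themes
  )
}

# Quick comparison tibble from parallel vectors.
make_records <- function(first, second, outcome,
                         respondent = "R1", group = "all", sitting = 1L) {
  as_comparisons(tibble::tibble(
    respondent_id = rep_len(respondent, length(first)),
    group = rep_len(group, length(first)),
    first_item = first,
    second_item = second,
    outcome = outcome,
    sitting = rep_len(sitting, length(first))
  ))
}

# Records in which `winner` beats `loser`, in the given order.
records_of_wins <- function(winners, losers, respondent = "R1") {
  make_records(winners, losers, rep("FIRST", length(winners)),
               respondent = respondent)
}

# Independent sequential Elo pass written in plain R (the oracle the C++
# path is checked against).
oracle_elo <- function(records, ids, k = 100, scale = 400, start = 0) {
  r <- stats::setNames(rep(start, length(ids)), ids)
  for (i in seq_len(nrow(records))) {
    w <- if (records$outcome[i] == "FIRST") records$first_item[i] else records$second_item[i]
    l <- if (records$outcome[i] == "FIRST") records$second_item[i] else records$first_item[i]
    e <- 1 / (1 + 10^((r[[l]] - r[[w]]) / scale))
    d <- k * (1 - e)
    r[[w]] <- r[[w]] + d
    r[[l]] <- r[[l]] - d
  }
  r
}

# Independent running consistency-index oracle (plain R).
oracle_consistency <- function(records, ids, k = 100, scale = 400, start = 0) {
  r <- stats::setNames(rep(start, length(ids)), ids)
  n_eval <- 0; n_up <- 0; w_eval <- 0; w_up <- 0
  for (i in seq_len(nrow(records))) {
    w <- if (records$outcome[i] == "FIRST") records$first_item[i] else records$second_item[i]
    l <- if (records$outcome[i] == "FIRST") records$second_item[i] else records$first_item[i]
    if (abs(r[[w]] - r[[l]]) > 1e-9) {
      wt <- abs(r[[w]] - r[[l]])
      n_eval <- n_eval + 1; w_eval <- w_eval + wt
      if (r[[w]] < r[[l]]) { n_up <- n_up + 1; w_up <- w_up + wt }
    }
    e <- 1 / (1 + 10^((r[[l]] - r[[w]]) / scale))
    d <- k * (1 - e)
    r[[w]] <- r[[w]] + d
    r[[l]] <- r[[l]] - d
  }
  list(unweighted = 1 - n_up / n_eval, weighted = 1 - w_up / w_eval,
       n_evaluated = n_eval, n_upsets = n_up)
}

# Responses to a triplet test in which every answer follows a fixed
# chooser function(first, second) -> chosen item.
answer_test <- function(test, chooser, respondent = "E1", sitting = 1L) {
  chosen <- mapply(chooser, test$first_item, test$second_item)
  tibble::tibble(
    respondent_id = respondent,
    triplet_id = test$triplet_id,
    first_item = test$first_item,
    second_item = test$second_item,
    outcome = ifelse(chosen == test$first_item, "FIRST", "SECOND"),
    sitting = sitting
  )
}
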