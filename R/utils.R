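# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Canonical key for an unordered item pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

outcome_levels <- c("FIRST", "SECOND", "SKIP")

# The item the respondent actually chose; NA for SKIP.
chosen_item <- function(records) {
  dplyr::case_when(
    records$outcome == "FIRST" ~ records$first_item,
    records$outcome == "SECOND" ~ records$second_item,
    .default = NA_character_
  )
}

assert_skip_free <- function(records, what = "records") {
  if (any(records$outcome == "SKIP")) {
    abort(paste0(
      what, " contain SKIP outcomes; run filter_skips() before this step"
    ))
  }
  invisible(records)
}

# Map records onto integer winner/loser indices into `item_ids`.
winner_loser_idx <- function(records, item_ids) {
  win <- chosen_item(records)
  lose <- ifelse(records$outcome == "FIRST",
                 records$second_item, records$first_item)
  w <- match(win, item_ids)
  l <- match(lose, item_ids)
  if (anyNA(w) || anyNA(l)) {
    bad <- unique(c(win[is.na(w)], lose[is.na(l)]))
    abort(paste0("records reference items absent from the item set: ",
                 paste(bad, collapse = ", ")))
  }
  list(winner = w, loser = l)
}

item_ids_of <- function(items) {
  if (is.data.frame(items)) as.character(items$item_id) else as.character(items)
}

new_tbl_subclass <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
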