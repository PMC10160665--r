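# Between-group and stability inference on n.mElo ratings and ranks:
# bootstrap CIs, difference CIs, respondent-level permutation tests,
# split-half reproducibility and the rank-stability curve.

# n.mElo vector from winner/loser index vectors; NA vector when the
# normalization is degenerate (all mElo equal), so resampling loops can
# drop the replicate instead of aborting.
nmelo_vec <- function(winner, loser, n_items, cfg, n_seq) {
  mat <- elo_sequences_cpp(winner, loser, n_items, cfg$k_factor, cfg$scale,
                           cfg$start_rating, n_seq)
  m <- rowMeans(mat)
  rng <- range(m)
  if (diff(rng) == 0) {
    return(rep(NA_real_, n_items))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

rank_of <- function(nmelo, ids) {
  ord <- order(-nmelo, ids)
  r <- integer(length(ids))
  r[ord] <- seq_along(ids)
  r
}

check_all_compared <- function(records, ids, what = "records") {
  seen <- unique(c(records$first_item, records$second_item))
  missing <- setdiff(ids, seen)
  if (length(missing) > 0) {
    abort(paste0("item(s) never compared in ", what, ": ",
                 paste(head(missing, 5), collapse = ", ")))
  }
}

#' Bootstrap confidence intervals for n.mElo ratings
#'
#' Resamples the comparison records with replacement to their original size
#' (or resamples whole respondents, `unit = "respondent"`), recomputes
#' n.mElo per replicate with a reduced number of randomized sequences, and
#' reports percentile intervals per item.
#'
#' @param records SKIP-free comparison records of one group.
#' @param items Item tibble or id vector.
#' @param cfg An [elo_config()] (used as-is for the point estimate).
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @param unit `"comparison"` (default, resample single records) or
#'   `"respondent"` (resample whole respondents).
#' @param boot_sequences Randomized sequences per replicate (default 20);
#'   sequence-averaging noise is second-order relative to resampling noise.
#' @return A `bootstrap_result` tibble: `item_id`, `estimate`, `conf_low`,
#'   `conf_high`.
#' @export
bootstrap_ci <- function(records, items, cfg = elo_config(), n_boot = 1000,
                         level = 0.95, seed = NULL,
                         unit = c("comparison", "respondent"),
                         boot_sequences = 20) {
  cfg <- as_elo_config(cfg)
  unit <- match.arg(unit)
  assert_skip_free(records)
  if (n_boot < 100) abort("n_boot must be at least 100")
  ids <- item_ids_of(items)
  check_all_compared(records, ids)
  wl <- winner_loser_idx(records, ids)
  n <- nrow(records)
  resp_rows <- split(seq_len(n), records$respondent_id)
  seed <- seed %||% cfg$seed
  point <- with_seed(seed, {
    nmelo_vec(wl$winner, wl$loser, length(ids), cfg, cfg$n_sequences)
  })
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rows <- if (unit == "comparison") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(resp_rows[sample.int(length(resp_rows), length(resp_rows),
                                    replace = TRUE)], use.names = FALSE)
      }
      nmelo_vec(wl$winner[rows], wl$loser[rows], length(ids), cfg,
                boot_sequences)
    }, numeric(length(ids)))
  })
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    item_id = ids,
    estimate = point,
    conf_low = apply(reps, 1, quantile, alpha, na.rm = TRUE),
    conf_high = apply(reps, 1, quantile, 1 - alpha, na.rm = TRUE)
  )
  new_tbl_subclass(out, "bootstrap_result", n_boot = n_boot, level = level,
                   seed = seed, unit = unit)
}

#' Bootstrap confidence interval for the between-group difference in n.mElo
#'
#' Per replicate, each group's records are resampled independently and the
#' per-item n.mElo difference (group 1 minus group 2) recomputed; percentile
#' intervals are reported with a flag for items whose interval excludes
#' zero. Each group's replicate stream restarts from the same seed — a
#' paired design under which a group compared against itself gives exactly
#' zero differences.
#'
#' @param records1,records2 SKIP-free records of the two groups; both must
#'   cover the same item set.
#' @inheritParams bootstrap_ci
#' @return A `bootstrap_result` tibble with `estimate` (observed
#'   difference), `conf_low`, `conf_high`, `excludes_zero`.
#' @export
difference_ci <- function(records1, records2, items, cfg = elo_config(),
                          n_boot = 1000, level = 0.95, seed = NULL,
                          unit = c("comparison", "respondent"),
                          boot_sequences = 20) {
  cfg <- as_elo_config(cfg)
  unit <- match.arg(unit)
  ids <- item_ids_of(items)
  covered1 <- intersect(ids, unique(c(records1$first_item, records1$second_item)))
  covered2 <- intersect(ids, unique(c(records2$first_item, records2$second_item)))
  if (!setequal(covered1, covered2) || !setequal(covered1, ids)) {
    abort("the two groups must cover the same (full) item set")
  }
  b1 <- boot_reps(records1, ids, cfg, n_boot, seed, unit, boot_sequences)
  b2 <- boot_reps(records2, ids, cfg, n_boot, seed, unit, boot_sequences)
  diff_reps <- b1$reps - b2$reps
  alpha <- (1 - level) / 2
  lo <- apply(diff_reps, 1, quantile, alpha, na.rm = TRUE)
  hi <- apply(diff_reps, 1, quantile, 1 - alpha, na.rm = TRUE)
  out <- tibble::tibble(
    item_id = ids,
    estimate = b1$point - b2$point,
    conf_low = lo,
    conf_high = hi,
    excludes_zero = lo > 0 | hi < 0
  )
  new_tbl_subclass(out, "bootstrap_result", n_boot = n_boot, level = level,
                   seed = seed, unit = unit)
}

boot_reps <- function(records, ids, cfg, n_boot, seed, unit, boot_sequences) {
  assert_skip_free(records)
  wl <- winner_loser_idx(records, ids)
  n <- nrow(records)
  resp_rows <- split(seq_len(n), records$respondent_id)
  point <- with_seed(seed, {
    nmelo_vec(wl$winner, wl$loser, length(ids), cfg, cfg$n_sequences)
  })
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rows <- if (unit == "comparison") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(resp_rows[sample.int(length(resp_rows), length(resp_rows),
                                    replace = TRUE)], use.names = FALSE)
      }
      nmelo_vec(wl$winner[rows], wl$loser[rows], length(ids), cfg,
                boot_sequences)
    }, numeric(length(ids)))
  })
  list(point = point, reps = reps)
}

#' Respondent-level permutation test for between-group n.mElo differences
#'
#' Permutes group labels at the respondent level (all of a respondent's
#' comparisons move together, since comparisons within a respondent share
#' rater effects), recomputes the per-item n.mElo difference for each
#' permutation, and reports two-sided p-values
#' `(1 + #\{|perm diff| >= |observed|\}) / (1 + n_perm)` with
#' Benjamini-Hochberg adjustment across items.
#'
#' @param records SKIP-free records carrying exactly two `group` labels.
#' @param items Item tibble or id vector.
#' @param cfg An [elo_config()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param n_sequences Randomized sequences per recomputation (default 20).
#' @return A `permutation_result` tibble: `item_id`, `observed_diff`
#'   (first group label minus second, alphabetically), `p_value`, `p_adj`.
#' @export
permutation_test <- function(records, items, cfg = elo_config(),
                             n_perm = 1000, seed = NULL, n_sequences = 20) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  groups <- sort(unique(records$group))
  if (length(groups) != 2) {
    abort("permutation_test requires records with exactly 2 group labels")
  }
  ids <- item_ids_of(items)
  wl <- winner_loser_idx(records, ids)
  resp <- dplyr::distinct(records, .data$respondent_id, .data$group)
  if (any(duplicated(resp$respondent_id))) {
    abort("each respondent must belong to a single group")
  }
  if (min(table(resp$group)) < 1) abort("each group needs at least one respondent")
  resp_rows <- split(seq_len(nrow(records)),
                     factor(records$respondent_id, resp$respondent_id))
  n_resp <- nrow(resp)
  n1 <- sum(resp$group == groups[1])
  seed <- seed %||% cfg$seed
  diff_for <- function(members1) {
    rows1 <- unlist(resp_rows[members1], use.names = FALSE)
    rows2 <- unlist(resp_rows[-members1], use.names = FALSE)
    nmelo_vec(wl$winner[rows1], wl$loser[rows1], length(ids), cfg, n_sequences) -
      nmelo_vec(wl$winner[rows2], wl$loser[rows2], length(ids), cfg, n_sequences)
  }
  res <- with_seed(seed, {
    observed <- diff_for(which(resp$group == groups[1]))
    perms <- vapply(seq_len(n_perm), function(p) {
      diff_for(sample.int(n_resp, n1))
    }, numeric(length(ids)))
    list(observed = observed, perms = perms)
  })
  exceed <- rowSums(abs(res$perms) >= abs(res$observed), na.rm = TRUE)
  p <- (1 + exceed) / (1 + n_perm)
  out <- tibble::tibble(
    item_id = ids,
    observed_diff = res$observed,
    p_value = p,
    p_adj = p.adjust(p, method = "BH")
  )
  new_tbl_subclass(out, "permutation_result", groups = groups,
                   n_perm = n_perm, seed = seed)
}

#' Split-half reproducibility of n.mElo ratings
#'
#' Respondents are randomly partitioned into two halves (odd counts put the
#' extra respondent in half 1), n.mElo is computed independently per half,
#' and the halves are compared by Pearson correlation on ratings and
#' Kendall's Tau on ranks.
#'
#' @param records SKIP-free records of one group (>= 4 respondents).
#' @param items Item tibble or id vector.
#' @param cfg An [elo_config()].
#' @param seed Integer seed.
#' @return A `split_half_result`: the two rating tables plus both
#'   correlation tests. `tidy()` gives one row per correlation.
#' @export
split_half <- function(records, items, cfg = elo_config(), seed = NULL) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  resp <- unique(records$respondent_id)
  if (length(resp) < 4) abort("split_half needs at least 4 respondents")
  seed <- seed %||% cfg$seed
  res <- with_seed(seed, {
    shuffled <- sample(resp)
    half1_ids <- shuffled[seq_len(ceiling(length(resp) / 2))]
    r1 <- records[records$respondent_id %in% half1_ids, ]
    r2 <- records[!records$respondent_id %in% half1_ids, ]
    t1 <- elo_rate(r1, items, cfg)
    t2 <- elo_rate(r2, items, cfg)
    list(half1 = t1, half2 = t2, half1_ids = half1_ids)
  })
  j <- dplyr::inner_join(
    tibble::tibble(item_id = res$half1$item_id, nmelo = res$half1$nmelo,
                   rank = res$half1$rank),
    tibble::tibble(item_id = res$half2$item_id, nmelo = res$half2$nmelo,
                   rank = res$half2$rank),
    by = "item_id", suffix = c("_1", "_2")
  )
  pearson <- cor.test(j$nmelo_1, j$nmelo_2, method = "pearson")
  kendall <- suppressWarnings(
    cor.test(j$rank_1, j$rank_2, method = "kendall")
  )
  structure(list(half1 = res$half1, half2 = res$half2,
                 pearson = pearson, kendall = kendall,
                 n_respondents = length(resp), seed = seed),
            class = "split_half_result")
}

#' @export
tidy.split_half_result <- function(x, ...) {
  tibble::tibble(
    method = c("pearson_nmelo", "kendall_rank"),
    estimate = c(unname(x$pearson$estimate), unname(x$kendall$estimate)),
    p_value = c(x$pearson$p.value, x$kendall$p.value)
  )
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("Split-half (%d respondents): Pearson r = %.3f, Kendall tau = %.3f\n",
              x$n_respondents, unname(x$pearson$estimate),
              unname(x$kendall$estimate)))
  invisible(x)
}

#' Rank-stability curve under incremental respondent inclusion
#'
#' Respondents are added one at a time in a seeded random order; after each
#' addition the n.mElo ranks are recomputed and the mean absolute rank
#' change relative to the previous step recorded. With a shared group
#' perspective the curve decreases toward zero.
#'
#' @param records SKIP-free records (>= 2 respondents).
#' @param items Item tibble or id vector.
#' @param cfg An [elo_config()].
#' @param seed Integer seed.
#' @param n_sequences Randomized sequences per recomputation (default 20).
#' @return A `rank_stability` tibble: `rater_count` (2..R),
#'   `mean_abs_rank_change`.
#' @export
rank_stability_curve <- function(records, items, cfg = elo_config(),
                                 seed = NULL, n_sequences = 20) {
  cfg <- as_elo_config(cfg)
  assert_skip_free(records)
  resp <- unique(records$respondent_id)
  if (length(resp) < 2) abort("rank_stability_curve needs >= 2 respondents")
  ids <- item_ids_of(items)
  wl <- winner_loser_idx(records, ids)
  resp_rows <- split(seq_len(nrow(records)), factor(records$respondent_id, resp))
  seed <- seed %||% cfg$seed
  out <- with_seed(seed, {
    ord <- sample(resp)
    prev_rank <- NULL
    changes <- numeric(length(resp) - 1)
    for (r in seq_along(ord)) {
      rows <- unlist(resp_rows[ord[seq_len(r)]], use.names = FALSE)
      nm <- nmelo_vec(wl$winner[rows], wl$loser[rows], length(ids), cfg,
                      n_sequences)
      rk <- if (anyNA(nm)) prev_rank else rank_of(nm, ids)
      if (r > 1) {
        changes[r - 1] <- if (is.null(prev_rank) || is.null(rk)) NA_real_
                          else mean(abs(rk - prev_rank))
      }
      if (!is.null(rk)) prev_rank <- rk
    }
    tibble::tibble(rater_count = seq_along(resp)[-1],
                   mean_abs_rank_change = changes)
  })
  new_tbl_subclass(out, "rank_stability", seed = seed)
}
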