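test_that("expected score follows the logistic closed form", {
  expect_equal(expected_score(0, 0), 0.5)
  expect_equal(expected_score(400, 0, 400), 10 / 11)
  set.seed(1)
  ra <- rnorm(50, sd = 300); rb <- rnorm(50, sd = 300)
  expect_equal(expected_score(ra, rb) + expected_score(rb, ra),
               rep(1, 50), tolerance = 1e-12)
})

test_that("single-comparison updates are zero-sum with the right magnitude", {
  r <- c(A = 0, B = 0, C = 0)
  r2 <- apply_comparison(r, "A", "B")
  expect_equal(unname(r2), c(50, -50, 0))

  r3 <- apply_comparison(c(A = 50, B = -50), "A", "B")
  gain <- 100 * (1 - 1 / (1 + 10^(-100 / 400)))
  expect_equal(r3[["A"]], 50 + gain)
  expect_equal(r3[["A"]], 86.0, tolerance = 1e-2)
  expect_equal(sum(r3), 0)
  expect_error(apply_comparison(r, "A", "A"), "differ")
  expect_error(apply_comparison(r, "A", "Z"), "present")
})

test_that("run_sequence matches an independent pure-R oracle", {
  items <- make_items(6)
  set.seed(7)
  n <- 80
  pairs <- t(replicate(n, sample(items$item_id, 2)))
  rec <- make_records(pairs[, 1], pairs[, 2],
                      sample(c("FIRST", "SECOND"), n, replace = TRUE))
  got <- run_sequence(rec, items)
  want <- oracle_elo(rec, items$item_id)
  expect_equal(got$rating, unname(want[got$item_id]), tolerance = 1e-12)
})

test_that("ratings are conserved and order-dependent", {
  items <- make_items(8)
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    pairs <- t(replicate(n, sample(items$item_id, 2)))
    rec <- make_records(pairs[, 1], pairs[, 2],
                        sample(c("FIRST", "SECOND"), n, replace = TRUE))
    r <- run_sequence(rec, items)
    expect_lt(abs(sum(r$rating) - 8 * 0), 1e-9)
  }

  # processing order matters: (A>B then B>C) vs (B>C then A>B)
  ab_then_bc <- records_of_wins(c("I01", "I02"), c("I02", "I03"))
  bc_then_ab <- ab_then_bc[2:1, ]
  r1 <- run_sequence(ab_then_bc, make_items(3))
  r2 <- run_sequence(bc_then_ab, make_items(3))
  expect_false(isTRUE(all.equal(r1$rating, r2$rating)))

  # empty stream: everything stays at the start rating
  r0 <- run_sequence(ab_then_bc[0, ], make_items(3))
  expect_equal(r0$rating, c(0, 0, 0))

  skip_rec <- make_records("I01", "I02", "SKIP")
  expect_error(run_sequence(skip_rec, make_items(2)), "SKIP")
})

test_that("filter_skips removes and reports SKIP records", {
  rec <- make_records(rep("I01", 10), rep("I02", 10),
                      c(rep("FIRST", 9), "SKIP"))
  out <- filter_skips(rec, quiet = TRUE)
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "n_skipped"), 1)
  noskip <- filter_skips(out, quiet = TRUE)
  expect_equal(nrow(noskip), 9)
  expect_equal(attr(noskip, "n_skipped"), 0)
})

test_that("mElo averages shuffled sequences deterministically", {
  items <- make_items(3)
  one <- make_records("I01", "I02", "FIRST")
  m1 <- mean_elo(one, items, elo_config(n_sequences = 1), seed = 1)
  expect_equal(m1$melo, run_sequence(one, items)$rating)

  # winner of every comparison ends above the loser for any seed
  rec <- make_records(rep("I01", 10), rep("I02", 10), rep("FIRST", 10))
  for (s in 1:10) {
    m <- mean_elo(rec, make_items(2), elo_config(n_sequences = 20), seed = s)
    expect_gt(m$melo[m$item_id == "I01"], m$melo[m$item_id == "I02"])
  }

  # transitive round-robin preferences recover the order for every seed
  items3 <- make_items(3)
  w <- rep(c("I01", "I02", "I01"), 10)
  l <- rep(c("I02", "I03", "I03"), 10)
  rr <- records_of_wins(w, l)
  for (s in 1:20) {
    m <- mean_elo(rr, items3, elo_config(n_sequences = 30), seed = s)
    expect_true(all(diff(m$melo[match(c("I01", "I02", "I03"), m$item_id)]) < 0))
  }

  # bit-identical under a fixed seed
  big <- generate_cohort(synthetic_config(n_items = 10, n_respondents = 10,
                                          m_per_respondent = 10, seed = 3))
  rec2 <- filter_skips(big$records, quiet = TRUE)
  a <- mean_elo(rec2, big$items, elo_config(n_sequences = 40), seed = 9)
  b <- mean_elo(rec2, big$items, elo_config(n_sequences = 40), seed = 9)
  expect_identical(a$melo, b$melo)

  expect_error(mean_elo(rec[0, ], items), "no records")
})

test_that("two-item mElo ordering equals the win-proportion ordering", {
  items <- make_items(2)
  for (s in 1:8) {
    set.seed(s)
    n <- 30
    out <- sample(c("FIRST", "SECOND"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (sum(out == "FIRST") * 2 == n) next # tie: ordering undefined
    rec <- make_records(rep("I01", n), rep("I02", n), out)
    m <- mean_elo(rec, items, elo_config(n_sequences = 30), seed = s)
    win_first <- mean(out == "FIRST") > 0.5
    expect_equal(m$melo[m$item_id == "I01"] > m$melo[m$item_id == "I02"],
                 win_first)
  }
})

test_that("min-max normalization maps ratings onto [0, 1] affinely", {
  rt <- tibble::tibble(item_id = c("A", "B", "C"), melo = c(-50, 0, 50))
  nm <- minmax_normalize(rt)
  expect_equal(nm$nmelo, c(0, 0.5, 1))

  # affine invariance
  rt2 <- rt; rt2$melo <- 3.7 * rt$melo + 42
  expect_equal(minmax_normalize(rt2)$nmelo, nm$nmelo, tolerance = 1e-12)

  # order and spacing preserved
  set.seed(4)
  rt3 <- tibble::tibble(item_id = sprintf("I%02d", 1:9), melo = rnorm(9, sd = 90))
  nm3 <- minmax_normalize(rt3)
  expect_equal(order(nm3$nmelo), order(rt3$melo))
  expect_equal(min(nm3$nmelo), 0)
  expect_equal(max(nm3$nmelo), 1)

  flat <- tibble::tibble(item_id = c("A", "B"), melo = c(1, 1))
  expect_error(minmax_normalize(flat), "degenerate")
})

test_that("ranking is a bijection with lexicographic tie-breaks", {
  rt <- tibble::tibble(item_id = c("A", "B", "C"),
                       melo = c(2, 1, 0), nmelo = c(1, 0.5, 0))
  rk <- rank_items(rt)
  expect_equal(rk$rank[match(c("A", "B", "C"), rk$item_id)], 1:3)
  expect_false(any(rk$tie))

  tie <- tibble::tibble(item_id = c("C", "B", "A"),
                        melo = c(0, 1, 2), nmelo = c(0.5, 0.5, 1))
  rk2 <- rank_items(tie)
  expect_equal(rk2$item_id, c("A", "B", "C")) # B before C on equal nmelo
  expect_equal(rk2$rank, 1:3)
  expect_equal(rk2$tie, c(FALSE, TRUE, TRUE))

  set.seed(2)
  rt91 <- tibble::tibble(item_id = sprintf("I%02d", 1:91),
                         melo = rnorm(91), nmelo = runif(91))
  expect_setequal(rank_items(rt91)$rank, 1:91)
})

test_that("theme medians summarise member items", {
  rt <- tibble::tibble(item_id = c("A", "B", "C", "D", "E"),
                       nmelo = c(0.2, 0.4, 0.9, 0.2, 0.4),
                       theme = c("X", "X", "X", "Y", "Y"))
  tm <- theme_medians(rt)
  expect_equal(tm$median_nmelo[tm$theme == "X"], 0.4)
  expect_equal(tm$median_nmelo[tm$theme == "Y"], 0.3)
  expect_equal(tm$rank, 1:2)

  rt$theme[1] <- NA
  expect_error(theme_medians(rt), "without a theme")
})

test_that("sequence-to-sequence variability shrinks relative to range as data grow", {
  cohort <- generate_cohort(synthetic_config(n_items = 8, n_respondents = 12,
                                             m_per_respondent = 10, beta = 2,
                                             epsilon = 0, seed = 21))
  rec <- cohort$records
  quadrupled <- dplyr::bind_rows(lapply(c("", "b", "c", "d"), function(sfx) {
    dplyr::mutate(rec, respondent_id = paste0(respondent_id, sfx))
  }))
  rel_spread <- function(records) {
    m <- mean_elo(records, cohort$items, elo_config(n_sequences = 120),
                  seed = 5, keep_sequences = TRUE)
    mat <- attr(m, "sequences")
    mean(apply(mat, 1, stats::sd)) / diff(range(rowMeans(mat)))
  }
  expect_lt(rel_spread(quadrupled), rel_spread(rec))
})
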