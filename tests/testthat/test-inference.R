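make_dominance_cohort <- function(n_items, n_respondents, m, beta, seed,
                                  theta = NULL) {
  generate_cohort(synthetic_config(
    n_items = n_items, n_respondents = n_respondents, m_per_respondent = m,
    beta = beta, epsilon = 0, seed = seed, theta = theta
  ))
}

test_that("bootstrap intervals separate dominant items and respect inputs", {
  # strict dominance: theta spread so wide that choices are deterministic
  cohort <- make_dominance_cohort(4, 20, 6, beta = 50, seed = 2,
                                  theta = c(3, 1, -1, -3))
  cfg <- elo_config(n_sequences = 20)
  bc <- bootstrap_ci(cohort$records, cohort$items, cfg, n_boot = 100, seed = 4,
                     boot_sequences = 10)
  top <- bc[bc$item_id == "I01", ]
  second <- bc[bc$item_id == "I02", ]
  expect_gt(top$conf_low, second$conf_high)
  expect_true(all(bc$conf_low >= 0 & bc$conf_high <= 1))
  expect_true(all(bc$conf_low <= bc$conf_high))

  expect_error(bootstrap_ci(cohort$records, cohort$items, cfg, n_boot = 50),
               "at least 100")
  items5 <- dplyr::bind_rows(cohort$items,
                             tibble::tibble(item_id = "I99", label = "ghost",
                                            theme = NA))
  expect_error(bootstrap_ci(cohort$records, items5, cfg, n_boot = 100),
               "I99")
})

test_that("doubling the data shrinks bootstrap interval widths", {
  small <- make_dominance_cohort(6, 10, 8, beta = 1.5, seed = 6)
  big_rec <- dplyr::bind_rows(
    small$records,
    dplyr::mutate(small$records, respondent_id = paste0(respondent_id, "b")),
    dplyr::mutate(small$records, respondent_id = paste0(respondent_id, "c")),
    dplyr::mutate(small$records, respondent_id = paste0(respondent_id, "d"))
  )
  cfg <- elo_config(n_sequences = 20)
  w1 <- with(bootstrap_ci(small$records, small$items, cfg, n_boot = 150,
                          seed = 1, boot_sequences = 10),
             median(conf_high - conf_low))
  w2 <- with(bootstrap_ci(big_rec, small$items, cfg, n_boot = 150,
                          seed = 1, boot_sequences = 10),
             median(conf_high - conf_low))
  expect_lt(w2, w1)
})

test_that("difference CIs are degenerate for a group against itself", {
  cohort <- make_dominance_cohort(5, 12, 8, beta = 2, seed = 8)
  cfg <- elo_config(n_sequences = 20)
  d <- difference_ci(cohort$records, cohort$records, cohort$items, cfg,
                     n_boot = 100, seed = 3, boot_sequences = 10)
  expect_equal(d$estimate, rep(0, 5))
  expect_equal(d$conf_low, rep(0, 5))
  expect_equal(d$conf_high, rep(0, 5))
  expect_false(any(d$excludes_zero))
})

test_that("difference CIs detect an opposite preference on one item", {
  theta <- c(2, 1, 0, -1, -2)
  g1 <- make_dominance_cohort(5, 30, 8, beta = 3, seed = 10, theta = theta)
  theta2 <- theta; theta2[1] <- -4 # item I01 flips from best to worst
  g2 <- generate_cohort(synthetic_config(n_items = 5, n_respondents = 30,
                                         m_per_respondent = 8, beta = 3,
                                         epsilon = 0, seed = 11,
                                         theta = theta2))
  cfg <- elo_config(n_sequences = 20)
  d <- difference_ci(g1$records, g2$records, g1$items, cfg, n_boot = 200,
                     seed = 5, boot_sequences = 10)
  expect_true(d$excludes_zero[d$item_id == "I01"])

  # identical-theta groups: the planted-null items mostly contain zero
  g3 <- generate_cohort(synthetic_config(n_items = 5, n_respondents = 30,
                                         m_per_respondent = 8, beta = 3,
                                         epsilon = 0, seed = 12, theta = theta))
  d0 <- difference_ci(g1$records, g3$records, g1$items, cfg, n_boot = 200,
                      seed = 5, boot_sequences = 10)
  expect_gt(mean(!d0$excludes_zero), 0.5)
})

test_that("a zero observed difference gives the maximal permutation p-value", {
  # both groups always pick I01 over I02: every shuffle gives nmelo {1, 0}
  rec <- make_records(rep("I01", 12), rep("I02", 12), rep("FIRST", 12),
                      respondent = rep(sprintf("R%02d", 1:6), each = 2),
                      group = rep(c("g1", "g2"), each = 6))
  p <- permutation_test(rec, make_items(2), elo_config(n_sequences = 5),
                        n_perm = 50, seed = 2)
  expect_equal(p$observed_diff, c(0, 0))
  expect_equal(p$p_value, c(1, 1))
})

test_that("a planted group effect is detected after BH adjustment", {
  theta <- c(1.5, 0.5, -0.5, -1.5)
  g1 <- generate_cohort(synthetic_config(n_items = 4, n_respondents = 25,
                                         m_per_respondent = 6, beta = 3,
                                         epsilon = 0, seed = 21, theta = theta))
  theta2 <- theta; theta2[2] <- -3
  g2 <- generate_cohort(synthetic_config(n_items = 4, n_respondents = 25,
                                         m_per_respondent = 6, beta = 3,
                                         epsilon = 0, seed = 22, theta = theta2))
  rec <- dplyr::bind_rows(
    dplyr::mutate(g1$records, group = "s1"),
    dplyr::mutate(g2$records, group = "s2",
                  respondent_id = paste0(respondent_id, "x"))
  )
  p <- permutation_test(rec, g1$items, elo_config(n_sequences = 10),
                        n_perm = 200, seed = 7, n_sequences = 10)
  expect_lt(p$p_adj[p$item_id == "I02"], 0.05)
  expect_true(all(p$p_adj >= p$p_value))

  expect_error(permutation_test(g1$records, g1$items, n_perm = 10),
               "2 group")
})

test_that("split-half halves correlate strongly for a shared perspective", {
  cohort <- make_dominance_cohort(15, 60, 25, beta = 2, seed = 30)
  sh <- split_half(cohort$records, cohort$items,
                   elo_config(n_sequences = 40), seed = 3)
  td <- tidy(sh)
  expect_gte(td$estimate[td$method == "pearson_nmelo"], 0.85)
  expect_gt(td$estimate[td$method == "kendall_rank"], 0.5)
  expect_equal(nrow(sh$half1), 15)

  rand <- make_dominance_cohort(15, 60, 25, beta = 0, seed = 31)
  shr <- split_half(rand$records, rand$items,
                    elo_config(n_sequences = 40), seed = 3)
  expect_lt(abs(unname(shr$pearson$estimate)), 0.5)

  few <- cohort$records[cohort$records$respondent_id %in%
                          c("R0001", "R0002", "R0003"), ]
  expect_error(split_half(few, cohort$items), "4 respondents")
})

test_that("rank changes shrink as a consistent cohort accumulates", {
  cohort <- make_dominance_cohort(10, 30, 15, beta = 3, seed = 33)
  rs <- rank_stability_curve(cohort$records, cohort$items,
                             elo_config(n_sequences = 15), seed = 4)
  expect_equal(rs$rater_count, 2:30)
  early <- mean(rs$mean_abs_rank_change[1:5])
  late <- mean(rs$mean_abs_rank_change[(nrow(rs) - 4):nrow(rs)])
  expect_lt(late, early)
  expect_lt(late, 1)

  # two items can swap ranks by at most one place each
  two <- make_records(rep("I01", 6), rep("I02", 6),
                      rep(c("FIRST", "SECOND"), 3),
                      respondent = rep(c("Ra", "Rb"), each = 3))
  rs2 <- rank_stability_curve(two, make_items(2), elo_config(n_sequences = 5),
                              seed = 1)
  expect_true(all(rs2$mean_abs_rank_change <= 1))

  one <- two[two$respondent_id == "Ra", ]
  expect_error(rank_stability_curve(one, make_items(2)), "2 respondents")
})
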