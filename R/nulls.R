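# Random-response null distributions and observed-vs-null one-sample tests.

#' Simulate a random-response null distribution for a reliability metric
#'
#' Generates responses drawn uniformly over the two options of each question
#' (no SKIP) and computes the requested metric:
#' \describe{
#'   \item{symmetry}{one symmetry-consistency rate per simulated respondent
#'     (`n_sims` respondents); summarized by median and range.}
#'   \item{transitivity}{one transitivity rate per simulated respondent;
#'     median and range.}
#'   \item{test_retest}{a fixed baseline of `n_respondents_per_sim` random
#'     respondents; each of `n_sims` repetitions regenerates independent
#'     responses and records the proportion matching the baseline
#'     question-by-question; mean and range. Because a fresh uniform answer
#'     matches any fixed answer with probability 1/2, the matching count is
#'     drawn as a single binomial per repetition.}
#'   \item{wmcr}{each of `n_sims` repetitions simulates
#'     `n_respondents_per_sim` respondents answering every question
#'     (per-question modal counts are binomial draws) and records the
#'     weighted mean consensus rate; mean and range.}
#' }
#'
#' @param metric One of `"symmetry"`, `"transitivity"`, `"test_retest"`,
#'   `"wmcr"`.
#' @param test A [build_triplet_test()] defining the question structure.
#' @param n_sims Number of simulated respondents (symmetry, transitivity) or
#'   repetitions (test_retest, wmcr); default 5000.
#' @param n_respondents_per_sim Respondents per repetition for the
#'   test_retest baseline and the wmcr null (default 5000).
#' @param seed Integer seed.
#' @return A `null_distribution`: `$samples`, `$center` (`"median"` or
#'   `"mean"`), `$summary` (center value, min, max) and the default test
#'   shape for [compare_to_null()].
#' @export
simulate_random_null <- function(metric = c("symmetry", "transitivity",
                                            "test_retest", "wmcr"),
                                 test, n_sims = 5000,
                                 n_respondents_per_sim = 5000, seed = NULL) {
  metric <- match.arg(metric)
  n_triplets <- nrow(attr(test, "triplets"))
  if (is.null(n_triplets)) abort("test must be a triplet_test")
  n_questions <- nrow(test)
  samples <- with_seed(seed, {
    switch(metric,
      symmetry = {
        # per respondent: each symmetric pair agrees iff two independent
        # uniform choices of the same pair coincide
        a1 <- matrix(runif(n_sims * n_triplets) < 0.5, n_sims)
        a2 <- matrix(runif(n_sims * n_triplets) < 0.5, n_sims)
        rowMeans(a1 == a2)
      },
      transitivity = {
        x <- matrix(runif(n_sims * n_triplets) < 0.5, n_sims) # A beats B
        y <- matrix(runif(n_sims * n_triplets) < 0.5, n_sims) # B beats C
        z <- matrix(runif(n_sims * n_triplets) < 0.5, n_sims) # A beats C
        cyclic <- (x & y & !z) | (!x & !y & z)
        1 - rowMeans(cyclic)
      },
      test_retest = {
        n_cells <- n_respondents_per_sim * n_questions
        rbinom(n_sims, n_cells, 0.5) / n_cells
      },
      wmcr = {
        n <- n_respondents_per_sim
        vapply(seq_len(n_sims), function(i) {
          k <- rbinom(n_questions, n, 0.5)
          mean(pmax(k, n - k) / n) # equal weights: every question answered n times
        }, numeric(1))
      }
    )
  })
  center <- if (metric %in% c("symmetry", "transitivity")) "median" else "mean"
  cval <- if (center == "median") median(samples) else mean(samples)
  structure(
    list(metric = metric, samples = samples, center = center,
         summary = tibble::tibble(center = center, value = cval,
                                  min = min(samples), max = max(samples)),
         n_sims = n_sims, n_respondents_per_sim = n_respondents_per_sim,
         seed = seed,
         default_shape = if (center == "median") "ordinal" else "approx_normal"),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Random-response null for %s: %s %.3f (range %.3f-%.3f), n = %d\n",
              x$metric, x$center, x$summary$value, x$summary$min,
              x$summary$max, x$n_sims))
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(metric = x$metric, sample = x$samples)
}

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(metric = x$metric, center = x$center,
                 value = x$summary$value, min = x$summary$min,
                 max = x$summary$max, n_sims = x$n_sims)
}

#' Test an observed reliability metric against its random-response null
#'
#' One-sided test of H1: the simulated (random-response) metric is *less*
#' than the observed metric. Ordinal / skewed null samples use a Wilcoxon
#' one-sample signed-rank test against the observed value; approximately
#' normal samples use a one-sample t-test. `shape = "auto"` follows the
#' null's own default (Wilcoxon for per-respondent proportions, t-test for
#' repetition means).
#'
#' @param null A [simulate_random_null()] result.
#' @param observed The observed metric value.
#' @param shape `"auto"`, `"ordinal"` or `"approx_normal"`.
#' @return A one-row tibble: metric, observed, null summary, method,
#'   statistic, `p_value`.
#' @export
compare_to_null <- function(null, observed, shape = c("auto", "ordinal",
                                                      "approx_normal")) {
  shape <- match.arg(shape)
  if (shape == "auto") shape <- null$default_shape
  s <- null$samples
  if (length(s) < 30) abort("null distribution has fewer than 30 samples")
  if (stats::var(s) == 0) {
    abort("null samples are constant: no variance to test against")
  }
  if (shape == "ordinal") {
    ht <- suppressWarnings(
      wilcox.test(s, mu = observed, alternative = "less", exact = FALSE)
    )
    method <- "wilcoxon_signed_rank"
  } else {
    ht <- t.test(s, mu = observed, alternative = "less")
    method <- "one_sample_t"
  }
  tibble::tibble(metric = null$metric, observed = observed,
                 null_center = null$summary$value,
                 null_min = null$summary$min, null_max = null$summary$max,
                 method = method,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}
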