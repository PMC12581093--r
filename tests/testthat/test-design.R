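spec2 <- toy_spec()
pairs_all <- t(combn(4L, 2L))   # all unordered candidate pairs of profiles

test_that("d_error matches the brute-force information oracle on all small designs", {
  set.seed(42)
  beta_cases <- list(c(0, 0), c(0.5, -0.3), rnorm(2))
  for (nt in 1:3) {
    sets <- combn(nrow(pairs_all), nt)
    for (ci in seq_len(ncol(sets))) {
      d <- design_from_pairs(spec2, pairs_all[sets[, ci], , drop = FALSE])
      for (beta in beta_cases) {
        expected <- brute_d_error(d, beta)
        got <- d_error(d, beta)
        if (is.finite(expected)) {
          expect_equal(got, expected, tolerance = 1e-6)
        } else {
          expect_identical(got, Inf)
        }
      }
    }
  }
})

test_that("a design where an attribute never varies is flagged singular", {
  # both alternatives always share the same 'benefit' level
  d <- design_from_pairs(spec2, rbind(c(1L, 3L), c(2L, 4L)))
  lv <- unique(c(d$tasks$benefit))
  expect_length(lv, 2L)   # varies across tasks but never within...
  d2 <- design_from_pairs(spec2, rbind(c(1L, 3L), c(1L, 3L), c(1L, 3L)))
  expect_identical(d_error(d2, c(0, 0)), Inf)
  expect_error(d_error(d2, c(0, 0, 0)), "length")
})

test_that("duplicating every task halves the D-error (information additivity)", {
  d1 <- design_from_pairs(spec2, rbind(c(1L, 4L), c(2L, 3L)))
  d2 <- design_from_pairs(spec2, rbind(c(1L, 4L), c(2L, 3L),
                                       c(1L, 4L), c(2L, 3L)))
  b <- c(0.3, -0.2)
  expect_equal(d_error(d2, b), d_error(d1, b) / 2, tolerance = 1e-10)
})

test_that("D-error is invariant to relabelling alternatives within a task", {
  d1 <- design_from_pairs(spec2, rbind(c(1L, 4L), c(2L, 3L)))
  d2 <- design_from_pairs(spec2, rbind(c(4L, 1L), c(2L, 3L)))
  b <- c(0.7, 0.1)
  expect_equal(d_error(d1, b), d_error(d2, b), tolerance = 1e-12)
})

test_that("adding an informative task never increases the D-error", {
  base_pairs <- rbind(c(1L, 4L), c(2L, 3L))
  d1 <- design_from_pairs(spec2, base_pairs)
  for (extra in seq_len(nrow(pairs_all))) {
    d2 <- design_from_pairs(spec2, rbind(base_pairs, pairs_all[extra, ]))
    expect_lte(d_error(d2, c(0.2, 0.4)), d_error(d1, c(0.2, 0.4)) + 1e-12)
  }
})

test_that("Bayesian D-error collapses correctly and tracks a Monte-Carlo oracle", {
  d <- design_from_pairs(spec2, rbind(c(1L, 4L), c(2L, 3L)))
  mu <- c(0.4, -0.1)
  # degenerate prior: exactly the fixed-coefficient D-error
  expect_identical(bayesian_d_error(d, mu, 0, n_draws = 50, seed = 7),
                   d_error(d, mu))
  # a single draw is the D-error at that draw
  b1 <- ocsdce:::prior_draws(mu, c(0.5, 0.5), 1L, seed = 11)
  expect_equal(bayesian_d_error(d, mu, 0.5, n_draws = 1, seed = 11),
               d_error(d, drop(b1)), tolerance = 1e-12)
  # 100 quasi-random draws land within 3 MC standard errors of a large
  # plain-Monte-Carlo oracle
  set.seed(99)
  n_oracle <- 5000L
  draws <- matrix(rnorm(n_oracle * 2, mean = rep(mu, each = n_oracle),
                        sd = 0.5), n_oracle, 2)
  vals <- apply(draws, 1, function(b) d_error(d, b))
  oracle <- mean(vals)
  mc_se <- sd(vals) / sqrt(100)
  got <- bayesian_d_error(d, mu, 0.5, n_draws = 100, seed = 3)
  expect_lt(abs(got - oracle), 3 * mc_se)
  expect_error(bayesian_d_error(d, mu, -0.1), "nonnegative")
})

test_that("the exchange search improves on its start, is monotone and reproducible", {
  spec <- ocs_design_spec(n_tasks = 12L, n_blocks = 2L)
  d1 <- optimize_design(spec, n_iterations = 150L, seed = 5)
  expect_lte(d1$d_error, d1$search_log[1])
  lg <- d1$search_log
  expect_true(all(lg[-1] <= lg[-length(lg)] + 1e-12))
  expect_true(is.finite(d1$d_error))
  d2 <- optimize_design(spec, n_iterations = 150L, seed = 5)
  expect_identical(d1$tasks, d2$tasks)
  expect_identical(d1$search_log, d2$search_log)
  # no duplicated unordered tasks, no task pairing identical profiles
  key <- vapply(unique(d1$tasks$task_id), function(id) {
    r <- d1$tasks[d1$tasks$task_id == id, ]
    prof <- apply(r[order(r$alt_id), -(1:3)], 1, paste, collapse = "|")
    expect_false(prof[1] == prof[2])
    paste(sort(prof), collapse = "||")
  }, character(1))
  expect_false(anyDuplicated(key) > 0)
})

test_that("requesting more tasks than usable candidate pairs is an error", {
  # with the dominance filter active a 2x2 binary system has only two
  # trade-off pairs, so a 4-task design is infeasible
  spec <- design_spec(list(
    attribute_spec("risk", c("low", "high"), "high", "binary-categorical",
                   preference_rank = c(2L, 1L)),
    attribute_spec("benefit", c("yes", "no"), "no", "binary-categorical",
                   preference_rank = c(2L, 1L))),
    n_tasks = 4L, n_blocks = 1L, prior_sd = 0)
  expect_error(optimize_design(spec, n_iterations = 10L, seed = 1),
               "usable")
})

test_that("on a tiny system the search attains the exhaustive optimum", {
  spec <- toy_spec(n_tasks = 3L, prior_sd = 0)
  sets <- combn(nrow(pairs_all), 3L)
  best <- Inf
  for (ci in seq_len(ncol(sets))) {
    d <- design_from_pairs(spec, pairs_all[sets[, ci], , drop = FALSE])
    best <- min(best, d_error(d, spec$prior_mean))
  }
  got <- optimize_design(spec, n_iterations = 400L, seed = 2, n_draws = 1L)
  expect_equal(d_error(got, spec$prior_mean), best, tolerance = 1e-9)
})

test_that("blocking balances level frequencies and matches exhaustive toy minima", {
  spec <- toy_spec(n_tasks = 4L, n_blocks = 2L)
  d <- design_from_pairs(spec, pairs_all[c(1, 2, 5, 6), ])
  expect_error(block_design(d, 3L), "divisible")
  # one block: trivial assignment, imbalance zero
  d1 <- block_design(d, 1L)
  expect_true(all(d1$tasks$block_id == 1L))
  counts <- ocsdce:::task_level_counts(d1)
  expect_equal(ocsdce:::block_imbalance(counts, rep(1L, 4), 1L), 0)
  # two blocks: exhaustive minimum over all balanced partitions
  parts <- combn(4L, 2L)
  best <- Inf
  for (ci in seq_len(ncol(parts))) {
    bl <- rep(2L, 4); bl[parts[, ci]] <- 1L
    best <- min(best, ocsdce:::block_imbalance(counts, bl, 2L))
  }
  d2 <- block_design(d, 2L)
  bl <- d2$tasks$block_id[d2$tasks$alt_id == 1L]
  expect_equal(sort(table(bl), decreasing = TRUE)[[1]], 2L)  # equal sizes
  expect_equal(ocsdce:::block_imbalance(counts, bl, 2L), best)
})

test_that("design files round-trip and task cards render every attribute", {
  spec <- ocs_design_spec(n_tasks = 4L, n_blocks = 2L)
  d <- optimize_design(spec, n_iterations = 50L, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(d, path)
  d2 <- read_design(path, spec)
  expect_identical(d$tasks, d2$tasks)
  cards <- render_task_cards(d)
  expect_length(cards, 4L)
  expect_true(all(grepl("Treatment A", cards)))
  expect_true(all(grepl("peak flow", cards)))
})
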