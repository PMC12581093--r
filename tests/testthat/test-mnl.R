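spec2 <- toy_spec()
toy_design <- design_from_pairs(spec2, rbind(c(1L, 4L), c(2L, 3L)))

test_that("model matrix construction validates and codes interactions", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, 0.5), n = 10, seed = 1)
  mm <- build_model_matrix(ch, spec2)
  expect_s3_class(mm, "mnl_model_matrix")
  expect_equal(colnames(mm$X), coef_names(spec2))
  # an interaction adds exactly one column equal to dummy x flag
  ch$flag <- rep(c(TRUE, FALSE), length.out = nrow(ch))
  mm2 <- build_model_matrix(ch, spec2,
                            interactions = list(c("flag", "risk:low")))
  expect_equal(ncol(mm2$X), 3L)
  expect_equal(unname(mm2$X[, 3]), unname(mm2$X[, "risk:low"] * ch$flag))
  expect_error(build_model_matrix(ch, spec2,
                                  interactions = list(c("nope", "risk:low"))),
               "not found")
  # duplicate chosen flags are refused with the task identified
  bad <- ch; bad$chosen[bad$respondent_id == "T0001" & bad$task_id == 1] <- 1L
  expect_error(build_model_matrix(bad, spec2), "forced-choice violation")
})

test_that("log-likelihood, gradient and Hessian match brute-force oracles", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, -0.2), n = 2, seed = 2)
  mm <- build_model_matrix(ch, spec2)   # 4 choice sets; subset to 3
  keep <- mm$set <= 3L
  mm3 <- mm
  mm3$X <- mm$X[keep, , drop = FALSE]
  mm3$chosen <- mm$chosen[keep]; mm3$set <- mm$set[keep]
  mm3$respondent <- mm$respondent[keep]; mm3$weight <- mm$weight[keep]
  # beta = 0 with N sets and two alternatives: -N ln 2
  expect_equal(mnl_loglik(c(0, 0), mm3), -3 * log(2), tolerance = 1e-12)
  for (beta in list(c(0, 0), c(0.8, -0.4), c(-1.2, 2))) {
    expect_equal(mnl_loglik(beta, mm3), brute_loglik(beta, mm3),
                 tolerance = 1e-10)
    # central finite differences on the value
    h <- 1e-5
    g_fd <- vapply(1:2, function(j) {
      e <- numeric(2); e[j] <- h
      (mnl_loglik(beta + e, mm3) - mnl_loglik(beta - e, mm3)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(mnl_gradient(beta, mm3)), g_fd, tolerance = 1e-6)
    H_fd <- vapply(1:2, function(j) {
      e <- numeric(2); e[j] <- h
      (mnl_gradient(beta + e, mm3) - mnl_gradient(beta - e, mm3)) / (2 * h)
    }, numeric(2))
    expect_equal(unname(mnl_hessian(beta, mm3)), unname(H_fd),
                 tolerance = 1e-5)
  }
  expect_error(mnl_loglik(c(NA, 0), mm3), "non-finite")
})

test_that("the Newton fit matches a dense grid search on a 2-coefficient toy", {
  ch <- simulate_toy(spec2, toy_design, c(0.6, -0.3), n = 40, seed = 3)
  mm <- build_model_matrix(ch, spec2)
  fit <- fit_mnl(mm)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
  grid <- seq(-2, 2, by = 0.02)
  best <- c(NA, NA); best_ll <- -Inf
  for (b1 in grid) for (b2 in grid) {
    ll <- mnl_loglik(c(b1, b2), mm)
    if (ll > best_ll) { best_ll <- ll; best <- c(b1, b2) }
  }
  expect_lt(max(abs(unname(coef(fit)) - best)), 0.021)  # grid resolution
  expect_gte(fit$loglik, best_ll)
  # ascent contract: optimum at least as good as the zero start
  expect_gte(fit$loglik, mnl_loglik(c(0, 0), mm))
})

test_that("fitted coefficients agree with conditional-logit as an independent check", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  ch <- simulate_toy(spec2, toy_design, c(0.7, 0.4), n = 120, seed = 4)
  mm <- build_model_matrix(ch, spec2)
  fit <- fit_mnl(mm)
  df <- data.frame(chosen = mm$chosen, x1 = mm$X[, 1], x2 = mm$X[, 2],
                   set = mm$set)
  cl <- survival::clogit(chosen ~ x1 + x2 + survival::strata(set), data = df)
  expect_equal(unname(coef(fit)), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(cl)))), tolerance = 1e-4)
})

test_that("likelihood is invariant to adding a constant to both alternatives", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, 0.5), n = 30, seed = 5)
  mm <- build_model_matrix(ch, spec2)
  mm_shift <- mm
  mm_shift$X <- mm$X + 3.7   # same constant added to every row of a set pair
  for (beta in list(c(0.2, -0.1), c(1, 1)))
    expect_equal(mnl_loglik(beta, mm_shift), mnl_loglik(beta, mm),
                 tolerance = 1e-9)
})

test_that("non-identified matrices are reported, not silently fitted", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, 0.5), n = 10, seed = 6)
  mm <- build_model_matrix(ch, spec2)
  mm$X <- cbind(mm$X, dup = mm$X[, 1])
  expect_error(fit_mnl(mm), "not identified")
})

test_that("weighted fits: unit weights reproduce the unweighted fit exactly", {
  ch <- simulate_toy(spec2, toy_design, c(0.4, -0.6), n = 60, seed = 7)
  f0 <- fit_mnl(build_model_matrix(ch, spec2))
  ch$w <- 1
  f1 <- fit_weighted(ch, spec2, weights = "w")
  expect_equal(coef(f1), coef(f0), tolerance = 1e-10)
  # rescaling all weights leaves the argmax unchanged, scales the loglik
  ch$w <- 2.5
  f2 <- fit_weighted(ch, spec2, weights = "w")
  expect_equal(coef(f2), coef(f0), tolerance = 1e-7)
  expect_equal(f2$loglik, 2.5 * f0$loglik, tolerance = 1e-6)
  ch$w <- -1
  expect_error(fit_weighted(ch, spec2, weights = "w"), "positive")
})

test_that("calibration weights hit the target share of total weight", {
  set.seed(8)
  grad <- runif(824) < 0.56
  w <- calibration_weights(grad, 0.30)
  expect_equal(sum(w[grad]) / sum(w), 0.30, tolerance = 1e-12)
  expect_equal(mean(w), 1, tolerance = 1e-12)
})

test_that("null calibration: with zero truth, ~5% of t-ratios exceed 1.96", {
  hits <- 0L; total <- 0L
  for (r in 1:25) {
    ch <- simulate_toy(spec2, toy_design, c(0, 0), n = 150, seed = 100 + r)
    fit <- fit_mnl(build_model_matrix(ch, spec2))
    t_ratios <- coef(fit) / sqrt(diag(fit$vcov))
    hits <- hits + sum(abs(t_ratios) > 1.96)
    total <- total + length(t_ratios)
  }
  expect_gt(hits / total, 0.005)
  expect_lt(hits / total, 0.12)
})

test_that("estimates concentrate on the truth as the sample grows", {
  truth <- c(0.6, -0.4)
  err <- function(n) {
    e <- 0
    for (r in 1:3) {
      ch <- simulate_toy(spec2, toy_design, truth, n = n, seed = 200 + r)
      e <- e + sum((coef(fit_mnl(build_model_matrix(ch, spec2))) - truth)^2)
    }
    e / 3
  }
  expect_lt(err(800), err(100))
})

test_that("clustered and model-based standard errors agree under correct specification", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, 0.3), n = 400, seed = 9)
  fit <- fit_mnl(build_model_matrix(ch, spec2))
  ratio <- sqrt(diag(vcov(fit, "clustered"))) / sqrt(diag(vcov(fit, "model")))
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("odds-ratio tables exponentiate correctly and mirror the published layout", {
  # closed form: beta = 1.9838, SE = 0.0655 -> OR 7.27, CI ~ 6.39-8.27
  beta <- 1.9838; se <- 0.0655
  expect_equal(round(exp(beta), 2), 7.27)
  expect_equal(exp(beta - 1.96 * se), 6.394, tolerance = 1e-3)
  expect_equal(exp(beta + 1.96 * se), 8.267, tolerance = 1e-3)
  spec <- ocs_design_spec(n_tasks = 12L, n_blocks = 2L)
  design <- optimize_design(spec, n_iterations = 100L, seed = 10)
  roster <- sample_roster("patient", 150, seed = 10)
  ch <- simulate_choices(roster, design,
                         published_truth("patient", FALSE), seed = 10)
  fit <- fit_mnl(build_model_matrix(ch, spec))
  tab <- odds_ratios(fit)
  expect_equal(nrow(tab), 16L)              # 10 coefficients + 6 references
  expect_equal(sum(tab$reference), 6L)
  expect_true(all(tab$or[tab$reference] == 1))
  expect_equal(unique(tab$attribute),
               vapply(spec$attributes, `[[`, character(1), "name"))
  expect_equal(tab$or[!tab$reference], exp(tab$estimate[!tab$reference]),
               tolerance = 1e-12)
  fit_bad <- fit; fit_bad$converged <- FALSE
  expect_error(odds_ratios(fit_bad), "non-converged")
})

test_that("a zero fit reports OR 1 with an interval containing 1", {
  ch <- simulate_toy(spec2, toy_design, c(0, 0), n = 300, seed = 11)
  fit <- fit_mnl(build_model_matrix(ch, spec2))
  tab <- odds_ratios(fit, include_reference = FALSE)
  expect_true(all(abs(tab$or - 1) < 0.25))
  expect_true(all(tab$ci_low < 1 & tab$ci_high > 1))
})

test_that("arm equivalence: duplicated data gives LR 0; distinct truths are detected", {
  ch <- simulate_toy(spec2, toy_design, c(0.5, -0.5), n = 80, seed = 12)
  dup <- ch
  dup$respondent_id <- paste0(dup$respondent_id, "b")
  ch$narrative_arm <- 1L; dup$narrative_arm <- 2L
  both <- rbind(ch, dup)
  res <- test_arm_equivalence(both, spec2)
  expect_lt(res$statistic, 1e-6)
  expect_equal(res$df, 2L)   # K coefficients x (2 arms - 1)
  # power: arm 2 truth scaled well away from arm 1 at large n
  ch1 <- simulate_toy(spec2, toy_design, c(0.5, 0.5), n = 500, seed = 13)
  ch2 <- simulate_toy(spec2, toy_design, c(1.5, 1.5), n = 500, seed = 14)
  ch1$narrative_arm <- 1L; ch2$narrative_arm <- 2L
  ch2$respondent_id <- paste0(ch2$respondent_id, "b")
  res2 <- test_arm_equivalence(rbind(ch1, ch2), spec2)
  expect_lt(res2$p_value, 1e-6)
  expect_error(test_arm_equivalence(ch1, spec2), "at least two")
})
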