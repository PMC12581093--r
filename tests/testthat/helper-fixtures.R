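# Small fixture builders shared across the suite.  Toy attribute systems use
# tied preference ranks so no candidate pair is filtered as dominated and
# exhaustive oracles can sweep the whole candidate space.

toy_spec <- function(n_tasks = 4L, n_blocks = 1L, prior_sd = 0) {
  design_spec(list(
    attribute_spec("risk", c("low", "high"), "high", "binary-categorical",
                   preference_rank = c(1L, 1L)),
    attribute_spec("benefit", c("yes", "no"), "no", "binary-categorical",
                   preference_rank = c(1L, 1L))),
    n_alternatives = 2L, n_tasks = n_tasks, n_blocks = n_blocks,
    prior_mean = 0, prior_sd = prior_sd)
}

# build a choice_design directly from a matrix of candidate-profile index
# pairs (rows = tasks, columns = the two alternatives)
design_from_pairs <- function(spec, pairs, block_id = NULL) {
  cand <- as.matrix(enumerate_profiles(spec))
  nt <- nrow(pairs)
  arr <- array(0L, c(nt, 2L, length(spec$attributes)))
  for (t in seq_len(nt)) {
    arr[t, 1L, ] <- cand[pairs[t, 1], ]
    arr[t, 2L, ] <- cand[pairs[t, 2], ]
  }
  ocsdce:::new_choice_design(spec, arr, block_id = block_id)
}

toy_roster <- function(n, n_blocks = 1L) {
  structure(
    data.frame(respondent_id = sprintf("T%04d", seq_len(n)), group = "toy",
               block_id = rep_len(seq_len(n_blocks), n),
               stringsAsFactors = FALSE),
    class = c("respondent_roster", "data.frame"))
}

# explicit-loop Fisher information / D-error oracle
brute_d_error <- function(design, beta) {
  spec <- design$spec
  tk <- design$tasks
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  K <- length(coef_names(spec))
  info <- matrix(0, K, K)
  for (id in unique(tk$task_id)) {
    rows <- tk[tk$task_id == id, ]
    X <- ocsdce:::code_levels(rows[, anames, drop = FALSE], spec)
    V <- drop(X %*% beta)
    p <- exp(V) / sum(exp(V))
    m <- matrix(0, K, K)
    for (j in seq_len(nrow(X))) m <- m + p[j] * tcrossprod(X[j, ])
    xbar <- colSums(X * p)
    info <- info + m - tcrossprod(xbar)
  }
  if (rcond(info) < 1e-10) return(Inf)   # same identification rule as d_error
  d <- det(info)
  if (d <= 0) return(Inf)
  d^(-1 / K)
}

# explicit-sum log-likelihood oracle over a model matrix
brute_loglik <- function(beta, mm) {
  total <- 0
  for (s in unique(mm$set)) {
    rows <- which(mm$set == s)
    V <- drop(mm$X[rows, , drop = FALSE] %*% beta)
    w <- mm$weight[rows][1]
    total <- total + w * (V[mm$chosen[rows] == 1L] - log(sum(exp(V))))
  }
  total
}

# choices for a toy roster from a bare coefficient vector
simulate_toy <- function(spec, design, beta, n, seed = 1L, n_blocks = 1L) {
  truth <- generative_truth(stats::setNames(beta, coef_names(spec)))
  simulate_choices(toy_roster(n, n_blocks = n_blocks), design, truth,
                   seed = seed)
}
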