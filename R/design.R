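# ---- internal: choice_design construction and coding --------------------

# profile_idx: integer array (n_tasks, n_alternatives, n_attributes) of
# 1-based level indices.
new_choice_design <- function(spec, profile_idx, block_id = NULL,
                              d_error = NA_real_, search_log = numeric()) {
  nt <- dim(profile_idx)[1]; na <- dim(profile_idx)[2]
  if (is.null(block_id)) block_id <- rep(1L, nt)
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  tasks <- data.frame(
    task_id = rep(seq_len(nt), each = na),
    block_id = rep(as.integer(block_id), each = na),
    alt_id = rep(seq_len(na), nt))
  for (k in seq_along(anames)) {
    lv <- spec$attributes[[k]]$levels
    tasks[[anames[k]]] <- lv[as.vector(t(profile_idx[, , k]))]
  }
  structure(
    list(spec = spec, tasks = tasks, d_error = d_error,
         search_log = search_log),
    class = "choice_design")
}

# Recover the (n_tasks, n_alts, n_attr) index array from the task table.
design_profile_idx <- function(design) {
  spec <- design$spec
  tk <- design$tasks
  ids <- unique(tk$task_id)
  na <- max(tk$alt_id)
  arr <- array(0L, c(length(ids), na, length(spec$attributes)))
  for (k in seq_along(spec$attributes)) {
    a <- spec$attributes[[k]]
    m <- match(tk[[a$name]], a$levels)
    if (anyNA(m)) stop("unknown level in design for attribute '", a$name, "'")
    arr[cbind(match(tk$task_id, ids), tk$alt_id, k)] <- m
  }
  arr
}

# Coded rows (n_tasks*n_alts x K) in task-major order plus the task index.
design_coded <- function(design) {
  spec <- design$spec
  tk <- design$tasks
  X <- code_levels(tk[, vapply(spec$attributes, `[[`, character(1), "name"),
                      drop = FALSE], spec)
  list(X = X, task = match(tk$task_id, unique(tk$task_id)))
}

#' @export
print.choice_design <- function(x, ...) {
  nt <- length(unique(x$tasks$task_id))
  cat("<choice_design> ", nt, " tasks x ", max(x$tasks$alt_id),
      " alternatives, ", length(unique(x$tasks$block_id)), " block(s)\n",
      sep = "")
  if (is.finite(x$d_error))
    cat("  Bayesian D-error of search: ", format(x$d_error, digits = 6), "\n",
        sep = "")
  invisible(x)
}

# ---- D-error ------------------------------------------------------------

# Fisher information of the MNL model for one respondent answering every
# task once: I(beta) = sum_t [ sum_j p_tj x_tj x_tj' - xbar_t xbar_t' ].
mnl_information <- function(X, task, beta) {
  V <- drop(X %*% beta)
  V <- V - ave(V, task, FUN = max)          # stabilise exp
  E <- exp(V)
  p <- E / ave(E, task, FUN = sum)
  A <- crossprod(X, X * p)
  Xbar <- rowsum(X * p, task)
  A - crossprod(Xbar)
}

d_error_from_info <- function(info, K) {
  if (!all(is.finite(info))) return(Inf)
  if (rcond(info) < 1e-10) return(Inf)
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  exp(-as.numeric(ld$modulus) / K)
}

#' D-error of a choice design
#'
#' The D-error is `det(I(beta)^{-1})^{1/K}` where `I(beta)` is the Fisher
#' information of the multinomial logit model evaluated at coefficient
#' vector `beta` for one pass through the design's tasks, and `K` is the
#' number of coefficients.  Lower is better; a design under which some
#' coefficient is not identified has infinite D-error.
#'
#' @param design A `choice_design`.
#' @param beta Numeric coefficient vector, one entry per non-reference
#'   level (see [coef_names()]).
#' @return A nonnegative scalar; `Inf` when the information matrix is
#'   singular.
#' @export
d_error <- function(design, beta) {
  stopifnot(inherits(design, "choice_design"))
  cd <- design_coded(design)
  K <- ncol(cd$X)
  if (length(beta) != K)
    stop("beta has length ", length(beta), " but the design codes ", K,
         " coefficients")
  d_error_from_info(mnl_information(cd$X, cd$task, beta), K)
}

# ---- Bayesian D-error ---------------------------------------------------

# Halton radical-inverse sequence, first `dim` prime bases, `skip` burn-in.
halton_matrix <- function(n, dim, skip = 50L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (dim > length(primes)) stop("halton_matrix supports up to 15 dimensions")
  out <- matrix(0, n, dim)
  idx <- (skip + 1L):(skip + n)
  for (d in seq_len(dim)) {
    b <- primes[d]
    r <- numeric(n); f <- 1 / b; ii <- idx
    while (any(ii > 0)) {
      r <- r + f * (ii %% b)
      ii <- ii %/% b
      f <- f / b
    }
    out[, d] <- r
  }
  out
}

# Quasi-random N(mean, sd) draws: randomly-shifted Halton points through the
# normal quantile function.  sd = 0 collapses every draw onto the mean.
prior_draws <- function(prior_mean, prior_sd, n_draws, seed) {
  K <- length(prior_mean)
  if (any(prior_sd < 0)) stop("prior_sd must be nonnegative")
  if (all(prior_sd == 0) || n_draws == 1L) {
    if (all(prior_sd == 0))
      return(matrix(prior_mean, 1L, K, byrow = TRUE))
  }
  set.seed(seed)
  shift <- stats::runif(K)
  u <- (halton_matrix(n_draws, K) + matrix(shift, n_draws, K, byrow = TRUE)) %% 1
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  z <- stats::qnorm(u)
  sweep(z, 2L, prior_sd, `*`) + matrix(prior_mean, n_draws, K, byrow = TRUE)
}

#' Bayesian D-error of a choice design
#'
#' Mean of [d_error()] over quasi-random (shifted Halton) draws from an
#' independent normal prior on the coefficients.  With `prior_sd = 0` the
#' prior is degenerate and the result equals `d_error(design, prior_mean)`
#' exactly.
#'
#' @inheritParams d_error
#' @param prior_mean,prior_sd Prior mean and standard deviation per
#'   coefficient (recycled if scalar).
#' @param n_draws Number of prior draws (default 100).
#' @param seed Integer seed for the random shift of the Halton points.
#' @return Nonnegative scalar; `Inf` if any draw's information is singular.
#' @export
bayesian_d_error <- function(design, prior_mean, prior_sd, n_draws = 100L,
                             seed = 1L) {
  stopifnot(inherits(design, "choice_design"), n_draws >= 1L)
  cd <- design_coded(design)
  K <- ncol(cd$X)
  prior_mean <- rep_len(as.numeric(prior_mean), K)
  prior_sd <- rep_len(as.numeric(prior_sd), K)
  B <- prior_draws(prior_mean, prior_sd, n_draws, seed)
  vals <- apply(B, 1L, function(b)
    d_error_from_info(mnl_information(cd$X, cd$task, b), K))
  mean(vals)
}

# ---- dominance ----------------------------------------------------------

# TRUE if one profile of the pair is at least as good on every attribute
# (by the a priori preference ranks) and strictly better on at least one:
# such a task carries no trade-off and is uninformative.
dominated_pair <- function(idx_a, idx_b, spec) {
  ra <- mapply(function(a, i) a$preference_rank[i], spec$attributes, idx_a)
  rb <- mapply(function(a, i) a$preference_rank[i], spec$attributes, idx_b)
  (all(ra >= rb) && any(ra > rb)) || (all(rb >= ra) && any(rb > ra))
}

# ---- design search ------------------------------------------------------

# 2-alternative task contribution to the information matrix at draws
# `Betas` (B x K): w_b * d d' with d = x1 - x2, w_b = p1 p2.
task_contribs <- function(x1, x2, Betas) {
  d <- x1 - x2
  eta <- drop(Betas %*% d)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  outer_dd <- tcrossprod(d)
  lapply(w, function(wb) wb * outer_dd)
}

#' Search for a Bayesian D-efficient blocked choice design
#'
#' Random-swap exchange search: starting from a random feasible design,
#' each iteration replaces one alternative of one task by a random
#' candidate profile and keeps the move if the Bayesian D-error improves.
#' Tasks are constrained to carry a genuine trade-off (no alternative may
#' dominate the other on every attribute under the a priori preference
#' direction), the two alternatives of a task must differ, and no two
#' tasks may be identical as unordered pairs.  The accepted-design D-error
#' trace is non-increasing by construction, and the whole search is
#' reproducible from `seed`.  The final design is blocked with
#' [block_design()].
#'
#' @param spec A `design_spec` (2 alternatives per task).
#' @param n_iterations Number of exchange proposals (default 10000).
#' @param seed Integer seed.
#' @param n_draws Prior draws for the Bayesian criterion (default 100).
#' @return A `choice_design` with `d_error` (the Bayesian criterion value
#'   of the returned design) and `search_log` (criterion value after each
#'   iteration).
#' @export
optimize_design <- function(spec, n_iterations = 10000L, seed = 1L,
                            n_draws = 100L) {
  stopifnot(inherits(spec, "design_spec"))
  if (spec$n_alternatives != 2L)
    stop("the design search supports 2-alternative (paired) tasks")
  set.seed(seed)
  cand <- as.matrix(enumerate_profiles(spec))
  Xc <- code_profiles(cand, spec)
  P <- nrow(cand); K <- ncol(Xc)
  nt <- spec$n_tasks

  # usable candidate pairs must exist
  if (P < 2L) stop("candidate set too small for paired tasks")

  Betas <- prior_draws(spec$prior_mean, spec$prior_sd, n_draws,
                       seed = seed + 1000L)
  nB <- nrow(Betas)

  task_key <- function(i, j) paste(sort(c(i, j)), collapse = "-")
  propose_pair <- function(used_keys) {
    for (tries in 1:200) {
      ij <- sample.int(P, 2L)
      if (dominated_pair(cand[ij[1], ], cand[ij[2], ], spec)) next
      if (task_key(ij[1], ij[2]) %in% used_keys) next
      return(ij)
    }
    stop("n_tasks exceeds usable (non-dominated, distinct) candidate pairs")
  }

  pairs <- matrix(0L, nt, 2L)
  keys <- character(0)
  for (t in seq_len(nt)) {
    ij <- propose_pair(keys)
    pairs[t, ] <- ij
    keys <- c(keys, task_key(ij[1], ij[2]))
  }

  # per-task, per-draw contributions and running information matrices
  contribs <- vector("list", nt)
  infos <- rep(list(matrix(0, K, K)), nB)
  for (t in seq_len(nt)) {
    ct <- task_contribs(Xc[pairs[t, 1], ], Xc[pairs[t, 2], ], Betas)
    contribs[[t]] <- ct
    for (b in seq_len(nB)) infos[[b]] <- infos[[b]] + ct[[b]]
  }
  # primary criterion: mean D-error over draws.  While the design is not
  # yet identified (infinite D-error) moves are ranked by a ridge-
  # regularised surrogate so the search can walk towards identification.
  crit <- function(info_list) {
    vals <- vapply(info_list, d_error_from_info, numeric(1), K = K)
    reg <- vapply(info_list, function(I)
      d_error_from_info(I + diag(1e-4, K), K), numeric(1))
    c(mean(vals), mean(reg))
  }
  better <- function(a, b) {
    if (a[1] < b[1]) return(TRUE)
    if (is.infinite(a[1]) && is.infinite(b[1]) && a[2] < b[2]) return(TRUE)
    FALSE
  }
  current <- crit(infos)

  log_vec <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    t <- sample.int(nt, 1L)
    side <- sample.int(2L, 1L)
    repl <- sample.int(P, 1L)
    new_pair <- pairs[t, ]
    new_pair[side] <- repl
    ok <- new_pair[1] != new_pair[2] &&
      !dominated_pair(cand[new_pair[1], ], cand[new_pair[2], ], spec) &&
      !(task_key(new_pair[1], new_pair[2]) %in% keys[-t])
    if (ok) {
      ct_new <- task_contribs(Xc[new_pair[1], ], Xc[new_pair[2], ], Betas)
      infos_new <- infos
      ct_old <- contribs[[t]]
      for (b in seq_len(nB))
        infos_new[[b]] <- infos[[b]] - ct_old[[b]] + ct_new[[b]]
      val <- crit(infos_new)
      if (better(val, current)) {
        current <- val
        infos <- infos_new
        contribs[[t]] <- ct_new
        pairs[t, ] <- new_pair
        keys[t] <- task_key(new_pair[1], new_pair[2])
      }
    }
    log_vec[it] <- current[1]
  }

  arr <- array(0L, c(nt, 2L, length(spec$attributes)))
  for (t in seq_len(nt)) {
    arr[t, 1L, ] <- cand[pairs[t, 1], ]
    arr[t, 2L, ] <- cand[pairs[t, 2], ]
  }
  design <- new_choice_design(spec, arr, d_error = current[1],
                              search_log = log_vec)
  block_design(design, spec$n_blocks)
}

# ---- blocking -----------------------------------------------------------

# level-frequency table per task: counts of every attribute level over the
# task's alternatives (reference levels included).
task_level_counts <- function(design) {
  spec <- design$spec
  arr <- design_profile_idx(design)
  nt <- dim(arr)[1]
  nlev <- sum(vapply(spec$attributes, function(a) length(a$levels), integer(1)))
  out <- matrix(0, nt, nlev)
  col0 <- 0L
  for (k in seq_along(spec$attributes)) {
    nl <- length(spec$attributes[[k]]$levels)
    for (l in seq_len(nl))
      out[, col0 + l] <- rowSums(arr[, , k, drop = FALSE] == l)
    col0 <- col0 + nl
  }
  out
}

block_imbalance <- function(counts, block, n_blocks) {
  target <- colSums(counts) / n_blocks
  s <- 0
  for (b in seq_len(n_blocks)) {
    dev <- colSums(counts[block == b, , drop = FALSE]) - target
    s <- s + sum(dev^2)
  }
  s
}

#' Assign design tasks to blocks
#'
#' Splits the tasks into `n_blocks` equally-sized blocks so that each block
#' sees attribute levels as evenly as possible.  The imbalance score is the
#' sum over attribute levels and blocks of the squared deviation of the
#' within-block level count from perfect balance; assignment starts from a
#' round-robin split and applies steepest-descent pairwise swaps until no
#' swap improves the score (deterministic, no randomness).
#'
#' @param design A `choice_design`.
#' @param n_blocks Number of blocks; must divide the task count.
#' @return The design with `block_id` reassigned.
#' @export
block_design <- function(design, n_blocks) {
  stopifnot(inherits(design, "choice_design"))
  n_blocks <- as.integer(n_blocks)
  ids <- unique(design$tasks$task_id)
  nt <- length(ids)
  if (nt %% n_blocks != 0L)
    stop("task count (", nt, ") not divisible by n_blocks (", n_blocks, ")")
  counts <- task_level_counts(design)
  block <- rep(seq_len(n_blocks), length.out = nt)
  score <- block_imbalance(counts, block, n_blocks)
  repeat {
    best <- list(score = score)
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
      if (block[i] == block[j]) next
      bl <- block; bl[c(i, j)] <- bl[c(j, i)]
      s <- block_imbalance(counts, bl, n_blocks)
      if (s < best$score - 1e-12) best <- list(score = s, block = bl)
    }
    if (is.null(best$block)) break
    block <- best$block; score <- best$score
  }
  design$tasks$block_id <- block[match(design$tasks$task_id, ids)]
  design
}

# ---- design file I/O and card rendering --------------------------------

#' Write / read a choice design table
#'
#' The design file is a delimited table with columns `task_id`, `block_id`,
#' `alt_id` and one column per attribute holding the level label.
#'
#' @param design A `choice_design`.
#' @param path File path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design$tasks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @param spec The `design_spec` the file was written against.
#' @export
read_design <- function(path, spec) {
  tk <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  tk$task_id <- as.integer(tk$task_id)
  tk$block_id <- as.integer(tk$block_id)
  tk$alt_id <- as.integer(tk$alt_id)
  need <- c("task_id", "block_id", "alt_id",
            vapply(spec$attributes, `[[`, character(1), "name"))
  missing <- setdiff(need, names(tk))
  if (length(missing))
    stop("design file lacks column(s): ", paste(missing, collapse = ", "))
  d <- structure(list(spec = spec, tasks = tk[, need],
                      d_error = NA_real_, search_log = numeric()),
                 class = "choice_design")
  design_profile_idx(d)   # validates the level labels
  d
}

#' Render choice tasks as plain-text cards
#'
#' One card per task, shaped like the survey's side-by-side presentation of
#' "Treatment A" and "Treatment B".
#'
#' @param design A `choice_design`.
#' @return Character vector, one multi-line card per task.
#' @export
render_task_cards <- function(design) {
  spec <- design$spec
  tk <- design$tasks
  labs <- vapply(spec$attributes, `[[`, character(1), "label")
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  wide <- max(nchar(labs)) + 2L
  vapply(unique(tk$task_id), function(id) {
    rows <- tk[tk$task_id == id, ]
    hdr <- sprintf("Task %d (block %d)", id, rows$block_id[1])
    head_line <- sprintf("  %-*s %-14s %-14s", wide, "Attribute",
                         "Treatment A", "Treatment B")
    body <- vapply(seq_along(anames), function(k) {
      sprintf("  %-*s %-14s %-14s", wide, labs[k],
              rows[[anames[k]]][rows$alt_id == 1L],
              rows[[anames[k]]][rows$alt_id == 2L])
    }, character(1))
    paste(c(hdr, head_line, body), collapse = "\n")
  }, character(1))
}
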