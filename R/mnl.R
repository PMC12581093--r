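# ---- model matrix -------------------------------------------------------

#' Build the dummy-coded MNL model matrix from long-format choice data
#'
#' Each non-reference attribute level becomes a 0/1 indicator column;
#' reference levels (15% GP re-treatment, 15% hospitalisation, 25% symptom
#' improvement, 0% peak-flow improvement, High permanent and High temporary
#' side-effect risk in the OCS system) map to all-zero rows.  Requested
#' interactions append one column per (covariate, level) pair equal to the
#' level dummy multiplied by the respondent's 0/1 covariate.  Column order
#' is deterministic: base levels in [coef_names()] order, then interactions
#' in the order requested.
#'
#' @param data A `choice_dataset` (or any long-format data.frame with
#'   `respondent_id`, `task_id`, `alt_id`, `chosen` and one column per
#'   attribute).
#' @param spec The `design_spec` the levels are coded against.
#' @param interactions Optional data.frame with columns `covariate` and
#'   `level` (level in `"attribute:level"` form), or a list of
#'   `c(covariate, level)` pairs.
#' @param weights Optional respondent weights: the name of a numeric column
#'   of `data`, or a numeric vector with one entry per row of `data`.
#'   Weights must be positive.
#' @return An object of class `mnl_model_matrix`.
#' @export
build_model_matrix <- function(data, spec, interactions = NULL,
                               weights = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  need <- c("respondent_id", "task_id", "alt_id", "chosen", anames)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("choice data lacks column(s): ", paste(missing, collapse = ", "))
  X <- code_levels(data[, anames, drop = FALSE], spec)
  cn <- colnames(X)

  if (!is.null(interactions)) {
    if (is.list(interactions) && !is.data.frame(interactions))
      interactions <- data.frame(
        covariate = vapply(interactions, `[[`, character(1), 1L),
        level = vapply(interactions, `[[`, character(1), 2L),
        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(interactions))) {
      cv <- interactions$covariate[r]; lv <- interactions$level[r]
      if (!cv %in% names(data))
        stop("interaction covariate '", cv, "' not found in data")
      if (!lv %in% cn)
        stop("interaction level '", lv, "' is not a model coefficient")
      col <- X[, lv] * as.numeric(as.logical(data[[cv]]))
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0(lv, " x ", cv)
    }
  }

  w <- rep(1, nrow(data))
  if (!is.null(weights)) {
    if (is.character(weights) && length(weights) == 1L) {
      if (!weights %in% names(data))
        stop("weights column '", weights, "' not found in data")
      w <- as.numeric(data[[weights]])
    } else {
      w <- rep_len(as.numeric(weights), nrow(data))
    }
    if (any(!is.finite(w)) || any(w <= 0))
      stop("weights must be positive and finite")
  }

  set <- as.integer(factor(paste(data$respondent_id, data$task_id,
                                 sep = "\r")))
  chosen <- as.integer(data$chosen)
  n_chosen <- rowsum(chosen, set)
  if (any(n_chosen != 1L)) {
    bad <- which(n_chosen != 1L)[1]
    key <- unique(paste(data$respondent_id, data$task_id)[set == bad])
    stop("forced-choice violation: respondent/task ", key,
         " has ", n_chosen[bad], " chosen alternatives (expected 1)")
  }
  structure(
    list(X = X, chosen = chosen, set = set,
         respondent = as.character(data$respondent_id), weight = w,
         spec = spec),
    class = "mnl_model_matrix")
}

#' @export
print.mnl_model_matrix <- function(x, ...) {
  cat("<mnl_model_matrix> ", nrow(x$X), " rows, ",
      length(unique(x$set)), " choice sets, ", ncol(x$X),
      " coefficients\n", sep = "")
  invisible(x)
}

# ---- likelihood ---------------------------------------------------------

# value, analytic gradient and Hessian of the weighted MNL log-likelihood:
# sum over choice sets of w * (V_chosen - log sum_j exp V_j).
mnl_ll_parts <- function(beta, mm, what = c("value", "gradient", "hessian")) {
  if (any(!is.finite(beta))) stop("non-finite coefficient vector")
  X <- mm$X; set <- mm$set
  V <- drop(X %*% beta)
  Vmax <- ave(V, set, FUN = max)
  E <- exp(V - Vmax)
  S <- ave(E, set, FUN = sum)
  p <- E / S
  # one weight per set (respondent weight, constant within set)
  w_row <- mm$weight
  out <- list()
  if ("value" %in% what) {
    lse_first <- (log(S) + Vmax)[!duplicated(set)]
    w_set <- w_row[!duplicated(set)]
    out$value <- sum(w_row * mm$chosen * V) - sum(w_set * lse_first)
  }
  if ("gradient" %in% what)
    out$gradient <- drop(crossprod(X, w_row * (mm$chosen - p)))
  if ("hessian" %in% what) {
    A <- crossprod(X, X * (w_row * p))
    Xbar <- rowsum(X * p, set)          # rows sorted by set id
    first <- !duplicated(set)
    w_set <- (w_row[first])[order(set[first])]
    B <- crossprod(Xbar * sqrt(w_set))
    out$hessian <- -(A - B)
  }
  out$p <- p
  out
}

#' MNL log-likelihood and analytic derivatives
#'
#' @param beta Coefficient vector (length = columns of the model matrix).
#' @param mm An `mnl_model_matrix`.
#' @return `mnl_loglik`: the scalar weighted log-likelihood.
#'   `mnl_gradient` / `mnl_hessian`: its exact first and second analytic
#'   derivatives.
#' @export
mnl_loglik <- function(beta, mm) {
  stopifnot(inherits(mm, "mnl_model_matrix"),
            length(beta) == ncol(mm$X))
  mnl_ll_parts(beta, mm, "value")$value
}

#' @rdname mnl_loglik
#' @export
mnl_gradient <- function(beta, mm) {
  stopifnot(inherits(mm, "mnl_model_matrix"),
            length(beta) == ncol(mm$X))
  mnl_ll_parts(beta, mm, "gradient")$gradient
}

#' @rdname mnl_loglik
#' @export
mnl_hessian <- function(beta, mm) {
  stopifnot(inherits(mm, "mnl_model_matrix"),
            length(beta) == ncol(mm$X))
  mnl_ll_parts(beta, mm, "hessian")$hessian
}

# ---- fitting ------------------------------------------------------------

# respondent-clustered sandwich covariance at the optimum
clustered_vcov <- function(beta, mm, bread) {
  parts <- mnl_ll_parts(beta, mm, "value")
  resid <- mm$weight * (mm$chosen - parts$p)
  G <- rowsum(mm$X * resid, mm$respondent)
  meat <- crossprod(G)
  bread %*% meat %*% bread
}

#' Fit the multinomial logit model by maximum likelihood
#'
#' Newton-Raphson ascent with the exact analytic gradient and Hessian and
#' step-halving line search; convergence is declared when the gradient
#' max-norm falls below `tol`.  The default covariance is the inverse
#' negative Hessian; a respondent-clustered sandwich covariance is also
#' computed and available via `vcov(fit, type = "clustered")`.
#' Non-identification (rank-deficient model matrix) and apparent separation
#' (coefficients running away) are reported as errors naming the problem
#' rather than returned as silently diverged fits.
#'
#' @param mm An `mnl_model_matrix`.
#' @param start Starting coefficient vector (default all zero).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `mnl_fit` with elements `coefficients`,
#'   `vcov`, `vcov_clustered`, `loglik`, `converged`, `gradient_norm`,
#'   `n_respondents`, `n_choicesets`, `spec`.
#' @export
fit_mnl <- function(mm, start = NULL, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(mm, "mnl_model_matrix"))
  K <- ncol(mm$X)
  # identification: within-set deviations from the set mean must have full
  # column rank, otherwise some coefficient is not identified
  Xd <- mm$X - apply(mm$X, 2L, function(col) ave(col, mm$set, FUN = mean))
  qr_rank <- qr(Xd)$rank
  if (qr_rank < K)
    stop("model not identified: the within-choice-set design matrix has rank ",
         qr_rank, " < ", K,
         " (an attribute level never varies, or columns are collinear)")
  beta <- if (is.null(start)) rep(0, K) else rep_len(as.numeric(start), K)
  ll <- mnl_loglik(beta, mm)
  converged <- FALSE
  gnorm <- Inf
  for (it in seq_len(max_iter)) {
    parts <- mnl_ll_parts(beta, mm, c("value", "gradient", "hessian"))
    g <- parts$gradient
    gnorm <- max(abs(g))
    if (gnorm < tol) { converged <- TRUE; ll <- parts$value; break }
    step <- tryCatch(solve(parts$hessian, -g),
                     error = function(e) g / max(1, sqrt(sum(g^2))))
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      ll_new <- mnl_loglik(cand, mm)
      if (is.finite(ll_new) && ll_new >= parts$value - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { cand <- beta; ll_new <- parts$value; break }
    }
    beta <- cand; ll <- ll_new
    if (max(abs(beta)) > 30)
      stop("apparent separation: coefficients diverging (|beta| > 30); ",
           "the data perfectly predict some choices")
  }
  H <- mnl_hessian(beta, mm)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, K, K))
  dimnames(vc) <- list(colnames(mm$X), colnames(mm$X))
  vc_cl <- clustered_vcov(beta, mm, vc)
  names(beta) <- colnames(mm$X)
  structure(
    list(coefficients = beta, vcov = vc, vcov_clustered = vc_cl,
         loglik = ll, converged = converged, gradient_norm = gnorm,
         n_respondents = length(unique(mm$respondent)),
         n_choicesets = length(unique(mm$set)),
         spec = mm$spec),
    class = "mnl_fit")
}

#' Fit a weighted MNL model
#'
#' Maximises the weight-multiplied log-likelihood.  With all weights equal
#' to one this is exactly [fit_mnl()] on the unweighted matrix; rescaling
#' every weight by a constant leaves the coefficient estimates unchanged.
#'
#' @inheritParams build_model_matrix
#' @inheritParams fit_mnl
#' @export
fit_weighted <- function(data, spec, weights, interactions = NULL,
                         start = NULL, tol = 1e-8, max_iter = 100L) {
  mm <- build_model_matrix(data, spec, interactions = interactions,
                           weights = weights)
  fit_mnl(mm, start = start, tol = tol, max_iter = max_iter)
}

#' Respondent weights calibrating a binary margin to a target share
#'
#' Returns one weight per element of `flag` such that the flagged group's
#' share of the total weight equals `target_share` (e.g., down-weighting a
#' 56%-graduate sample so graduates carry 30% of the weight, matching the
#' population margin).  Weights are normalised to mean one.
#'
#' @param flag Logical vector (one per respondent or per row).
#' @param target_share Desired share of total weight for `flag == TRUE`.
#' @return Numeric weights, mean one.
#' @export
calibration_weights <- function(flag, target_share) {
  flag <- as.logical(flag)
  stopifnot(target_share > 0, target_share < 1)
  obs <- mean(flag)
  if (obs %in% c(0, 1))
    stop("cannot reweight: the flag is constant in the sample")
  w <- ifelse(flag, target_share / obs, (1 - target_share) / (1 - obs))
  w / mean(w)
}

# ---- methods ------------------------------------------------------------

#' @export
print.mnl_fit <- function(x, digits = 4, ...) {
  cat("<mnl_fit> ", x$n_choicesets, " choice sets from ", x$n_respondents,
      " respondents; logLik = ", format(x$loglik, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = round(x$coefficients, digits),
                    se = round(se, digits),
                    t = round(x$coefficients / se, 2),
                    OR = round(exp(x$coefficients), digits))
  print(tab)
  invisible(x)
}

#' @export
coef.mnl_fit <- function(object, ...) object$coefficients

#' @export
vcov.mnl_fit <- function(object, type = c("model", "clustered"), ...) {
  type <- match.arg(type)
  if (type == "model") object$vcov else object$vcov_clustered
}

#' @export
logLik.mnl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

# ---- odds ratios --------------------------------------------------------

#' Odds-ratio table of a fitted MNL model
#'
#' Exponentiates the coefficients and their Wald limits
#' (`exp(beta +/- 1.96 SE)`) and attaches two-sided p-values from the
#' normal approximation to the t-ratio, consistent with the +/-1.96
#' significance rule.  When the fit carries its design specification,
#' reference levels are included as `OR = 1` rows so the table mirrors the
#' published layout (attributes in descriptive-system order, reference
#' rows flagged).
#'
#' @param fit A converged `mnl_fit`.
#' @param vcov_type `"model"` (inverse negative Hessian) or `"clustered"`.
#' @param include_reference Add OR = 1 rows for reference levels.
#' @return A data.frame with columns `attribute`, `level`, `term`,
#'   `estimate` (log-odds), `se`, `t`, `or`, `ci_low`, `ci_high`, `p`,
#'   `reference`.
#' @export
odds_ratios <- function(fit, vcov_type = c("model", "clustered"),
                        include_reference = TRUE) {
  stopifnot(inherits(fit, "mnl_fit"))
  if (!fit$converged)
    stop("refusing to report odds ratios for a non-converged fit")
  vcov_type <- match.arg(vcov_type)
  vc <- if (vcov_type == "model") fit$vcov else fit$vcov_clustered
  beta <- fit$coefficients
  se <- sqrt(diag(vc))
  z <- beta / se
  tab <- data.frame(
    term = names(beta),
    estimate = unname(beta), se = unname(se), t = unname(z),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta - 1.96 * se)),
    ci_high = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    reference = FALSE,
    stringsAsFactors = FALSE)
  is_base <- grepl("^[^ ]+:[^ ]+$", tab$term) & !grepl(" x ", tab$term)
  tab$attribute <- ifelse(is_base, sub(":.*$", "", tab$term), NA_character_)
  tab$level <- ifelse(is_base, sub("^.*?:", "", tab$term), tab$term)
  if (include_reference && !is.null(fit$spec)) {
    refs <- do.call(rbind, lapply(fit$spec$attributes, function(a)
      data.frame(term = paste(a$name, a$reference_level, sep = ":"),
                 estimate = 0, se = NA_real_, t = NA_real_, or = 1,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                 reference = TRUE, attribute = a$name,
                 level = a$reference_level, stringsAsFactors = FALSE)))
    tab <- rbind(tab, refs)
    # attributes in descriptive-system order, levels in declared order
    aorder <- vapply(fit$spec$attributes, `[[`, character(1), "name")
    lv_rank <- function(attr, lev) {
      i <- match(attr, aorder)
      ifelse(is.na(i), NA_integer_,
             mapply(function(ii, l) match(l, fit$spec$attributes[[ii]]$levels),
                    i, lev))
    }
    ord <- order(match(tab$attribute, aorder),
                 lv_rank(tab$attribute, tab$level),
                 na.last = TRUE)
    tab <- tab[ord, ]
    rownames(tab) <- NULL
  }
  tab[, c("attribute", "level", "term", "estimate", "se", "t",
          "or", "ci_low", "ci_high", "p", "reference")]
}

# ---- narrative-arm equivalence ------------------------------------------

#' Likelihood-ratio test of preference equality across survey arms
#'
#' Compares a pooled MNL model against a fully arm-interacted model (every
#' coefficient free to differ by arm, fitted equivalently as separate
#' models per arm).  The statistic is
#' `2 * (sum of arm log-likelihoods - pooled log-likelihood)` on
#' `K * (n_arms - 1)` degrees of freedom.  Used to check that different
#' introductory narratives did not shift preferences.
#'
#' @param data A `choice_dataset` containing `arm_col`.
#' @param spec The `design_spec`.
#' @param arm_col Name of the arm label column (default `"narrative_arm"`).
#' @return A list with `statistic`, `df`, `p_value`, `loglik_pooled`,
#'   `loglik_arms`.
#' @export
test_arm_equivalence <- function(data, spec, arm_col = "narrative_arm") {
  if (!arm_col %in% names(data))
    stop("arm column '", arm_col, "' not found in data")
  arms <- sort(unique(data[[arm_col]]))
  if (length(arms) < 2L)
    stop("need at least two populated arms; found ", length(arms))
  pooled <- fit_mnl(build_model_matrix(data, spec))
  ll_arms <- vapply(arms, function(a) {
    sub <- data[data[[arm_col]] == a, ]
    if (!nrow(sub)) stop("arm '", a, "' has no respondents")
    fit_mnl(build_model_matrix(sub, spec))$loglik
  }, numeric(1))
  K <- length(pooled$coefficients)
  stat <- 2 * (sum(ll_arms) - pooled$loglik)
  stat <- max(stat, 0)
  df <- K * (length(arms) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       loglik_pooled = pooled$loglik, loglik_arms = ll_arms)
}
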