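# Accept either a fitted model or a bare named coefficient vector (e.g.,
# log-transformed published odds ratios); vcov is NULL in the latter case.
as_mnl_coef <- function(x) {
  if (inherits(x, "mnl_fit")) {
    if (!x$converged) stop("refusing post-estimation on a non-converged fit")
    list(beta = x$coefficients, vcov = x$vcov)
  } else if (is.numeric(x) && !is.null(names(x))) {
    list(beta = x, vcov = NULL)
  } else {
    stop("expected an 'mnl_fit' or a named numeric coefficient vector")
  }
}

#' Per-percentage-point disutility of 28-day treatment failure
#'
#' Treatment failure is the need for further GP treatment or
#' hospitalisation within 28 days.  The per-point slope of each failure
#' channel is taken from its widest, best-estimated contrast: the 5% level
#' coefficient (5% vs the 15% reference) divided by 10.  The combined slope
#' treats a one-point increase in failure risk as split equally between the
#' GP and hospitalisation channels, i.e., the mean of the two per-point
#' slopes.
#'
#' @param fit An `mnl_fit` or named coefficient vector on the log-odds
#'   scale.
#' @param channel `"both"` (mean of the two channels, default),
#'   `"gp"` or `"hospital"`.
#' @return Scalar utility per percentage point of failure-risk reduction.
#' @export
failure_slope <- function(fit, channel = c("both", "gp", "hospital")) {
  channel <- match.arg(channel)
  beta <- as_mnl_coef(fit)$beta
  need <- c("gp_retreatment:5%", "hospitalisation:5%")
  miss <- setdiff(need, names(beta))
  if (length(miss))
    stop("fit lacks failure-level coefficient(s): ",
         paste(miss, collapse = ", "))
  gp <- unname(beta["gp_retreatment:5%"]) / 10
  hosp <- unname(beta["hospitalisation:5%"]) / 10
  switch(channel, both = (gp + hosp) / 2, gp = gp, hospital = hosp)
}

# gradient of the combined failure slope w.r.t. the full beta vector
failure_slope_grad <- function(beta, channel) {
  g <- numeric(length(beta)); names(g) <- names(beta)
  if (channel %in% c("both", "gp"))
    g["gp_retreatment:5%"] <- 1 / 10 / (if (channel == "both") 2 else 1)
  if (channel %in% c("both", "hospital"))
    g["hospitalisation:5%"] <- 1 / 10 / (if (channel == "both") 2 else 1)
  g
}

#' Marginal rate of substitution: failure risk accepted to avoid permanent
#' side effects
#'
#' The MRS is the absolute increase in 28-day treatment failure (in
#' percentage points) a respondent group would accept in exchange for a
#' treatment with no risk of permanent side effects: the
#' no-permanent-side-effects coefficient divided by the per-point failure
#' slope ([failure_slope()]).  It informs the minimum clinically important
#' difference (MCID) for the treatment-failure outcome.  Uncertainty comes
#' either from Krinsky-Robb simulation (draws from the estimated
#' multivariate-normal coefficient distribution, percentile interval) or
#' the first-order delta method for a ratio.
#'
#' @param fit An `mnl_fit` (for intervals) or named coefficient vector
#'   (point estimate only).
#' @param method `"krinsky-robb"` (default), `"delta"`, or `"none"`.
#' @param n_draws Krinsky-Robb draws (default 10000).
#' @param seed Seed for the Krinsky-Robb draws.
#' @param numerator_level Coefficient forming the numerator (default
#'   `"permanent_se:None"`).
#' @param channel Failure channel passed to [failure_slope()].
#' @return An object of class `mrs_result`: list with `point`, `ci_low`,
#'   `ci_high` (percentage points), `method`, `n_draws`, `seed`, `slope`,
#'   `unstable`.
#' @export
mrs_mcid <- function(fit, method = c("krinsky-robb", "delta", "none"),
                     n_draws = 10000L, seed = 1L,
                     numerator_level = "permanent_se:None",
                     channel = "both") {
  method <- match.arg(method)
  cf <- as_mnl_coef(fit)
  beta <- cf$beta
  if (!numerator_level %in% names(beta))
    stop("fit lacks the numerator coefficient '", numerator_level, "'")
  slope <- failure_slope(beta, channel)
  if (abs(slope) < 1e-10)
    stop("treatment-failure slope is numerically zero: the MRS ratio is ",
         "unstable and not reported")
  num <- unname(beta[numerator_level])
  point <- num / slope
  ci_low <- ci_high <- NA_real_
  unstable <- FALSE
  if (method != "none") {
    if (is.null(cf$vcov))
      stop("method '", method, "' needs a fitted covariance; pass an ",
           "'mnl_fit' or use method = \"none\"")
    if (method == "krinsky-robb") {
      set.seed(seed)
      draws <- MASS::mvrnorm(n_draws, beta, cf$vcov)
      colnames(draws) <- names(beta)
      sl <- (draws[, "gp_retreatment:5%"] / 10 +
               draws[, "hospitalisation:5%"] / 10) / 2
      if (channel == "gp") sl <- draws[, "gp_retreatment:5%"] / 10
      if (channel == "hospital") sl <- draws[, "hospitalisation:5%"] / 10
      ratio <- draws[, numerator_level] / sl
      flip <- mean(sign(sl) != sign(slope))
      if (flip > 0.025) unstable <- TRUE
      qs <- stats::quantile(ratio, c(0.025, 0.975), names = FALSE)
      ci_low <- qs[1]; ci_high <- qs[2]
    } else {
      gn <- numeric(length(beta)); names(gn) <- names(beta)
      gn[numerator_level] <- 1
      gs <- failure_slope_grad(beta, channel)
      grad <- gn / slope - num * gs / slope^2
      v <- drop(t(grad) %*% cf$vcov %*% grad)
      ci_low <- point - 1.96 * sqrt(v)
      ci_high <- point + 1.96 * sqrt(v)
    }
  }
  structure(
    list(point = point, ci_low = ci_low, ci_high = ci_high,
         method = method, n_draws = if (method == "krinsky-robb") n_draws
         else NA_integer_,
         seed = if (method == "krinsky-robb") seed else NA_integer_,
         slope = slope, numerator = num, unstable = unstable),
    class = "mrs_result")
}

#' @export
print.mrs_result <- function(x, ...) {
  cat(sprintf("MRS/MCID: %.1f percentage points of 28-day treatment failure\n",
              x$point))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% CI [%.1f, %.1f]  (%s)\n", x$ci_low, x$ci_high,
                x$method))
  if (x$unstable)
    cat("  WARNING: denominator sign unstable across draws; interval ",
        "unreliable\n", sep = "")
  invisible(x)
}

# ---- scenarios ----------------------------------------------------------

#' Define a forecasting scenario
#'
#' A scenario names one level per attribute for each hypothetical
#' alternative.
#'
#' @param name Scenario name.
#' @param alternatives Named list; each element a named character vector
#'   mapping attribute name to level label, covering every attribute
#'   exactly once.
#' @param spec A `design_spec` to validate against.
#' @return An object of class `dce_scenario`.
#' @export
scenario <- function(name, alternatives, spec) {
  stopifnot(inherits(spec, "design_spec"), length(alternatives) >= 2L)
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  for (alt in names(alternatives)) {
    lv <- alternatives[[alt]]
    if (!setequal(names(lv), anames))
      stop("alternative '", alt, "' must assign every attribute exactly once")
    for (a in spec$attributes)
      if (!lv[[a$name]] %in% a$levels)
        stop("alternative '", alt, "': unknown level '", lv[[a$name]],
             "' for attribute '", a$name, "'")
  }
  structure(list(name = name, alternatives = alternatives, spec = spec),
            class = "dce_scenario")
}

#' The OCS-equivalent vs placebo-equivalent forecasting scenario
#'
#' OCS-equivalent: 5% relapse to GP, 5% relapse to hospital, 100% symptom
#' improvement, 40% peak-flow improvement, high risk of permanent and
#' temporary side effects.  Placebo-equivalent (ineffective treatment):
#' 15% relapse to GP, 15% relapse to hospital, 25% symptom improvement,
#' 0% peak-flow improvement, no permanent or temporary side effects.
#'
#' @param spec A `design_spec` (default [ocs_design_spec()]).
#' @return A `dce_scenario`.
#' @export
ocs_vs_placebo_scenario <- function(spec = ocs_design_spec()) {
  scenario("ocs_vs_placebo", list(
    ocs_equivalent = c(gp_retreatment = "5%", hospitalisation = "5%",
                       symptom_improvement = "100%", pef_improvement = "40%",
                       permanent_se = "High", temporary_se = "High"),
    placebo_equivalent = c(gp_retreatment = "15%", hospitalisation = "15%",
                           symptom_improvement = "25%", pef_improvement = "0%",
                           permanent_se = "None", temporary_se = "None")),
    spec)
}

#' Read / write a scenario file
#'
#' Delimited table with columns `alternative`, `attribute`, `level`: one
#' row per alternative x attribute.
#'
#' @param path File path.
#' @param name Scenario name (reader only; defaults to the file name).
#' @param spec A `design_spec`.
#' @export
read_scenario <- function(path, spec, name = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("alternative", "attribute", "level")
  if (!all(need %in% names(df)))
    stop("scenario file needs columns: ", paste(need, collapse = ", "))
  alts <- lapply(split(df, df$alternative), function(d)
    stats::setNames(d$level, d$attribute))
  scenario(name %||% sub("\\.[^.]+$", "", basename(path)), alts, spec)
}

#' @rdname read_scenario
#' @param scn A `dce_scenario`.
#' @export
write_scenario <- function(scn, path) {
  df <- do.call(rbind, lapply(names(scn$alternatives), function(alt)
    data.frame(alternative = alt,
               attribute = names(scn$alternatives[[alt]]),
               level = unname(scn$alternatives[[alt]]),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# code a scenario into a (n_alternatives x K) dummy matrix
scenario_matrix <- function(scn) {
  spec <- scn$spec
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  df <- as.data.frame(do.call(rbind, lapply(scn$alternatives, `[`, anames)),
                      stringsAsFactors = FALSE)
  names(df) <- anames
  code_levels(df, spec)
}

#' Forecast choice shares for a hypothetical scenario
#'
#' The utility of each alternative is the sum of the fitted coefficients at
#' its non-reference levels; choice probabilities follow the logit formula
#' `P(j) = exp(V_j) / sum_k exp(V_k)`.  With a fitted covariance available,
#' a simulation standard error is attached by drawing coefficients from
#' their estimated multivariate-normal distribution.
#'
#' @param fit An `mnl_fit` or named coefficient vector.
#' @param scn A `dce_scenario`.
#' @param n_draws Simulation draws for the standard errors (default 2000).
#' @param seed Seed for those draws.
#' @return An object of class `forecast_result`: data.frame with columns
#'   `alternative`, `utility`, `probability`, `se`.
#' @export
forecast <- function(fit, scn, n_draws = 2000L, seed = 1L) {
  stopifnot(inherits(scn, "dce_scenario"))
  cf <- as_mnl_coef(fit)
  Xs <- scenario_matrix(scn)
  miss <- setdiff(colnames(Xs), names(cf$beta))
  if (length(miss))
    stop("fit lacks coefficient(s) needed by the scenario: ",
         paste(miss, collapse = ", "))
  b <- cf$beta[colnames(Xs)]
  V <- drop(Xs %*% b)
  p <- exp(V - max(V)); p <- p / sum(p)
  se <- rep(NA_real_, length(p))
  if (!is.null(cf$vcov)) {
    set.seed(seed)
    draws <- MASS::mvrnorm(n_draws, cf$beta, cf$vcov)
    Vd <- draws[, colnames(Xs), drop = FALSE] %*% t(Xs)
    Pd <- exp(Vd - apply(Vd, 1L, max))
    Pd <- Pd / rowSums(Pd)
    se <- apply(Pd, 2L, stats::sd)
  }
  structure(
    data.frame(alternative = names(scn$alternatives), utility = V,
               probability = p, se = se, stringsAsFactors = FALSE,
               row.names = NULL),
    class = c("forecast_result", "data.frame"))
}

#' Check scale behaviour of forecasts and MRS
#'
#' Multiplying every utility coefficient by a positive constant `k`
#' rescales the unobserved-error variance of the logit model: forecast
#' probabilities change (sharpening towards 0/1 as `k` grows, flattening
#' to 1/2 as `k` shrinks), but every marginal rate of substitution is a
#' ratio of coefficients and must be exactly unchanged.  This harness
#' computes both quantities at `beta` and `k * beta` and reports the
#' comparison.
#'
#' @param fit An `mnl_fit` or named coefficient vector.
#' @param scn A `dce_scenario`.
#' @param k Positive scale factor.
#' @return A list with `k`, `mrs`, `mrs_scaled`, `mrs_invariant`,
#'   `forecast`, `forecast_scaled`, `forecast_changed`.
#' @export
scale_invariance_check <- function(fit, scn, k) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive scalar")
  beta <- as_mnl_coef(fit)$beta
  m0 <- mrs_mcid(beta, method = "none")$point
  m1 <- mrs_mcid(beta * k, method = "none")$point
  f0 <- forecast(beta, scn)$probability
  f1 <- forecast(beta * k, scn)$probability
  list(k = k, mrs = m0, mrs_scaled = m1,
       mrs_invariant = isTRUE(all.equal(m0, m1, tolerance = 1e-10)),
       forecast = f0, forecast_scaled = f1,
       forecast_max_abs_change = max(abs(f0 - f1)))
}
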