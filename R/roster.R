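# Find latent normal (mu, sigma) such that an integer ACT score obtained by
# rounding and clipping to the 5-25 instrument range has the target mean and
# SD.  Expected moments are computed analytically over the integer grid, so
# the calibration itself is deterministic.
act_latent_params <- function(target_mean, target_sd) {
  grid <- 5:25
  moments <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    hi <- c(grid[-length(grid)] + 0.5, Inf)
    lo <- c(-Inf, grid[-1] - 0.5)
    p <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
    m <- sum(grid * p)
    s <- sqrt(sum((grid - m)^2 * p))
    c(m, s)
  }
  obj <- function(par) {
    ms <- moments(par)
    (ms[1] - target_mean)^2 + (ms[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Calibration targets for the synthetic respondent roster
#'
#' Returns the marginal covariate distribution used by [sample_roster()],
#' matching the published sample margins: ACT mean 18.4 (SD 5.1) on the
#' 5-25 range, 48% ever hospitalised for asthma, 56% with a university
#' degree, 12% non-white, 45% UK (vs NZ), mean age 56 on 18-86 for
#' patients; and the care-setting / gender margins for HCPs.
#'
#' @param group `"patient"` or `"hcp"`.
#' @return A named list of marginal proportions and moments.
#' @export
roster_calibration <- function(group = c("patient", "hcp")) {
  group <- match.arg(tolower(group), c("patient", "hcp"))
  if (group == "patient") {
    list(act_mean = 18.4, act_sd = 5.1,
         ever_hospitalised = 0.48, university = 0.56, nonwhite = 0.12,
         uk = 0.45, age_mean = 56, age_sd = 15, age_min = 18, age_max = 86)
  } else {
    list(male = 0.39, uk = 0.68,
         setting = c(hospital = 0.60, general_practice = 0.28,
                     emergency = 0.04, community = 0.01, non_clinical = 0.07))
  }
}

#' Sample a synthetic respondent roster
#'
#' Draws respondents whose covariates follow the calibrated marginal
#' distributions (independently across covariates: the published margins
#' carry no correlation structure).  Patients get an integer ACT score from
#' a discretised, range-clipped normal whose latent parameters are solved
#' so the clipped distribution hits the target mean/SD, plus flags derived
#' from it; block assignment is uniform over blocks; the introductory
#' narrative arm is a pure label with no generating effect.
#'
#' @param group `"patient"` or `"hcp"`.
#' @param n Number of respondents.
#' @param n_blocks Number of design blocks respondents are randomised over.
#' @param calibration Marginals, see [roster_calibration()].
#' @param seed Integer seed.
#' @return A data.frame of class `respondent_roster`, one row per
#'   respondent.  Patient columns: `act_score`, `act_le_15`,
#'   `ever_hospitalised`, `university`, `no_university`, `nonwhite`, `age`,
#'   `age_over_65`, `country`, `narrative_arm`.  HCP columns: `male`,
#'   `setting`, `country`.
#' @export
sample_roster <- function(group = c("patient", "hcp"), n,
                          n_blocks = 2L,
                          calibration = roster_calibration(group),
                          seed = 1L) {
  group <- match.arg(tolower(group), c("patient", "hcp"))
  stopifnot(n >= 1L)
  prop_names <- intersect(names(calibration),
                          c("ever_hospitalised", "university", "nonwhite",
                            "uk", "male"))
  for (nm in prop_names)
    if (calibration[[nm]] < 0 || calibration[[nm]] > 1)
      stop("calibration proportion '", nm, "' outside [0, 1]")
  set.seed(seed)
  out <- data.frame(
    respondent_id = paste0(ifelse(group == "patient", "P", "H"),
                           formatC(seq_len(n), width = 5, flag = "0")),
    group = group,
    block_id = sample(rep_len(seq_len(n_blocks), n)),
    stringsAsFactors = FALSE)
  if (group == "patient") {
    lat <- act_latent_params(calibration$act_mean, calibration$act_sd)
    act <- round(stats::rnorm(n, lat$mu, lat$sigma))
    out$act_score <- as.integer(pmin(pmax(act, 5L), 25L))
    out$act_le_15 <- out$act_score <= 15L
    out$ever_hospitalised <- stats::runif(n) < calibration$ever_hospitalised
    out$university <- stats::runif(n) < calibration$university
    out$no_university <- !out$university
    out$nonwhite <- stats::runif(n) < calibration$nonwhite
    age <- round(stats::rnorm(n, calibration$age_mean, calibration$age_sd))
    out$age <- as.integer(pmin(pmax(age, calibration$age_min),
                               calibration$age_max))
    out$age_over_65 <- out$age > 65L
    out$country <- ifelse(stats::runif(n) < calibration$uk, "UK", "NZ")
    out$narrative_arm <- sample(rep_len(1:2, n))
  } else {
    out$male <- stats::runif(n) < calibration$male
    out$setting <- sample(names(calibration$setting), n, replace = TRUE,
                          prob = calibration$setting)
    out$country <- ifelse(stats::runif(n) < calibration$uk, "UK", "NZ")
  }
  class(out) <- c("respondent_roster", "data.frame")
  out
}

#' Simulate forced choices for a roster over a blocked design
#'
#' Each respondent answers the 2-alternative tasks of their block.  The
#' utility of an alternative is the sum of the generating base utilities of
#' its non-reference levels plus, for each interaction whose covariate the
#' respondent carries (covariate flag TRUE), the interaction log-odds-ratio
#' times the level dummy.  The chosen alternative is a direct categorical
#' draw from the implied logit probabilities
#' `P(j) = exp(V_j) / sum_k exp(V_k)`; exactly one alternative per
#' respondent-task is marked chosen.
#'
#' @param roster A `respondent_roster`.
#' @param design A blocked `choice_design`.
#' @param truth A `generative_truth` dimensioned to the design's spec.
#' @param seed Integer seed.
#' @return A long-format data.frame of class `choice_dataset`: one row per
#'   respondent x task x alternative with the attribute level labels, a
#'   `chosen` 0/1 flag and the roster covariates joined on.
#' @export
simulate_choices <- function(roster, design, truth, seed = 1L) {
  stopifnot(is.data.frame(roster), inherits(design, "choice_design"),
            inherits(truth, "generative_truth"))
  if (max(design$tasks$alt_id) != 2L)
    stop("simulate_choices supports 2-alternative designs")
  spec <- design$spec
  cn <- coef_names(spec)
  beta0 <- truth$base_utilities[cn]
  if (anyNA(beta0))
    stop("truth base_utilities do not cover the design coefficients: ",
         paste(setdiff(cn, names(truth$base_utilities)), collapse = ", "))
  ints <- truth$interactions
  if (nrow(ints)) {
    bad <- setdiff(unique(ints$covariate), names(roster))
    if (length(bad))
      stop("interaction references covariate(s) absent from roster: ",
           paste(bad, collapse = ", "))
  }
  cd <- design_coded(design)
  tk <- design$tasks
  set.seed(seed)

  # per-respondent coefficient vector = base + sum of carried interactions
  n <- nrow(roster)
  beta_mat <- matrix(beta0, n, length(cn), byrow = TRUE,
                     dimnames = list(NULL, cn))
  if (nrow(ints)) {
    for (r in seq_len(nrow(ints))) {
      flag <- as.logical(roster[[ints$covariate[r]]])
      beta_mat[, ints$level[r]] <- beta_mat[, ints$level[r]] +
        ifelse(flag, ints$log_or[r], 0)
    }
  }

  pieces <- vector("list", n)
  attr_cols <- vapply(spec$attributes, `[[`, character(1), "name")
  for (i in seq_len(n)) {
    rows <- which(tk$block_id == roster$block_id[i])
    Xb <- cd$X[rows, , drop = FALSE]
    task_b <- tk$task_id[rows]
    V <- drop(Xb %*% beta_mat[i, ])
    # two alternatives per task, rows ordered alt 1 then alt 2
    o <- order(task_b, tk$alt_id[rows])
    rows <- rows[o]; V <- V[o]; task_b <- task_b[o]
    v1 <- V[seq(1, length(V), by = 2)]
    v2 <- V[seq(2, length(V), by = 2)]
    p1 <- stats::plogis(v1 - v2)
    pick1 <- stats::runif(length(p1)) < p1
    chosen <- integer(length(V))
    chosen[seq(1, length(V), by = 2)] <- as.integer(pick1)
    chosen[seq(2, length(V), by = 2)] <- as.integer(!pick1)
    df <- tk[rows, c("task_id", "block_id", "alt_id", attr_cols)]
    df$chosen <- chosen
    df$respondent_id <- roster$respondent_id[i]
    pieces[[i]] <- df
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  cov_cols <- setdiff(names(roster), c("block_id"))
  out <- merge(out, roster[, cov_cols], by = "respondent_id", sort = FALSE)
  out <- out[order(match(out$respondent_id, roster$respondent_id),
                   out$task_id, out$alt_id), ]
  rownames(out) <- NULL
  out$group <- as.character(out$group)
  first <- c("respondent_id", "group", "block_id", "task_id", "alt_id",
             attr_cols, "chosen")
  out <- out[, c(first, setdiff(names(out), first))]
  class(out) <- c("choice_dataset", "data.frame")
  out
}
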