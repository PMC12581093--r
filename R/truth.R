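# Published full-sample odds ratios for the OCS risk-benefit DCE, one per
# non-reference attribute level, in coef_names(ocs_design_spec()) order.
published_or_table <- function(group = c("patient", "hcp")) {
  group <- match.arg(tolower(group), c("patient", "hcp"))
  or <- switch(group,
    patient = c(
      "gp_retreatment:5%"       = 1.34,
      "gp_retreatment:10%"      = 1.24,
      "hospitalisation:5%"      = 1.10,
      "hospitalisation:10%"     = 1.02,
      "symptom_improvement:100%" = 2.04,
      "symptom_improvement:50%"  = 1.27,
      "pef_improvement:40%"     = 1.57,
      "pef_improvement:20%"     = 1.16,
      "permanent_se:None"       = 7.27,
      "temporary_se:None"       = 1.48),
    hcp = c(
      "gp_retreatment:5%"       = 2.09,
      "gp_retreatment:10%"      = 1.30,
      "hospitalisation:5%"      = 1.86,
      "hospitalisation:10%"     = 1.36,
      "symptom_improvement:100%" = 3.47,
      "symptom_improvement:50%"  = 1.51,
      "pef_improvement:40%"     = 1.41,
      "pef_improvement:20%"     = 1.02,
      "permanent_se:None"       = 5.79,
      "temporary_se:None"       = 1.67))
  or
}

# Published subgroup interaction odds ratios (ratio-of-odds-ratios scale):
# how a covariate shifts the preference weight of one attribute level.
published_interaction_table <- function(group = c("patient", "hcp")) {
  group <- match.arg(tolower(group), c("patient", "hcp"))
  if (group == "patient") {
    data.frame(
      covariate = c("act_le_15", "ever_hospitalised", "nonwhite",
                    "no_university", "no_university", "no_university",
                    "age_over_65", "age_over_65"),
      level = c("permanent_se:None", "permanent_se:None", "permanent_se:None",
                "permanent_se:None", "symptom_improvement:100%",
                "gp_retreatment:5%",
                "temporary_se:None", "symptom_improvement:100%"),
      or = c(0.67, 0.69, 0.73, 0.48, 0.69, 0.76, 1.22, 1.30),
      stringsAsFactors = FALSE)
  } else {
    data.frame(covariate = "male", level = "hospitalisation:5%", or = 2.52,
               stringsAsFactors = FALSE)
  }
}

#' Generative preference truth from the published estimates
#'
#' Returns the published full-sample odds ratios, log-transformed onto the
#' utility (log-odds) scale, as the base utilities of a random-utility
#' model, optionally together with the published socio-demographic
#' interaction multipliers (also log-transformed).  Reference levels carry
#' utility zero by construction.  This object is the generating truth used
#' by [simulate_choices()] and the natural input for parameter-recovery
#' studies.
#'
#' Patient interactions: poorly controlled asthma (ACT <= 15), prior
#' hospitalisation for asthma, and non-white ethnicity each reduce the
#' weight on avoiding permanent side effects; no university education
#' reduces the weights on no-permanent-side-effects, complete symptom
#' improvement and the 5% GP re-treatment level; age over 65 increases the
#' weights on avoiding temporary side effects and on complete symptom
#' improvement.  HCP interaction: male HCPs weight the 5% hospitalisation
#' level more strongly.
#'
#' @param group `"patient"` or `"hcp"`.
#' @param include_interactions Attach the interaction multipliers (default
#'   `TRUE`).  Set `FALSE` for a homogeneous-preference population whose
#'   every respondent carries exactly the published full-sample utilities.
#' @return An object of class `generative_truth`: list with
#'   `base_utilities` (named numeric, log-OR scale) and `interactions`
#'   (data.frame covariate / level / log_or).
#' @export
published_truth <- function(group = c("patient", "hcp"),
                            include_interactions = TRUE) {
  group <- match.arg(tolower(group), c("patient", "hcp"))
  base <- log(published_or_table(group))
  ints <- published_interaction_table(group)
  ints$log_or <- log(ints$or)
  if (!include_interactions) ints <- ints[0, ]
  structure(list(group = group, base_utilities = base,
                 interactions = ints),
            class = "generative_truth")
}

#' Construct a generative truth from arbitrary utilities
#'
#' @param base_utilities Named numeric vector on the log-odds scale, one
#'   entry per non-reference level (names as [coef_names()]).
#' @param interactions Optional data.frame with columns `covariate`,
#'   `level`, `log_or`.
#' @return A `generative_truth`.
#' @export
generative_truth <- function(base_utilities, interactions = NULL) {
  if (is.null(names(base_utilities)) || any(!nzchar(names(base_utilities))))
    stop("base_utilities must be a fully named vector")
  if (is.null(interactions))
    interactions <- data.frame(covariate = character(), level = character(),
                               log_or = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("covariate", "level", "log_or") %in% names(interactions)))
  if (!all(interactions$level %in% names(base_utilities)))
    stop("interaction level(s) not among the base utility names")
  structure(list(group = NA_character_, base_utilities = base_utilities,
                 interactions = interactions),
            class = "generative_truth")
}

#' @export
print.generative_truth <- function(x, ...) {
  cat("<generative_truth>", if (!is.na(x$group)) paste0(" (", x$group, ")"),
      "\n", sep = "")
  print(round(x$base_utilities, 4))
  if (nrow(x$interactions)) {
    cat("interactions:\n")
    print(x$interactions[, c("covariate", "level", "log_or")])
  }
  invisible(x)
}
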