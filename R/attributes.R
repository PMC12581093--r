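#' Define a single DCE attribute
#'
#' An attribute is one characteristic of a hypothetical treatment (e.g.,
#' "chance of hospitalisation within 28 days") together with the discrete
#' levels it can take in a choice task.  One level is declared the
#' reference: its utility is fixed at zero under dummy coding, so every
#' estimated coefficient is interpreted against it.
#'
#' @param name Short machine name of the attribute (used in column headers
#'   and coefficient names).
#' @param levels Character vector of level labels, e.g. `c("5%","10%","15%")`.
#' @param reference_level One of `levels`; the dummy-coding reference.
#' @param kind `"quantitative-percent"` for levels that are percentages, or
#'   `"binary-categorical"` for None/High style levels.
#' @param preference_rank Integer vector, same length as `levels`: the a
#'   priori ordering of levels from worst (lowest rank) to best.  Used by
#'   the design search to discard dominated choice tasks; it encodes only
#'   the direction of preference (less risk is better, more benefit is
#'   better), never its magnitude.
#' @param label Optional human-readable description for rendered task cards.
#' @return An object of class `dce_attribute`.
#' @export
attribute_spec <- function(name, levels, reference_level,
                           kind = c("quantitative-percent", "binary-categorical"),
                           preference_rank = seq_along(levels),
                           label = name) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (anyDuplicated(levels))
    stop("attribute '", name, "': levels must be unique")
  if (!reference_level %in% levels)
    stop("attribute '", name, "': reference_level '", reference_level,
         "' is not one of the levels")
  if (length(preference_rank) != length(levels))
    stop("attribute '", name, "': preference_rank must match levels")
  values <- rep(NA_real_, length(levels))
  if (kind == "quantitative-percent") {
    values <- suppressWarnings(as.numeric(sub("%$", "", levels)))
    if (anyNA(values) || any(values < 0) || any(values > 100))
      stop("attribute '", name,
           "': quantitative levels must be percentages in [0, 100]")
  }
  structure(
    list(name = name, levels = as.character(levels),
         values = values, reference_level = reference_level,
         kind = kind, preference_rank = as.integer(preference_rank),
         label = label),
    class = "dce_attribute")
}

#' The OCS treatment attribute system
#'
#' The six-attribute descriptive system for acute asthma treatment: two
#' treatment-failure risks (further GP treatment, hospitalisation, both
#' within 28 days), two clinical benefits (symptom improvement and peak
#' expiratory flow improvement within 7 days) and two side-effect risks
#' (permanent: weak bones, heart disease, diabetes; temporary: anxiety,
#' insomnia, indigestion).  Reference levels are the worst level of each
#' benefit and risk attribute (15% failure risks, 25% symptoms, 0% peak
#' flow, High side-effect risk), so all dummy coefficients are expected
#' positive.
#'
#' @return A list of six [attribute_spec()] objects.
#' @export
ocs_attributes <- function() {
  list(
    attribute_spec("gp_retreatment", c("5%", "10%", "15%"), "15%",
                   "quantitative-percent", preference_rank = c(3L, 2L, 1L),
                   label = "Chance you need more asthma treatment from your GP within 28 days"),
    attribute_spec("hospitalisation", c("5%", "10%", "15%"), "15%",
                   "quantitative-percent", preference_rank = c(3L, 2L, 1L),
                   label = "Chance you need hospital treatment within 28 days"),
    attribute_spec("symptom_improvement", c("100%", "50%", "25%"), "25%",
                   "quantitative-percent", preference_rank = c(3L, 2L, 1L),
                   label = "Amount your asthma symptoms improve within 7 days"),
    attribute_spec("pef_improvement", c("40%", "20%", "0%"), "0%",
                   "quantitative-percent", preference_rank = c(3L, 2L, 1L),
                   label = "Amount your peak flow (lung function) improves within 7 days"),
    attribute_spec("permanent_se", c("None", "High"), "High",
                   "binary-categorical", preference_rank = c(2L, 1L),
                   label = "Chance you get permanent side effects from treatment"),
    attribute_spec("temporary_se", c("None", "High"), "High",
                   "binary-categorical", preference_rank = c(2L, 1L),
                   label = "Chance you get side effects while taking treatment"))
}

#' Define a choice-design specification
#'
#' Bundles the attribute system with the experimental layout (number of
#' alternatives per task, tasks, blocks) and the coefficient priors used by
#' the Bayesian D-efficiency criterion.
#'
#' @param attributes List of [attribute_spec()] objects.
#' @param n_alternatives Alternatives per choice task (unlabelled).
#' @param n_tasks Total choice tasks in the design.
#' @param n_blocks Number of blocks the tasks are split into; must divide
#'   `n_tasks`.
#' @param prior_mean,prior_sd Numeric vectors with one entry per
#'   non-reference level (in coefficient order, see [coef_names()]), or a
#'   single value recycled.  `prior_sd = 0` makes the Bayesian criterion
#'   collapse to plain D-efficiency at `prior_mean`.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(attributes, n_alternatives = 2L, n_tasks = 24L,
                        n_blocks = 2L, prior_mean = 0, prior_sd = 0.5) {
  if (length(attributes) == 0L)
    stop("specification error: empty attribute list")
  stopifnot(all(vapply(attributes, inherits, logical(1), "dce_attribute")))
  nm <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("attribute names must be unique")
  n_tasks <- as.integer(n_tasks); n_blocks <- as.integer(n_blocks)
  if (n_tasks %% n_blocks != 0L)
    stop("n_tasks (", n_tasks, ") must be divisible by n_blocks (", n_blocks, ")")
  k <- sum(vapply(attributes, function(a) length(a$levels) - 1L, integer(1)))
  prior_mean <- rep_len(as.numeric(prior_mean), k)
  prior_sd <- rep_len(as.numeric(prior_sd), k)
  if (any(prior_sd < 0)) stop("prior_sd must be nonnegative")
  structure(
    list(attributes = attributes, n_alternatives = as.integer(n_alternatives),
         n_tasks = n_tasks, n_blocks = n_blocks,
         prior_mean = prior_mean, prior_sd = prior_sd),
    class = "design_spec")
}

#' The published OCS study layout
#'
#' Convenience constructor: the [ocs_attributes()] system with 2 unlabelled
#' alternatives, 24 tasks in 2 blocks of 12, and weakly-informative priors
#' (mean 0, SD 0.5 per coefficient) for the Bayesian D-efficiency criterion.
#'
#' @inheritParams design_spec
#' @return A `design_spec`.
#' @export
ocs_design_spec <- function(n_tasks = 24L, n_blocks = 2L,
                            prior_mean = 0, prior_sd = 0.5) {
  design_spec(ocs_attributes(), n_alternatives = 2L, n_tasks = n_tasks,
              n_blocks = n_blocks, prior_mean = prior_mean, prior_sd = prior_sd)
}

#' Coefficient names of a design specification
#'
#' One name per non-reference attribute level, in reporting order:
#' attributes in their declared order, levels within each attribute in their
#' declared order with the reference level dropped.  All model matrices,
#' coefficient vectors and prior vectors in the package use this order.
#'
#' @param spec A `design_spec`.
#' @return Character vector of `"attribute:level"` names.
#' @export
coef_names <- function(spec) {
  unlist(lapply(spec$attributes, function(a) {
    lv <- setdiff(a$levels, a$reference_level)
    paste(a$name, lv, sep = ":")
  }), use.names = FALSE)
}

#' Enumerate the full-factorial candidate profiles
#'
#' A profile is one treatment alternative: one level per attribute.  The
#' candidate set for the design search is the full factorial over all
#' attribute levels.
#'
#' @param spec A `design_spec`.
#' @return A data.frame with one column per attribute (integer level index,
#'   1-based into `attribute$levels`) and one row per profile; its size is
#'   the product of the level counts.
#' @export
enumerate_profiles <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  idx <- lapply(spec$attributes, function(a) seq_along(a$levels))
  names(idx) <- vapply(spec$attributes, `[[`, character(1), "name")
  out <- rev(expand.grid(rev(idx), KEEP.OUT.ATTRS = FALSE))
  rownames(out) <- NULL
  out
}

# Dummy-code a matrix/data.frame of level indices (rows = profiles) into the
# 0/1 coefficient columns of `coef_names(spec)`.
code_profiles <- function(profile_idx, spec) {
  profile_idx <- as.matrix(profile_idx)
  cols <- vector("list", length(spec$attributes))
  for (i in seq_along(spec$attributes)) {
    a <- spec$attributes[[i]]
    keep <- which(a$levels != a$reference_level)
    m <- matrix(0, nrow(profile_idx), length(keep))
    for (j in seq_along(keep)) m[, j] <- as.numeric(profile_idx[, i] == keep[j])
    cols[[i]] <- m
  }
  out <- do.call(cbind, cols)
  colnames(out) <- coef_names(spec)
  out
}

# Dummy-code level *labels* (character columns named by attribute).
code_levels <- function(level_df, spec) {
  idx <- matrix(0L, nrow(level_df), length(spec$attributes))
  for (i in seq_along(spec$attributes)) {
    a <- spec$attributes[[i]]
    m <- match(as.character(level_df[[a$name]]), a$levels)
    if (anyNA(m)) {
      bad <- unique(as.character(level_df[[a$name]])[is.na(m)])
      stop("unknown level(s) for attribute '", a$name, "': ",
           paste(bad, collapse = ", "))
    }
    idx[, i] <- m
  }
  code_profiles(idx, spec)
}

#' @export
print.dce_attribute <- function(x, ...) {
  cat("<dce_attribute> ", x$name, " [", x$kind, "]\n", sep = "")
  cat("  levels: ", paste(x$levels, collapse = ", "),
      " (reference: ", x$reference_level, ")\n", sep = "")
  invisible(x)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", length(x$attributes), " attributes, ",
      x$n_alternatives, " alternatives, ", x$n_tasks, " tasks in ",
      x$n_blocks, " block(s)\n", sep = "")
  cat("  coefficients: ", paste(coef_names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
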