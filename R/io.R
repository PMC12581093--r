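# ---- long-format choice data I/O ---------------------------------------

#' Write / read the long-format choice data file
#'
#' Fixed column order: `respondent_id`, `group`, `block_id`, `task_id`,
#' `alt_id`, the six attribute columns (level labels), `chosen`, then any
#' covariate columns.  The reader validates the schema and the
#' forced-choice invariant (exactly one chosen alternative per
#' respondent-task) and reports violations with the offending file lines.
#'
#' @param data A `choice_dataset`.
#' @param path File path.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @param spec The `design_spec` levels are validated against.
#' @export
read_choice_data <- function(path, spec) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  anames <- vapply(spec$attributes, `[[`, character(1), "name")
  need <- c("respondent_id", "group", "block_id", "task_id", "alt_id",
            anames, "chosen")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("choice file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  # level labels (line numbers are 1-based file lines incl. header)
  for (a in spec$attributes) {
    bad <- which(!df[[a$name]] %in% a$levels)
    if (length(bad))
      stop("choice file ", path, ", line ", bad[1] + 1L,
           ": unknown level '", df[[a$name]][bad[1]], "' for attribute '",
           a$name, "'")
  }
  if (!all(df$chosen %in% 0:1))
    stop("choice file ", path, ": 'chosen' must be 0/1")
  key <- paste(df$respondent_id, df$task_id)
  n_chosen <- tapply(df$chosen, key, sum)
  bad <- names(n_chosen)[n_chosen != 1L]
  if (length(bad)) {
    lines <- which(key == bad[1]) + 1L
    stop("choice file ", path, ": respondent/task '", bad[1], "' has ",
         n_chosen[bad[1]], " chosen alternatives (expected exactly 1); ",
         "see lines ", paste(lines, collapse = ", "))
  }
  class(df) <- c("choice_dataset", "data.frame")
  df
}

#' Write a fit report table
#'
#' The published-table-shaped report: one row per attribute level
#' (reference rows included with OR = 1), odds ratios rounded to 2 decimals
#' in `or_2dp` alongside the full-precision machine-readable columns.
#'
#' @param fit A converged `mnl_fit`.
#' @param path File path.
#' @export
write_fit_report <- function(fit, path) {
  tab <- odds_ratios(fit)
  tab$or_2dp <- round(tab$or, 2)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# ---- pipeline configuration and run log --------------------------------

#' Configure an end-to-end pipeline run
#'
#' @param outdir Output directory (created if absent).
#' @param n_patients,n_hcps Respondent counts (defaults: the study's 824
#'   patients and 171 HCPs).
#' @param n_tasks,n_blocks Design layout (defaults 24 tasks, 2 blocks).
#' @param design_iterations Exchange-search iterations for the design stage.
#' @param n_draws Prior draws for the Bayesian D-error.
#' @param kr_draws Krinsky-Robb draws for the MRS intervals.
#' @param include_interactions Simulate the published preference
#'   heterogeneity (default `TRUE`).
#' @param seeds Named list of integer seeds: `design`, `roster`, `choices`,
#'   `kr`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(outdir,
                       n_patients = 824L, n_hcps = 171L,
                       n_tasks = 24L, n_blocks = 2L,
                       design_iterations = 2000L, n_draws = 100L,
                       kr_draws = 10000L, include_interactions = TRUE,
                       seeds = list(design = 101L, roster = 202L,
                                    choices = 303L, kr = 404L)) {
  need <- c("design", "roster", "choices", "kr")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "))
  for (s in need)
    if (!is.numeric(seeds[[s]]) || seeds[[s]] != round(seeds[[s]]))
      stop("seed '", s, "' must be an integer")
  for (nm in c("n_patients", "n_hcps", "n_tasks", "n_blocks",
               "design_iterations", "n_draws", "kr_draws")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1) stop(nm, " must be a positive count")
  }
  structure(list(outdir = outdir, n_patients = as.integer(n_patients),
                 n_hcps = as.integer(n_hcps), n_tasks = as.integer(n_tasks),
                 n_blocks = as.integer(n_blocks),
                 design_iterations = as.integer(design_iterations),
                 n_draws = as.integer(n_draws),
                 kr_draws = as.integer(kr_draws),
                 include_interactions = isTRUE(include_interactions),
                 seeds = lapply(seeds, as.integer)),
            class = "run_config")
}

#' Run the full DCE pipeline
#'
#' Executes design -> roster/choice simulation (patients and HCPs) -> MNL
#' fits -> MRS/MCID -> scenario forecasts -> report files, all under the
#' named seeds of the configuration, and returns a run log with one record
#' per stage (seed, row counts, output file, md5 digest).  A stage failure
#' halts the pipeline with the stage named; outputs of earlier stages are
#' left on disk.  Identical configurations reproduce identical output
#' digests.
#'
#' The MRS stage follows the study protocol: HCPs contribute their full
#' sample, patients the poorly-controlled subgroup (ACT <= 15); forecasts
#' compare the OCS-equivalent and placebo-equivalent alternatives for both
#' groups.
#'
#' @param config A `run_config`.
#' @return A data.frame run log (one row per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  add <- function(stage, seed, n_rows, file) {
    digest <- if (!is.na(file)) unname(tools::md5sum(file)) else NA_character_
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      seed = seed, n_rows = n_rows,
      file = ifelse(is.na(file), NA_character_, basename(file)),
      md5 = digest, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(f) file.path(config$outdir, f)

  design <- run_stage("design", {
    spec <- ocs_design_spec(n_tasks = config$n_tasks,
                            n_blocks = config$n_blocks)
    d <- optimize_design(spec, n_iterations = config$design_iterations,
                         seed = config$seeds$design,
                         n_draws = config$n_draws)
    write_design(d, out("design.csv"))
    d
  })
  spec <- design$spec
  add("design", config$seeds$design, nrow(design$tasks), out("design.csv"))

  sims <- list()
  for (grp in c("patient", "hcp")) {
    n <- if (grp == "patient") config$n_patients else config$n_hcps
    roster <- run_stage(paste0("roster_", grp), {
      r <- sample_roster(grp, n, n_blocks = config$n_blocks,
                         seed = config$seeds$roster +
                           (grp == "hcp"))
      utils::write.csv(r, out(paste0("roster_", grp, ".csv")),
                       row.names = FALSE)
      r
    })
    add(paste0("roster_", grp), config$seeds$roster + (grp == "hcp"),
        nrow(roster), out(paste0("roster_", grp, ".csv")))

    choices <- run_stage(paste0("simulate_", grp), {
      truth <- published_truth(grp, config$include_interactions)
      ch <- simulate_choices(roster, design, truth,
                             seed = config$seeds$choices + (grp == "hcp"))
      write_choice_data(ch, out(paste0("choices_", grp, ".csv")))
      ch
    })
    add(paste0("simulate_", grp), config$seeds$choices + (grp == "hcp"),
        nrow(choices), out(paste0("choices_", grp, ".csv")))

    fit <- run_stage(paste0("fit_", grp), {
      f <- fit_mnl(build_model_matrix(choices, spec))
      write_fit_report(f, out(paste0("fit_", grp, ".csv")))
      f
    })
    add(paste0("fit_", grp), NA_integer_, length(coef(fit)),
        out(paste0("fit_", grp, ".csv")))
    sims[[grp]] <- list(choices = choices, fit = fit)
  }

  mrs_tab <- run_stage("mrs", {
    poorly <- sims$patient$choices[as.logical(sims$patient$choices$act_le_15), ]
    fit_poor <- fit_mnl(build_model_matrix(poorly, spec))
    rows <- lapply(list(patient_act_le_15 = fit_poor, hcp = sims$hcp$fit),
                   function(f) mrs_mcid(f, method = "krinsky-robb",
                                        n_draws = config$kr_draws,
                                        seed = config$seeds$kr))
    tab <- data.frame(group = names(rows),
                      mrs = vapply(rows, `[[`, numeric(1), "point"),
                      ci_low = vapply(rows, `[[`, numeric(1), "ci_low"),
                      ci_high = vapply(rows, `[[`, numeric(1), "ci_high"),
                      method = "krinsky-robb", stringsAsFactors = FALSE)
    utils::write.csv(tab, out("mrs.csv"), row.names = FALSE)
    tab
  })
  add("mrs", config$seeds$kr, nrow(mrs_tab), out("mrs.csv"))

  fc_tab <- run_stage("forecast", {
    scn <- ocs_vs_placebo_scenario(spec)
    poorly <- sims$patient$choices[as.logical(sims$patient$choices$act_le_15), ]
    fit_poor <- fit_mnl(build_model_matrix(poorly, spec))
    tabs <- lapply(list(patient_act_le_15 = fit_poor, hcp = sims$hcp$fit),
                   function(f) forecast(f, scn, seed = config$seeds$kr))
    tab <- do.call(rbind, Map(function(g, t) cbind(group = g, t),
                              names(tabs), tabs))
    rownames(tab) <- NULL
    utils::write.csv(tab, out("forecast.csv"), row.names = FALSE)
    tab
  })
  add("forecast", config$seeds$kr, nrow(fc_tab), out("forecast.csv"))

  log_df <- do.call(rbind, log)
  utils::write.csv(log_df, out("run_log.csv"), row.names = FALSE)
  log_df
}
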