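#' Run the full bioblitz outcome analysis
#'
#' Chains every stage on in-memory tables: qualification against the
#' bioblitz definition, per-project summaries and timing histograms,
#' participant categorization, the paired-difference panel and decay fit
#' (with derived half-life and cumulative boost), per-event
#' observer-identifier network statistics, and (optionally) the
#' platform-level extrapolation. Only qualified projects enter the
#' engagement and network stages.
#'
#' @param observations Observation table (e.g. [read_observations()] or
#'   [generate_bioblitz_data()]).
#' @param identifications Identification table.
#' @param projects Project table.
#' @param criteria [qualification_criteria()] for the definitional filter.
#' @param weeks Post-event weeks in the difference panel (default 50).
#' @param fit_method `"two_stage"` or `"pooled"` (see [fit_decay()]).
#' @param min_users_per_project Passed to [fit_decay()].
#' @param seed Seed for the fit's jittered restarts.
#' @param extrapolation Optional list with `n_participants`,
#'   `obs_per_day` and `total_observations` for [extrapolate_boost()]; the
#'   continuation rate defaults to the observed continuing fraction and the
#'   cumulative days to the fitted cumulative boost, either overridable by
#'   list entries of those names.
#' @param output_dir Optional directory; when given, every stage output is
#'   written as CSV plus a single JSON report.
#' @return A `bioblitz_report` (a list): `qualification`, `summaries`,
#'   `timing`, `categories`, `category_fractions`, `panel`, `fit`
#'   (`decay_fit`), `half_life_weeks`, `cumulative_boost_days`,
#'   `extrapolation`, `network_stats`, `schema_version`.
#' @export
run_pipeline <- function(observations, identifications, projects,
                         criteria = qualification_criteria(), weeks = 50L,
                         fit_method = "two_stage",
                         min_users_per_project = 3L, seed = 1L,
                         extrapolation = NULL, output_dir = NULL) {
  qualification <- qualify_projects(projects, observations, identifications,
                                    criteria)
  qualified <- projects[projects$project_id %in%
                          qualification$project_id[qualification$qualifies],
                        , drop = FALSE]
  summaries <- summarize_projects(projects, observations, identifications)
  timing <- timing_histograms(projects)

  categories <- purrr::map(seq_len(nrow(qualified)), function(i) {
    tryCatch(categorize_participants(observations, qualified[i, ]),
             bioblitzr_precondition_error = function(e) NULL)
  }) |>
    dplyr::bind_rows()
  category_fractions <- categories |>
    dplyr::count(.data$category, .drop = FALSE, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))

  panel <- build_panel(observations, qualified, weeks = weeks)
  fit <- fit_decay(panel, method = fit_method,
                   min_users_per_project = min_users_per_project,
                   seed = seed)
  hl <- if (isTRUE(fit$converged)) half_life(fit$b_hat) else NA_real_
  cb <- if (isTRUE(fit$converged)) cumulative_boost(fit$a_hat, fit$b_hat)
        else NA_real_

  network_stats <- purrr::map(seq_len(nrow(qualified)), function(i) {
    g <- build_network(event_observations(observations, qualified[i, ]),
                       identifications)
    roles <- table(g$nodes$role)
    tibble::tibble(project_id = qualified$project_id[i],
                   n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
                   n_identifications = g$n_identifications,
                   n_observer_only = roles[["observer"]],
                   n_identifier_only = roles[["identifier"]],
                   n_both = roles[["both"]])
  }) |>
    dplyr::bind_rows()

  extrap <- NULL
  if (!is.null(extrapolation)) {
    cont_frac <- sum(category_fractions$fraction[
      category_fractions$category %in% c("continuing_new",
                                         "continuing_veteran")])
    extrap <- extrapolate_boost(
      n_participants = extrapolation$n_participants,
      continuation_rate = extrapolation$continuation_rate %||% cont_frac,
      cumulative_days = extrapolation$cumulative_days %||% cb,
      obs_per_day = extrapolation$obs_per_day %||% 1,
      total_observations = extrapolation$total_observations)
  }

  report <- structure(
    list(schema_version = "1.0",
         n_projects = nrow(projects), n_qualified = nrow(qualified),
         qualification = qualification, summaries = summaries,
         timing = timing, categories = categories,
         category_fractions = category_fractions, panel = panel,
         fit = fit, half_life_weeks = hl, cumulative_boost_days = cb,
         extrapolation = extrap, network_stats = network_stats),
    class = "bioblitz_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration names the three input CSVs (`observations`,
#' `identifications`, `projects` under `paths:`), an optional column map
#' (inline, same layout as [read_col_map()]), optional `criteria:`
#' (`min_observers`, `min_identifiers`, `max_duration_hours`), and optional
#' `weeks`, `fit_method`, `seed` and `output_dir`. All referenced paths are
#' checked before any stage runs.
#'
#' @param config_path Path to the YAML configuration.
#' @return A `bioblitz_report` (see [run_pipeline()]).
#' @export
run_pipeline_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (tbl in c("observations", "identifications", "projects")) {
    path <- cfg$paths[[tbl]]
    if (is.null(path)) {
      abort_bioblitzr(sprintf("configuration is missing paths$%s", tbl),
                      class = "bioblitzr_config_error")
    }
    if (!file.exists(path)) {
      abort_bioblitzr(sprintf("configured %s file does not exist: %s",
                              tbl, path),
                      class = "bioblitzr_config_error")
    }
  }
  colmap <- col_map(observations = cfg$observations,
                    identifications = cfg$identifications,
                    projects = cfg$projects,
                    date_format = cfg$date_format %||% "%Y-%m-%d",
                    datetime_format = cfg$datetime_format %||%
                      "%Y-%m-%dT%H:%M:%S",
                    delimiter = cfg$delimiter %||% ",")
  crit <- qualification_criteria(
    min_observers = cfg$criteria$min_observers %||% 2L,
    min_identifiers = cfg$criteria$min_identifiers %||% 1L,
    max_duration_hours = cfg$criteria$max_duration_hours %||% 336)
  obs <- read_observations(cfg$paths$observations, colmap)
  ids <- read_identifications(cfg$paths$identifications, colmap)
  prj <- read_projects(cfg$paths$projects, colmap)
  run_pipeline(obs, ids, prj, criteria = crit,
               weeks = cfg$weeks %||% 50L,
               fit_method = cfg$fit_method %||% "two_stage",
               seed = cfg$seed %||% 1L,
               output_dir = cfg$output_dir)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qual <- report$qualification |>
    dplyr::mutate(failed_criteria = purrr::map_chr(
      .data$failed_criteria, paste, collapse = ";"))
  readr::write_csv(qual, file.path(dir, "qualification.csv"))
  readr::write_csv(report$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(report$categories, file.path(dir, "categories.csv"))
  readr::write_csv(report$panel, file.path(dir, "panel.csv"))
  readr::write_csv(report$fit$weekly, file.path(dir, "weekly_means.csv"))
  readr::write_csv(report$fit$project_effects,
                   file.path(dir, "project_effects.csv"))
  readr::write_csv(report$network_stats, file.path(dir, "network_stats.csv"))
  json <- list(
    schema_version = report$schema_version,
    n_projects = report$n_projects,
    n_qualified = report$n_qualified,
    category_fractions = report$category_fractions,
    decay = as.list(glance(report$fit)),
    half_life_weeks = report$half_life_weeks,
    cumulative_boost_days = report$cumulative_boost_days,
    extrapolation = if (!is.null(report$extrapolation))
      as.list(report$extrapolation) else NULL)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

#' @export
print.bioblitz_report <- function(x, ...) {
  cat("Bioblitz outcome analysis\n")
  cat(sprintf("  projects: %d candidate, %d qualified\n", x$n_projects,
              x$n_qualified))
  cat(sprintf("  participants categorized: %d\n", nrow(x$categories)))
  fr <- x$category_fractions
  cat(sprintf("  mix: %s\n",
              paste(sprintf("%s %.1f%%", fr$category, 100 * fr$fraction),
                    collapse = ", ")))
  if (isTRUE(x$fit$converged)) {
    cat(sprintf("  decay: a = %.3f d/wk, b = %.3f /wk (SE %.3f), half-life %.1f wk, cumulative boost %.1f d\n",
                x$fit$a_hat, x$fit$b_hat, x$fit$se_b, x$half_life_weeks,
                x$cumulative_boost_days))
  } else {
    cat("  decay fit not converged or degenerate\n")
  }
  invisible(x)
}
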