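#' Qualification thresholds for the bioblitz definition
#'
#' A bioblitz is a short-term event from a specific place with more than one
#' observer and at least one identifier. These thresholds make that
#' definition operational: a candidate project qualifies when it has at least
#' `min_observers` observers, at least `min_identifiers` identifiers, and a
#' duration of at most `max_duration_hours`.
#'
#' The default duration cutoff is 336 h (14 days): most bioblitzes last under
#' 72 h but longer events do occur, so 72 h is offered as a strict preset
#' (`qualification_criteria(max_duration_hours = 72)`) rather than the
#' default. "More than one observer" is read strictly, hence
#' `min_observers = 2`.
#'
#' @param min_observers Minimum distinct observers within the event window
#'   (default 2).
#' @param min_identifiers Minimum distinct identifiers of event records
#'   (default 1). Observers who also identify count.
#' @param max_duration_hours Maximum event duration in hours (default 336).
#' @return A `qualification_criteria` object.
#' @export
qualification_criteria <- function(min_observers = 2L, min_identifiers = 1L,
                                   max_duration_hours = 336) {
  stopifnot(min_observers >= 1, min_identifiers >= 0, max_duration_hours > 0)
  structure(
    list(min_observers = as.integer(min_observers),
         min_identifiers = as.integer(min_identifiers),
         max_duration_hours = as.numeric(max_duration_hours)),
    class = "qualification_criteria"
  )
}

# Observations belonging to a project-event: matching project_id AND
# observed on a calendar day within [start, end]. Records with a matching
# project_id outside the window are deliberately not members (platform
# projects accrue records outside the event); qualify_projects() reports
# them separately.
member_mask <- function(observations, project_id, start, end) {
  if (!"project_id" %in% names(observations)) {
    return(rep(FALSE, nrow(observations)))
  }
  d0 <- as.Date(start)
  d1 <- as.Date(end)
  !is.na(observations$project_id) &
    observations$project_id == project_id &
    observations$observed_date >= d0 &
    observations$observed_date <= d1
}

#' Observations belonging to one project-event
#'
#' Filters an observation table to the records of a single event: matching
#' `project_id` and observed on a calendar day within the event window.
#'
#' @param observations Observation table.
#' @param project A one-row project table (or a row from one).
#' @return The member observations, a tibble.
#' @export
event_observations <- function(observations, project) {
  stopifnot(nrow(project) == 1)
  observations[member_mask(observations, project$project_id,
                           project$start, project$end), , drop = FALSE]
}

project_counts <- function(project, observations, identifications) {
  m <- member_mask(observations, project$project_id, project$start,
                   project$end)
  member <- observations[m, , drop = FALSE]
  outside <- sum(!is.na(observations$project_id) &
                   observations$project_id == project$project_id & !m)
  ids_on_event <- identifications[
    identifications$observation_id %in% member$observation_id, , drop = FALSE]
  list(member = member,
       n_observations = nrow(member),
       n_observers = dplyr::n_distinct(member$observer_id),
       n_identifiers = dplyr::n_distinct(ids_on_event$identifier_id),
       n_obs_outside_window = outside,
       ids_on_event = ids_on_event)
}

#' Qualify candidate projects against the bioblitz definition
#'
#' Applies the definitional filter to every candidate project: distinct
#' observers and identifiers are counted over records within the event window
#' (see [event_observations()]) and the duration is checked against the
#' cutoff. Records carrying the project id but observed outside the window do
#' not count toward qualification and are tallied in
#' `n_obs_outside_window`.
#'
#' @param projects Project table ([read_projects()] or
#'   [generate_bioblitz_data()]).
#' @param observations Observation table.
#' @param identifications Identification table.
#' @param criteria A [qualification_criteria()] object.
#' @return A tibble, one row per project: `project_id`, `qualifies`,
#'   `n_observers`, `n_identifiers`, `duration_hours`,
#'   `n_obs_outside_window`, and `failed_criteria` (a list-column of
#'   criterion names, empty iff `qualifies`).
#' @export
qualify_projects <- function(projects, observations, identifications,
                             criteria = qualification_criteria()) {
  assert_columns(projects, c("project_id", "start", "end"), "projects")
  assert_columns(observations, c("observation_id", "observer_id",
                                 "observed_date"), "observations")
  assert_columns(identifications, c("observation_id", "identifier_id"),
                 "identifications")
  stopifnot(inherits(criteria, "qualification_criteria"))

  duration <- as.numeric(difftime(projects$end, projects$start,
                                  units = "hours"))
  rows <- purrr::map(seq_len(nrow(projects)), function(i) {
    p <- projects[i, ]
    cnt <- project_counts(p, observations, identifications)
    failed <- character()
    if (cnt$n_observers < criteria$min_observers) {
      failed <- c(failed, "min_observers")
    }
    if (cnt$n_identifiers < criteria$min_identifiers) {
      failed <- c(failed, "min_identifiers")
    }
    if (duration[i] > criteria$max_duration_hours) {
      failed <- c(failed, "max_duration_hours")
    }
    tibble::tibble(project_id = p$project_id,
                   qualifies = length(failed) == 0,
                   n_observers = cnt$n_observers,
                   n_identifiers = cnt$n_identifiers,
                   duration_hours = duration[i],
                   n_obs_outside_window = cnt$n_obs_outside_window,
                   failed_criteria = list(failed))
  })
  dplyr::bind_rows(rows)
}

#' Per-project summary statistics
#'
#' Counts, for each project-event, the observations made within the event
#' window, the distinct (non-missing) taxa among them, the distinct observers
#' and identifiers, and the event's duration and start timing. These are the
#' per-event analogues of corpus figures such as "the average bioblitz
#' yielded N observations of S species".
#'
#' @inheritParams qualify_projects
#' @return A tibble, one row per project: `project_id`, `n_observations`,
#'   `n_taxa`, `n_observers`, `n_identifiers`, `duration_hours`,
#'   `start_weekday` (factor, Monday first), `start_month` (factor).
#' @export
summarize_projects <- function(projects, observations, identifications) {
  assert_columns(projects, c("project_id", "start", "end"), "projects")
  rows <- purrr::map(seq_len(nrow(projects)), function(i) {
    p <- projects[i, ]
    cnt <- project_counts(p, observations, identifications)
    taxa <- if ("taxon" %in% names(cnt$member)) {
      dplyr::n_distinct(cnt$member$taxon[!is.na(cnt$member$taxon)])
    } else 0L
    tibble::tibble(
      project_id = p$project_id,
      n_observations = cnt$n_observations,
      n_taxa = as.integer(taxa),
      n_observers = cnt$n_observers,
      n_identifiers = cnt$n_identifiers,
      duration_hours = as.numeric(difftime(p$end, p$start, units = "hours")),
      start_weekday = weekday_of(as.Date(p$start)),
      start_month = month_of(as.Date(p$start))
    )
  })
  dplyr::bind_rows(rows)
}

#' Timing distributions of event starts
#'
#' Tabulates on which weekday and in which month events start — bioblitzes
#' cluster on weekends (Saturdays especially) and in spring/autumn months.
#'
#' @param projects Project table with a `start` column.
#' @return A list of two tibbles: `weekday` (`weekday`, `n`; all seven
#'   levels, Monday first) and `month` (`month`, `n`; all twelve levels).
#'   Each `n` column sums to the number of projects.
#' @export
timing_histograms <- function(projects) {
  assert_columns(projects, "start", "projects")
  if (nrow(projects) == 0) {
    abort_bioblitzr("timing_histograms() needs at least one project",
                    class = "bioblitzr_input_error")
  }
  start_date <- as.Date(projects$start)
  wd <- weekday_of(start_date)
  mo <- month_of(start_date)
  list(
    weekday = tibble::tibble(weekday = factor(.weekday_levels,
                                              levels = .weekday_levels),
                             n = as.integer(table(wd))),
    month = tibble::tibble(month = factor(.month_levels,
                                          levels = .month_levels),
                           n = as.integer(table(mo)))
  )
}

#' Word frequencies over project descriptions
#'
#' Tokenizes free-text event descriptions (the material behind word clouds of
#' how bioblitzes are promoted): lowercases, strips punctuation, drops
#' stopwords and short tokens, and counts the rest.
#'
#' @param descriptions Character vector of descriptions (`NA`s ignored).
#' @param stopwords Character vector of words to drop (compared lowercase).
#' @param min_length Minimum token length retained (default 3).
#' @return A tibble (`word`, `n`) sorted by decreasing `n` then word; `n`
#'   sums to the number of retained tokens.
#' @export
word_frequencies <- function(descriptions, stopwords = character(),
                             min_length = 3L) {
  descriptions <- descriptions[!is.na(descriptions)]
  if (length(descriptions) == 0) {
    return(tibble::tibble(word = character(), n = integer()))
  }
  tokens <- descriptions |>
    stringr::str_to_lower() |>
    stringr::str_replace_all("[^[:alnum:][:space:]]", " ") |>
    stringr::str_split("[[:space:]]+") |>
    unlist()
  tokens <- tokens[nchar(tokens) >= min_length &
                     !(tokens %in% stringr::str_to_lower(stopwords))]
  if (length(tokens) == 0) {
    return(tibble::tibble(word = character(), n = integer()))
  }
  tab <- table(tokens)
  out <- tibble::tibble(word = names(tab), n = as.integer(tab))
  dplyr::arrange(out, dplyr::desc(.data$n), .data$word)
}
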