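#' Weekly devoted days relative to an anchor date
#'
#' The engagement metric is *weekly devoted days*: the number of distinct
#' calendar days in a 7-day block on which a user recorded at least one
#' observation (0-7). Blocks are anchored to the end of an event: post-event
#' week `w` (w >= 1) covers days `anchor + 1 + 7(w-1)` through `anchor + 7w`,
#' and pre-event week `-w` covers the block exactly 364 days earlier than
#' week `w`. The 364-day (52 whole weeks) offset keeps paired weeks aligned
#' on the same weekday, which is what lets the paired design cancel weekday
#' and seasonal effects.
#'
#' Multiple observations on one day count once; observations from all
#' projects count (platform-wide activity).
#'
#' @param observations Observation table with `observer_id` and
#'   `observed_date` columns (any number of users).
#' @param anchor Anchor `Date` (typically the event's end date).
#' @param horizon_weeks Number of weeks on each side (default 50).
#' @param exclude Optional `Date` vector of days to ignore entirely (e.g.
#'   the event days themselves).
#' @return A tibble (`user_id`, `week_index`, `devoted_days`) covering every
#'   user in the input and every week in `-horizon_weeks..-1, 1..horizon_weeks`
#'   (zeros where the user was inactive).
#' @export
weekly_devoted_days <- function(observations, anchor, horizon_weeks = 50L,
                                exclude = NULL) {
  assert_columns(observations, c("observer_id", "observed_date"),
                 "observations")
  anchor <- as.Date(anchor)
  stopifnot(!is.na(anchor), horizon_weeks >= 1)
  horizon_weeks <- as.integer(horizon_weeks)

  days <- dplyr::distinct(observations, user_id = .data$observer_id,
                          date = .data$observed_date)
  if (!is.null(exclude)) {
    days <- days[!(days$date %in% as.Date(exclude)), , drop = FALSE]
  }
  users <- unique(observations$observer_id)
  grid <- tidyr::expand_grid(
    user_id = users,
    week_index = c(-(horizon_weeks:1), 1:horizon_weeks)
  )
  if (nrow(days) == 0) {
    return(dplyr::mutate(grid, devoted_days = 0L))
  }

  offset <- as.integer(days$date - anchor)
  post_w <- ifelse(offset >= 1, (offset + 6L) %/% 7L, NA_integer_)
  pre_off <- offset + 364L
  pre_w <- ifelse(offset < 1 & pre_off >= 1, (pre_off + 6L) %/% 7L,
                  NA_integer_)
  days$week_index <- dplyr::case_when(
    !is.na(post_w) & post_w <= horizon_weeks ~ post_w,
    !is.na(pre_w) & pre_w <= horizon_weeks ~ -pre_w,
    TRUE ~ NA_integer_
  )
  counts <- days |>
    dplyr::filter(!is.na(.data$week_index)) |>
    dplyr::count(.data$user_id, .data$week_index, name = "devoted_days")
  grid |>
    dplyr::left_join(counts, by = c("user_id", "week_index")) |>
    dplyr::mutate(devoted_days = as.integer(
      tidyr::replace_na(.data$devoted_days, 0L))) |>
    dplyr::arrange(.data$user_id, .data$week_index)
}

#' Classify event participants by their activity around the event
#'
#' Participants (users with at least one in-event record of the project) fall
#' into four exhaustive, mutually exclusive categories based on platform-wide
#' activity outside the event window: `only_during` (no activity before or
#' after), `lapsed` (active before, not after), `continuing_new` (no prior
#' activity, active after) and `continuing_veteran` (active both before and
#' after). "Before" means any observation in the `window_days` days ending
#' the day before the event starts; "after" any observation in the
#' `window_days` days starting the day after it ends. Event days themselves
#' establish participation only, never continuation.
#'
#' @param observations Observation table (platform-wide, all users'
#'   records).
#' @param project One-row project table.
#' @param window_days Look-back/look-ahead window in days (default 364, i.e.
#'   52 whole weeks).
#' @return A tibble (`user_id`, `project_id`, `category`) with one row per
#'   participant; `category` is a factor with the four levels above.
#' @export
categorize_participants <- function(observations, project,
                                    window_days = 364L) {
  assert_columns(observations, c("observer_id", "observed_date"),
                 "observations")
  stopifnot(nrow(project) == 1)
  d0 <- as.Date(project$start)
  d1 <- as.Date(project$end)
  participants <- unique(
    observations$observer_id[member_mask(observations, project$project_id,
                                         project$start, project$end)])
  if (length(participants) == 0) {
    abort_bioblitzr(
      sprintf("project %s has no in-event observations; no participants to categorize",
              project$project_id),
      class = "bioblitzr_precondition_error")
  }
  obs <- observations[observations$observer_id %in% participants, ,
                      drop = FALSE]
  act <- obs |>
    dplyr::group_by(user_id = .data$observer_id) |>
    dplyr::summarise(
      prior = any(.data$observed_date >= d0 - window_days &
                    .data$observed_date <= d0 - 1),
      post = any(.data$observed_date >= d1 + 1 &
                   .data$observed_date <= d1 + window_days),
      .groups = "drop")
  levels <- c("only_during", "lapsed", "continuing_new",
              "continuing_veteran")
  act |>
    dplyr::mutate(
      project_id = project$project_id,
      category = factor(dplyr::case_when(
        !.data$prior & !.data$post ~ "only_during",
        .data$prior & !.data$post ~ "lapsed",
        !.data$prior & .data$post ~ "continuing_new",
        TRUE ~ "continuing_veteran"
      ), levels = levels)) |>
    dplyr::select("user_id", "project_id", "category")
}

#' Seasonality-paired before/after activity differences
#'
#' For each continuing participant of an event, compares weekly devoted days
#' in post-event week `t` (t = 1..`weeks`) with the weekday-aligned week
#' exactly 364 days earlier: `diff = devoted_days(week t) -
#' devoted_days(week -t)`. The pairing cancels seasonal variation in
#' recording (species detectability varies through the year) and weekday
#' effects. Only continuing participants enter the panel — the boost is
#' defined conditional on continued platform use. Event days are excluded
#' from both blocks so the boost estimate cannot absorb event-day activity.
#'
#' With the default 50-week horizon a 2-week guard band is left at the year
#' boundary. Each `diff` lies in \[-7, 7\].
#'
#' @inheritParams categorize_participants
#' @param weeks Number of post-event weeks (default 50).
#' @param coverage Optional length-2 `Date` vector giving the span of the
#'   log's valid coverage; weeks whose pre or post block falls partly outside
#'   it are reported as missing (`NA`), not zero.
#' @return A tibble (`user_id`, `project_id`, `week_after`, `diff`).
#' @export
paired_differences <- function(observations, project, weeks = 50L,
                               coverage = NULL) {
  stopifnot(nrow(project) == 1)
  weeks <- as.integer(weeks)
  cats <- categorize_participants(observations, project,
                                  window_days = 7L * weeks + 14L)
  keep <- cats$user_id[cats$category %in% c("continuing_new",
                                            "continuing_veteran")]
  if (length(keep) == 0) {
    return(tibble::tibble(user_id = character(),
                          project_id = character(),
                          week_after = integer(), diff = integer()))
  }
  d1 <- as.Date(project$end)
  event_days <- seq(as.Date(project$start), d1, by = "day")
  obs <- observations[observations$observer_id %in% keep, , drop = FALSE]
  wdd <- weekly_devoted_days(obs, anchor = d1, horizon_weeks = weeks,
                             exclude = event_days)
  wide <- wdd |>
    dplyr::mutate(side = ifelse(.data$week_index > 0, "post", "pre"),
                  week_after = abs(.data$week_index)) |>
    tidyr::pivot_wider(id_cols = c("user_id", "week_after"),
                       names_from = "side",
                       values_from = "devoted_days") |>
    dplyr::mutate(diff = .data$post - .data$pre,
                  project_id = project$project_id)
  if (!is.null(coverage)) {
    coverage <- as.Date(coverage)
    stopifnot(length(coverage) == 2)
    w <- wide$week_after
    post_lo <- d1 + 1 + 7 * (w - 1)
    post_hi <- d1 + 7 * w
    ok <- post_lo - 364 >= coverage[1] & post_hi <= coverage[2]
    wide$diff[!ok] <- NA_integer_
  }
  wide |>
    dplyr::select("user_id", "project_id", "week_after", "diff") |>
    dplyr::arrange(.data$user_id, .data$week_after)
}

#' Paired-difference panel over many events
#'
#' Applies [paired_differences()] to every project and stacks the results
#' into the panel that [fit_decay()] consumes.
#'
#' @param observations Observation table (platform-wide).
#' @param projects Project table (one row per event).
#' @param weeks Number of post-event weeks per event (default 50).
#' @param coverage Optional coverage span passed through.
#' @return A tibble (`user_id`, `project_id`, `week_after`, `diff`).
#' @export
build_panel <- function(observations, projects, weeks = 50L,
                        coverage = NULL) {
  purrr::map(seq_len(nrow(projects)), function(i) {
    tryCatch(
      paired_differences(observations, projects[i, ], weeks = weeks,
                         coverage = coverage),
      bioblitzr_precondition_error = function(e) NULL)
  }) |>
    dplyr::bind_rows()
}
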