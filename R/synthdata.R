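#' Parameters of the synthetic event-log generator
#'
#' Bundles every knob of [generate_bioblitz_data()] with defaults that encode
#' the study conditions the engagement analysis assumes: a corpus of 100
#' events with ~34 participants each; a participant mix of 77% active only
#' during the event, 1.5% lapsing afterwards, and 21.5% continuing (split
#' 11.6% new / 9.9% veteran — the split follows from the relative sample
#' sizes of the all-user and new-user fits, 777 vs ~419 continuing users); a
#' post-event boost to weekly devoted days of `a = 0.4` days/week decaying at
#' `b = 0.054` per week (so the cumulative boost integrates to 7.4 days and
#' the half-life is 12.8 weeks); lognormal between-project heterogeneity on
#' the boost height; and a sinusoidal seasonal modulation of baseline
#' activity peaking in spring.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_projects Number of events to simulate.
#' @param users_per_project Mean participants per event (Poisson, min 1).
#' @param category_mix Named fractions (`only_during`, `lapsed`,
#'   `continuing_new`, `continuing_veteran`) summing to 1.
#' @param baseline_rate Mean weekly devoted days of a veteran's baseline
#'   (days/week; per-user lognormal variation around it).
#' @param seasonal_amplitude Relative amplitude of the seasonal modulation
#'   of baseline activity (0-1).
#' @param boost_a Initial post-event boost, days/week.
#' @param boost_b Decay constant of the boost, per week (> 0).
#' @param project_sd Log-scale SD of the per-project multiplier on
#'   `boost_a` (mean-1 lognormal).
#' @param event_duration_hours Event duration in hours.
#' @param obs_per_devoted_day Mean observations per active day (>= 1).
#' @param n_external_identifiers Size of the platform-wide pool of
#'   identifiers who did not attend any event.
#' @param id_rate Mean identifications per event record (Poisson).
#' @param weekday_weights Length-7 start-weekday weights (Monday first);
#'   default is Saturday-heavy, matching how events cluster on weekends.
#' @param month_weights Length-12 start-month weights; default peaks in
#'   April and September.
#' @param horizon_weeks Weeks of pre/post activity generated per user
#'   (default 50).
#' @return A `synth_params` object (a validated list).
#' @export
synth_params <- function(seed = 1L, n_projects = 100L,
                         users_per_project = 34,
                         category_mix = c(only_during = 0.77,
                                          lapsed = 0.015,
                                          continuing_new = 0.116,
                                          continuing_veteran = 0.099),
                         baseline_rate = 1, seasonal_amplitude = 0.3,
                         boost_a = 0.4, boost_b = 0.054, project_sd = 0.3,
                         event_duration_hours = 24,
                         obs_per_devoted_day = 1.5,
                         n_external_identifiers = 30L, id_rate = 1.2,
                         weekday_weights = NULL, month_weights = NULL,
                         horizon_weeks = 50L) {
  needed <- c("only_during", "lapsed", "continuing_new",
              "continuing_veteran")
  if (!setequal(names(category_mix), needed)) {
    abort_bioblitzr(
      sprintf("category_mix must be named fractions for: %s",
              paste(needed, collapse = ", ")),
      class = "bioblitzr_parameter_error")
  }
  category_mix <- category_mix[needed]
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    abort_bioblitzr("category_mix must be non-negative and sum to 1",
                    class = "bioblitzr_parameter_error")
  }
  if (boost_b <= 0) {
    abort_bioblitzr("boost_b must be positive",
                    class = "bioblitzr_parameter_error")
  }
  stopifnot(n_projects >= 1, users_per_project >= 0, baseline_rate >= 0,
            seasonal_amplitude >= 0, seasonal_amplitude <= 1, boost_a >= 0,
            project_sd >= 0, event_duration_hours > 0,
            obs_per_devoted_day >= 1, n_external_identifiers >= 0,
            id_rate >= 0, horizon_weeks >= 1)
  weekday_weights <- weekday_weights %||%
    c(0.08, 0.08, 0.08, 0.08, 0.12, 0.40, 0.16)
  month_weights <- month_weights %||%
    c(0.04, 0.04, 0.06, 0.20, 0.10, 0.06, 0.05, 0.06, 0.20, 0.10, 0.05,
      0.04)
  stopifnot(length(weekday_weights) == 7, length(month_weights) == 12)
  structure(
    list(seed = as.integer(seed), n_projects = as.integer(n_projects),
         users_per_project = users_per_project,
         category_mix = category_mix, baseline_rate = baseline_rate,
         seasonal_amplitude = seasonal_amplitude, boost_a = boost_a,
         boost_b = boost_b, project_sd = project_sd,
         event_duration_hours = event_duration_hours,
         obs_per_devoted_day = obs_per_devoted_day,
         n_external_identifiers = as.integer(n_external_identifiers),
         id_rate = id_rate, weekday_weights = weekday_weights,
         month_weights = month_weights,
         horizon_weeks = as.integer(horizon_weeks)),
    class = "synth_params"
  )
}

# Seasonal modulation of baseline activity by week of year (1..53):
# peaks around week 15 (mid-April) with the default phase of 2.
season_factor <- function(dates, amplitude) {
  woy <- ((as.integer(strftime(dates, "%j")) - 1) %/% 7) + 1
  pmax(1 + amplitude * sin(2 * pi * (woy - 2) / 52), 0)
}

# Event start timestamps: weighted month and weekday, 09:00 start.
gen_project_table <- function(p) {
  n <- p$n_projects
  year <- sample(2016:2019, n, replace = TRUE)
  month <- sample(1:12, n, replace = TRUE, prob = p$month_weights)
  day <- sample(1:28, n, replace = TRUE)
  base <- as.Date(sprintf("%d-%02d-%02d", year, month, day))
  target_wd <- sample(1:7, n, replace = TRUE, prob = p$weekday_weights)
  shift <- (target_wd - as.integer(strftime(base, "%u"))) %% 7
  start_date <- base + shift
  start <- as.POSIXct(start_date, tz = "UTC") + 9 * 3600
  end <- start + p$event_duration_hours * 3600
  tibble::tibble(
    project_id = sprintf("P%04d", seq_len(n)),
    title = sprintf("BioBlitz %04d", seq_len(n)),
    description = sprintf(
      "Join the bioblitz challenge: find and record as many species as possible in park area %04d with the community.",
      seq_len(n)),
    start = start, end = end,
    place_label = sprintf("Park %04d", seq_len(n)))
}

gen_user_table <- function(p, projects) {
  n_u <- pmax(stats::rpois(nrow(projects), p$users_per_project), 1L)
  users <- tibble::tibble(
    project_id = rep(projects$project_id, n_u))
  users$user_id <- sprintf("U%06d", seq_len(nrow(users)))
  users$category <- factor(
    sample(names(p$category_mix), nrow(users), replace = TRUE,
           prob = p$category_mix),
    levels = names(p$category_mix))
  users$baseline <- if (p$baseline_rate > 0) {
    p$baseline_rate * stats::rlnorm(nrow(users), meanlog = -0.125,
                                    sdlog = 0.5)
  } else rep(0, nrow(users))
  users
}

# Day-level activity realization for a week grid carrying a weekly
# expectation mu (devoted days/week): each of the 7 days of the block is
# active independently with probability min(mu/7, 1), so devoted days per
# week are Binomial(7, mu/7) with day identities uniform within the block.
realize_days <- function(grid) {
  if (nrow(grid) == 0) {
    return(tibble::tibble(user_id = character(), project_id = character(),
                          date = as.Date(character())))
  }
  days <- tidyr::expand_grid(i = seq_len(nrow(grid)), offset = 0:6)
  days$p <- pmin(grid$mu[days$i] / 7, 1)
  days$active <- stats::rbinom(nrow(days), 1, days$p) == 1
  days <- days[days$active, , drop = FALSE]
  tibble::tibble(user_id = grid$user_id[days$i],
                 project_id = NA_character_,
                 date = grid$block_start[days$i] + days$offset)
}

#' Generate synthetic bioblitz event logs
#'
#' Simulates a corpus of events with the statistical structure the
#' engagement analysis assumes, yielding the three event-log tables that the
#' rest of the package consumes plus a truth table of every generating
#' quantity.
#'
#' Per event, participants are drawn with the configured category mix. Every
#' participant records on at least one event day. Users with pre-event
#' history (`lapsed`, `continuing_veteran`) get a seasonal baseline:
#' in the 7-day block paired with post-event week `w` (exactly 364 days
#' earlier), each day is active with probability
#' `baseline_u * season(week) / 7`, so weekly devoted days are
#' Binomial(7, p). Continuing users get post-event weeks with expectation
#' `base * season + m_p * boost_a * exp(-boost_b * w)` (clamped to \[0, 7\]),
#' where `m_p` is the project's lognormal boost multiplier and `base` is the
#' user baseline for veterans and 0 for new users — a new continuer's
#' activity is the event-attributable boost itself. Identifications are
#' assigned to event records from a pool of external identifiers plus the
#' event's own participants.
#'
#' The generator is fully reproducible: identical parameters (including the
#' seed) give identical output, and the global RNG state is left untouched.
#'
#' @param params A [synth_params()] object.
#' @return A list of class `bioblitz_sim`: `projects`, `observations`,
#'   `identifications` (all readable/writable by the event-log module) and
#'   `truth` (list with `users`, `projects` and the `params`).
#' @export
generate_bioblitz_data <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_impl(params))
}

generate_impl <- function(p) {
  projects <- gen_project_table(p)
  projects$m_p <- stats::rlnorm(nrow(projects),
                                meanlog = -p$project_sd^2 / 2,
                                sdlog = p$project_sd)
  users <- gen_user_table(p, projects)
  users <- dplyr::left_join(
    users, dplyr::select(projects, "project_id", "start", "end", "m_p"),
    by = "project_id")
  users$start_date <- as.Date(users$start)
  users$end_date <- as.Date(users$end)

  # --- event-day records: each event day active w.p. 0.7, at least one ---
  event_span <- purrr::map2(users$start_date, users$end_date, seq,
                            by = "day")
  n_days <- lengths(event_span)
  ev <- tibble::tibble(
    user_id = rep(users$user_id, n_days),
    project_id = rep(users$project_id, n_days),
    date = as.Date(unlist(event_span), origin = "1970-01-01"))
  ev$active <- stats::rbinom(nrow(ev), 1, 0.7) == 1
  got_one <- unique(ev$user_id[ev$active])
  none <- ev$user_id %in% setdiff(users$user_id, got_one)
  # users with no active event day: activate their first event day
  ev$active[none & !duplicated(ev$user_id)] <- TRUE
  event_days <- ev[ev$active, c("user_id", "project_id", "date")]

  # --- weekly out-of-event activity ---
  H <- p$horizon_weeks
  pre_users <- users[users$category %in% c("lapsed", "continuing_veteran"),
                     , drop = FALSE]
  post_users <- users[users$category %in% c("continuing_new",
                                            "continuing_veteran"), ,
                      drop = FALSE]

  pre_grid <- tidyr::expand_grid(i = seq_len(nrow(pre_users)), w = 1:H)
  pre_grid <- tibble::tibble(
    user_id = pre_users$user_id[pre_grid$i],
    block_start = pre_users$end_date[pre_grid$i] + 1 +
      7 * (pre_grid$w - 1) - 364,
    mu = pre_users$baseline[pre_grid$i])
  pre_grid$mu <- pre_grid$mu *
    season_factor(pre_grid$block_start, p$seasonal_amplitude)

  post_grid <- tidyr::expand_grid(i = seq_len(nrow(post_users)), w = 1:H)
  base_post <- ifelse(post_users$category == "continuing_veteran",
                      post_users$baseline, 0)
  post_grid <- tibble::tibble(
    user_id = post_users$user_id[post_grid$i],
    block_start = post_users$end_date[post_grid$i] + 1 +
      7 * (post_grid$w - 1),
    mu = base_post[post_grid$i] *
      season_factor(post_users$end_date[post_grid$i] + 1 +
                      7 * (post_grid$w - 1), p$seasonal_amplitude) +
      post_users$m_p[post_grid$i] * p$boost_a *
      exp(-p$boost_b * post_grid$w))
  post_grid$mu <- pmin(post_grid$mu, 7)

  active_days <- dplyr::bind_rows(
    event_days,
    realize_days(pre_grid),
    realize_days(post_grid))

  # --- observations: >= 1 per active day ---
  n_obs <- 1L + stats::rpois(nrow(active_days),
                             max(p$obs_per_devoted_day - 1, 0))
  obs <- active_days[rep(seq_len(nrow(active_days)), n_obs), , drop = FALSE]
  obs <- dplyr::arrange(obs, .data$user_id, .data$date)
  centers <- tibble::tibble(project_id = projects$project_id,
                            lat0 = stats::runif(nrow(projects), -55, 65),
                            lon0 = stats::runif(nrow(projects), -170, 170))
  user_center <- dplyr::left_join(
    dplyr::select(users, "user_id", "project_id"), centers,
    by = "project_id")
  obs <- dplyr::left_join(obs,
                          dplyr::select(user_center, "user_id", "lat0",
                                        "lon0"),
                          by = "user_id")
  observations <- tibble::tibble(
    observation_id = sprintf("O%07d", seq_len(nrow(obs))),
    observer_id = obs$user_id,
    observed_date = obs$date,
    project_id = obs$project_id,
    taxon = sample(sprintf("Species %03d", 1:300), nrow(obs),
                   replace = TRUE),
    latitude = round(obs$lat0 + stats::runif(nrow(obs), -0.05, 0.05), 5),
    longitude = round(obs$lon0 + stats::runif(nrow(obs), -0.05, 0.05), 5))

  # --- identifications on event records ---
  ev_obs <- observations[!is.na(observations$project_id), , drop = FALSE]
  n_ids <- stats::rpois(nrow(ev_obs), p$id_rate)
  idx <- rep(seq_len(nrow(ev_obs)), n_ids)
  externals <- if (p$n_external_identifiers > 0) {
    sprintf("EXT%04d", seq_len(p$n_external_identifiers))
  } else character()
  pools <- split(users$user_id, users$project_id)
  id_project <- ev_obs$project_id[idx]
  identifier <- character(length(idx))
  for (pid in unique(id_project)) {
    sel <- id_project == pid
    pool <- c(pools[[pid]], externals)
    identifier[sel] <- sample(pool, sum(sel), replace = TRUE)
  }
  identifications <- tibble::tibble(
    identification_id = sprintf("I%07d", seq_along(idx)),
    observation_id = ev_obs$observation_id[idx],
    identifier_id = identifier,
    identified_date = ev_obs$observed_date[idx] +
      sample(0:14, length(idx), replace = TRUE))

  truth_users <- dplyr::select(users, "user_id", "project_id", "category",
                               "baseline")
  truth_projects <- projects |>
    dplyr::mutate(boost_a_p = .data$m_p * p$boost_a,
                  boost_b = p$boost_b) |>
    dplyr::select("project_id", "m_p", "boost_a_p", "boost_b")
  projects$m_p <- NULL

  structure(
    list(projects = projects, observations = observations,
         identifications = identifications,
         truth = list(users = truth_users, projects = truth_projects,
                      params = p)),
    class = "bioblitz_sim"
  )
}

#' Generate a paired-difference panel directly
#'
#' Samples the weekly-level model of [generate_bioblitz_data()] without
#' materializing day-level event logs: for every continuing user, post-event
#' and paired pre-event weekly devoted days are drawn as Binomial(7, mu/7)
#' with the same expectations as the full generator, and their difference is
#' returned. Distributionally identical to running [build_panel()] on the
#' full generator output, and much faster — intended for repeated
#' parameter-recovery simulations.
#'
#' @param params A [synth_params()] object.
#' @return A list: `panel` (tibble `user_id`, `project_id`, `week_after`,
#'   `diff`) and `truth` (as in [generate_bioblitz_data()], restricted to
#'   continuing users).
#' @export
generate_panel <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_panel_impl(params))
}

generate_panel_impl <- function(p) {
  projects <- gen_project_table(p)
  projects$m_p <- stats::rlnorm(nrow(projects),
                                meanlog = -p$project_sd^2 / 2,
                                sdlog = p$project_sd)
  users <- gen_user_table(p, projects)
  users <- dplyr::left_join(
    users, dplyr::select(projects, "project_id", "end", "m_p"),
    by = "project_id")
  cont <- users[users$category %in% c("continuing_new",
                                      "continuing_veteran"), , drop = FALSE]
  cont$end_date <- as.Date(cont$end)
  H <- p$horizon_weeks
  g <- tidyr::expand_grid(i = seq_len(nrow(cont)), w = 1:H)
  post_start <- cont$end_date[g$i] + 1 + 7 * (g$w - 1)
  base <- ifelse(cont$category[g$i] == "continuing_veteran",
                 cont$baseline[g$i], 0)
  mu_pre <- base * season_factor(post_start - 364, p$seasonal_amplitude)
  mu_post <- pmin(base * season_factor(post_start, p$seasonal_amplitude) +
                    cont$m_p[g$i] * p$boost_a * exp(-p$boost_b * g$w), 7)
  dd_post <- stats::rbinom(nrow(g), 7, pmin(mu_post / 7, 1))
  dd_pre <- stats::rbinom(nrow(g), 7, pmin(mu_pre / 7, 1))
  panel <- tibble::tibble(
    user_id = cont$user_id[g$i],
    project_id = cont$project_id[g$i],
    week_after = g$w,
    diff = as.integer(dd_post - dd_pre)) |>
    dplyr::arrange(.data$project_id, .data$user_id, .data$week_after)
  truth_projects <- projects |>
    dplyr::mutate(boost_a_p = .data$m_p * p$boost_a, boost_b = p$boost_b) |>
    dplyr::select("project_id", "m_p", "boost_a_p", "boost_b")
  list(panel = panel,
       truth = list(users = dplyr::select(cont, "user_id", "project_id",
                                          "category", "baseline"),
                    projects = truth_projects, params = p))
}

#' Generate a synthetic multi-rater rating matrix
#'
#' Rater 1 scores each (item, aim) cell uniformly on 1..5; every other rater
#' copies rater 1 and independently resamples each cell (uniformly on 1..5,
#' so possibly to the same score) with probability `disagreement_rate`.
#' Under this scheme two raters agree on a cell with probability
#' `1 - 0.8 * disagreement_rate`, which makes the expected Jaccard
#' coefficient available in closed form for checking.
#'
#' @param seed Integer seed.
#' @param n_items Number of rated items (publications).
#' @param n_raters Number of raters (>= 1).
#' @param disagreement_rate Per-cell resampling probability (0-1).
#' @return A long-format rating tibble (`item_id`, `rater_id`, `aim`,
#'   `score`) accepted by [rank_tally()] and [jaccard_agreement()].
#' @export
generate_ratings <- function(seed = 1L, n_items = 59L, n_raters = 2L,
                             disagreement_rate = 0.2) {
  stopifnot(n_raters >= 1, n_items >= 1,
            disagreement_rate >= 0, disagreement_rate <= 1)
  withr::with_seed(seed, {
    base <- tidyr::expand_grid(item_id = sprintf("pub%03d",
                                                 seq_len(n_items)),
                               aim = bioblitz_aims())
    base$score <- sample(1:5, nrow(base), replace = TRUE)
    out <- purrr::map(seq_len(n_raters), function(r) {
      d <- base
      d$rater_id <- sprintf("R%d", r)
      if (r > 1) {
        flip <- stats::runif(nrow(d)) < disagreement_rate
        d$score[flip] <- sample(1:5, sum(flip), replace = TRUE)
      }
      d
    }) |>
      dplyr::bind_rows()
    dplyr::select(out, "item_id", "rater_id", "aim", "score")
  })
}

#' Write a simulated corpus to CSV files
#'
#' Writes the three event-log tables plus the truth tables of a simulation
#' to a directory, in the canonical CSV form the readers accept.
#'
#' @param sim A `bioblitz_sim` from [generate_bioblitz_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "bioblitz_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             identifications = file.path(dir, "identifications.csv"),
             projects = file.path(dir, "projects.csv"),
             truth_users = file.path(dir, "truth_users.csv"),
             truth_projects = file.path(dir, "truth_projects.csv"))
  write_observations(sim$observations, paths[["observations"]])
  write_identifications(sim$identifications, paths[["identifications"]])
  write_projects(sim$projects, paths[["projects"]])
  readr::write_csv(sim$truth$users, paths[["truth_users"]])
  readr::write_csv(sim$truth$projects, paths[["truth_projects"]])
  invisible(paths)
}
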