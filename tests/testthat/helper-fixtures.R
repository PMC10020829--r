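# Shared fixtures, built in code. The small simulated corpus is cached so
# several test files can reuse it without regenerating.
.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_bioblitz_data(
      synth_params(seed = 99, n_projects = 12, users_per_project = 20))
  }
  .fixture_cache$sim
}

# Hand-built observation table
make_obs <- function(ids, users, dates, project = NA_character_,
                     taxon = NA_character_) {
  tibble::tibble(observation_id = as.character(ids),
                 observer_id = as.character(users),
                 observed_date = as.Date(dates),
                 project_id = project, taxon = taxon)
}

make_ids <- function(ids, obs, users, dates = NA) {
  tibble::tibble(identification_id = as.character(ids),
                 observation_id = as.character(obs),
                 identifier_id = as.character(users),
                 identified_date = as.Date(dates))
}

make_project <- function(id = "P1", start = "2019-02-22 09:00:00",
                         end = "2019-02-23 09:00:00") {
  tibble::tibble(project_id = id, title = paste("BioBlitz", id),
                 start = as.POSIXct(start, tz = "UTC"),
                 end = as.POSIXct(end, tz = "UTC"))
}

# Independent brute-force recount of per-project qualification facts,
# written with base loops so it shares no code with the implementation.
brute_force_project_facts <- function(projects, observations,
                                      identifications) {
  out <- list()
  for (i in seq_len(nrow(projects))) {
    pid <- projects$project_id[i]
    d0 <- as.Date(projects$start[i])
    d1 <- as.Date(projects$end[i])
    members <- character()
    observers <- character()
    taxa <- character()
    for (j in seq_len(nrow(observations))) {
      if (!is.na(observations$project_id[j]) &&
          observations$project_id[j] == pid &&
          observations$observed_date[j] >= d0 &&
          observations$observed_date[j] <= d1) {
        members <- c(members, observations$observation_id[j])
        observers <- c(observers, observations$observer_id[j])
        if ("taxon" %in% names(observations) &&
            !is.na(observations$taxon[j])) {
          taxa <- c(taxa, observations$taxon[j])
        }
      }
    }
    identifiers <- character()
    for (j in seq_len(nrow(identifications))) {
      if (identifications$observation_id[j] %in% members) {
        identifiers <- c(identifiers, identifications$identifier_id[j])
      }
    }
    out[[i]] <- data.frame(
      project_id = pid,
      n_observations = length(members),
      n_taxa = length(unique(taxa)),
      n_observers = length(unique(observers)),
      n_identifiers = length(unique(identifiers)),
      duration_hours = as.numeric(difftime(projects$end[i],
                                           projects$start[i],
                                           units = "hours")))
  }
  do.call(rbind, out)
}

# Brute-force distinct-active-day count per 7-day block for one user.
brute_force_devoted_days <- function(dates, anchor, horizon) {
  dates <- unique(as.Date(dates))
  anchor <- as.Date(anchor)
  res <- list()
  for (w in 1:horizon) {
    lo <- anchor + 1 + 7 * (w - 1)
    hi <- anchor + 7 * w
    res[[length(res) + 1]] <- data.frame(
      week_index = w, devoted_days = sum(dates >= lo & dates <= hi))
    res[[length(res) + 1]] <- data.frame(
      week_index = -w,
      devoted_days = sum(dates >= lo - 364 & dates <= hi - 364))
  }
  df <- do.call(rbind, res)
  df[order(df$week_index), ]
}
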