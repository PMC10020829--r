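test_that("qualification applies the definitional thresholds exactly", {
  p <- make_project()
  obs <- make_obs(c("o1", "o2"), c("u1", "u2"),
                  c("2019-02-22", "2019-02-22"), project = "P1")
  ids <- make_ids("i1", "o1", "u3")
  q <- qualify_projects(p, obs, ids)
  expect_true(q$qualifies)
  expect_equal(q$failed_criteria[[1]], character(0))
  expect_equal(q$duration_hours, 24)

  # one observer only
  obs1 <- make_obs(c("o1", "o2"), c("u1", "u1"),
                   c("2019-02-22", "2019-02-22"), project = "P1")
  q1 <- qualify_projects(p, obs1, ids)
  expect_false(q1$qualifies)
  expect_equal(q1$failed_criteria[[1]], "min_observers")

  # no observations at all
  q0 <- qualify_projects(p, obs1[0, ], ids[0, ])
  expect_false(q0$qualifies)
  expect_true("min_observers" %in% q0$failed_criteria[[1]])
})

test_that("records outside the event window do not qualify a project", {
  p <- make_project()
  obs <- make_obs(c("o1", "o2"), c("u1", "u2"),
                  c("2019-02-22", "2019-06-01"), project = "P1")
  ids <- make_ids("i1", "o1", "u3")
  q <- qualify_projects(p, obs, ids)
  expect_false(q$qualifies)
  expect_equal(q$n_observers, 1)
  expect_equal(q$n_obs_outside_window, 1)
})

test_that("qualification matches a brute-force recount on a synthetic corpus", {
  sim <- small_sim()
  crit <- qualification_criteria(min_observers = 5, min_identifiers = 8,
                                 max_duration_hours = 72)
  q <- qualify_projects(sim$projects, sim$observations,
                        sim$identifications, crit)
  bf <- brute_force_project_facts(sim$projects, sim$observations,
                                  sim$identifications)
  expect_equal(q$n_observers, bf$n_observers)
  expect_equal(q$n_identifiers, bf$n_identifiers)
  bf_qualifies <- bf$n_observers >= 5 & bf$n_identifiers >= 8 &
    bf$duration_hours <= 72
  expect_equal(q$qualifies, bf_qualifies)
})

test_that("relaxing any criterion never shrinks the qualified set", {
  sim <- small_sim()
  base <- qualification_criteria(min_observers = 6, min_identifiers = 10,
                                 max_duration_hours = 20)
  qualified_under <- function(crit) {
    q <- qualify_projects(sim$projects, sim$observations,
                          sim$identifications, crit)
    q$project_id[q$qualifies]
  }
  q0 <- qualified_under(base)
  relaxed <- list(
    qualification_criteria(2, 10, 20),
    qualification_criteria(6, 1, 20),
    qualification_criteria(6, 10, 400),
    qualification_criteria(1, 0, 1000))
  for (crit in relaxed) {
    expect_true(all(q0 %in% qualified_under(crit)))
  }
})

test_that("project summaries count observations, taxa and people", {
  p <- make_project()
  obs <- make_obs(paste0("o", 1:5), c("u1", "u1", "u2", "u2", "u2"),
                  rep("2019-02-22", 5), project = "P1",
                  taxon = c("a", "b", "c", "a", "b"))
  s <- summarize_projects(p, obs, make_ids(character(), character(),
                                           character()))
  expect_equal(s$n_observations, 5)
  expect_equal(s$n_taxa, 3)
  expect_equal(s$n_observers, 2)
  expect_equal(s$start_weekday, factor("Friday", levels = levels(s$start_weekday)))
  expect_equal(as.character(s$start_month), "February")

  # all taxa missing
  obs$taxon <- NA_character_
  s0 <- summarize_projects(p, obs, make_ids(character(), character(),
                                            character()))
  expect_equal(s0$n_taxa, 0)
})

test_that("summaries equal a brute-force recount and ignore row order", {
  sim <- small_sim()
  s <- summarize_projects(sim$projects, sim$observations,
                          sim$identifications)
  bf <- brute_force_project_facts(sim$projects, sim$observations,
                                  sim$identifications)
  expect_equal(s$n_observations, bf$n_observations)
  expect_equal(s$n_taxa, bf$n_taxa)
  expect_equal(s$n_observers, bf$n_observers)
  expect_equal(s$n_identifiers, bf$n_identifiers)

  perm <- withr::with_seed(7, sample(nrow(sim$observations)))
  s2 <- summarize_projects(sim$projects, sim$observations[perm, ],
                           sim$identifications)
  expect_equal(s, s2)
})

test_that("timing histograms tally start weekdays and months", {
  p <- dplyr::bind_rows(
    make_project("P1", "2019-02-23 09:00:00", "2019-02-24 09:00:00"),
    make_project("P2", "2019-03-02 09:00:00", "2019-03-03 09:00:00"),
    make_project("P3", "2019-03-09 09:00:00", "2019-03-10 09:00:00"))
  th <- timing_histograms(p)
  expect_equal(th$weekday$n[th$weekday$weekday == "Saturday"], 3)
  expect_equal(sum(th$weekday$n), 3)
  expect_equal(sum(th$month$n), 3)
  expect_equal(th$month$n[th$month$month == "March"], 2)
  expect_error(timing_histograms(p[0, ]), class = "bioblitzr_input_error")
})

test_that("a Saturday-only generator yields a Saturday mode", {
  sim <- generate_bioblitz_data(synth_params(
    seed = 5, n_projects = 40, users_per_project = 2,
    weekday_weights = c(0, 0, 0, 0, 0, 1, 0)))
  th <- timing_histograms(sim$projects)
  expect_equal(th$weekday$n[th$weekday$weekday == "Saturday"], 40)
})

test_that("uniform random starts spread evenly across weekdays", {
  # 7000 uniform draws: each weekday count is Binomial(7000, 1/7),
  # mean 1000, SD sqrt(7000 * (1/7) * (6/7)) ~ 29.3; require within 5 SD
  sim <- generate_bioblitz_data(synth_params(
    seed = 11, n_projects = 7000, users_per_project = 0,
    weekday_weights = rep(1 / 7, 7), month_weights = rep(1 / 12, 12)))
  th <- timing_histograms(sim$projects)
  sd <- sqrt(7000 * (1 / 7) * (6 / 7))
  expect_true(all(abs(th$weekday$n - 1000) <= 5 * sd))
})

test_that("word frequencies lowercase, strip and filter tokens", {
  wf <- word_frequencies(c("BioBlitz fun", "fun for all"),
                         stopwords = c("for", "all"), min_length = 3)
  expect_equal(wf$n[wf$word == "bioblitz"], 1)
  expect_equal(wf$n[wf$word == "fun"], 2)
  expect_equal(sum(wf$n), 3)

  expect_equal(nrow(word_frequencies(character())), 0)
  expect_equal(nrow(word_frequencies(NA_character_)), 0)
})

test_that("word frequencies equal the known token multiset of a built corpus", {
  words <- c("wildlife", "park", "species", "community", "nature")
  counts <- c(5L, 3L, 7L, 2L, 4L)
  tokens <- withr::with_seed(3, sample(rep(words, counts)))
  docs <- split(tokens, rep(1:4, length.out = length(tokens))) |>
    vapply(paste, "", collapse = " ")
  wf <- word_frequencies(docs, min_length = 1)
  expect_equal(wf$n[match(words, wf$word)], counts)
  expect_equal(sum(wf$n), sum(counts))
})
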