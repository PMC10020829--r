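test_that("the generator is deterministic in its seed", {
  p <- synth_params(seed = 123, n_projects = 4, users_per_project = 10)
  s1 <- generate_bioblitz_data(p)
  s2 <- generate_bioblitz_data(p)
  expect_identical(s1$projects, s2$projects)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$identifications, s2$identifications)
  expect_identical(s1$truth$users, s2$truth$users)

  s3 <- generate_bioblitz_data(synth_params(seed = 124, n_projects = 4,
                                            users_per_project = 10))
  expect_false(identical(s1$observations, s3$observations))

  # the global RNG stream is left untouched
  withr::with_seed(1, {
    before <- .Random.seed
    generate_bioblitz_data(p)
    expect_identical(before, .Random.seed)
  })
})

test_that("parameter validation rejects impossible settings", {
  expect_error(synth_params(category_mix = c(only_during = 0.9,
                                             lapsed = 0.2,
                                             continuing_new = 0.1,
                                             continuing_veteran = -0.2)),
               class = "bioblitzr_parameter_error")
  expect_error(synth_params(category_mix = c(only_during = 1,
                                             lapsed = 0,
                                             wrong_name = 0,
                                             continuing_veteran = 0)),
               class = "bioblitzr_parameter_error")
  expect_error(synth_params(boost_b = 0),
               class = "bioblitzr_parameter_error")
})

test_that("generated logs are internally consistent", {
  sim <- small_sim()
  expect_equal(anyDuplicated(sim$observations$observation_id), 0)
  expect_equal(anyDuplicated(sim$identifications$identification_id), 0)
  expect_true(all(sim$identifications$observation_id %in%
                    sim$observations$observation_id))
  expect_true(all(sim$projects$end >= sim$projects$start))
  # every generated participant has at least one in-event record
  for (i in seq_len(nrow(sim$projects))) {
    ev <- event_observations(sim$observations, sim$projects[i, ])
    members <- sim$truth$users$user_id[
      sim$truth$users$project_id == sim$projects$project_id[i]]
    expect_setequal(unique(ev$observer_id), members)
  }
})

test_that("the pipeline recovers the generator's participant categories", {
  sim <- small_sim()
  cats <- dplyr::bind_rows(lapply(seq_len(nrow(sim$projects)), function(i) {
    categorize_participants(sim$observations, sim$projects[i, ])
  }))
  m <- dplyr::inner_join(cats, sim$truth$users,
                         by = c("user_id", "project_id"),
                         suffix = c("_got", "_true"))
  expect_equal(nrow(m), nrow(sim$truth$users))
  agreement <- mean(as.character(m$category_got) ==
                      as.character(m$category_true))
  expect_gt(agreement, 0.98)
})

test_that("a zero-boost generator yields a degenerate or near-zero fit", {
  gp <- generate_panel(synth_params(seed = 6, n_projects = 30,
                                    users_per_project = 30, boost_a = 0))
  # differences are Binomial(7,p) - Binomial(7,p): mean zero by design
  expect_lt(abs(mean(gp$panel$diff)), 0.02)
  fit <- fit_decay(gp$panel, seed = 6)
  a_eff <- if (fit$degenerate || !fit$converged) 0 else fit$a_hat
  expect_lt(abs(a_eff), 0.05)
})

test_that("generated category fractions match the configured mix", {
  sim <- generate_bioblitz_data(synth_params(seed = 31, n_projects = 59,
                                             users_per_project = 34))
  n <- nrow(sim$truth$users)
  mix <- c(only_during = 0.77, lapsed = 0.015, continuing_new = 0.116,
           continuing_veteran = 0.099)
  got <- table(sim$truth$users$category)[names(mix)] / n
  for (k in names(mix)) {
    sd <- sqrt(mix[[k]] * (1 - mix[[k]]) / n)
    expect_lt(abs(got[[k]] - mix[[k]]), 3 * sd + 1e-12)
  }
})

test_that("the fast panel generator matches the full log pipeline in law", {
  # same model, two sampling paths: week-1 mean difference ~ boost_a
  p <- synth_params(seed = 13, n_projects = 40, users_per_project = 30,
                    project_sd = 0)
  gp <- generate_panel(p)
  m1 <- mean(gp$panel$diff[gp$panel$week_after <= 2])
  sim <- generate_bioblitz_data(p)
  panel <- build_panel(sim$observations, sim$projects)
  m2 <- mean(panel$diff[panel$week_after <= 2])
  expect_lt(abs(m1 - m2), 0.1)
  expect_lt(abs(m1 - 0.4 * exp(-0.054 * 1.5)), 0.08)
})

test_that("simulated corpora write and re-read losslessly", {
  dir <- withr::local_tempdir()
  sim <- generate_bioblitz_data(synth_params(seed = 8, n_projects = 3,
                                             users_per_project = 8))
  paths <- write_sim(sim, dir)
  obs <- read_observations(paths[["observations"]])
  expect_equal(obs$observation_id, sim$observations$observation_id)
  expect_equal(obs$observed_date, sim$observations$observed_date)
  expect_equal(obs$latitude, sim$observations$latitude)
  ids <- read_identifications(paths[["identifications"]], observations = obs)
  expect_equal(nrow(ids), nrow(sim$identifications))
  expect_equal(nrow(rejections(ids)), 0)
  prj <- read_projects(paths[["projects"]])
  expect_equal(prj$start, sim$projects$start)
})
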