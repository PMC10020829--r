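test_that("devoted days count distinct active days per 7-day block", {
  anchor <- as.Date("2019-06-30")
  # 3 distinct days in week 1 (anchor+1 .. anchor+7), one day twice
  obs <- make_obs(paste0("o", 1:4), "u1",
                  anchor + c(1, 1, 3, 7))
  wdd <- weekly_devoted_days(obs, anchor, horizon_weeks = 2)
  expect_equal(wdd$devoted_days[wdd$week_index == 1], 3)
  expect_equal(wdd$devoted_days[wdd$week_index == 2], 0)
  expect_true(all(wdd$devoted_days[wdd$week_index < 0] == 0))
})

test_that("devoted days match a brute-force calendar recount on random logs", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      anchor <- as.Date("2018-01-01") + sample(0:700, 1)
      dates <- anchor + sample(-400:400, 120, replace = TRUE)
      obs <- make_obs(seq_along(dates), "u1", dates)
      wdd <- weekly_devoted_days(obs, anchor, horizon_weeks = 50)
      bf <- brute_force_devoted_days(dates, anchor, 50)
      expect_equal(wdd$devoted_days, bf$devoted_days)
      expect_true(all(wdd$devoted_days >= 0 & wdd$devoted_days <= 7))
    }
  })
})

test_that("paired weeks start on the same weekday", {
  anchor <- as.Date("2019-06-30")
  for (w in c(1, 17, 50)) {
    post_start <- anchor + 1 + 7 * (w - 1)
    pre_start <- post_start - 364
    expect_equal(strftime(post_start, "%u"), strftime(pre_start, "%u"))
  }
})

test_that("participants are classified by activity around the event", {
  p <- make_project()
  in_event <- as.Date("2019-02-22")

  cats <- categorize_participants(
    make_obs("o1", "u1", in_event, project = "P1"), p)
  expect_equal(as.character(cats$category), "only_during")

  obs <- dplyr::bind_rows(
    make_obs("o1", "u1", in_event, project = "P1"),
    make_obs("o2", "u1", in_event - 10),
    make_obs("o3", "u1", in_event + 10))
  cats <- categorize_participants(obs, p)
  expect_equal(as.character(cats$category), "continuing_veteran")

  obs_lapsed <- dplyr::bind_rows(
    make_obs("o1", "u1", in_event, project = "P1"),
    make_obs("o2", "u1", in_event - 10))
  expect_equal(as.character(categorize_participants(obs_lapsed, p)$category),
               "lapsed")

  obs_new <- dplyr::bind_rows(
    make_obs("o1", "u1", in_event, project = "P1"),
    make_obs("o3", "u1", in_event + 10))
  expect_equal(as.character(categorize_participants(obs_new, p)$category),
               "continuing_new")

  # no in-event observation -> precondition violation
  expect_error(
    categorize_participants(make_obs("o9", "u1", in_event + 10), p),
    class = "bioblitzr_precondition_error")
})

test_that("identical activity in both years gives all-zero differences", {
  p <- make_project()
  d1 <- as.Date(p$end)
  dates_post <- d1 + c(2, 9, 10, 30)
  obs <- dplyr::bind_rows(
    make_obs("e1", "u1", as.Date("2019-02-22"), project = "P1"),
    make_obs(paste0("a", 1:4), "u1", dates_post),
    make_obs(paste0("b", 1:4), "u1", dates_post - 364))
  pd <- paired_differences(obs, p)
  expect_equal(nrow(pd), 50)
  expect_true(all(pd$diff == 0))
})

test_that("the maximal difference of 7 is attained and bounds always hold", {
  p <- make_project()
  d1 <- as.Date(p$end)
  obs <- dplyr::bind_rows(
    make_obs("e1", "u1", as.Date("2019-02-22"), project = "P1"),
    make_obs(paste0("a", 1:7), "u1", d1 + 1:7))
  pd <- paired_differences(obs, p)
  expect_equal(pd$diff[pd$week_after == 1], 7)
  expect_true(all(pd$diff >= -7 & pd$diff <= 7))
})

test_that("differences reproduce a hand-built boost schedule", {
  p <- make_project()
  d1 <- as.Date(p$end)
  # post weeks 1..4 get 5, 3, 2, 1 active days; pre year week 2 has 2 days
  post_days <- c(d1 + 1 + 0:4,          # 5 days in week 1
                 d1 + 8 + c(0, 2, 4),   # 3 days in week 2
                 d1 + 15 + c(1, 3),     # 2 days in week 3
                 d1 + 22)               # 1 day in week 4
  pre_days <- (d1 + 8 + c(1, 5)) - 364  # 2 days paired with week 2
  obs <- dplyr::bind_rows(
    make_obs("e1", "u1", as.Date("2019-02-22"), project = "P1"),
    make_obs(paste0("a", seq_along(post_days)), "u1", post_days),
    make_obs(paste0("b", seq_along(pre_days)), "u1", pre_days))
  pd <- paired_differences(obs, p)
  expect_equal(pd$diff[pd$week_after %in% 1:5], c(5, 1, 2, 1, 0))
})

test_that("event days are excluded from the difference blocks", {
  # a 15-day event reaches back into the block paired with post week 50;
  # its in-event days must not deflate that week's difference
  p <- make_project("P1", "2019-02-08 09:00:00", "2019-02-23 09:00:00")
  d1 <- as.Date(p$end)  # pre week 50 covers d1-19 .. d1-13 (Feb 4-10)
  obs <- dplyr::bind_rows(
    make_obs("e1", "u1", as.Date("2019-02-09"), project = "P1"),
    make_obs("a1", "u1", d1 + 10))  # keeps the user continuing
  pd <- paired_differences(obs, p)
  expect_equal(pd$diff[pd$week_after == 50], 0)
  expect_equal(pd$diff[pd$week_after == 2], 1)
})

test_that("shifting a log by 364 days leaves the differences unchanged", {
  sim <- small_sim()
  p <- sim$projects[1, ]
  obs <- sim$observations
  pd1 <- paired_differences(obs, p)

  obs2 <- dplyr::mutate(obs, observed_date = observed_date + 364)
  p2 <- dplyr::mutate(p, start = start + 364 * 86400,
                      end = end + 364 * 86400)
  pd2 <- paired_differences(obs2, p2)
  expect_equal(pd1, pd2)
})

test_that("weeks outside the declared coverage are missing, not zero", {
  p <- make_project()
  d1 <- as.Date(p$end)
  obs <- dplyr::bind_rows(
    make_obs("e1", "u1", as.Date("2019-02-22"), project = "P1"),
    make_obs("a1", "u1", d1 + 3))
  pd <- paired_differences(obs, p, coverage = c(d1 - 364, d1 + 70))
  expect_false(any(is.na(pd$diff[pd$week_after <= 10])))
  expect_true(all(is.na(pd$diff[pd$week_after > 10])))
})

test_that("the panel over a simulated corpus respects the difference bounds", {
  sim <- small_sim()
  panel <- build_panel(sim$observations, sim$projects)
  expect_true(all(panel$diff >= -7 & panel$diff <= 7))
  expect_true(all(panel$week_after >= 1 & panel$week_after <= 50))
  # only continuing participants enter the panel
  cont <- sim$truth$users$user_id[
    sim$truth$users$category %in% c("continuing_new", "continuing_veteran")]
  expect_true(all(unique(panel$user_id) %in% cont))
})
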