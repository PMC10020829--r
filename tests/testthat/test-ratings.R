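test_that("rank tallies count the primary rater's scores per aim", {
  r <- tidyr::expand_grid(item_id = c("pub1", "pub2"),
                          rater_id = "R1", aim = bioblitz_aims()) |>
    dplyr::mutate(score = ifelse(aim == "public_engagement", 5L, 2L))
  tally <- rank_tally(r)
  expect_equal(tally$n[tally$aim == "public_engagement" & tally$score == 5],
               2)
  # each item scores every aim: per-aim column sums are constant
  sums <- tapply(tally$n, tally$aim, sum)
  expect_true(all(sums == 2))
})

test_that("a single item contributes exactly one count per aim", {
  r <- generate_ratings(seed = 4, n_items = 1, n_raters = 1)
  tally <- rank_tally(r)
  expect_true(all(tapply(tally$n, tally$aim, sum) == 1))
})

test_that("tallies equal a brute-force recount on a random matrix", {
  r <- generate_ratings(seed = 21, n_items = 40, n_raters = 3,
                        disagreement_rate = 0.5)
  tally <- rank_tally(r)
  r1 <- r[r$rater_id == "R1", ]  # first-listed rater for every item
  for (aim in bioblitz_aims()) {
    for (s in 1:5) {
      expected <- sum(r1$aim == aim & r1$score == s)
      expect_equal(tally$n[tally$aim == aim & tally$score == s], expected)
    }
  }
})

test_that("double-scored items can be tallied under a designated rater", {
  r <- generate_ratings(seed = 9, n_items = 10, n_raters = 2,
                        disagreement_rate = 1)
  t1 <- rank_tally(r)
  t2 <- rank_tally(r, rater = "R2")
  r2 <- r[r$rater_id == "R2", ]
  for (aim in bioblitz_aims()) {
    for (s in 1:5) {
      expect_equal(t2$n[t2$aim == aim & t2$score == s],
                   sum(r2$aim == aim & r2$score == s))
    }
  }
  expect_false(identical(t1, t2))
})

test_that("Jaccard agreement matches hand-set arithmetic", {
  # two raters, one item; disagree on exactly one of five aims:
  # |A n B| = 4, |A u B| = 6
  base <- tibble::tibble(item_id = "pub1", aim = bioblitz_aims(),
                         score = c(5L, 4L, 3L, 2L, 1L))
  a <- dplyr::mutate(base, rater_id = "A")
  b <- dplyr::mutate(base, rater_id = "B",
                     score = ifelse(aim == "learning", 5L, score))
  r <- dplyr::bind_rows(a, b)
  expect_equal(jaccard_agreement(r, "A", "B"), 4 / 6)

  # identical score sets
  r2 <- dplyr::bind_rows(a, dplyr::mutate(a, rater_id = "B"))
  expect_equal(jaccard_agreement(r2, "A", "B"), 1.0)
})

test_that("Jaccard is symmetric, reflexive and bounded on random matrices", {
  for (seed in 1:5) {
    r <- generate_ratings(seed = seed, n_items = 15, n_raters = 2,
                          disagreement_rate = 0.6)
    j_ab <- jaccard_agreement(r, "R1", "R2")
    j_ba <- jaccard_agreement(r, "R2", "R1")
    expect_equal(j_ab, j_ba)
    expect_gte(j_ab, 0)
    expect_lte(j_ab, 1)
    expect_equal(jaccard_agreement(r, "R1", "R1"), 1.0)

    # brute-force set oracle
    key <- function(d) paste(d$item_id, d$aim, d$score)
    A <- key(r[r$rater_id == "R1", ])
    B <- key(r[r$rater_id == "R2", ])
    expect_equal(j_ab, length(intersect(A, B)) / length(union(A, B)))
  }
})

test_that("raters with disjoint item sets are a precondition error", {
  a <- tibble::tibble(item_id = "pub1", rater_id = "A",
                      aim = bioblitz_aims(), score = 1:5)
  b <- tibble::tibble(item_id = "pub2", rater_id = "B",
                      aim = bioblitz_aims(), score = 1:5)
  expect_error(jaccard_agreement(dplyr::bind_rows(a, b), "A", "B"),
               class = "bioblitzr_precondition_error")
})

test_that("rating validation rejects malformed matrices", {
  r <- generate_ratings(seed = 1, n_items = 3, n_raters = 1)
  bad_score <- dplyr::mutate(r, score = ifelse(dplyr::row_number() == 1,
                                               9L, score))
  expect_error(validate_ratings(bad_score), class = "bioblitzr_input_error")
  missing_aim <- r[-1, ]
  expect_error(validate_ratings(missing_aim),
               class = "bioblitzr_input_error")
  perm <- tibble::tibble(item_id = "pub1", rater_id = "A",
                         aim = bioblitz_aims(), score = c(1L, 1L, 3L, 4L, 5L))
  expect_error(validate_ratings(perm, strict_permutation = TRUE),
               class = "bioblitzr_input_error")
  ok <- tibble::tibble(item_id = "pub1", rater_id = "A",
                       aim = bioblitz_aims(), score = c(2L, 1L, 3L, 4L, 5L))
  expect_silent(validate_ratings(ok, strict_permutation = TRUE))
})

test_that("agreement over generated raters follows the closed-form curve", {
  # cells agree with probability q = 1 - 0.8 d; E[J] ~ q / (2 - q)
  for (d in c(0, 0.3, 0.7, 1)) {
    r <- generate_ratings(seed = 17, n_items = 400, n_raters = 2,
                          disagreement_rate = d)
    q <- 1 - 0.8 * d
    expected <- q / (2 - q)
    j <- jaccard_agreement(r, "R1", "R2")
    if (d == 0) {
      expect_equal(j, 1.0)
    } else {
      # binomial noise on 2000 cells: tolerate 4 SD of the agreement count
      n <- 400 * 5
      tol <- 4 * sqrt(q * (1 - q) / n)
      expect_lt(abs(j - expected), tol + 0.02)
    }
  }
  rep <- agreement_report(generate_ratings(seed = 2, n_items = 13,
                                           n_raters = 3,
                                           disagreement_rate = 0.2))
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$jaccard >= 0 & rep$jaccard <= 1))
})
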