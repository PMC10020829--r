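#' The five canonical bioblitz aims
#'
#' Reported bioblitzes are scored against five recurring aims: creating a
#' biodiversity inventory, improving participants' knowledge (learning),
#' discovering species new to an area, promoting an organization, and
#' engaging the public.
#'
#' @return Character vector of the five aim labels.
#' @export
bioblitz_aims <- function() {
  c("inventory", "learning", "new_species", "promotion",
    "public_engagement")
}

#' Validate a long-format rating matrix
#'
#' Ratings are long-format rows (`item_id`, `rater_id`, `aim`, `score`) where
#' each (item, rater) pair scores all five aims with integers 1 (lowest
#' importance) to 5 (highest). Scores are accepted as independent values in
#' 1..5; set `strict_permutation = TRUE` to additionally require each
#' (item, rater) block to be a permutation of 1..5 (forced ranking).
#'
#' @param ratings Long-format rating tibble.
#' @param strict_permutation Require each block to use each score exactly
#'   once? Default `FALSE`.
#' @return Invisibly, `ratings`; errors describe the first violation found.
#' @export
validate_ratings <- function(ratings, strict_permutation = FALSE) {
  assert_columns(ratings, c("item_id", "rater_id", "aim", "score"),
                 "ratings")
  if (!all(ratings$aim %in% bioblitz_aims())) {
    abort_bioblitzr(
      sprintf("unknown aim label(s): %s",
              paste(setdiff(unique(ratings$aim), bioblitz_aims()),
                    collapse = ", ")),
      class = "bioblitzr_input_error")
  }
  if (!all(ratings$score %in% 1:5)) {
    abort_bioblitzr("scores must be integers between 1 and 5",
                    class = "bioblitzr_input_error")
  }
  cover <- ratings |>
    dplyr::group_by(.data$item_id, .data$rater_id) |>
    dplyr::summarise(n_aims = dplyr::n_distinct(.data$aim),
                     n_rows = dplyr::n(),
                     perm = dplyr::n() == 5L &&
                       identical(sort(as.integer(.data$score)), 1:5),
                     .groups = "drop")
  bad <- cover[cover$n_aims != 5L | cover$n_rows != 5L, , drop = FALSE]
  if (nrow(bad) > 0) {
    abort_bioblitzr(
      sprintf("each (item, rater) pair must score all five aims exactly once; first offender: item %s, rater %s",
              bad$item_id[1], bad$rater_id[1]),
      class = "bioblitzr_input_error")
  }
  if (strict_permutation && !all(cover$perm)) {
    bad <- cover[!cover$perm, , drop = FALSE]
    abort_bioblitzr(
      sprintf("strict permutation requested but item %s, rater %s does not use each score 1..5 exactly once",
              bad$item_id[1], bad$rater_id[1]),
      class = "bioblitzr_input_error")
  }
  invisible(ratings)
}

#' Tally scores per aim across rated items
#'
#' Counts, for each aim, how many items received each score 1..5 — the
#' summary behind stacked-bar views of which aims matter most. For items
#' scored by several raters, one designated rater is tallied per item: the
#' first-listed rater in the table unless `rater` picks one explicitly.
#'
#' @param ratings Long-format rating tibble (see [validate_ratings()]).
#' @param rater Optional rater id whose scores are tallied for all items it
#'   rated; items it did not rate fall back to their first-listed rater.
#' @return A tibble (`aim`, `score`, `n`) covering every aim x score cell
#'   (zeros included); per aim, `n` sums to the number of items.
#' @export
rank_tally <- function(ratings, rater = NULL) {
  validate_ratings(ratings)
  first_rater <- ratings |>
    dplyr::distinct(.data$item_id, .data$rater_id) |>
    dplyr::group_by(.data$item_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (!is.null(rater)) {
    has_pref <- ratings |>
      dplyr::distinct(.data$item_id, .data$rater_id) |>
      dplyr::filter(.data$rater_id == rater)
    first_rater <- first_rater |>
      dplyr::filter(!(.data$item_id %in% has_pref$item_id)) |>
      dplyr::bind_rows(has_pref)
  }
  chosen <- dplyr::inner_join(ratings, first_rater,
                              by = c("item_id", "rater_id"))
  grid <- tidyr::expand_grid(aim = bioblitz_aims(), score = 1:5)
  chosen |>
    dplyr::count(.data$aim, .data$score, name = "n") |>
    dplyr::right_join(grid, by = c("aim", "score")) |>
    dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L))) |>
    dplyr::arrange(.data$aim, .data$score)
}

#' Jaccard inter-rater agreement
#'
#' Measures agreement between two raters as the Jaccard similarity
#' coefficient `J = |A n B| / |A u B|` over their sets of
#' `(item, aim, score)` triples, restricted to the items both rated. Because
#' a triple is shared exactly when both raters gave the same aim of the same
#' item the same score, `J` reads directly as a fraction of agreement: 1 for
#' identical scoring, down to 0.
#'
#' @param ratings Long-format rating tibble.
#' @param rater_a,rater_b The two rater ids to compare.
#' @param mode Agreement mode; `"exact_pairs"` (triples must match exactly)
#'   is the only mode implemented.
#' @return The coefficient, a number in \[0, 1\].
#' @export
jaccard_agreement <- function(ratings, rater_a, rater_b,
                              mode = "exact_pairs") {
  mode <- match.arg(mode, "exact_pairs")
  validate_ratings(ratings)
  ra <- ratings[ratings$rater_id == rater_a, , drop = FALSE]
  rb <- ratings[ratings$rater_id == rater_b, , drop = FALSE]
  common <- intersect(unique(ra$item_id), unique(rb$item_id))
  if (length(common) == 0) {
    abort_bioblitzr(
      sprintf("raters %s and %s share no items", rater_a, rater_b),
      class = "bioblitzr_precondition_error")
  }
  triple <- function(d) {
    d <- d[d$item_id %in% common, , drop = FALSE]
    paste(d$item_id, d$aim, d$score, sep = "\r")
  }
  a <- triple(ra)
  b <- triple(rb)
  length(intersect(a, b)) / length(union(a, b))
}

#' Agreement report over all rater pairs
#'
#' Computes [jaccard_agreement()] for every pair of raters that shares at
#' least one item (e.g. the double-scored subset of a review corpus).
#'
#' @param ratings Long-format rating tibble.
#' @return A tibble (`rater_a`, `rater_b`, `n_shared_items`, `jaccard`).
#' @export
agreement_report <- function(ratings) {
  validate_ratings(ratings)
  raters <- sort(unique(ratings$rater_id))
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  items_of <- split(ratings$item_id, ratings$rater_id) |>
    lapply(unique)
  purrr::map(pairs, function(p) {
    shared <- intersect(items_of[[p[1]]], items_of[[p[2]]])
    if (length(shared) == 0) return(NULL)
    tibble::tibble(rater_a = p[1], rater_b = p[2],
                   n_shared_items = length(shared),
                   jaccard = jaccard_agreement(ratings, p[1], p[2]))
  }) |>
    dplyr::bind_rows()
}
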