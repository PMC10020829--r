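#' Fit the exponential decay model of the post-event activity boost
#'
#' Models the paired-week activity difference as `y = a * exp(-b * x)`, with
#' `x` the week since the event (1..50) and `y` the difference in weekly
#' devoted days against the weekday-aligned week one year earlier. `a` is the
#' initial boost (days/week) and `b` the decay constant (per week).
#'
#' Two estimators are available. `"two_stage"` (the default) first fits, per
#' project, nonlinear least squares of the project-mean difference per week
#' on `a * exp(-b * x)`, then pools the per-project log-parameters into
#' population values by precision-weighted averaging (weights proportional
#' to each project's user count), with standard errors taken from the
#' weighted dispersion of the per-project estimates. This
#' treats the project as the unit of heterogeneity, mirroring a mixed model
#' with project as a random factor, while staying deterministic and
#' dependency-light. `"pooled"` fits a single NLS to all user-week rows and
#' reports no project effects.
#'
#' Stage-1 initialization: `a0` is the mean difference over weeks 1-4; `b0`
#' comes from the least-squares slope of `log(pmax(weekly mean, 0.01))` over
#' weeks with positive means, falling back to 0.05 when fewer than 3 weekly
#' means are positive. Non-converged projects are retried with jittered
#' starting values (the only use of `seed`). Projects whose fitted `a` or `b`
#' is non-positive, or whose fit fails, are excluded from pooling and listed
#' in `project_effects` with a reason.
#'
#' Projects with fewer than `min_users_per_project` users are merged into a
#' single pseudo-project (`".pooled"`) before stage 1: per-project NLS on one
#' or two users is unstable.
#'
#' @param panel Difference panel: tibble with `user_id`, `project_id`,
#'   `week_after`, `diff` (see [build_panel()]). Missing `diff` rows are
#'   dropped.
#' @param method `"two_stage"` or `"pooled"`.
#' @param min_users_per_project Minimum users for a project to be fitted on
#'   its own (default 3).
#' @param seed Integer seed used only for jittered restarts after a failed
#'   convergence; the fit is deterministic given the seed.
#' @param max_restarts Jittered restarts per project before giving up.
#' @return A `decay_fit` object with fields `a_hat`, `b_hat`, `se_a`, `se_b`,
#'   `n_points` (user-week rows used), `n_projects` (projects pooled),
#'   `project_effects` (per-project estimates, standard errors, user counts,
#'   retention flag and reason), `method`, `converged`, `degenerate`, and
#'   `weekly` (observed vs fitted population weekly means, for plotting).
#'   Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   `print()`, [ggplot2::autoplot()].
#' @seealso [half_life()], [cumulative_boost()], [extrapolate_boost()]
#' @export
fit_decay <- function(panel, method = c("two_stage", "pooled"),
                      min_users_per_project = 3L, seed = 1L,
                      max_restarts = 5L) {
  method <- match.arg(method)
  assert_columns(panel, c("user_id", "project_id", "week_after", "diff"),
                 "panel")
  panel <- panel[!is.na(panel$diff), , drop = FALSE]
  if (nrow(panel) == 0) {
    abort_bioblitzr("panel is empty (no non-missing differences)",
                    class = "bioblitzr_input_error")
  }
  n_points <- nrow(panel)

  weekly_all <- panel |>
    dplyr::group_by(x = .data$week_after) |>
    dplyr::summarise(observed = mean(.data$diff), .groups = "drop")

  # Degenerate panel: no boost signal at all.
  if (all(panel$diff == 0)) {
    return(new_decay_fit(a_hat = 0, b_hat = NA_real_, se_a = 0,
                         se_b = NA_real_, n_points = n_points,
                         n_projects = 0L,
                         project_effects = empty_project_effects(),
                         method = method, converged = FALSE,
                         degenerate = TRUE, weekly = weekly_all))
  }

  if (method == "pooled") {
    fit <- fit_nls_decay(panel$week_after, panel$diff, seed = seed,
                         max_restarts = max_restarts)
    if (!fit$ok) {
      return(new_decay_fit(a_hat = NA_real_, b_hat = NA_real_,
                           se_a = NA_real_, se_b = NA_real_,
                           n_points = n_points, n_projects = 0L,
                           project_effects = empty_project_effects(),
                           method = method, converged = FALSE,
                           degenerate = FALSE, weekly = weekly_all,
                           diagnostics = fit$reason))
    }
    weekly_all$fitted <- fit$a * exp(-fit$b * weekly_all$x)
    return(new_decay_fit(a_hat = fit$a, b_hat = fit$b, se_a = fit$se_a,
                         se_b = fit$se_b, n_points = n_points,
                         n_projects = dplyr::n_distinct(panel$project_id),
                         project_effects = empty_project_effects(),
                         method = method,
                         converged = is.finite(fit$b) && fit$b > 0,
                         degenerate = FALSE, weekly = weekly_all))
  }

  # --- two-stage ---
  users_per_project <- panel |>
    dplyr::group_by(.data$project_id) |>
    dplyr::summarise(n_users = dplyr::n_distinct(.data$user_id),
                     .groups = "drop")
  small <- users_per_project$project_id[
    users_per_project$n_users < min_users_per_project]
  panel$fit_group <- ifelse(panel$project_id %in% small, ".pooled",
                            panel$project_id)

  weekly_by_project <- panel |>
    dplyr::group_by(.data$fit_group, x = .data$week_after) |>
    dplyr::summarise(m = mean(.data$diff), .groups = "drop")
  group_users <- panel |>
    dplyr::group_by(.data$fit_group) |>
    dplyr::summarise(n_users = dplyr::n_distinct(.data$user_id),
                     .groups = "drop")

  groups <- unique(weekly_by_project$fit_group)
  effects <- purrr::imap(groups, function(g, i) {
    df <- weekly_by_project[weekly_by_project$fit_group == g, ]
    fit <- fit_nls_decay(df$x, df$m, seed = seed + i,
                         max_restarts = max_restarts)
    if (!fit$ok) {
      return(tibble::tibble(project_id = g, a = NA_real_, b = NA_real_,
                            se_a = NA_real_, se_b = NA_real_,
                            retained = FALSE, reason = fit$reason))
    }
    reason <- NA_character_
    retained <- TRUE
    if (!is.finite(fit$b) || fit$b <= 0) {
      retained <- FALSE; reason <- "nonpositive decay constant"
    } else if (!is.finite(fit$a) || fit$a <= 0) {
      retained <- FALSE; reason <- "nonpositive initial boost"
    } else if (!is.finite(fit$se_a) || !is.finite(fit$se_b)) {
      retained <- FALSE; reason <- "unavailable standard errors"
    }
    tibble::tibble(project_id = g, a = fit$a, b = fit$b,
                   se_a = fit$se_a, se_b = fit$se_b,
                   retained = retained, reason = reason)
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(group_users, by = c(project_id = "fit_group"))

  kept <- effects[effects$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(new_decay_fit(a_hat = NA_real_, b_hat = NA_real_,
                         se_a = NA_real_, se_b = NA_real_,
                         n_points = n_points, n_projects = 0L,
                         project_effects = effects, method = method,
                         converged = FALSE, degenerate = FALSE,
                         weekly = weekly_all,
                         diagnostics = "no project-level fit was retained"))
  }

  pool_a <- pool_log_params(kept$a, kept$se_a, kept$n_users)
  pool_b <- pool_log_params(kept$b, kept$se_b, kept$n_users)
  weekly_all$fitted <- pool_a$est * exp(-pool_b$est * weekly_all$x)

  new_decay_fit(a_hat = pool_a$est, b_hat = pool_b$est,
                se_a = pool_a$se, se_b = pool_b$se,
                n_points = n_points, n_projects = nrow(kept),
                project_effects = effects, method = method,
                converged = TRUE, degenerate = FALSE, weekly = weekly_all)
}

# Precision-weighted pooling on the log scale. The precision weight is the
# project's panel size (number of users): a deterministic proxy for the
# sampling precision of the stage-1 fit. Weighting by the estimated
# standard errors instead is tempting but biased — in small projects the
# estimated relative SE of b correlates with the estimate itself, so such
# weights systematically up-weight large decay constants. The pooled SE
# comes from the weighted dispersion of the per-project log-estimates about
# the pooled mean, so between-project scatter (heterogeneity as well as
# stage-1 noise) inflates it.
pool_log_params <- function(est, se, n_users) {
  l <- log(est)
  w <- n_users
  lbar <- sum(w * l) / sum(w)
  k <- length(l)
  se_lbar <- if (k >= 2) {
    sqrt(sum(w * (l - lbar)^2) / ((k - 1) * sum(w)))
  } else {
    se / est
  }
  list(est = exp(lbar), se = exp(lbar) * se_lbar)
}

# Single NLS of y on a*exp(-b*x) with the documented initialization and
# jittered restarts. Levenberg-Marquardt handles zero-residual (noise-free)
# fits that Gauss-Newton rejects.
fit_nls_decay <- function(x, y, seed, max_restarts = 5L) {
  df <- data.frame(x = x, y = y)
  means <- stats::aggregate(y ~ x, data = df, FUN = mean)
  a0 <- mean(means$y[means$x <= 4])
  if (!is.finite(a0) || a0 <= 0) a0 <- max(mean(means$y), 0.01)
  pos <- means[means$y > 0, , drop = FALSE]
  b0 <- 0.05
  if (nrow(pos) >= 3) {
    slope <- stats::coef(stats::lm(log(pmax(y, 0.01)) ~ x, data = pos))[["x"]]
    if (is.finite(slope) && slope < 0) b0 <- -slope
  }
  starts <- list(c(a = a0, b = b0))
  if (max_restarts > 0) {
    jit <- withr::with_seed(seed, {
      purrr::map(seq_len(max_restarts), function(i) {
        c(a = a0 * stats::runif(1, 0.3, 3), b = b0 * stats::runif(1, 0.3, 3))
      })
    })
    starts <- c(starts, jit)
  }
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-b * x), data = df,
                        start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
      se_a <- if (!is.null(sm)) sm["a", "Std. Error"] else NA_real_
      se_b <- if (!is.null(sm)) sm["b", "Std. Error"] else NA_real_
      return(list(ok = TRUE, a = unname(cf["a"]), b = unname(cf["b"]),
                  se_a = se_a, se_b = se_b))
    }
  }
  list(ok = FALSE, reason = "nonlinear least squares did not converge")
}

empty_project_effects <- function() {
  tibble::tibble(project_id = character(), a = numeric(), b = numeric(),
                 se_a = numeric(), se_b = numeric(), retained = logical(),
                 reason = character(), n_users = integer())
}

new_decay_fit <- function(a_hat, b_hat, se_a, se_b, n_points, n_projects,
                          project_effects, method, converged, degenerate,
                          weekly, diagnostics = NULL) {
  structure(
    list(a_hat = a_hat, b_hat = b_hat, se_a = se_a, se_b = se_b,
         n_points = n_points, n_projects = n_projects,
         project_effects = project_effects, method = method,
         converged = converged, degenerate = degenerate, weekly = weekly,
         diagnostics = diagnostics),
    class = "decay_fit"
  )
}

#' Half-life of the activity boost
#'
#' Time for the post-event boost to halve: `ln(2) / b` weeks. Rounding (the
#' conventional report precision is one decimal) is left to the caller.
#'
#' @param b Decay constant(s), per week; must be positive.
#' @return Half-life in weeks (vectorized over `b`).
#' @export
half_life <- function(b) {
  if (any(!is.finite(b) | b <= 0)) {
    abort_bioblitzr("half_life() requires a positive decay constant",
                    class = "bioblitzr_domain_error")
  }
  log(2) / b
}

#' Cumulative additional recording days attributable to an event
#'
#' Integrates the boost `a * exp(-b * t)` over post-event time: the
#' infinite-horizon total is `a / b` days, and the finite-horizon variant is
#' `a/b * (1 - exp(-b * W))` for a horizon of `W` weeks.
#'
#' @param a Initial boost, days/week; must be non-negative.
#' @param b Decay constant, per week; must be positive.
#' @param horizon_weeks Integration horizon in weeks (default `Inf`).
#' @return Additional devoted days per continuing participant.
#' @export
cumulative_boost <- function(a, b, horizon_weeks = Inf) {
  if (any(!is.finite(b) | b <= 0)) {
    abort_bioblitzr("cumulative_boost() requires a positive decay constant",
                    class = "bioblitzr_domain_error")
  }
  if (any(a < 0)) {
    abort_bioblitzr("cumulative_boost() requires a non-negative boost",
                    class = "bioblitzr_domain_error")
  }
  ifelse(is.infinite(horizon_weeks), a / b,
         a / b * (1 - exp(-b * horizon_weeks)))
}

#' Platform-level extrapolation of the engagement boost
#'
#' Scales the per-participant cumulative boost up to a platform: with
#' `n_participants` people engaged in events, a fraction `continuation_rate`
#' of whom continue using the platform, each adding `cumulative_days` of
#' recording at `obs_per_day` observations per day, the events add
#' `n_participants * continuation_rate * cumulative_days * obs_per_day`
#' observations beyond the events themselves. When the total number of
#' observations made during the events is supplied, the additional
#' observations are also expressed as a share of it.
#'
#' @param n_participants Number of event participants.
#' @param continuation_rate Fraction of participants who continue (0-1).
#' @param cumulative_days Additional recording days per continuing
#'   participant (see [cumulative_boost()]).
#' @param obs_per_day Observations per additional recording day (default 1).
#' @param total_observations Optional total observations during the events;
#'   enables `share_of_total`. Zero is a domain error.
#' @return A one-row tibble: `additional_observations`, `share_of_total`
#'   (`NA` when no total is supplied).
#' @export
extrapolate_boost <- function(n_participants, continuation_rate,
                              cumulative_days, obs_per_day = 1,
                              total_observations = NULL) {
  stopifnot(n_participants >= 0, cumulative_days >= 0, obs_per_day >= 0)
  if (continuation_rate < 0 || continuation_rate > 1) {
    abort_bioblitzr("continuation_rate must lie in [0, 1]",
                    class = "bioblitzr_domain_error")
  }
  additional <- n_participants * continuation_rate * cumulative_days *
    obs_per_day
  share <- NA_real_
  if (!is.null(total_observations)) {
    if (total_observations == 0) {
      abort_bioblitzr("share requested with total_observations = 0",
                      class = "bioblitzr_domain_error")
    }
    share <- additional / total_observations
  }
  tibble::tibble(additional_observations = additional,
                 share_of_total = share)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential decay fit of the post-event activity boost\n")
  cat(sprintf("  method: %s   projects pooled: %d   n (user-weeks): %d\n",
              x$method, x$n_projects, x$n_points))
  if (x$degenerate) {
    cat("  degenerate fit: no boost signal in the panel (a = 0)\n")
    return(invisible(x))
  }
  if (!x$converged) {
    cat("  fit did not converge:", x$diagnostics %||% "unknown reason", "\n")
    return(invisible(x))
  }
  cat(sprintf("  a (initial boost) = %.3f days/week (SE %.3f)\n",
              x$a_hat, x$se_a))
  cat(sprintf("  b (decay constant) = %.3f /week (SE %.3f)\n",
              x$b_hat, x$se_b))
  cat(sprintf("  half-life = %.1f weeks   cumulative boost = %.1f days\n",
              half_life(x$b_hat), cumulative_boost(x$a_hat, x$b_hat)))
  invisible(x)
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with one row per population parameter (`term`,
#'   `estimate`, `std.error`).
#' @importFrom generics tidy
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"),
                 estimate = c(x$a_hat, x$b_hat),
                 std.error = c(x$se_a, x$se_b))
}

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble: parameter estimates, standard errors, derived
#'   half-life and cumulative boost, sample sizes, method and convergence
#'   flags.
#' @importFrom generics glance
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  ok <- isTRUE(x$converged)
  tibble::tibble(
    a_hat = x$a_hat, b_hat = x$b_hat, se_a = x$se_a, se_b = x$se_b,
    half_life_weeks = if (ok) half_life(x$b_hat) else NA_real_,
    cumulative_boost_days = if (ok) cumulative_boost(x$a_hat, x$b_hat)
                            else NA_real_,
    n_points = x$n_points, n_projects = x$n_projects,
    method = x$method, converged = x$converged, degenerate = x$degenerate
  )
}

#' Plot observed vs fitted weekly mean differences
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot: population weekly mean differences (points) with the
#'   fitted decay curve.
#' @importFrom ggplot2 autoplot
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$weekly, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "grey30") +
    ggplot2::labs(
      x = "Weeks since event",
      y = "Mean difference in weekly devoted days",
      title = "Post-event activity boost and its decay"
    ) +
    ggplot2::theme_minimal()
  if ("fitted" %in% names(object$weekly)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fitted),
                                colour = "#2c7fb8", linewidth = 0.8)
  }
  p
}
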