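`%||%` <- function(x, y) if (is.null(x)) y else x

# English day/month labels, locale-independent
.weekday_levels <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                     "Saturday", "Sunday")
.month_levels <- month.name

#' @keywords internal
weekday_of <- function(d) {
  # %u: ISO weekday 1 = Monday
  factor(.weekday_levels[as.integer(strftime(d, "%u"))],
         levels = .weekday_levels)
}

#' @keywords internal
month_of <- function(d) {
  factor(.month_levels[as.integer(strftime(d, "%m"))], levels = .month_levels)
}

abort_bioblitzr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "bioblitzr_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_bioblitzr(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "bioblitzr_config_error"
    )
  }
  invisible(df)
}
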