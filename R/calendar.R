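#' Survey period calendar
#'
#' A diary survey runs over two one-week windows. Every calendar date in a
#' window belongs to exactly one of four exclusive periods:
#'
#' * `I`   — weekdays during the school semester (first window),
#' * `II`  — weekdays during the school vacation (second window),
#' * `III` — weekend days that are not holidays,
#' * `IV`  — Lunar New Year holidays (taking precedence over weekends).
#'
#' The default calendar covers the two survey weeks 2023-12-06 to 2023-12-12
#' and 2024-02-07 to 2024-02-13, with the statutory Seollal holiday block
#' 2024-02-09 to 2024-02-12 (including the substitute holiday). The holiday
#' set is a configuration input, not a hard-coded fact.
#'
#' @param window_a Length-2 `Date` (or coercible) vector: first window
#'   (semester week), inclusive.
#' @param window_b Length-2 `Date` vector: second window (vacation /
#'   holiday week), inclusive.
#' @param holidays `Date` vector of holiday dates (classified as period IV).
#' @return An object of class `period_calendar`: a list with elements
#'   `window_a`, `window_b`, `holidays` and `days`, the latter a tibble with
#'   one row per survey date and columns `date`, `window`, `wday`, `period`.
#' @examples
#' cal <- survey_calendar()
#' dplyr::count(cal$days, period)
#' @export
survey_calendar <- function(window_a = c("2023-12-06", "2023-12-12"),
                            window_b = c("2024-02-07", "2024-02-13"),
                            holidays = seq(as.Date("2024-02-09"),
                                           as.Date("2024-02-12"), by = "day")) {
  window_a <- as.Date(window_a)
  window_b <- as.Date(window_b)
  holidays <- as.Date(holidays)
  stopifnot(length(window_a) == 2L, length(window_b) == 2L,
            !anyNA(window_a), !anyNA(window_b),
            window_a[1] <= window_a[2], window_b[1] <= window_b[2])

  dates_a <- seq(window_a[1], window_a[2], by = "day")
  dates_b <- seq(window_b[1], window_b[2], by = "day")
  if (anyDuplicated(c(dates_a, dates_b))) {
    rlang::abort("survey windows overlap", class = "contactdiaries_config_error")
  }
  days <- tibble::tibble(
    date = c(dates_a, dates_b),
    window = rep(c("a", "b"), c(length(dates_a), length(dates_b)))
  )
  # ISO weekday 1 = Monday ... 7 = Sunday (locale-independent)
  days$wday <- as.POSIXlt(days$date)$wday
  days$wday[days$wday == 0L] <- 7L
  is_holiday <- days$date %in% holidays
  is_weekend <- days$wday >= 6L
  period <- ifelse(is_holiday, "IV",
            ifelse(is_weekend, "III",
            ifelse(days$window == "a", "I", "II")))
  days$period <- factor(period, levels = period_levels())

  structure(
    list(window_a = window_a, window_b = window_b,
         holidays = holidays, days = days),
    class = "period_calendar"
  )
}

#' @export
print.period_calendar <- function(x, ...) {
  cat("<period_calendar>\n")
  cat("  window a:", format(x$window_a[1]), "to", format(x$window_a[2]), "\n")
  cat("  window b:", format(x$window_b[1]), "to", format(x$window_b[2]), "\n")
  cat("  holidays:", paste(format(x$holidays), collapse = ", "), "\n")
  tab <- table(x$days$period)
  cat("  period days:", paste(names(tab), unname(tab), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Period labels
#'
#' @return Character vector `c("I", "II", "III", "IV")`.
#' @export
period_levels <- function() c("I", "II", "III", "IV")

#' Classify survey dates into periods
#'
#' Holidays take precedence over weekends: a holiday falling on a Saturday is
#' period IV, keeping the four periods exclusive.
#'
#' @param date `Date` vector (or coercible).
#' @param calendar A [survey_calendar()] object.
#' @return Factor with levels `I`--`IV`, one element per date.
#' @examples
#' cal <- survey_calendar()
#' classify_period(as.Date(c("2023-12-06", "2023-12-09", "2024-02-10")), cal)
#' @export
classify_period <- function(date, calendar) {
  stopifnot(inherits(calendar, "period_calendar"))
  date <- as.Date(date)
  idx <- match(date, calendar$days$date)
  if (anyNA(idx)) {
    bad <- unique(date[is.na(idx)])
    rlang::abort(
      paste0("date(s) outside both survey windows: ",
             paste(format(bad), collapse = ", ")),
      class = "contactdiaries_validation_error"
    )
  }
  calendar$days$period[idx]
}

#' Age-group presets
#'
#' `age_breaks_analysis()` gives the ten analysis groups used in the
#' covariate model (0-4, 5-9, 10-14, 15-19, then decades to 70+), chosen for
#' the epidemiological importance of young children and school ages.
#' `age_breaks_recruitment()` gives the eight decade groups used for quota
#' recruitment.
#'
#' @return Integer vector of lower bin edges, starting at 0; the last bin is
#'   open-ended.
#' @export
age_breaks_analysis <- function() c(0L, 5L, 10L, 15L, 20L, 30L, 40L, 50L, 60L, 70L)

#' @rdname age_breaks_analysis
#' @export
age_breaks_recruitment <- function() seq(0L, 70L, by = 10L)

#' Labels for a set of age-bin lower edges
#'
#' @param breaks Increasing integer vector of lower edges, first element 0.
#' @return Character vector of labels such as `"0-4"`, `"70+"`.
#' @export
age_bin_labels <- function(breaks = age_breaks_analysis()) {
  stopifnot(breaks[1] == 0L, !is.unsorted(breaks, strictly = TRUE))
  n <- length(breaks)
  c(paste0(breaks[-n], "-", breaks[-1] - 1L), paste0(breaks[n], "+"))
}

#' Assign ages to half-open age bins
#'
#' Bins are half-open `[lo, hi + 1)` on integer years; the last bin is
#' open-ended, so the mapping is total on non-negative ages and monotone.
#'
#' @param age_years Integer vector of ages in years (NA allowed, propagated).
#' @param breaks Lower bin edges, see [age_breaks_analysis()].
#' @return Ordered factor of bin labels.
#' @examples
#' age_bin(c(4, 5, 93))
#' @export
age_bin <- function(age_years, breaks = age_breaks_analysis()) {
  if (any(age_years < 0, na.rm = TRUE)) {
    rlang::abort("negative age", class = "contactdiaries_validation_error")
  }
  labs <- age_bin_labels(breaks)
  idx <- findInterval(age_years, breaks)
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Household-size classes
#'
#' Households of six or more members are merged with size five into the
#' `"5+"` class, reflecting the small number of larger households.
#'
#' @param household_size Integer vector, each at least 1.
#' @return Factor with levels `1`, `2`, `3`, `4`, `5+`.
#' @export
household_class <- function(household_size) {
  if (any(household_size < 1, na.rm = TRUE)) {
    rlang::abort("household size must be >= 1",
                 class = "contactdiaries_validation_error")
  }
  labs <- household_levels()
  factor(ifelse(household_size >= 5, "5+", as.character(household_size)),
         levels = labs)
}

#' @rdname household_class
#' @export
household_levels <- function() c("1", "2", "3", "4", "5+")
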