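#' Per participant-day contact counts
#'
#' Tabulates the diary into one row per participant and calendar day with
#' the number of reported contacts (zero-contact days included) and the
#' day's period. This balanced participant-day table underlies all
#' descriptive summaries and the regression model.
#'
#' @param diary A [survey_diary()].
#' @return Tibble with columns `participant_id`, `date`, `period`,
#'   `n_contacts`.
#' @export
daily_counts <- function(diary) {
  stopifnot(inherits(diary, "survey_diary"))
  days <- diary$calendar$days
  grid <- tidyr::expand_grid(
    participant_id = diary$participants$participant_id,
    date = days$date
  )
  grid$period <- days$period[match(grid$date, days$date)]
  tallied <- diary$contacts |>
    dplyr::count(.data$participant_id, .data$date, name = "n_contacts")
  grid |>
    dplyr::left_join(tallied, by = c("participant_id", "date")) |>
    dplyr::mutate(n_contacts = dplyr::coalesce(.data$n_contacts, 0L))
}

#' Overall mean daily contact rate
#'
#' Total reported contacts divided by (participants x diary days).
#'
#' @param diary A [survey_diary()].
#' @return Mean contacts per participant per day.
#' @seealso [contact_rate()] for the bare arithmetic on printed totals.
#' @export
overall_mean <- function(diary) {
  stopifnot(inherits(diary, "survey_diary"))
  if (nrow(diary$participants) == 0L || n_diary_days(diary) == 0L) {
    rlang::abort("empty diary", class = "contactdiaries_validation_error")
  }
  contact_rate(nrow(diary$contacts), nrow(diary$participants),
               n_diary_days(diary))
}

#' @rdname overall_mean
#' @param n_contacts,n_participants,n_days Totals of a diary study.
#' @export
contact_rate <- function(n_contacts, n_participants, n_days) {
  n_contacts / (n_participants * n_days)
}

#' Crude rate ratio
#'
#' Ratio of a covariate level's marginal mean daily contact rate to the
#' reference level's. Computed from unrounded means; conventionally reported
#' at 2 decimal places.
#'
#' @param mean_level,mean_reference Marginal mean rates.
#' @return The ratio `mean_level / mean_reference`.
#' @export
crude_ratio <- function(mean_level, mean_reference) {
  if (any(mean_reference <= 0)) {
    rlang::abort("reference mean must be positive",
                 class = "contactdiaries_validation_error")
  }
  mean_level / mean_reference
}

covariate_of <- function(diary, covariate) {
  p <- diary$participants
  switch(covariate,
    age = as.character(age_bin(p$age_years)),
    sex = p$sex,
    household = as.character(p$household_size_class),
    rlang::abort(paste0("unknown covariate: ", covariate),
                 class = "contactdiaries_validation_error"))
}

covariate_levels <- function(covariate) {
  switch(covariate,
    age = age_bin_labels(),
    sex = sex_levels(),
    household = household_levels(),
    period = period_levels())
}

#' Marginal mean contact rates by covariate level
#'
#' For demographic covariates (`age`, `sex`, `household`) the marginal mean
#' is the mean over the level's participants of each participant's mean
#' daily contacts, and the SD is across those participants. For `period`,
#' every participant contributes days to every level; the mean is the pooled
#' participant-day mean over the period's days and the SD is across
#' participant-days. Crude ratios are taken against the first (reference)
#' level from the unrounded means.
#'
#' @param diary A [survey_diary()].
#' @param covariate One of `"age"`, `"sex"`, `"household"`, `"period"`.
#' @return Tibble with columns `covariate`, `level`, `n_participants`,
#'   `marginal_mean`, `marginal_sd`, `crude_ratio`.
#' @export
marginal_means <- function(diary, covariate = c("age", "sex", "household",
                                                "period")) {
  covariate <- match.arg(covariate)
  counts <- daily_counts(diary)
  if (covariate == "period") {
    out <- counts |>
      dplyr::group_by(level = as.character(.data$period)) |>
      dplyr::summarise(
        n_participants = dplyr::n_distinct(.data$participant_id),
        marginal_mean = mean(.data$n_contacts),
        marginal_sd = stats::sd(.data$n_contacts),
        .groups = "drop")
  } else {
    lev <- tibble::tibble(
      participant_id = diary$participants$participant_id,
      level = covariate_of(diary, covariate))
    out <- counts |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(part_mean = mean(.data$n_contacts), .groups = "drop") |>
      dplyr::left_join(lev, by = "participant_id") |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(
        n_participants = dplyr::n(),
        marginal_mean = mean(.data$part_mean),
        marginal_sd = stats::sd(.data$part_mean),
        .groups = "drop")
  }
  levels <- covariate_levels(covariate)
  out <- out |>
    dplyr::mutate(level = factor(.data$level, levels = levels)) |>
    dplyr::arrange(.data$level)
  if (nrow(out) == 0L || is.na(out$marginal_mean[1])) {
    rlang::abort("empty reference level", class = "contactdiaries_validation_error")
  }
  out |>
    dplyr::mutate(
      covariate = covariate,
      crude_ratio = crude_ratio(.data$marginal_mean, out$marginal_mean[1]),
      .before = 1) |>
    dplyr::relocate("covariate", "level")
}

#' @rdname marginal_means
#' @param level A single level of the covariate.
#' @return For `marginal_mean()`: a one-row tibble with `mean`, `sd`, `n`.
#' @export
marginal_mean <- function(diary, covariate, level) {
  tab <- marginal_means(diary, covariate)
  row <- tab[as.character(tab$level) == level, ]
  if (nrow(row) == 0L) {
    rlang::abort(paste0("empty or unknown level: ", level),
                 class = "contactdiaries_validation_error")
  }
  tibble::tibble(mean = row$marginal_mean, sd = row$marginal_sd,
                 n = row$n_participants)
}

#' Overdispersion check of participant-day counts
#'
#' Mean and sample variance (n - 1 denominator) of the participant-day
#' contact counts, and their variance-to-mean ratio. A ratio well above 1
#' motivates the negative binomial over the Poisson.
#'
#' @param diary A [survey_diary()].
#' @return One-row tibble with `mean`, `variance`, `ratio`.
#' @export
dispersion_check <- function(diary) {
  y <- daily_counts(diary)$n_contacts
  if (length(y) < 2L) {
    rlang::abort("need at least 2 participant-days",
                 class = "contactdiaries_validation_error")
  }
  m <- mean(y)
  v <- stats::var(y)
  tibble::tibble(mean = m, variance = v,
                 ratio = if (m > 0) v / m else 0)
}

composition_attributes <- function() {
  c("relation", "frequency", "duration", "residential_area", "contact_type")
}

attribute_values <- function(diary, attribute) {
  ct <- diary$contacts
  unk <- unknown_label()
  switch(attribute,
    relation = list(x = ct$relation, levels = relation_levels()),
    frequency = list(x = ct$frequency_class, levels = frequency_levels()),
    duration = list(x = ct$duration_class, levels = duration_levels()),
    location = list(x = ct$location, levels = location_levels()),
    contact_type = list(
      x = ifelse(ct$physical, "physical", "non_physical"),
      levels = c("physical", "non_physical")),
    residential_area = {
      pidx <- match(ct$participant_id, diary$participants$participant_id)
      creg <- region5_of(ct$contact_region17)
      x <- ifelse(creg == unk, unk,
                  ifelse(creg == diary$participants$region5[pidx],
                         "same_region", "different_region"))
      list(x = x, levels = c("same_region", "different_region", unk))
    },
    rlang::abort(paste0("unknown attribute: ", attribute),
                 class = "contactdiaries_validation_error"))
}

#' Per-period composition of contacts by an attribute
#'
#' For each period and attribute level, the mean number of contacts per
#' participant per day (the stacked-bar-chart quantity) and the within-period
#' proportion. `residential_area` compares the contact's major region with
#' the participant's (`same_region` / `different_region` / `unknown`);
#' `contact_type` is physical vs non-physical. Summing the cells over levels
#' recovers the period's overall mean daily contact rate.
#'
#' @param diary A [survey_diary()].
#' @param attribute One of `r paste(composition_attributes(), collapse = ", ")`.
#' @return Tibble of class `composition_table` with columns `attribute`,
#'   `period`, `level`, `mean_contacts`, `proportion`.
#' @export
composition_table <- function(diary, attribute = composition_attributes()) {
  attribute <- match.arg(attribute)
  av <- attribute_values(diary, attribute)
  pidx <- match(diary$contacts$date, diary$calendar$days$date)
  period <- diary$calendar$days$period[pidx]
  days_per_period <- table(diary$calendar$days$period)
  n_part <- nrow(diary$participants)

  grid <- tidyr::expand_grid(period = factor(period_levels(),
                                             levels = period_levels()),
                             level = factor(av$levels, levels = av$levels))
  tab <- tibble::tibble(period = period,
                        level = factor(av$x, levels = av$levels)) |>
    dplyr::count(.data$period, .data$level) |>
    dplyr::right_join(grid, by = c("period", "level")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$period) |>
    dplyr::mutate(
      mean_contacts = .data$n /
        (n_part * as.integer(days_per_period[as.character(.data$period)])),
      proportion = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    dplyr::ungroup() |>
    dplyr::mutate(attribute = attribute, .before = 1) |>
    dplyr::select(-"n") |>
    dplyr::arrange(.data$period, .data$level)
  class(tab) <- c("composition_table", class(tab))
  tab
}

#' Cross-tabulated contact-attribute proportions
#'
#' Row-normalised two-way proportions between two contact attributes within
#' a period group (periods I-II pattern alike, as do III-IV). For each row
#' level, the proportions over column levels sum to 1.
#'
#' @param diary A [survey_diary()].
#' @param row_attr,col_attr Attribute names accepted by [composition_table()]
#'   plus `"location"`.
#' @param period_group `"I-II"` or `"III-IV"`.
#' @return Matrix of probabilities, rows = `row_attr` levels, columns =
#'   `col_attr` levels.
#' @export
cross_tab_proportions <- function(diary, row_attr, col_attr,
                                  period_group = c("I-II", "III-IV")) {
  period_group <- match.arg(period_group)
  keep_periods <- if (period_group == "I-II") c("I", "II") else c("III", "IV")
  period <- classify_period(diary$contacts$date, diary$calendar)
  sel <- period %in% keep_periods
  if (!any(sel)) {
    rlang::abort("no contacts in the requested period group",
                 class = "contactdiaries_validation_error")
  }
  sub <- diary
  sub$contacts <- diary$contacts[sel, ]
  rv <- attribute_values(sub, row_attr)
  cv <- attribute_values(sub, col_attr)
  tab <- table(factor(rv$x, levels = rv$levels),
               factor(cv$x, levels = cv$levels))
  prop <- prop.table(tab, margin = 1)
  out <- matrix(as.numeric(prop), nrow = nrow(tab),
                dimnames = list(rv$levels, cv$levels))
  out[rowSums(tab) == 0, ] <- NA_real_
  out
}
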