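# Shared fixtures, built in code.

# minimal two-window calendar: n_a weekdays from Dec 6 2023, n_b days from
# Feb 7 2024, no holidays unless given
short_calendar <- function(n_a = 1L, n_b = 1L, holidays = as.Date(character())) {
  survey_calendar(
    window_a = c(as.Date("2023-12-06"), as.Date("2023-12-06") + n_a - 1L),
    window_b = c(as.Date("2024-02-07"), as.Date("2024-02-07") + n_b - 1L),
    holidays = holidays)
}

make_participants <- function(age = c(30, 8, 70),
                              sex = c("female", "male", "female"),
                              hh = c(2, 4, 1),
                              region = c("Seoul", "Busan", "Jeju")) {
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_along(age)),
    age_years = as.integer(age),
    sex = sex,
    household_size = as.integer(hh),
    region17 = region,
    occupation = "other")
}

make_contact <- function(participant_id, date, contact_age = 30,
                         contact_sex = "female", contact_region = "Seoul",
                         relation = "other", location = "home",
                         duration = "15min-1h", frequency = "daily",
                         physical = FALSE, n = 1L) {
  tibble::tibble(
    participant_id = rep(participant_id, n),
    date = rep(as.Date(date), n),
    contact_age_years = as.integer(rep(contact_age, n)),
    contact_sex = rep(contact_sex, n),
    contact_region17 = rep(contact_region, n),
    relation = rep(relation, n),
    location = rep(location, n),
    duration_class = rep(duration, n),
    frequency_class = rep(frequency, n),
    physical = rep(physical, n))
}

default_population <- function(total = 1e6) {
  w <- default_participant_margins()$age
  tibble::tibble(age_bin = names(w), count = round(total * w / sum(w)))
}

tiny_diary <- function(calendar = survey_calendar()) {
  participants <- make_participants()
  contacts <- dplyr::bind_rows(
    make_contact("P01", "2023-12-06", n = 2L),
    make_contact("P02", "2023-12-09", contact_age = 8, relation = "educational"),
    make_contact("P03", "2024-02-10", contact_age = 40,
                 relation = "extended_family", n = 2L))
  survey_diary(participants, contacts, default_population(), calendar)
}

# generator config with all covariate effects off (flat), explicit moments
flat_config <- function(n = 100, alpha = log(3), tau = 0, phi = 1e8,
                        seed = 1L, ...) {
  bins <- age_bin_labels()
  generator_config(
    n_participants = n, seed = seed, alpha = alpha, tau = tau, phi = phi,
    beta_age = stats::setNames(rep(0, length(bins)), bins),
    beta_hh = stats::setNames(rep(0, 5), household_levels()),
    beta_period = stats::setNames(rep(0, 4), period_levels()),
    beta_sex = stats::setNames(rep(0, 2), sex_levels()),
    ...)
}

# small diary under the default Table-1-calibrated configuration
small_survey <- function(n = 60, seed = 42L) {
  generate_survey(generator_config(n_participants = n, seed = seed))
}
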