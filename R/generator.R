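#' Configuration of the synthetic diary generator
#'
#' Builds the parameter set that drives [generate_survey()]. The generative
#' model mirrors the analysis model: each participant carries a lognormal
#' random intercept `effect ~ N(0, tau)` constant across the 14 diary days,
#' and daily contact counts are negative binomial with mean
#' `exp(alpha + beta_age + beta_hh + beta_period + beta_sex + effect)` and
#' dispersion `phi`. Reference levels (age 0-4, household size 1, period I,
#' female) carry coefficient 0.
#'
#' Default coefficients are the logs of the crude rate ratios of the study's
#' covariate summary (age, sex, period, household size); default sampling
#' weights are the study's participant margins. The intercept `alpha` and
#' dispersion `phi` are calibrated in closed form so that the marginal mean
#' and variance of daily counts match `target_mean` and `target_variance`
#' (defaults 4.81 contacts/participant/day and 16.57, a variance-to-mean
#' ratio of about 3.4). With independent covariate margins,
#' `E(count) = exp(alpha + tau^2/2) * prod_c sum_l w_cl exp(beta_cl)`, which
#' is solved for `alpha`; `phi` is then solved from
#' `Var(count) = E(mu) + E(mu^2)/phi + Var(mu)`.
#'
#' Contact attributes (relation, location, duration, frequency, physical
#' type) are drawn from period-specific categorical kernels; the defaults
#' qualitatively reproduce the study's period contrasts (school-vacation
#' drop in educational contacts, weekend drop in coworker contacts, Lunar
#' New Year surge in extended-family, long-duration, physical and
#' cross-region contacts). Contact ages come from a two-component kernel:
#' probability `p_same_age` of an age in the participant's own bin
#' (assortative mass), otherwise an age drawn from the population
#' distribution; assortativity is lower in period IV. Contact regions equal
#' the participant's region with probability `p_within_region`, lower in
#' period IV.
#'
#' @param n_participants Number of participants (default 1987).
#' @param seed Default seed used by the generator functions.
#' @param tau Random-intercept SD on the log scale.
#' @param target_mean,target_variance Marginal moments of daily counts used
#'   to calibrate `alpha` and `phi`.
#' @param alpha,phi Optional explicit intercept / dispersion, overriding the
#'   calibration.
#' @param beta_age,beta_hh,beta_period,beta_sex Named log-rate-ratio
#'   vectors; reference levels must be 0.
#' @param age_weights,hh_weights,sex_weights,region17_weights Named sampling
#'   weights (normalised internally).
#' @param population_weights Named age-bin weights of the reference
#'   population; defaults to `age_weights` (quota sampling matches the
#'   population margins).
#' @param population_total National population size used to scale
#'   `population_weights` into counts `G_j`.
#' @param kernels Per-period attribute kernels as produced by
#'   [default_attribute_kernels()]; entries can be selectively overridden.
#' @param age_breaks Age-bin lower edges, see [age_breaks_analysis()].
#' @param calendar Calendar used for period day-shares in the calibration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 1987,
                             seed = 1L,
                             tau = 0.4,
                             target_mean = 4.81,
                             target_variance = 16.57,
                             alpha = NULL,
                             phi = NULL,
                             beta_age = NULL,
                             beta_hh = NULL,
                             beta_period = NULL,
                             beta_sex = NULL,
                             age_weights = NULL,
                             hh_weights = NULL,
                             sex_weights = NULL,
                             region17_weights = NULL,
                             population_weights = NULL,
                             population_total = 5.13e7,
                             kernels = default_attribute_kernels(),
                             age_breaks = age_breaks_analysis(),
                             calendar = survey_calendar()) {
  bins <- age_bin_labels(age_breaks)

  if (is.null(beta_age)) beta_age <- log(default_crude_ratios()$age)
  if (is.null(beta_hh)) beta_hh <- log(default_crude_ratios()$household)
  if (is.null(beta_period)) beta_period <- log(default_crude_ratios()$period)
  if (is.null(beta_sex)) beta_sex <- log(default_crude_ratios()$sex)

  if (is.null(age_weights)) age_weights <- default_participant_margins()$age
  if (is.null(hh_weights)) hh_weights <- default_participant_margins()$household
  if (is.null(sex_weights)) sex_weights <- default_participant_margins()$sex
  if (is.null(region17_weights)) region17_weights <- default_region17_weights()
  if (is.null(population_weights)) population_weights <- age_weights

  norm_w <- function(w, what) {
    if (any(w < 0) || sum(w) <= 0) {
      rlang::abort(paste0("degenerate ", what, " weights"),
                   class = "contactdiaries_config_error")
    }
    w / sum(w)
  }
  age_weights <- norm_w(age_weights, "age")
  hh_weights <- norm_w(hh_weights, "household")
  sex_weights <- norm_w(sex_weights, "sex")
  region17_weights <- norm_w(region17_weights, "region")
  population_weights <- norm_w(population_weights, "population")

  stopifnot(identical(names(beta_age), bins),
            identical(names(age_weights), bins),
            identical(names(population_weights), bins),
            identical(names(beta_hh), household_levels()),
            identical(names(beta_period), period_levels()),
            identical(names(beta_sex), sex_levels()))
  ref_zero <- c(beta_age[1], beta_hh[1], beta_period[1], beta_sex[1])
  if (any(ref_zero != 0)) {
    rlang::abort("reference-level coefficients must be 0",
                 class = "contactdiaries_config_error")
  }
  if (tau < 0) {
    rlang::abort("tau must be non-negative", class = "contactdiaries_config_error")
  }

  day_shares <- prop.table(table(calendar$days$period))[period_levels()]

  # closed-form calibration of alpha and phi from the target moments
  e_b <- sum(age_weights * exp(beta_age)) *
         sum(hh_weights * exp(beta_hh)) *
         sum(sex_weights * exp(beta_sex)) *
         sum(as.numeric(day_shares) * exp(beta_period))
  if (is.null(alpha)) alpha <- log(target_mean) - tau^2 / 2 - log(e_b)
  if (is.null(phi)) {
    e_b2 <- sum(age_weights * exp(2 * beta_age)) *
            sum(hh_weights * exp(2 * beta_hh)) *
            sum(sex_weights * exp(2 * beta_sex)) *
            sum(as.numeric(day_shares) * exp(2 * beta_period))
    e_mu <- exp(alpha + tau^2 / 2) * e_b
    e_mu2 <- exp(2 * alpha + 2 * tau^2) * e_b2
    denom <- target_variance - e_mu - (e_mu2 - e_mu^2)
    if (denom <= 0) {
      rlang::abort(
        "target variance too small for the covariate spread; no positive phi exists",
        class = "contactdiaries_config_error")
    }
    phi <- e_mu2 / denom
  }
  if (phi <= 0) {
    rlang::abort("phi must be positive", class = "contactdiaries_config_error")
  }

  structure(
    list(n_participants = n_participants, seed = seed,
         alpha = alpha, tau = tau, phi = phi,
         beta_age = beta_age, beta_hh = beta_hh,
         beta_period = beta_period, beta_sex = beta_sex,
         age_weights = age_weights, hh_weights = hh_weights,
         sex_weights = sex_weights, region17_weights = region17_weights,
         population_weights = population_weights,
         population_total = population_total,
         kernels = kernels, age_breaks = age_breaks),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  participants:", x$n_participants, " seed:", x$seed, "\n")
  cat(sprintf("  alpha: %.4f  tau: %.3f  phi: %.3f\n", x$alpha, x$tau, x$phi))
  cat("  age bins:", paste(names(x$beta_age), collapse = " "), "\n")
  invisible(x)
}

#' Study crude rate ratios used as default generator coefficients
#'
#' @return Named list of crude-ratio vectors by covariate; reference levels
#'   are 1.
#' @export
default_crude_ratios <- function() {
  list(
    age = c("0-4" = 1, "5-9" = 1.50, "10-14" = 1.50, "15-19" = 1.40,
            "20-29" = 0.57, "30-39" = 0.62, "40-49" = 0.72, "50-59" = 0.78,
            "60-69" = 0.92, "70+" = 0.97),
    household = c("1" = 1, "2" = 1.30, "3" = 1.40, "4" = 1.50, "5+" = 1.80),
    period = c(I = 1, II = 0.89, III = 0.67, IV = 0.81),
    sex = c(female = 1, male = 0.99)
  )
}

#' Study participant margins used as default sampling weights
#'
#' @return Named list of count vectors (age bins, household classes, sex).
#' @export
default_participant_margins <- function() {
  list(
    age = c("0-4" = 60, "5-9" = 84, "10-14" = 96, "15-19" = 83,
            "20-29" = 256, "30-39" = 292, "40-49" = 352, "50-59" = 316,
            "60-69" = 273, "70+" = 166),
    household = c("1" = 254, "2" = 453, "3" = 583, "4" = 561, "5+" = 136),
    sex = c(female = 1036, male = 951)
  )
}

# Approximate resident-population sizes (millions) of the 17 provincial
# regions, used as quota weights.
default_region17_weights <- function() {
  c(Seoul = 9.4, Incheon = 3.0, Gyeonggi = 13.6,
    Daejeon = 1.44, Sejong = 0.39, Chungbuk = 1.59, Chungnam = 2.13,
    Gangwon = 1.53,
    Busan = 3.3, Daegu = 2.37, Ulsan = 1.1, Gyeongbuk = 2.55, Gyeongnam = 3.25,
    Gwangju = 1.42, Jeonbuk = 1.75, Jeonnam = 1.8, Jeju = 0.68)
}

#' Default period-specific contact-attribute kernels
#'
#' One categorical distribution per period and attribute. The period
#' contrasts are qualitative emulations of the survey's composition results:
#' educational contacts halve in the vacation week, coworker and educational
#' contacts collapse at weekends, and the Lunar New Year holidays (period
#' IV) boost extended-family, infrequent, long-duration, physical and
#' cross-region contacts while lowering age assortativity.
#'
#' @return Named list with matrices `relation`, `location`, `duration`,
#'   `frequency` (rows = periods I-IV, columns = levels) and per-period
#'   probability vectors `physical`, `p_same_age`, `p_within_region`, plus
#'   scalars `p_unknown_age`, `p_unknown_sex`, `p_unknown_region`.
#' @export
default_attribute_kernels <- function() {
  per <- period_levels()
  m <- function(levels, ...) {
    x <- rbind(...)
    dimnames(x) <- list(per, levels)
    sweep(x, 1, rowSums(x), "/")
  }
  list(
    relation = m(relation_levels(),
      c(0.32, 0.02, 0.04, 0.25, 0.25, 0.12),
      c(0.36, 0.03, 0.05, 0.28, 0.13, 0.15),
      c(0.45, 0.06, 0.10, 0.05, 0.04, 0.30),
      c(0.40, 0.22, 0.06, 0.05, 0.03, 0.24)),
    location = m(location_levels(),
      c(0.30, 0.25, 0.22, 0.23),
      c(0.35, 0.28, 0.10, 0.27),
      c(0.45, 0.06, 0.04, 0.45),
      c(0.50, 0.04, 0.03, 0.43)),
    duration = m(duration_levels(),
      c(0.15, 0.20, 0.25, 0.22, 0.18),
      c(0.15, 0.20, 0.25, 0.20, 0.20),
      c(0.15, 0.18, 0.24, 0.20, 0.23),
      c(0.12, 0.15, 0.20, 0.22, 0.31)),
    frequency = m(frequency_levels(),
      c(0.40, 0.22, 0.12, 0.08, 0.08, 0.10),
      c(0.45, 0.15, 0.12, 0.09, 0.09, 0.10),
      c(0.50, 0.10, 0.12, 0.10, 0.08, 0.10),
      c(0.45, 0.08, 0.10, 0.12, 0.15, 0.10)),
    physical = c(I = 0.35, II = 0.35, III = 0.40, IV = 0.50),
    p_same_age = c(I = 0.55, II = 0.55, III = 0.45, IV = 0.35),
    p_within_region = c(I = 0.95, II = 0.95, III = 0.93, IV = 0.82),
    p_unknown_age = 0.03,
    p_unknown_sex = 0.02,
    p_unknown_region = 0.05
  )
}

sample_level <- function(n, levels, prob) {
  if (n == 0L) return(character())
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

# uniform integer age within the bin containing each `bin_idx`; the open top
# bin spans 20 years
sample_age_in_bin <- function(bin_idx, breaks) {
  lo <- breaks[bin_idx]
  hi <- c(breaks[-1], breaks[length(breaks)] + 20L)[bin_idx]
  lo + floor(stats::runif(length(bin_idx)) * (hi - lo))
}

#' Generate a synthetic participant table
#'
#' Ages are drawn within bins proportional to the configured age weights
#' (uniformly inside each bin), regions by provincial population weights,
#' household-size class and sex by the configured margins. Deterministic
#' given the seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Tibble of participants matching the diary schema.
#' @export
generate_participants <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  if (n < 1) {
    rlang::abort("n_participants must be >= 1",
                 class = "contactdiaries_config_error")
  }
  set.seed(seed)
  breaks <- config$age_breaks
  bin_idx <- sample.int(length(config$age_weights), n, replace = TRUE,
                        prob = config$age_weights)
  age <- sample_age_in_bin(bin_idx, breaks)
  hh_class <- sample_level(n, household_levels(), config$hh_weights)
  hh_size <- as.integer(replace(hh_class, hh_class == "5+", "5")) +
    ifelse(hh_class == "5+", stats::rbinom(n, 2L, 0.2), 0L)
  occupations <- c("office_technical", "student", "homemaker", "service_sales",
                   "professional", "retired_unemployed", "preschool", "other")
  occ_w <- c(0.331, 0.165, 0.135, 0.12, 0.08, 0.10, 0.04, 0.029)
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    age_years = as.integer(age),
    sex = sample_level(n, sex_levels(), config$sex_weights),
    household_size = as.integer(hh_size),
    region17 = sample_level(n, names(config$region17_weights),
                            config$region17_weights),
    occupation = sample_level(n, occupations, occ_w)
  ) |>
    derive_participant_fields()
}

#' Generate daily contact counts
#'
#' One row per participant-day. Each participant receives a random intercept
#' `effect ~ N(0, tau)` held constant across days; the count for a day in
#' period `p` is negative binomial with mean
#' `exp(alpha + beta_age + beta_hh + beta_period[p] + beta_sex + effect)`
#' and dispersion `phi`.
#'
#' @param participants Participant table from [generate_participants()].
#' @param calendar A [survey_calendar()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Tibble with columns `participant_id`, `date`, `period`,
#'   `n_contacts`.
#' @export
generate_counts <- function(participants, calendar, config,
                            seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$phi <= 0) {
    rlang::abort("phi must be positive", class = "contactdiaries_config_error")
  }
  if (config$tau < 0) {
    rlang::abort("tau must be non-negative", class = "contactdiaries_config_error")
  }
  set.seed(seed)
  n <- nrow(participants)
  effects <- stats::rnorm(n, 0, config$tau)
  bins <- age_bin(participants$age_years, config$age_breaks)
  eta_p <- config$alpha +
    config$beta_age[as.character(bins)] +
    config$beta_hh[as.character(participants$household_size_class)] +
    config$beta_sex[participants$sex] +
    effects

  days <- calendar$days
  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    date = days$date
  )
  grid$period <- days$period[match(grid$date, days$date)]
  eta <- rep(eta_p, each = nrow(days)) +
    config$beta_period[as.character(grid$period)]
  grid$n_contacts <- stats::rnbinom(nrow(grid), size = config$phi,
                                    mu = exp(unname(eta)))
  grid
}

#' Generate contact records from daily counts
#'
#' Expands each participant-day into exactly `n_contacts` records, drawing
#' every attribute from the period's kernel. Contact age uses the
#' assortative two-component kernel; contact region equals the participant's
#' region with the period's within-region probability. A small configured
#' fraction of contact ages, sexes and regions is masked to `"unknown"` /
#' `NA`.
#'
#' @inheritParams generate_counts
#' @param counts Output of [generate_counts()].
#' @return Tibble of contact records matching the diary schema.
#' @export
generate_contacts <- function(counts, participants, config,
                              seed = config$seed + 2L) {
  stopifnot(inherits(config, "generator_config"))
  K <- config$kernels
  for (att in c("relation", "location", "duration", "frequency")) {
    if (!identical(rownames(K[[att]]), period_levels())) {
      rlang::abort(paste0("kernel '", att, "' must have one row per period"),
                   class = "contactdiaries_config_error")
    }
  }
  set.seed(seed)
  keep <- counts$n_contacts > 0L
  idx <- rep(which(keep), counts$n_contacts[keep])
  m <- length(idx)
  period <- as.character(counts$period[idx])

  p_match <- match(counts$participant_id[idx], participants$participant_id)
  part_bin_idx <- as.integer(age_bin(participants$age_years,
                                     config$age_breaks))[p_match]
  part_region <- participants$region17[p_match]

  draw_attr <- function(kernel) {
    out <- character(m)
    for (p in period_levels()) {
      sel <- period == p
      out[sel] <- sample_level(sum(sel), colnames(kernel), kernel[p, ])
    }
    out
  }

  same_age <- stats::runif(m) < unname(K$p_same_age[period])
  bg_bin <- sample.int(length(config$population_weights), m, replace = TRUE,
                       prob = config$population_weights)
  c_bin <- ifelse(same_age, part_bin_idx, bg_bin)
  c_age <- sample_age_in_bin(c_bin, config$age_breaks)

  within <- stats::runif(m) < unname(K$p_within_region[period])
  bg_region <- sample_level(m, names(config$region17_weights),
                            config$region17_weights)
  c_region <- ifelse(within, part_region, bg_region)

  c_sex <- sample_level(m, sex_levels(), config$sex_weights)

  unk <- unknown_label()
  c_age[stats::runif(m) < K$p_unknown_age] <- NA_integer_
  c_sex[stats::runif(m) < K$p_unknown_sex] <- unk
  c_region[stats::runif(m) < K$p_unknown_region] <- unk

  tibble::tibble(
    participant_id = counts$participant_id[idx],
    date = counts$date[idx],
    contact_age_years = as.integer(c_age),
    contact_sex = c_sex,
    contact_region17 = c_region,
    relation = draw_attr(K$relation),
    location = draw_attr(K$location),
    duration_class = draw_attr(K$duration),
    frequency_class = draw_attr(K$frequency),
    physical = stats::runif(m) < unname(K$physical[period])
  )
}

#' Generate a complete synthetic survey diary
#'
#' Composes [generate_participants()], [generate_counts()] and
#' [generate_contacts()] and attaches a population table obtained by scaling
#' the configured population age weights to `population_total`. The result
#' passes all diary validations and is byte-identical under a fixed seed.
#'
#' @inheritParams generate_counts
#' @return A validated [survey_diary()].
#' @export
generate_survey <- function(config = generator_config(),
                            calendar = survey_calendar(),
                            seed = config$seed) {
  participants <- generate_participants(config, seed = seed)
  counts <- generate_counts(participants, calendar, config, seed = seed + 1L)
  contacts <- generate_contacts(counts, participants, config, seed = seed + 2L)
  population <- tibble::tibble(
    age_bin = names(config$population_weights),
    count = unname(round(config$population_weights * config$population_total))
  )
  survey_diary(participants, contacts, population, calendar)
}

#' Expected contact matrix under a generator configuration
#'
#' Closed-form expectation of the (raw, per-participant-per-day) age-grouped
#' contact matrix implied by the generator: for a participant in age bin
#' `j`, the expected number of daily contacts with bin-`i` persons in period
#' `p` is `mu_jp * ((1 - u) * (s_p 1[i=j] + (1 - s_p) w_i))`, where `mu_jp`
#' is the marginal NB mean for bin `j` in period `p` (averaging the
#' household, sex and random-effect margins), `s_p` the assortative mass,
#' `w` the population age weights and `u` the unknown-age masking fraction
#' (unknown-age contacts are excluded from age matrices). Periods are
#' averaged with their day shares unless a single period is requested.
#'
#' Used as the ground truth in bootstrap-coverage experiments.
#'
#' @param config A [generator_config()].
#' @param calendar A [survey_calendar()].
#' @param period Optional single period label to condition on.
#' @return Square matrix, rows = contact age bin, columns = participant bin.
#' @export
expected_contact_matrix <- function(config, calendar = survey_calendar(),
                                    period = NULL) {
  bins <- names(config$age_weights)
  nb <- length(bins)
  shares <- prop.table(table(calendar$days$period))[period_levels()]
  if (!is.null(period)) {
    stopifnot(period %in% period_levels())
    shares[] <- 0
    shares[period] <- 1
  }
  e_hh <- sum(config$hh_weights * exp(config$beta_hh))
  e_sex <- sum(config$sex_weights * exp(config$beta_sex))
  base_j <- exp(config$alpha + config$beta_age + config$tau^2 / 2) *
    e_hh * e_sex
  u <- config$kernels$p_unknown_age
  w <- config$population_weights
  m <- matrix(0, nb, nb, dimnames = list(bins, bins))
  for (p in period_levels()) {
    if (shares[p] == 0) next
    s <- config$kernels$p_same_age[p]
    mu_jp <- base_j * exp(config$beta_period[p])
    kern <- (1 - s) * matrix(w, nb, nb) + s * diag(nb)
    m <- m + as.numeric(shares[p]) * (1 - u) *
      sweep(kern, 2, mu_jp, "*")
  }
  m
}
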