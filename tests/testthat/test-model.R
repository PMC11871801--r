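# model tests use uniform age weights so every design level is observed in
# small samples
uniform_cfg <- function(n, seed, ...) {
  bins <- age_bin_labels()
  w <- stats::setNames(rep(1, length(bins)), bins)
  generator_config(n_participants = n, seed = seed, age_weights = w,
                   population_weights = w, ...)
}

ratio_truth <- function(cfg) {
  c(exp(cfg$beta_age[-1]), exp(cfg$beta_hh[-1]), exp(cfg$beta_period[-1]),
    exp(cfg$beta_sex[-1]))
}

fit_errors <- function(fit, cfg) {
  rr <- rate_ratio_table(fit)
  rr <- rr[!rr$reference, ]
  key <- paste0(rr$term, ":", rr$level)
  truth <- ratio_truth(cfg)
  names(truth) <- sub("^beta_", "", names(truth))
  tr <- c(exp(cfg$beta_age), exp(cfg$beta_hh), exp(cfg$beta_period),
          exp(cfg$beta_sex))
  names(tr) <- c(paste0("age:", names(cfg$beta_age)),
                 paste0("household:", names(cfg$beta_hh)),
                 paste0("period:", names(cfg$beta_period)),
                 paste0("sex:", names(cfg$beta_sex)))
  abs(rr$estimate - tr[key]) / tr[key]
}

test_that("linear predictor reproduces closed-form cases and a matrix oracle", {
  d <- small_survey(n = 25, seed = 61L)
  md <- contactdiaries:::build_model_data(d)
  cols <- colnames(md$X)[-1]
  params0 <- model_parameters(
    alpha = log(3), beta = stats::setNames(rep(0, length(cols)), cols),
    effects = stats::setNames(rep(0, 25), d$participants$participant_id),
    tau = 0.5, phi = 5)
  lp <- linear_predictor(d, params0)
  expect_true(all(abs(lp$mu - 3) < 1e-12))

  # male/female ratio equals exp(beta_sex) when all else is reference
  params1 <- params0
  params1$beta["sex:male"] <- log(0.94)
  lp1 <- linear_predictor(d, params1)
  sex <- d$participants$sex[match(lp1$participant_id,
                                  d$participants$participant_id)]
  expect_equal(mean(lp1$mu[sex == "male"]) / mean(lp1$mu[sex == "female"]),
               0.94)

  # random parameters against explicit design-matrix multiplication
  set.seed(62)
  paramsr <- params0
  paramsr$alpha <- stats::rnorm(1)
  paramsr$beta[] <- stats::rnorm(length(cols), 0, 0.3)
  paramsr$effects[] <- stats::rnorm(25, 0, 0.2)
  lp2 <- linear_predictor(d, paramsr)
  mu_oracle <- exp(as.numeric(md$X %*% c(paramsr$alpha, paramsr$beta)) +
                     paramsr$effects[md$pid])
  expect_equal(lp2$mu, mu_oracle)
  bad <- paramsr
  bad$beta <- bad$beta[-1]
  expect_error(linear_predictor(d, bad),
               class = "contactdiaries_validation_error")
})

test_that("log posterior is additive in observations and honours its formula", {
  cal <- short_calendar()
  p1 <- make_participants(age = 30, sex = "female", hh = 1, region = "Seoul")
  ct1 <- dplyr::bind_rows(make_contact("P01", "2023-12-06", n = 4L),
                          make_contact("P01", "2024-02-07", n = 1L))
  d1 <- survey_diary(p1, ct1, default_population(), cal)
  # identical twin participant doubles likelihood and effect terms only
  p2 <- dplyr::bind_rows(p1, dplyr::mutate(p1, participant_id = "P02"))
  ct2 <- dplyr::bind_rows(ct1, dplyr::mutate(ct1, participant_id = "P02"))
  d2 <- survey_diary(p2, ct2, default_population(), cal)

  pri <- prior_spec(alpha_location = log(2))
  cols1 <- colnames(contactdiaries:::build_model_data(d1)$X)[-1]
  mk <- function(ids, e) model_parameters(
    alpha = log(2.5), beta = stats::setNames(rep(0.1, length(cols1)), cols1),
    effects = stats::setNames(rep(e, length(ids)), ids), tau = 0.4, phi = 3)
  lp1 <- log_posterior(d1, mk("P01", 0.2), pri)
  lp2 <- log_posterior(d2, mk(c("P01", "P02"), 0.2), pri)
  prior_part <- stats::dnorm(log(2.5), log(2), 1.5, log = TRUE) +
    sum(stats::dnorm(rep(0.1, length(cols1)), 0, 2.5, log = TRUE)) +
    stats::dnorm(0.4, 0, 1, log = TRUE) + log(2) +
    stats::dexp(3, 0.1, log = TRUE)
  expect_equal(lp2 - lp1, lp1 - prior_part)

  # out-of-support parameters by contract
  bad <- mk("P01", 0)
  bad$tau <- -1
  expect_identical(log_posterior(d1, bad, pri), -Inf)
})

test_that("log posterior gradient matches finite differences", {
  d <- small_survey(n = 10, seed = 63L)
  md <- contactdiaries:::build_model_data(d)
  cols <- colnames(md$X)[-1]
  pri <- prior_spec(alpha_location = log(3))
  set.seed(64)
  params <- model_parameters(
    alpha = log(3) + 0.2,
    beta = stats::setNames(stats::rnorm(length(cols), 0, 0.2), cols),
    effects = stats::setNames(stats::rnorm(10, 0, 0.3),
                              d$participants$participant_id),
    tau = 0.45, phi = 4.2)

  lp <- function(pp) log_posterior(d, pp, pri)
  num_grad <- function(set, h = 1e-6) {
    up <- set(params, h); dn <- set(params, -h)
    (lp(up) - lp(dn)) / (2 * h)
  }
  eta <- log(linear_predictor(d, params)$mu)
  mu <- exp(eta)
  y <- md$y
  phi <- params$phi
  r <- phi * (y - mu) / (mu + phi)

  # alpha
  g_alpha <- sum(r) - (params$alpha - log(3)) / 1.5^2
  expect_equal(num_grad(function(p, h) {p$alpha <- p$alpha + h; p}),
               g_alpha, tolerance = 1e-4)
  # one coefficient (period III touches a subset of rows)
  k <- which(colnames(md$X) == "period:III")
  g_beta <- sum(r[md$X[, k] == 1]) - params$beta[["period:III"]] / 2.5^2
  expect_equal(num_grad(function(p, h) {
    p$beta["period:III"] <- p$beta[["period:III"]] + h; p}),
    g_beta, tolerance = 1e-4)
  # tau (half-normal prior scale 1)
  e <- unname(params$effects)
  g_tau <- sum(e^2 / params$tau^3 - 1 / params$tau) - params$tau
  expect_equal(num_grad(function(p, h) {p$tau <- p$tau + h; p}),
               g_tau, tolerance = 1e-4)
  # phi
  g_phi <- sum(digamma(y + phi) - digamma(phi) + log(phi / (mu + phi)) +
                 1 - (y + phi) / (mu + phi)) - 0.1
  expect_equal(num_grad(function(p, h) {p$phi <- p$phi + h; p}),
               g_phi, tolerance = 1e-4)
  # one participant effect
  i1 <- md$pid == 1L
  g_e1 <- sum(r[i1]) - e[1] / params$tau^2
  expect_equal(num_grad(function(p, h) {p$effects[1] <- p$effects[1] + h; p}),
               g_e1, tolerance = 1e-4)
})

test_that("MAP recovers generator rate ratios on a medium synthetic diary", {
  cfg <- uniform_cfg(400, seed = 71L)
  d <- generate_survey(cfg)
  fit <- fit_map(d)
  expect_true(fit$converged)
  err <- fit_errors(fit, cfg)
  # strongly identified within-participant contrasts
  expect_lt(err[["period:III"]], 0.15)
  expect_lt(err[["period:II"]], 0.15)
  expect_lt(err[["age:5-9"]], 0.15)
  expect_lt(stats::median(err), 0.10)
  expect_lt(abs(fit$params$tau - cfg$tau), 0.15)
})

test_that("MAP drives tau to zero when the generator has no random effect", {
  cfg <- uniform_cfg(200, seed = 73L, tau = 1e-6)
  d <- generate_survey(cfg)
  fit <- fit_map(d)
  expect_lt(fit$params$tau, 0.05)
})

test_that("duplicating the data leaves the MAP point essentially unchanged", {
  cfg <- uniform_cfg(120, seed = 75L)
  d <- generate_survey(cfg)
  d2 <- d
  d2$participants <- dplyr::bind_rows(
    d$participants,
    dplyr::mutate(d$participants, participant_id = paste0(participant_id, "b")))
  d2$contacts <- dplyr::bind_rows(
    d$contacts,
    dplyr::mutate(d$contacts, participant_id = paste0(participant_id, "b")))
  f1 <- fit_map(d)
  f2 <- fit_map(d2)
  expect_lt(max(abs(log(f2$rate_ratios$estimate) -
                      log(f1$rate_ratios$estimate))), 0.02)
})

test_that("the MCMC sampler recovers truth and agrees with the MAP fit", {
  cfg <- uniform_cfg(150, seed = 77L)
  d <- generate_survey(cfg)
  fit <- suppressWarnings(
    fit_mcmc(d, chains = 2L, iterations = 900L, warmup = 300L, seed = 3L))
  expect_equal(nrow(fit$diagnostics), ncol(fit$md$X) + 2L)
  expect_lt(max(fit$diagnostics$rhat), 1.05)
  err <- fit_errors(fit, cfg)
  expect_lt(err[["period:III"]], 0.20)
  expect_lt(err[["period:IV"]], 0.20)
  expect_lt(stats::median(err), 0.20)

  # MAP and posterior medians agree within posterior spread
  fmap <- fit_map(d)
  pooled <- do.call(rbind, fit$draws)
  sds <- apply(pooled[, 2:ncol(fit$md$X)], 2, stats::sd)
  gap <- abs(log(fmap$rate_ratios$estimate[!fmap$rate_ratios$reference]) -
               log(fit$rate_ratios$estimate[!fit$rate_ratios$reference]))
  expect_lt(max(gap / (3 * sds)), 1)

  # posterior quantile structure of the rate-ratio table
  rr <- rate_ratio_table(fit)
  expect_true(all(rr$conf_low <= rr$estimate & rr$estimate <= rr$conf_high))
  refs <- rr[rr$reference, ]
  expect_true(all(refs$estimate == 1 & refs$conf_low == 1 & refs$conf_high == 1))
})

test_that("an all-zero-count diary pulls the intercept below its prior location", {
  cal <- survey_calendar()
  p <- make_participants(age = c(30, 40), sex = c("female", "male"),
                         hh = c(1, 1), region = c("Seoul", "Seoul"))
  d <- survey_diary(p, make_contact("P01", "2023-12-06")[0, ],
                    default_population(), cal)
  pri <- prior_spec(alpha_location = log(3))
  fit <- suppressWarnings(
    fit_mcmc(d, priors = pri, covariates = c("period", "sex"),
             chains = 2L, iterations = 400L, warmup = 150L, seed = 9L))
  pooled <- do.call(rbind, fit$draws)
  expect_lt(stats::median(pooled[, 1]), log(3))
})

test_that("predictive comparison prefers the generating covariate set", {
  cfg <- uniform_cfg(120, seed = 79L)
  d <- generate_survey(cfg)
  cmp <- suppressWarnings(compare_models(
    d,
    models = list(full = c("age", "sex", "period", "household"),
                  no_period = c("age", "sex", "household")),
    chains = 2L, iterations = 500L, warmup = 200L, seed = 11L))
  expect_equal(cmp$model[which.max(cmp$elpd_waic)], "full")
  expect_equal(cmp$model[which.max(cmp$elpd_loo)], "full")
  expect_lt(cmp$delta_elpd_waic[cmp$model == "no_period"], -10)
})

test_that("MAP estimates agree with an independent mixed-model fit (glmmTMB)", {
  skip_if_not_installed("glmmTMB")
  cfg <- uniform_cfg(250, seed = 81L)
  d <- generate_survey(cfg)
  counts <- daily_counts(d)
  pidx <- match(counts$participant_id, d$participants$participant_id)
  df <- data.frame(
    y = counts$n_contacts,
    age = factor(as.character(age_bin(d$participants$age_years))[pidx],
                 levels = age_bin_labels()),
    hh = factor(as.character(d$participants$household_size_class)[pidx],
                levels = household_levels()),
    period = factor(as.character(counts$period), levels = period_levels()),
    sex = factor(d$participants$sex[pidx], levels = sex_levels()),
    id = counts$participant_id)
  ref <- glmmTMB::glmmTMB(y ~ age + hh + period + sex + (1 | id),
                          family = glmmTMB::nbinom2, data = df)
  fe <- glmmTMB::fixef(ref)$cond
  fit <- fit_map(d)
  rr <- fit$rate_ratios[!fit$rate_ratios$reference, ]
  ours <- stats::setNames(log(rr$estimate), paste0(rr$term, rr$level))
  key <- sub("^hh", "household", names(fe[-1]))
  theirs <- stats::setNames(unname(fe[-1]),
                            sub("^(age|household|period|sex)", "\\1", key))
  theirs <- stats::setNames(unname(fe[-1]), key)
  expect_lt(max(abs(ours[names(theirs)] - theirs)), 0.08)
  tau_ref <- sqrt(glmmTMB::VarCorr(ref)$cond$id[1])
  expect_lt(abs(fit$params$tau - tau_ref), 0.1)
  expect_lt(abs(log(fit$params$phi) - log(stats::sigma(ref))), 0.3)
})
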