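# Model frame and posterior density of the negative-binomial
# random-intercept regression of daily contact counts.

#' Prior specification for the contact-rate model
#'
#' Weakly-informative defaults: Normal(0, 2.5) on covariate coefficients,
#' Normal(log of the observed mean count, 1.5) on the intercept,
#' half-Normal(0, 1) on the random-intercept SD `tau` and Exponential(0.1)
#' on the dispersion `phi`. All are overridable.
#'
#' @param coef_scale SD of the Normal prior on non-intercept coefficients.
#' @param alpha_location Location of the intercept prior; `NULL` means
#'   `log(mean(y))` computed from the data at fit time.
#' @param alpha_scale SD of the intercept prior.
#' @param tau_scale Scale of the half-Normal prior on `tau`.
#' @param phi_rate Rate of the Exponential prior on `phi`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_scale = 2.5, alpha_location = NULL,
                       alpha_scale = 1.5, tau_scale = 1, phi_rate = 0.1) {
  stopifnot(coef_scale > 0, alpha_scale > 0, tau_scale > 0, phi_rate > 0)
  structure(list(coef_scale = coef_scale, alpha_location = alpha_location,
                 alpha_scale = alpha_scale, tau_scale = tau_scale,
                 phi_rate = phi_rate),
            class = "prior_spec")
}

model_covariates <- function() c("age", "sex", "period", "household")

# Flattens a diary into the regression frame: response vector, dense design
# matrix with treatment contrasts (reference levels: age 0-4, household 1,
# period I, female), participant index, and per-column row index sets used
# by the samplers for incremental likelihood updates.
build_model_data <- function(diary, covariates = model_covariates(),
                             require_identifiable = FALSE) {
  stopifnot(inherits(diary, "survey_diary"))
  covariates <- match.arg(covariates, model_covariates(), several.ok = TRUE)
  counts <- daily_counts(diary)
  p <- diary$participants
  pidx <- match(counts$participant_id, p$participant_id)

  df <- tibble::tibble(row = seq_len(nrow(counts)))
  if ("age" %in% covariates) {
    df$age <- factor(as.character(age_bin(p$age_years))[pidx],
                     levels = age_bin_labels())
  }
  if ("household" %in% covariates) {
    df$household <- factor(as.character(p$household_size_class)[pidx],
                           levels = household_levels())
  }
  if ("period" %in% covariates) {
    df$period <- factor(as.character(counts$period), levels = period_levels())
  }
  if ("sex" %in% covariates) {
    df$sex <- factor(p$sex[pidx], levels = sex_levels())
  }
  terms <- intersect(c("age", "household", "period", "sex"), covariates)
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, df)
  observed <- colSums(abs(X)) > 0
  if (!all(observed)) {
    if (require_identifiable) {
      rlang::abort(paste0("unidentifiable design; unobserved level(s): ",
                          paste(colnames(X)[!observed], collapse = ", ")),
                   class = "contactdiaries_validation_error")
    }
    X <- X[, observed, drop = FALSE]
  }
  # readable column labels: term:level
  labels <- colnames(X)
  for (tm in terms) {
    labels <- sub(paste0("^", tm), paste0(tm, ":"), labels)
  }
  labels[1] <- "(Intercept)"
  colnames(X) <- labels

  col_rows <- lapply(seq_len(ncol(X)), function(k) which(X[, k] != 0))
  # participants fully contained in a column's row set (participant-level
  # covariates); used by the sampler for likelihood-invariant shift moves
  col_parts <- lapply(col_rows, function(rows) {
    pids <- unique(pidx[rows])
    if (length(rows) == sum(tabulate(pidx, nrow(p))[pids])) pids else NULL
  })
  list(y = counts$n_contacts,
       X = X,
       pid = pidx,
       n_part = nrow(p),
       participant_id = p$participant_id,
       covariates = covariates,
       col_rows = col_rows,
       col_parts = col_parts)
}

#' Model parameters of the contact-rate regression
#'
#' Bundles the intercept, the named non-reference coefficient vector (log
#' rate ratios), the participant random intercepts and the positive scale
#' parameters into a `model_parameters` object. Reference levels carry no
#' parameter.
#'
#' @param alpha Intercept on the log scale.
#' @param beta Named numeric vector of coefficients, one per non-reference
#'   design column (names like `"age:5-9"`, `"sex:male"`).
#' @param effects Numeric vector of participant random intercepts.
#' @param tau Positive random-intercept SD.
#' @param phi Positive NB dispersion.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(alpha, beta, effects, tau, phi) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), !is.null(names(beta)) || length(beta) == 0L,
            tau > 0 || tau == 0, phi > 0)
  structure(list(alpha = alpha, beta = beta, effects = effects,
                 tau = tau, phi = phi),
            class = "model_parameters")
}

#' Linear predictor and mean of the contact-rate model
#'
#' Evaluates `mu = exp(alpha + x'beta + effect)` for every participant-day
#' of the diary under the given parameters.
#'
#' @param diary A [survey_diary()].
#' @param params A [model_parameters()] whose `beta` names match the design
#'   columns implied by `covariates`.
#' @param covariates Covariates included in the design.
#' @return Tibble with `participant_id`, `date`, `period`, `mu`.
#' @export
linear_predictor <- function(diary, params,
                             covariates = model_covariates()) {
  md <- build_model_data(diary, covariates)
  beta_full <- params_to_beta(params, md)
  eta <- as.numeric(md$X %*% beta_full) + params$effects[md$pid]
  counts <- daily_counts(diary)
  tibble::tibble(participant_id = counts$participant_id, date = counts$date,
                 period = counts$period, mu = exp(eta))
}

params_to_beta <- function(params, md) {
  cols <- colnames(md$X)
  beta_full <- c(params$alpha, params$beta[cols[-1]])
  if (anyNA(beta_full)) {
    missing <- setdiff(cols[-1], names(params$beta))
    rlang::abort(paste0("params$beta is missing coefficient(s): ",
                        paste(missing, collapse = ", ")),
                 class = "contactdiaries_validation_error")
  }
  unname(beta_full)
}

resolve_alpha_location <- function(priors, y) {
  if (!is.null(priors$alpha_location)) priors$alpha_location
  else log(max(mean(y), 0.1))
}

# log posterior on prepared model data; out-of-support -> -Inf
log_posterior_md <- function(md, alpha, beta_vec, effects, tau, phi, priors,
                             alpha_loc) {
  if (tau <= 0 || phi <= 0) return(-Inf)
  eta <- as.numeric(md$X %*% c(alpha, beta_vec)) + effects[md$pid]
  ll <- sum(nb_log_pmf(md$y, exp(eta), phi))
  lp <- ll +
    sum(stats::dnorm(effects, 0, tau, log = TRUE)) +
    stats::dnorm(alpha, alpha_loc, priors$alpha_scale, log = TRUE) +
    sum(stats::dnorm(beta_vec, 0, priors$coef_scale, log = TRUE)) +
    stats::dnorm(tau, 0, priors$tau_scale, log = TRUE) + log(2) +
    stats::dexp(phi, priors$phi_rate, log = TRUE)
  lp
}

#' Log posterior density of the contact-rate model
#'
#' Sum of the NB log-likelihood over participant-days, the Normal(0, tau)
#' density of the participant effects, and the log prior densities. Returns
#' `-Inf` for parameters outside the support (non-positive `tau` or `phi`).
#'
#' @inheritParams linear_predictor
#' @param priors A [prior_spec()].
#' @return Scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(diary, params, priors = prior_spec(),
                          covariates = model_covariates()) {
  if (params$tau <= 0 || params$phi <= 0) return(-Inf)
  md <- build_model_data(diary, covariates)
  beta_full <- params_to_beta(params, md)
  log_posterior_md(md, beta_full[1], beta_full[-1], params$effects,
                   params$tau, params$phi, priors,
                   resolve_alpha_location(priors, md$y))
}
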