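# Fitting engines for the NB random-intercept model: a deterministic
# penalised MAP (Laplace-profiled tau) and a self-contained block
# adaptive-Metropolis MCMC sampler.

# fast unchecked NB log pmf on the eta scale
nbll_eta <- function(y, eta, phi) {
  mu <- exp(eta)
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    y * (eta - log(mu + phi)) + phi * (log(phi) - log(mu + phi))
}

#' Maximum a posteriori fit of the contact-rate model
#'
#' Deterministic fit used for fast parameter recovery and as an MCMC
#' cross-check. Participant effects are treated as penalised parameters with
#' their Normal(0, tau) density; for each `tau` on a profile grid the
#' coefficients, dispersion and effects are maximised by alternating BFGS
#' (coefficients, log dispersion; analytic gradients) with per-participant
#' Newton steps for the effects. The profile criterion for `tau` is the
#' Laplace approximation to the marginal posterior (joint maximum plus a
#' curvature correction over the effects), which avoids the degeneracy of
#' the joint mode at `tau = 0`.
#'
#' @param diary A [survey_diary()].
#' @param priors A [prior_spec()].
#' @param covariates Covariates included in the design.
#' @param tau_grid Profile grid for the random-intercept SD.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change between outer iterations.
#' @param max_outer Maximum alternating iterations per grid point.
#' @return An object of class `contact_fit` with `method = "map"`.
#' @export
fit_map <- function(diary, priors = prior_spec(),
                    covariates = model_covariates(),
                    tau_grid = c(0.001, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4,
                                 0.5, 0.7, 1, 1.5),
                    tol = 1e-5, max_outer = 50L) {
  md <- build_model_data(diary, covariates, require_identifiable = TRUE)
  alpha_loc <- resolve_alpha_location(priors, md$y)
  p <- ncol(md$X)

  state <- list(beta = c(alpha_loc, rep(0, p - 1L)),
                lphi = log(5), effects = rep(0, md$n_part))
  best <- NULL
  for (tau in sort(tau_grid)) {
    state <- map_inner(md, tau, priors, alpha_loc, state, tol, max_outer)
    crit <- map_laplace_criterion(md, tau, priors, alpha_loc, state)
    if (is.null(best) || crit > best$crit) {
      best <- list(crit = crit, tau = tau, state = state)
    }
  }
  st <- best$state
  beta <- st$beta[-1]
  names(beta) <- colnames(md$X)[-1]
  params <- model_parameters(alpha = st$beta[1], beta = beta,
                             effects = stats::setNames(st$effects,
                                                       md$participant_id),
                             tau = best$tau, phi = exp(st$lphi))
  fit <- structure(
    list(method = "map", params = params, covariates = covariates,
         priors = priors, md = md, lp = best$crit,
         converged = st$converged, draws = NULL, effect_draws = NULL,
         diagnostics = NULL),
    class = "contact_fit")
  fit$rate_ratios <- rate_ratio_table(fit)
  fit
}

map_inner <- function(md, tau, priors, alpha_loc, state, tol, max_outer) {
  y <- md$y
  X <- md$X
  p <- ncol(X)
  beta <- state$beta
  lphi <- state$lphi
  effects <- state$effects
  prior_sd <- c(priors$alpha_scale, rep(priors$coef_scale, p - 1L))
  prior_mean <- c(alpha_loc, rep(0, p - 1L))

  # penalised profile log-likelihood in lphi given beta and effects
  lphi_obj <- function(lphi, eta) {
    phi <- exp(lphi)
    sum(nbll_eta(y, eta, phi)) +
      stats::dexp(phi, priors$phi_rate, log = TRUE) + lphi
  }

  converged <- FALSE
  for (it in seq_len(max_outer)) {
    old_beta <- beta
    phi <- exp(lphi)
    # Fisher-scoring (penalised IRLS) steps for the coefficients
    for (k in 1:3) {
      eta <- as.numeric(X %*% beta) + effects[md$pid]
      mu <- exp(eta)
      r <- phi * (y - mu) / (mu + phi)
      w <- phi * mu * (y + phi) / (mu + phi)^2
      score <- as.numeric(crossprod(X, r)) - (beta - prior_mean) / prior_sd^2
      H <- crossprod(X * w, X) + diag(1 / prior_sd^2, p)
      step <- solve(H, score)
      beta <- beta + pmax(pmin(step, 1), -1)
    }
    # per-participant Newton steps for the effects
    eta_fixed <- as.numeric(X %*% beta)
    for (k in 1:3) {
      eta <- eta_fixed + effects[md$pid]
      mu <- exp(eta)
      score <- as.numeric(rowsum(phi * (y - mu) / (mu + phi), md$pid)) -
        effects / tau^2
      info <- as.numeric(rowsum(phi * mu * (y + phi) / (mu + phi)^2,
                                md$pid)) + 1 / tau^2
      step <- score / info
      effects <- effects + pmax(pmin(step, 1), -1)
    }
    # one-dimensional update of the dispersion on the log scale
    eta <- eta_fixed + effects[md$pid]
    lphi <- stats::optimize(lphi_obj, c(log(0.05), log(1e4)), eta = eta,
                            maximum = TRUE, tol = 1e-7)$maximum
    if (max(abs(beta - old_beta)) < tol && it > 1L) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, lphi = lphi, effects = effects, converged = converged)
}

map_laplace_criterion <- function(md, tau, priors, alpha_loc, state) {
  phi <- exp(state$lphi)
  lp <- log_posterior_md(md, state$beta[1], state$beta[-1], state$effects,
                         tau, phi, priors, alpha_loc)
  eta <- as.numeric(md$X %*% state$beta) + state$effects[md$pid]
  mu <- exp(eta)
  info <- as.numeric(rowsum(phi * mu * (md$y + phi) / (mu + phi)^2,
                            md$pid)) + 1 / tau^2
  lp + 0.5 * md$n_part * log(2 * pi) - 0.5 * sum(log(info))
}

#' MCMC fit of the contact-rate model
#'
#' Self-contained Metropolis-within-Gibbs sampler over four blocks per
#' iteration: (1) the full coefficient vector through a one-step-Newton
#' (penalised IRLS) Gaussian proposal with exact Metropolis-Hastings
#' correction; (2) an exact Gibbs recentering of each participant-level
#' coefficient against the mean of its participants' effects (the flat
#' ridge direction of hierarchical models, conditionally Gaussian and
#' therefore sampled in closed form); (3) a vectorised independent
#' random-walk sweep over all participant effects; (4) log-scale random
#' walks for the random-intercept SD and the dispersion. Random-walk scales
#' adapt towards 44% acceptance during warmup and are frozen afterwards;
#' chains initialise with overdispersed jitter around a short
#' penalised-likelihood mode. Split R-hat is computed for every scalar
#' parameter; the fit is flagged converged when all are at or below 1.01.
#'
#' The defaults (4 chains of 20,000 iterations, half warmup) match the
#' study's sampler settings; scaled-down settings are appropriate for small
#' synthetic diaries.
#'
#' @inheritParams fit_map
#' @param chains Number of independent chains.
#' @param iterations Total iterations per chain, warmup included.
#' @param warmup Warmup (adaptation) iterations discarded from inference.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param effect_draws Maximum number of joint (effects included) draws per
#'   chain retained for pointwise log-likelihood computation.
#' @return An object of class `contact_fit` with `method = "mcmc"`,
#'   posterior draws, split R-hat diagnostics and a rate-ratio table.
#' @export
fit_mcmc <- function(diary, priors = prior_spec(),
                     covariates = model_covariates(),
                     chains = 4L, iterations = 20000L, warmup = 10000L,
                     seed = 1L, thin = 1L, effect_draws = 50L) {
  chains <- as.integer(chains)
  iterations <- as.integer(iterations)
  warmup <- as.integer(warmup)
  thin <- as.integer(thin)
  stopifnot(chains >= 1L, iterations > warmup, warmup >= 10L, thin >= 1L)
  md <- build_model_data(diary, covariates, require_identifiable = TRUE)
  alpha_loc <- resolve_alpha_location(priors, md$y)
  p <- ncol(md$X)

  # initialise all chains near a quick penalised-likelihood mode and seed
  # the joint proposal covariance with the inverse coefficient Hessian
  ini <- map_inner(md, tau = 0.3, priors, alpha_loc,
                   list(beta = c(alpha_loc, rep(0, p - 1L)), lphi = log(5),
                        effects = rep(0, md$n_part)),
                   tol = 1e-4, max_outer = 15L)
  phi0 <- exp(ini$lphi)
  eta0 <- as.numeric(md$X %*% ini$beta) + ini$effects[md$pid]
  mu0 <- exp(eta0)
  w0 <- phi0 * mu0 * (md$y + phi0) / (mu0 + phi0)^2
  H0 <- crossprod(md$X * w0, md$X) +
    diag(1 / c(priors$alpha_scale, rep(priors$coef_scale, p - 1L))^2, p)
  cov0 <- tryCatch(solve(H0), error = function(e) diag(0.01, p))
  init <- list(beta = ini$beta, effects = ini$effects, phi = phi0,
               cov_beta = cov0)  # cov_beta kept for jitter scaling

  chain_draws <- vector("list", chains)
  chain_effects <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- run_chain(md, priors, alpha_loc, iterations, warmup, thin,
                     effect_draws, seed = seed + ch, init = init)
    chain_draws[[ch]] <- res$draws
    chain_effects[[ch]] <- res$effects
  }
  par_names <- c(colnames(md$X), "tau", "phi")
  kept <- nrow(chain_draws[[1]])

  rhat <- vapply(seq_along(par_names), function(j) {
    split_rhat(vapply(chain_draws, function(d) d[, j], numeric(kept)))
  }, numeric(1))
  diagnostics <- tibble::tibble(parameter = par_names, rhat = rhat)

  pooled <- do.call(rbind, chain_draws)
  colnames(pooled) <- par_names
  med <- apply(pooled, 2, stats::median)
  beta <- med[2:p]
  names(beta) <- colnames(md$X)[-1]
  eff_pooled <- do.call(rbind, lapply(chain_effects, `[[`, "effects"))
  params <- model_parameters(
    alpha = med[1], beta = beta,
    effects = stats::setNames(colMeans(eff_pooled), md$participant_id),
    tau = med["tau"], phi = med["phi"])

  fit <- structure(
    list(method = "mcmc", params = params, covariates = covariates,
         priors = priors, md = md,
         draws = chain_draws, par_names = par_names,
         effect_draws = chain_effects,
         diagnostics = diagnostics,
         converged = all(rhat <= 1.01),
         chains = chains, iterations = iterations, warmup = warmup,
         seed = seed),
    class = "contact_fit")
  if (!fit$converged) {
    rlang::warn(paste0("chains not converged: max split R-hat = ",
                       format(round(max(rhat), 4))))
  }
  fit$rate_ratios <- rate_ratio_table(fit)
  fit
}

run_chain <- function(md, priors, alpha_loc, iterations, warmup, thin,
                      effect_draws, seed, init = NULL) {
  set.seed(seed)
  y <- md$y
  X <- md$X
  pid <- md$pid
  p <- ncol(X)
  n_part <- md$n_part
  prior_sd <- c(priors$alpha_scale, rep(priors$coef_scale, p - 1L))
  prior_mean <- c(alpha_loc, rep(0, p - 1L))
  if (is.null(init)) {
    beta <- prior_mean + stats::rnorm(p, 0, 0.2)
    effects <- stats::rnorm(n_part, 0, 0.1)
    phi <- exp(log(5) + stats::rnorm(1, 0, 0.3))
  } else {
    # overdispersed jitter around the mode, scaled by the local curvature
    sds <- sqrt(pmax(diag(init$cov_beta), 1e-8))
    beta <- init$beta + stats::rnorm(p, 0, 2 * sds)
    effects <- init$effects + stats::rnorm(n_part, 0, 0.2)
    phi <- init$phi * exp(stats::rnorm(1, 0, 0.3))
  }
  tau <- exp(log(0.3) + stats::rnorm(1, 0, 0.3))

  eta <- as.numeric(X %*% beta) + effects[pid]
  ll_row <- nbll_eta(y, eta, phi)

  s_eff <- 0.3
  s_tau <- 0.3
  s_phi <- 0.2
  prior_prec <- diag(1 / prior_sd^2, p)

  # one-step-Newton (penalised IRLS) Gaussian proposal for the coefficient
  # block: N(beta + H^-1 score, H^-1) with H the local Fisher information
  newton_prop <- function(beta_cur, eta_cur) {
    mu <- exp(eta_cur)
    r <- phi * (y - mu) / (mu + phi)
    w <- phi * mu * (y + phi) / (mu + phi)^2
    score <- as.numeric(crossprod(X, r)) - (beta_cur - prior_mean) / prior_sd^2
    H <- crossprod(X * w, X) + prior_prec
    ch <- chol(H)
    m <- beta_cur + backsolve(ch, backsolve(ch, score, transpose = TRUE))
    list(m = m, ch = ch)
  }
  logq <- function(x, prop) {
    u <- prop$ch %*% (x - prop$m)
    sum(log(diag(prop$ch))) - 0.5 * sum(u * u)
  }

  kept_idx <- seq(warmup + thin, iterations, by = thin)
  draws <- matrix(NA_real_, length(kept_idx), p + 2L)
  eff_keep_idx <- kept_idx[unique(round(seq(1, length(kept_idx),
                                            length.out = min(effect_draws,
                                                             length(kept_idx)))))]
  eff_store <- matrix(NA_real_, length(eff_keep_idx), n_part)
  eff_scalar <- matrix(NA_real_, length(eff_keep_idx), p + 2L)
  ki <- 0L
  ei <- 0L

  for (it in seq_len(iterations)) {
    adapting <- it <= warmup
    gamma <- 1 / it^0.55

    # joint coefficient block via the one-step-Newton MH proposal
    fw <- newton_prop(beta, eta)
    beta_new <- as.numeric(fw$m + backsolve(fw$ch, stats::rnorm(p)))
    eta_new <- eta + as.numeric(X %*% (beta_new - beta))
    ll_new <- nbll_eta(y, eta_new, phi)
    rv <- newton_prop(beta_new, eta_new)
    d <- sum(ll_new) - sum(ll_row) +
      sum(stats::dnorm(beta_new, prior_mean, prior_sd, log = TRUE)) -
      sum(stats::dnorm(beta, prior_mean, prior_sd, log = TRUE)) +
      logq(beta, rv) - logq(beta_new, fw)
    if (is.finite(d) && log(stats::runif(1)) < d) {
      beta <- beta_new
      eta <- eta_new
      ll_row <- ll_new
    }

    # exact recentering along the coefficient/effect ridge: shifting a
    # participant-level coefficient by delta and its participants' effects
    # by -delta leaves every eta unchanged, and the conditional density of
    # delta is Gaussian, so it is Gibbs-sampled directly
    for (sweep in 1:2) {
      for (k in seq_len(p)) {
        parts <- md$col_parts[[k]]
        if (is.null(parts)) next
        prec <- length(parts) / tau^2 + 1 / prior_sd[k]^2
        mu_d <- (sum(effects[parts]) / tau^2 -
                   (beta[k] - prior_mean[k]) / prior_sd[k]^2) / prec
        delta <- stats::rnorm(1, mu_d, 1 / sqrt(prec))
        beta[k] <- beta[k] + delta
        effects[parts] <- effects[parts] - delta
      }
    }

    # participant effects: vectorised independent updates
    prop <- stats::rnorm(n_part, 0, s_eff)
    eta_new <- eta + prop[pid]
    ll_new <- nbll_eta(y, eta_new, phi)
    d_part <- as.numeric(rowsum(ll_new - ll_row, pid)) +
      stats::dnorm(effects + prop, 0, tau, log = TRUE) -
      stats::dnorm(effects, 0, tau, log = TRUE)
    acc_part <- log(stats::runif(n_part)) < d_part
    if (any(acc_part)) {
      effects[acc_part] <- effects[acc_part] + prop[acc_part]
      upd <- acc_part[pid]
      eta[upd] <- eta_new[upd]
      ll_row[upd] <- ll_new[upd]
    }
    if (adapting) {
      s_eff <- s_eff * exp(gamma * (mean(acc_part) - 0.44))
    }

    # random-intercept SD (log scale)
    ltau_new <- log(tau) + stats::rnorm(1, 0, s_tau)
    tau_new <- exp(ltau_new)
    d <- sum(stats::dnorm(effects, 0, tau_new, log = TRUE)) -
      sum(stats::dnorm(effects, 0, tau, log = TRUE)) +
      stats::dnorm(tau_new, 0, priors$tau_scale, log = TRUE) -
      stats::dnorm(tau, 0, priors$tau_scale, log = TRUE) +
      ltau_new - log(tau)
    acc <- is.finite(d) && log(stats::runif(1)) < d
    if (acc) tau <- tau_new
    if (adapting) s_tau <- s_tau * exp(gamma * ((acc * 1) - 0.44))

    # dispersion (log scale)
    lphi_new <- log(phi) + stats::rnorm(1, 0, s_phi)
    phi_new <- exp(lphi_new)
    ll_new <- nbll_eta(y, eta, phi_new)
    d <- sum(ll_new) - sum(ll_row) +
      stats::dexp(phi_new, priors$phi_rate, log = TRUE) -
      stats::dexp(phi, priors$phi_rate, log = TRUE) +
      lphi_new - log(phi)
    acc <- is.finite(d) && log(stats::runif(1)) < d
    if (acc) {
      phi <- phi_new
      ll_row <- ll_new
    }
    if (adapting) s_phi <- s_phi * exp(gamma * ((acc * 1) - 0.44))

    if (!adapting && it %in% kept_idx) {
      ki <- ki + 1L
      draws[ki, ] <- c(beta, tau, phi)
      if (it %in% eff_keep_idx) {
        ei <- ei + 1L
        eff_store[ei, ] <- effects
        eff_scalar[ei, ] <- c(beta, tau, phi)
      }
    }
  }
  list(draws = draws,
       effects = list(effects = eff_store, scalars = eff_scalar))
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Evaluates the NB log-likelihood of every participant-day observation at
#' each retained joint posterior draw (effects included), for use with
#' [waic()] and [loo_is()].
#'
#' @param fit A `contact_fit` from [fit_mcmc()].
#' @return Matrix, draws in rows and observations in columns.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "contact_fit"))
  if (is.null(fit$effect_draws)) {
    rlang::abort("pointwise log-likelihood requires an MCMC fit",
                 class = "contactdiaries_validation_error")
  }
  md <- fit$md
  p <- ncol(md$X)
  blocks <- lapply(fit$effect_draws, function(ed) {
    t(vapply(seq_len(nrow(ed$effects)), function(s) {
      beta <- ed$scalars[s, seq_len(p)]
      phi <- ed$scalars[s, p + 2L]
      eta <- as.numeric(md$X %*% beta) + ed$effects[s, ][md$pid]
      nbll_eta(md$y, eta, phi)
    }, numeric(length(md$y))))
  })
  do.call(rbind, blocks)
}

#' Posterior rate-ratio table
#'
#' Exponentiated coefficients summarised by the posterior median and the
#' central 95% credible interval (MCMC fits) or the MAP point estimate
#' (credible-interval columns `NA`). Reference levels are fixed at 1.
#'
#' @param fit A `contact_fit`.
#' @return Tibble with columns `term`, `level`, `estimate`, `conf_low`,
#'   `conf_high`, `reference`.
#' @export
rate_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "contact_fit"))
  cols <- colnames(fit$md$X)[-1]
  term <- sub(":.*$", "", cols)
  level <- sub("^[^:]*:", "", cols)
  if (is.null(fit$draws)) {
    est <- exp(unname(fit$params$beta[cols]))
    lo <- hi <- rep(NA_real_, length(cols))
  } else {
    pooled <- exp(do.call(rbind, fit$draws)[, 2:(length(cols) + 1L),
                                            drop = FALSE])
    est <- apply(pooled, 2, stats::median)
    lo <- apply(pooled, 2, stats::quantile, 0.025)
    hi <- apply(pooled, 2, stats::quantile, 0.975)
  }
  out <- tibble::tibble(term = term, level = level, estimate = est,
                        conf_low = lo, conf_high = hi, reference = FALSE)
  ref_levels <- list(age = age_bin_labels()[1], sex = sex_levels()[1],
                     period = period_levels()[1],
                     household = household_levels()[1])
  refs <- tibble::tibble(
    term = intersect(fit$covariates, names(ref_levels)),
    level = unlist(ref_levels[intersect(fit$covariates, names(ref_levels))]),
    estimate = 1,
    conf_low = if (is.null(fit$draws)) NA_real_ else 1,
    conf_high = if (is.null(fit$draws)) NA_real_ else 1,
    reference = TRUE)
  dplyr::bind_rows(refs, out) |>
    dplyr::arrange(factor(.data$term, levels = model_covariates()),
                   dplyr::desc(.data$reference))
}

#' @export
print.contact_fit <- function(x, ...) {
  cat("<contact_fit>", x$method, "fit,",
      length(x$md$y), "participant-days,",
      x$md$n_part, "participants\n")
  cat(sprintf("  tau = %.3f, phi = %.2f\n", x$params$tau, x$params$phi))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max split R-hat = %.4f (%s)\n",
                max(x$diagnostics$rhat),
                if (x$converged) "converged" else "NOT converged"))
  }
  print(x$rate_ratios, n = 8)
  invisible(x)
}

#' Tidy a contact-rate model fit
#'
#' @param x A `contact_fit`.
#' @param ... Unused.
#' @return The rate-ratio table, see [rate_ratio_table()].
#' @method tidy contact_fit
#' @export
tidy.contact_fit <- function(x, ...) rate_ratio_table(x)

#' One-row summary of a contact-rate model fit
#'
#' @param x A `contact_fit`.
#' @param ... Unused.
#' @return Tibble with sampler metadata, `tau`, `phi`, `max_rhat`,
#'   `converged`, and (for MCMC fits) `elpd_waic` and `elpd_loo`.
#' @method glance contact_fit
#' @export
glance.contact_fit <- function(x, ...) {
  elpd_w <- elpd_l <- NA_real_
  if (!is.null(x$effect_draws)) {
    ll <- pointwise_loglik(x)
    elpd_w <- waic(ll)$elpd_waic
    elpd_l <- suppressWarnings(loo_is(ll)$elpd_loo)
  }
  tibble::tibble(
    method = x$method,
    n_obs = length(x$md$y),
    n_participants = x$md$n_part,
    tau = x$params$tau,
    phi = x$params$phi,
    max_rhat = if (is.null(x$diagnostics)) NA_real_ else max(x$diagnostics$rhat),
    converged = isTRUE(x$converged),
    elpd_waic = elpd_w,
    elpd_loo = elpd_l)
}

#' Compare covariate combinations by predictive accuracy
#'
#' Fits the requested covariate subsets by MCMC and ranks them by WAIC and
#' IS-LOO expected log predictive density, reported as differences to the
#' best model.
#'
#' @param diary A [survey_diary()].
#' @param models Named list of covariate character vectors.
#' @param ... Passed to [fit_mcmc()] (chains, iterations, warmup, seed, ...).
#' @return Tibble with one row per model: `model`, `elpd_waic`, `elpd_loo`,
#'   `delta_elpd_waic`, `delta_elpd_loo`.
#' @export
compare_models <- function(diary,
                           models = list(
                             full = c("age", "sex", "period", "household"),
                             no_sex = c("age", "period", "household")),
                           ...) {
  rows <- purrr::imap(models, function(covs, nm) {
    fit <- fit_mcmc(diary, covariates = covs, ...)
    ll <- pointwise_loglik(fit)
    tibble::tibble(model = nm,
                   elpd_waic = waic(ll)$elpd_waic,
                   elpd_loo = suppressWarnings(loo_is(ll)$elpd_loo))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(delta_elpd_waic = .data$elpd_waic - max(.data$elpd_waic),
                  delta_elpd_loo = .data$elpd_loo - max(.data$elpd_loo))
}
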