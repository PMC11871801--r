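#' Split-chain potential scale reduction (R-hat)
#'
#' Textbook split-R-hat: each chain is halved, the between- and
#' within-sequence variances of the resulting `2 * chains` sequences are
#' combined, and the square-root of the variance ratio is returned.
#' Values at or below 1.01 are the usual convergence criterion. Chains that
#' are constant (zero within- and between-variance) return 1 by convention.
#'
#' @param draws Matrix of posterior draws, iterations x chains (a vector is
#'   treated as a single chain and split in two).
#' @return The split R-hat statistic.
#' @export
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  if (n < 4L) {
    rlang::abort("need at least 4 iterations", class = "contactdiaries_validation_error")
  }
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0 && b == 0) return(1)
  if (w == 0) return(Inf)
  var_plus <- (half - 1) / half * w + b / half
  sqrt(var_plus / w)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Watanabe-Akaike information criterion
#'
#' From a pointwise log-likelihood matrix (posterior draws x observations):
#' `lppd = sum_i log mean_s exp(ll_si)` (computed with log-sum-exp),
#' `p_waic = sum_i var_s(ll_si)` and `elpd_waic = lppd - p_waic`.
#'
#' @param pointwise_loglik Matrix, draws in rows and observations in columns.
#' @return One-row tibble with `elpd_waic`, `p_waic`, `lppd`.
#' @export
waic <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) {
    rlang::abort("pointwise log-likelihood must be finite",
                 class = "contactdiaries_validation_error")
  }
  lppd <- sum(apply(ll, 2, log_mean_exp))
  p <- if (nrow(ll) < 2L) 0 else sum(apply(ll, 2, stats::var))
  tibble::tibble(elpd_waic = lppd - p, p_waic = p, lppd = lppd)
}

#' Importance-sampling leave-one-out expected log predictive density
#'
#' Basic IS-LOO (no tail smoothing): for each observation the LOO predictive
#' density is estimated with importance weights `w_si = 1 / p(y_i | theta_s)`,
#' giving `elpd_loo_i = -log mean_s exp(-ll_si)`, evaluated stably on the
#' log scale. A warning is emitted when any observation's normalised weights
#' are dominated by a single draw (heavy importance-weight tail), in which
#' case the estimate is unreliable.
#'
#' @inheritParams waic
#' @return One-row tibble with `elpd_loo` and `n_heavy`, the number of
#'   observations with heavy-tailed weights.
#' @export
loo_is <- function(pointwise_loglik) {
  ll <- as.matrix(pointwise_loglik)
  if (!all(is.finite(ll))) {
    rlang::abort("pointwise log-likelihood must be finite",
                 class = "contactdiaries_validation_error")
  }
  elpd_i <- -apply(-ll, 2, log_mean_exp)
  max_w <- apply(ll, 2, function(l) {
    lw <- -l
    lse <- max(lw) + log(sum(exp(lw - max(lw))))
    exp(max(lw) - lse)
  })
  n_heavy <- sum(max_w > 0.5 & nrow(ll) > 1L)
  if (n_heavy > 0L) {
    rlang::warn(paste0("heavy importance-weight tail for ", n_heavy,
                       " observation(s); IS-LOO may be unreliable"))
  }
  tibble::tibble(elpd_loo = sum(elpd_i), n_heavy = n_heavy)
}
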