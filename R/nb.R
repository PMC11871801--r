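#' Negative binomial log pmf (mean/dispersion parameterisation)
#'
#' Log probability of `y` under `NegBinomial(mu, phi)` with
#' `Pr(Y = y) = C(y + phi - 1, y) (mu/(mu+phi))^y (phi/(mu+phi))^phi`,
#' where the generalised binomial coefficient is evaluated through
#' log-gamma so `phi` need not be an integer. The distribution has mean
#' `mu`, variance `mu + mu^2/phi`, and converges pointwise to
#' `Poisson(mu)` as `phi` grows.
#'
#' @param y Non-negative integer counts.
#' @param mu Positive mean.
#' @param phi Positive dispersion size.
#' @return Log probabilities, vectorised over the arguments.
#' @examples
#' nb_log_pmf(0, mu = 1, phi = 1)  # log(1/2)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(mu <= 0) || any(phi <= 0)) {
    rlang::abort("mu and phi must be positive",
                 class = "contactdiaries_validation_error")
  }
  if (any(y < 0) || any(y != floor(y))) {
    rlang::abort("y must be a non-negative integer",
                 class = "contactdiaries_validation_error")
  }
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    y * (log(mu) - log(mu + phi)) +
    phi * (log(phi) - log(mu + phi))
}
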