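#' Dominant eigenvalue of a non-negative matrix
#'
#' Spectral radius (Perron root), the quantity the next-generation approach
#' compares across contact matrices when all age groups contribute equally
#' to transmission. Computed by power iteration; if the iteration fails to
#' converge (e.g. a reducible matrix), the dense eigendecomposition is used
#' as a fallback.
#'
#' @param m Square matrix with non-negative, finite entries.
#' @param tol Convergence tolerance on successive Rayleigh quotients.
#' @param max_iter Maximum power-iteration steps.
#' @return The spectral radius, a non-negative real number.
#' @examples
#' dominant_eigenvalue(matrix(c(2, 1, 1, 2), 2))  # 3
#' @export
dominant_eigenvalue <- function(m, tol = 1e-12, max_iter = 10000L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(!is.finite(m))) {
    rlang::abort("matrix entries must be finite",
                 class = "contactdiaries_validation_error")
  }
  if (any(m < 0)) {
    rlang::abort("matrix entries must be non-negative",
                 class = "contactdiaries_validation_error")
  }
  if (all(m == 0)) return(0)
  v <- rep(1, nrow(m))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- as.numeric(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break   # reducible: iterate hit a null direction
    w <- w / nw
    lambda_new <- as.numeric(crossprod(w, m %*% w))
    if (abs(lambda_new - lambda) <= tol * max(1, abs(lambda_new))) {
      return(lambda_new)
    }
    lambda <- lambda_new
    v <- w
  }
  # fallback: dense decomposition
  max(Re(eigen(m, only.values = TRUE)$values))
}

#' Eigenvalue ratios of contact matrices across strata
#'
#' Under the next-generation approach with equal age-specific
#' transmissibility, the ratio of basic reproduction numbers between two
#' settings equals the ratio of the dominant eigenvalues of their contact
#' matrices. Computes the dominant eigenvalue of each stratum's
#' (reciprocity-corrected) matrix and its ratio to the reference stratum.
#'
#' @param matrices Named list of square matrices (or `contact_matrix`
#'   objects, whose `boot_mean` is used) sharing the same group bins.
#' @param reference Name of the reference stratum (default the first).
#' @return Tibble of class `eigen_report` with columns `stratum`,
#'   `dominant_eigenvalue`, `ratio_to_reference`, and the reference name as
#'   attribute `reference`.
#' @export
r0_ratio <- function(matrices, reference = names(matrices)[1]) {
  stopifnot(is.list(matrices), !is.null(names(matrices)),
            reference %in% names(matrices))
  ms <- lapply(matrices, function(x) {
    if (inherits(x, "contact_matrix")) x$boot_mean else x
  })
  bins <- lapply(ms, dim)
  if (length(unique(bins)) != 1L) {
    rlang::abort("all matrices must share the same bins",
                 class = "contactdiaries_validation_error")
  }
  ev <- vapply(ms, dominant_eigenvalue, numeric(1))
  if (ev[[reference]] == 0) {
    rlang::abort("reference matrix has zero dominant eigenvalue",
                 class = "contactdiaries_validation_error")
  }
  out <- tibble::tibble(
    stratum = names(ms),
    dominant_eigenvalue = unname(ev),
    ratio_to_reference = unname(ev / ev[[reference]]))
  class(out) <- c("eigen_report", class(out))
  attr(out, "reference") <- reference
  out
}
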