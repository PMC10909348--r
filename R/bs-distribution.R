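#' The Birnbaum-Saunders (fatigue-life) distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the two-parameter Birnbaum-Saunders distribution with shape `alpha`
#' and scale `beta`.
#'
#' The density is
#' \deqn{f(x) = \frac{1}{2\alpha\beta\sqrt{2\pi}}
#'   \left[(\beta/x)^{1/2} + (\beta/x)^{3/2}\right]
#'   \exp\left\{-\frac{1}{2\alpha^2}\left(\frac{x}{\beta} +
#'   \frac{\beta}{x} - 2\right)\right\}, \quad x > 0.}
#' Equivalently, \eqn{Z = (\sqrt{x/\beta} - \sqrt{\beta/x})/\alpha} is
#' standard normal, which gives the distribution function
#' \eqn{F(x) = \Phi(Z)} and the closed-form quantile
#' \deqn{\theta_p = \frac{\beta}{4}\left(\alpha z_p +
#'   \sqrt{\alpha^2 z_p^2 + 4}\right)^2,}
#' with \eqn{z_p = \Phi^{-1}(p)}. The median is exactly `beta`, and
#' quantiles satisfy the reciprocal symmetry
#' \eqn{\theta_p \theta_{1-p} = \beta^2}.
#'
#' @param x vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations.
#' @param alpha positive shape parameter.
#' @param beta positive scale parameter (same units as the data).
#' @param log,log.p logical; if `TRUE` probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}.
#'
#' @return `dbs` gives the density, `pbs` the distribution function,
#'   `qbs` the quantile function, and `rbs` generates random deviates.
#'
#' @examples
#' qbs(0.5, alpha = 0.5, beta = 2)   # the median equals beta
#' pbs(qbs(0.9, 1, 3), 1, 3)         # round-trips to 0.9
#' @name bs-distribution
NULL

check_bs_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("'alpha' and 'beta' must be finite and strictly positive",
         call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname bs-distribution
#' @export
dbs <- function(x, alpha, beta, log = FALSE) {
  check_bs_params(alpha, beta)
  if (any(x <= 0 | !is.finite(x))) {
    stop("'x' must be finite and strictly positive", call. = FALSE)
  }
  b_over_x <- beta / x
  logden <- -log(2 * alpha * beta) - 0.5 * log(2 * pi) +
    log(sqrt(b_over_x) * (1 + b_over_x)) -
    (x / beta + b_over_x - 2) / (2 * alpha^2)
  if (log) logden else exp(logden)
}

#' @rdname bs-distribution
#' @export
pbs <- function(x, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_bs_params(alpha, beta)
  if (any(x <= 0 | !is.finite(x))) {
    stop("'x' must be finite and strictly positive", call. = FALSE)
  }
  z <- (sqrt(x / beta) - sqrt(beta / x)) / alpha
  stats::pnorm(z, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname bs-distribution
#' @export
qbs <- function(p, alpha, beta) {
  check_bs_params(alpha, beta)
  if (any(p <= 0 | p >= 1 | !is.finite(p))) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  bs_percentile(alpha, beta, p)
}

#' @rdname bs-distribution
#' @export
rbs <- function(n, alpha, beta) {
  check_bs_params(alpha, beta)
  z <- stats::rnorm(n)
  bs_from_normal(z, alpha, beta)
}

# Monotone transform from a standard normal deviate to a BS deviate:
# X = beta * (1 + a^2 z^2 / 2 + a z sqrt(a^2 z^2 / 4 + 1)).
bs_from_normal <- function(z, alpha, beta) {
  az <- alpha * z
  beta * (1 + az^2 / 2 + az * sqrt(az^2 / 4 + 1))
}

#' Closed-form percentile of the Birnbaum-Saunders distribution
#'
#' Computes \eqn{\theta_p = (\beta/4)(\alpha z_p + \sqrt{\alpha^2 z_p^2 + 4})^2}
#' with \eqn{z_p = \Phi^{-1}(p)}. This is the quantity all interval methods
#' in the package target; at `p = 0.5` it reduces to `beta` exactly.
#'
#' @inheritParams bs-distribution
#' @param p probability in (0, 1); may be a vector.
#' @return the percentile(s), positive and strictly increasing in `p`.
#' @export
bs_percentile <- function(alpha, beta, p) {
  check_bs_params(alpha, beta)
  if (any(p <= 0 | p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  zp <- stats::qnorm(p)
  azp <- alpha * zp
  (beta / 4) * (azp + sqrt(azp^2 + 4))^2
}

#' Sufficient summaries of a positive sample
#'
#' Returns the summaries that feed the generalized pivotal quantities:
#' `I` (mean of \eqn{\sqrt{x_i}}), `J` (mean of \eqn{1/\sqrt{x_i}}),
#' `K` and `L` (the corresponding sums of squared deviations), and
#' `S1 = sum(x)`, `S2 = sum(1/x)`.
#'
#' @param x numeric vector of strictly positive values, length at least 2.
#' @return a list of class `"bs_stats"` with elements
#'   `n, I, J, K, L, S1, S2`.
#' @export
bs_stats <- function(x) {
  check_sample(x, n_min = 2)
  sx <- sqrt(x)
  I <- mean(sx)
  J <- mean(1 / sx)
  structure(list(
    n  = length(x),
    I  = I,
    J  = J,
    K  = sum((sx - I)^2),
    L  = sum((1 / sx - J)^2),
    S1 = sum(x),
    S2 = sum(1 / x)
  ), class = "bs_stats")
}

# Shared validation: positive, finite, numeric; reports offending indices.
check_sample <- function(x, n_min = 2) {
  if (!is.numeric(x)) stop("sample must be numeric", call. = FALSE)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop(sprintf("sample contains nonpositive or non-finite values at index %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (length(x) < n_min) {
    stop(sprintf("sample must contain at least %d values", n_min),
         call. = FALSE)
  }
  invisible(x)
}
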