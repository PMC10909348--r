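#' Generalized pivotal quantity for the scale parameter
#'
#' Given the sufficient summaries of a sample and a Student-t draw `t_draw`
#' (df n-1), solves the quadratic \eqn{A\beta^2 - 2B\beta + C = 0} with
#' \deqn{A = (n-1)J^2 - \tfrac{1}{n} L T^2,\quad
#'       B = (n-1)IJ - (1 - IJ)T^2,\quad
#'       C = (n-1)I^2 - \tfrac{1}{n} K T^2,}
#' and returns the larger root when \eqn{T \le 0}, the smaller when
#' \eqn{T > 0}. Draws whose roots are not both real and positive are flagged
#' invalid (`NA`), signalling the caller to resimulate `T`; at `T = 0` the
#' quadratic has the double root \eqn{I/J}.
#'
#' @param stats a [bs_stats()] object.
#' @param t_draw numeric vector of t(n-1) pivots.
#' @return numeric vector of the same length as `t_draw`; `NA` marks an
#'   invalid draw.
#' @export
gpq_beta <- function(stats, t_draw) {
  stopifnot(inherits(stats, "bs_stats"))
  n <- stats$n
  T2 <- t_draw^2
  A <- (n - 1) * stats$J^2 - stats$L * T2 / n
  B <- (n - 1) * stats$I * stats$J - (1 - stats$I * stats$J) * T2
  C <- (n - 1) * stats$I^2 - stats$K * T2 / n
  disc <- B^2 - A * C
  out <- rep(NA_real_, length(t_draw))
  ok <- is.finite(disc) & disc >= 0 & A != 0
  if (any(ok)) {
    rt <- sqrt(disc[ok])
    r1 <- (B[ok] - rt) / A[ok]
    r2 <- (B[ok] + rt) / A[ok]
    both_pos <- r1 > 0 & r2 > 0
    sel <- ifelse(t_draw[ok] <= 0, pmax(r1, r2), pmin(r1, r2))
    sel[!both_pos] <- NA_real_
    out[ok] <- sel
  }
  out
}

#' Generalized pivotal quantity for the shape parameter
#'
#' \deqn{R_\alpha = \sqrt{\frac{S_2 R_\beta^2 - 2 n R_\beta + S_1}
#'   {R_\beta V}},}
#' with `v_draw` a chi-squared(n) pivot. The radicand is nonnegative for any
#' positive \eqn{R_\beta} by the AM-GM inequality; a (numerically) negative
#' radicand yields `NA` as an invalid-draw signal.
#'
#' @param stats a [bs_stats()] object.
#' @param r_beta positive scale pivotal value(s) from [gpq_beta()].
#' @param v_draw positive chi-squared(n) draw(s).
#' @return numeric vector of shape pivotal values (`NA` where invalid).
#' @export
gpq_alpha <- function(stats, r_beta, v_draw) {
  stopifnot(inherits(stats, "bs_stats"))
  rad <- stats$S2 * r_beta^2 - 2 * stats$n * r_beta + stats$S1
  out <- sqrt(ifelse(rad >= 0, rad, NA_real_) / (r_beta * v_draw))
  out
}

#' Generalized pivotal quantity for the percentile
#'
#' Substitutes the scale and shape pivotals into the closed-form percentile:
#' \eqn{R_\theta = (R_\beta/4)(R_\alpha z_p + \sqrt{R_\alpha^2 z_p^2 + 4})^2}.
#' At `p = 0.5` (or when `r_alpha` is 0) this reduces to `r_beta`.
#'
#' @param r_beta,r_alpha pivotal values (vectors of equal length;
#'   `r_alpha` may be 0).
#' @param p percentile of interest in (0, 1).
#' @return numeric vector of percentile pivotal values.
#' @export
gpq_theta <- function(r_beta, r_alpha, p) {
  check_p(p)
  zp <- stats::qnorm(p)
  az <- r_alpha * zp
  (r_beta / 4) * (az + sqrt(az^2 + 4))^2
}

#' Generalized confidence interval for a Birnbaum-Saunders percentile
#'
#' Simulates `M` generalized pivotal quantities for the percentile
#' (a t(n-1) pivot for the scale, a chi-squared(n) pivot for the shape) and
#' returns the equal-tailed empirical quantiles of the simulated
#' \eqn{R_\theta} values. Invalid scale pivots (quadratic roots not both
#' real-positive) are resimulated; the resimulation count is reported in the
#' result.
#'
#' @param x positive sample, length >= 2.
#' @param p percentile of interest in (0, 1).
#' @param level confidence level in (0, 1).
#' @param M number of pivotal draws (>= 100).
#' @param seed optional integer seed.
#' @return a `"bs_interval"` with extra fields `draws`, `seed`,
#'   `resimulated`.
#' @examples
#' x <- rbs(50, 0.5, 1)
#' gci_interval(x, p = 0.5, M = 1000, seed = 42)
#' @export
gci_interval <- function(x, p = 0.5, level = 0.95, M = 5000, seed = NULL) {
  check_sample(x)
  check_p(p)
  check_level(level)
  if (M < 100) stop("'M' must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- bs_stats(x)
  draws <- gci_theta_draws(st, p, M)
  q <- equal_tail_interval(draws$theta, level)
  new_bs_interval(q[1], q[2], level, "GCI", p,
                  extra = list(draws = M, seed = seed,
                               resimulated = draws$resimulated))
}

# Vectorized GPQ simulation with resimulation of invalid draws.
# Used by both gci_interval and the simulation engine.
gci_theta_draws <- function(st, p, M) {
  n <- st$n
  t_draw <- stats::rt(M, df = n - 1)
  r_beta <- gpq_beta(st, t_draw)
  t_kept <- t_draw
  resim <- 0L
  attempts <- M
  while (anyNA(r_beta)) {
    bad <- which(is.na(r_beta))
    resim <- resim + length(bad)
    attempts <- attempts + length(bad)
    if (attempts > 100 * M) {
      stop("resimulation budget exhausted while drawing scale pivots",
           call. = FALSE)
    }
    t_new <- stats::rt(length(bad), df = n - 1)
    r_beta[bad] <- gpq_beta(st, t_new)
    t_kept[bad] <- t_new
  }
  v <- stats::rchisq(M, df = n)
  r_alpha <- gpq_alpha(st, r_beta, v)
  while (anyNA(r_alpha)) {
    bad <- which(is.na(r_alpha))
    resim <- resim + length(bad)
    attempts <- attempts + length(bad)
    if (attempts > 100 * M) {
      stop("resimulation budget exhausted while drawing shape pivots",
           call. = FALSE)
    }
    t_new <- stats::rt(length(bad), df = n - 1)
    rb_new <- gpq_beta(st, t_new)
    v_new <- stats::rchisq(length(bad), df = n)
    r_beta[bad] <- rb_new
    r_alpha[bad] <- gpq_alpha(st, rb_new, v_new)
  }
  list(theta = gpq_theta(r_beta, r_alpha, p), resimulated = resim)
}
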