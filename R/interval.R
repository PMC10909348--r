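#' @keywords internal
new_bs_interval <- function(lower, upper, level, method, p,
                            extra = list()) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower <= upper)
  structure(c(list(
    lower = lower, upper = upper, length = upper - lower,
    level = level, method = method, p = p
  ), extra), class = "bs_interval")
}

#' @export
print.bs_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%d%% %s interval for the %g-percentile\n",
              round(100 * x$level), x$method, 100 * x$p))
  cat(sprintf("  [%.*f, %.*f]   length %.*f\n",
              digits, x$lower, digits, x$upper, digits, x$length))
  if (!is.null(x$seed)) {
    cat(sprintf("  draws = %d, seed = %s\n", x$draws, format(x$seed)))
  }
  invisible(x)
}

#' @export
as.data.frame.bs_interval <- function(x, ...) {
  data.frame(method = x$method, p = x$p, level = x$level,
             lower = x$lower, upper = x$upper, length = x$length,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed,
             draws = if (is.null(x$draws)) NA_integer_ else x$draws)
}

# Equal-tailed interval from draws: linear-interpolation empirical quantiles
# (type 7), the convention used throughout the package.
equal_tail_interval <- function(draws, level) {
  g <- (1 - level) / 2
  q <- stats::quantile(draws, c(g, 1 - g), names = FALSE, type = 7)
  q
}

#' Equal-tailed credible interval from posterior draws
#'
#' Returns the \eqn{\gamma/2} and \eqn{1-\gamma/2} empirical quantiles
#' (linear interpolation between order statistics) of a set of draws.
#'
#' @param draws numeric vector of (posterior) draws, length >= 100.
#' @param level credible level in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  check_level(level)
  if (length(draws) < 100) stop("need at least 100 draws", call. = FALSE)
  equal_tail_interval(draws, level)
}

#' Highest posterior density interval from draws
#'
#' Computes the HPD interval by the sorted-window method: among all
#' contiguous windows of \eqn{\lceil \mathrm{level} \cdot M \rceil} sorted
#' draws, the one of minimal length is returned (ties broken in favour of
#' the smallest lower endpoint). For a unimodal posterior this is the
#' shortest interval with the stated posterior mass, and its length is never
#' larger than the equal-tailed interval's on the same draws.
#'
#' @inheritParams credible_interval
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  check_level(level)
  m <- length(draws)
  if (m < 100) stop("need at least 100 draws", call. = FALSE)
  s <- sort(draws)
  k <- ceiling(level * m)
  if (k >= m) return(c(s[1], s[m]))
  width <- s[(k + 1):m] - s[1:(m - k)]
  i <- which.min(width)  # which.min returns the first (smallest lower end)
  c(s[i], s[i + k])
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1 ||
      level <= 0 || level >= 1) {
    stop("'level' must be a single number strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(level)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("'p' must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  }
  invisible(p)
}

#' Confidence or credible interval for a Birnbaum-Saunders percentile
#'
#' One front door to the four interval constructions: the generalized
#' confidence interval (`"gci"`), the bias-corrected parametric bootstrap
#' percentile interval (`"bootstrap"`), the equal-tailed Bayesian credible
#' interval (`"bayes"`), and the highest posterior density interval
#' (`"hpd"`).
#'
#' @param x positive sample (numeric vector) or a [bs_fit()] object.
#' @param p percentile of interest, in (0, 1). Default 0.5 (the median).
#' @param level confidence/credible level. Default 0.95.
#' @param method one of `"gci"`, `"bootstrap"`, `"bayes"`, `"hpd"`.
#' @param seed integer seed; every stochastic step flows through it.
#' @param M pivotal/posterior draw count (GCI, Bayesian and HPD methods).
#' @param B bootstrap replicate count.
#' @param resampling bootstrap scheme, `"parametric"` or `"nonparametric"`.
#' @param hyper prior settings for the Bayesian methods ([bs_hyper()]).
#' @return a `"bs_interval"` object.
#' @examples
#' x <- rbs(100, 0.5, 2)
#' bs_percentile_ci(x, p = 0.5, method = "gci", M = 1000, seed = 1)
#' @export
bs_percentile_ci <- function(x, p = 0.5, level = 0.95,
                             method = c("gci", "bootstrap", "bayes", "hpd"),
                             seed = NULL, M = 5000, B = 500,
                             resampling = "parametric",
                             hyper = bs_hyper()) {
  if (inherits(x, "bs_fit")) x <- x$data
  method <- match.arg(method)
  switch(method,
    gci       = gci_interval(x, p = p, level = level, M = M, seed = seed),
    bootstrap = bootstrap_interval(x, p = p, level = level, B = B,
                                   resampling = resampling, seed = seed),
    bayes     = bayes_interval(x, p = p, level = level, M = M,
                               hyper = hyper, seed = seed,
                               type = "equal-tail"),
    hpd       = bayes_interval(x, p = p, level = level, M = M,
                               hyper = hyper, seed = seed, type = "hpd")
  )
}
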