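#' Monte Carlo coverage and average length for one configuration
#'
#' Evaluates the interval methods at one \eqn{(n, p, \alpha, \beta)} cell:
#' for each replicate a Birnbaum-Saunders sample is drawn, every requested
#' interval is built on the *same* data (paired design), and the indicator
#' \eqn{\theta \in [L, U]} and the length \eqn{U - L} are recorded, where
#' \eqn{\theta} is the true percentile. Replicate `k` runs under a child
#' seed derived from the master seed, so cells are reproducible and methods
#' within a replicate share data.
#'
#' The Bayesian equal-tailed and HPD intervals share one posterior sample
#' per replicate. Replicates where a method fails are redrawn (bounded
#' retries).
#'
#' @param n sample size per replicate.
#' @param alpha,beta true shape and scale.
#' @param p percentile under study (default 0.5).
#' @param level nominal confidence level.
#' @param reps number of Monte Carlo replications.
#' @param methods subset of `c("gci", "bootstrap", "bayes", "hpd")`.
#' @param M_gci GPQ draws per replicate.
#' @param B_boot bootstrap replicates per replicate.
#' @param M_bayes posterior draws per replicate.
#' @param hyper prior settings for the Bayesian methods ([bs_hyper()]).
#' @param seed master integer seed.
#' @return a data frame of class `"bs_sim_result"` with one row per method:
#'   `method`, `coverage`, `avg_length`, `mc_stderr`
#'   (\eqn{\sqrt{c(1-c)/\mathrm{reps}}}), plus the cell settings as columns.
#' @examples
#' bs_coverage_cell(n = 10, alpha = 0.5, reps = 50, methods = "gci",
#'                  M_gci = 500, seed = 1)
#' @export
bs_coverage_cell <- function(n, alpha, beta = 1, p = 0.5, level = 0.95,
                             reps = 5000,
                             methods = c("gci", "bootstrap", "bayes", "hpd"),
                             M_gci = 5000, B_boot = 500, M_bayes = 1000,
                             hyper = bs_hyper(), seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (reps < 1) stop("'reps' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, reps)
  theta_true <- bs_percentile(alpha, beta, p)
  gam <- 1 - level
  hit <- matrix(0, reps, length(methods), dimnames = list(NULL, methods))
  len <- matrix(0, reps, length(methods), dimnames = list(NULL, methods))
  for (k in seq_len(reps)) {
    set.seed(child_seeds[k])
    done <- FALSE
    for (attempt in 1:20) {
      x <- rbs(n, alpha, beta)
      res <- tryCatch(
        sim_intervals_one(x, p, level, methods, M_gci, B_boot, M_bayes,
                          hyper),
        error = function(e) NULL)
      if (!is.null(res)) { done <- TRUE; break }
    }
    if (!done) {
      stop(sprintf("replicate %d failed repeatedly", k), call. = FALSE)
    }
    hit[k, ] <- as.numeric(res[, "lower"] <= theta_true &
                             theta_true <= res[, "upper"])
    len[k, ] <- res[, "upper"] - res[, "lower"]
  }
  cov <- colMeans(hit)
  out <- data.frame(
    n = n, p = p, alpha = alpha, beta = beta, level = level, reps = reps,
    method = methods,
    coverage = as.numeric(cov),
    avg_length = as.numeric(colMeans(len)),
    mc_stderr = as.numeric(sqrt(cov * (1 - cov) / reps)),
    row.names = NULL
  )
  class(out) <- c("bs_sim_result", "data.frame")
  out
}

# One replicate: build all requested intervals on the same sample.
# Returns a matrix with rows = methods, cols = lower/upper. Runs on the
# ambient RNG stream (seeded per replicate by the caller).
sim_intervals_one <- function(x, p, level, methods, M_gci, B_boot, M_bayes,
                              hyper) {
  out <- matrix(NA_real_, length(methods), 2,
                dimnames = list(methods, c("lower", "upper")))
  if ("gci" %in% methods) {
    st <- bs_stats(x)
    draws <- gci_theta_draws(st, p, M_gci)
    out["gci", ] <- equal_tail_interval(draws$theta, level)
  }
  if ("bootstrap" %in% methods) {
    ci <- suppressWarnings(
      bootstrap_interval(x, p = p, level = level, B = B_boot, seed = NULL))
    out["bootstrap", ] <- c(ci$lower, ci$upper)
  }
  if (any(c("bayes", "hpd") %in% methods)) {
    post <- bs_posterior(x, hyper, M_bayes, seed = NULL)
    theta <- posterior_theta(post, p)
    if ("bayes" %in% methods) {
      out["bayes", ] <- equal_tail_interval(theta, level)
    }
    if ("hpd" %in% methods) {
      out["hpd", ] <- hpd_interval(theta, level)
    }
  }
  out
}

#' Monte Carlo study over a grid of sample sizes and shapes
#'
#' Runs [bs_coverage_cell()] over the cross of `n_values` and
#' `alpha_values` at fixed `p` and `beta`, mirroring the standard coverage
#' study layout (n in \{10, 30, 50, 100\} by shape in
#' \{0.10, 0.25, 0.50, 0.75, 1.00\}, median, unit scale). Each cell gets a
#' child seed derived from the master seed.
#'
#' @param n_values integer vector of sample sizes.
#' @param alpha_values numeric vector of true shape values.
#' @inheritParams bs_coverage_cell
#' @return a `"bs_sim_result"` data frame with one row per cell and method.
#' @export
bs_coverage_grid <- function(n_values = c(10, 30, 50, 100),
                             alpha_values = c(0.10, 0.25, 0.50, 0.75, 1.00),
                             beta = 1, p = 0.5, level = 0.95, reps = 5000,
                             methods = c("gci", "bootstrap", "bayes", "hpd"),
                             M_gci = 5000, B_boot = 500, M_bayes = 1000,
                             hyper = bs_hyper(), seed = NULL) {
  if (!length(n_values) || !length(alpha_values)) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(alpha = alpha_values, n = n_values,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- sample.int(.Machine$integer.max - 1, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rows[[i]] <- bs_coverage_cell(
      n = cells$n[i], alpha = cells$alpha[i], beta = beta, p = p,
      level = level, reps = reps, methods = methods, M_gci = M_gci,
      B_boot = B_boot, M_bayes = M_bayes, hyper = hyper,
      seed = cell_seeds[i])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bs_sim_result", "data.frame")
  out
}

#' @export
print.bs_sim_result <- function(x, digits = 4, ...) {
  cat("Monte Carlo coverage study\n")
  df <- as.data.frame(x)
  df$coverage <- round(df$coverage, digits)
  df$avg_length <- round(df$avg_length, digits)
  df$mc_stderr <- signif(df$mc_stderr, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
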