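test_that("log marginal kernel matches direct evaluation and has integrable tails", {
  x <- make_bs_sample(12, 0.5, 1, seed = 51)
  hyper <- bs_hyper()
  # direct (non-log) evaluation of the kernel at moderate scale values
  direct <- function(b) {
    n <- length(x)
    b^(-(n + hyper$a1 + 1)) * exp(-hyper$b1 / b) *
      prod((b / x)^0.5 + (b / x)^1.5) *
      (sum((x / b + b / x - 2) / 2) + hyper$b2)^(-(n + 1) / 2 - hyper$a2)
  }
  b1 <- 0.8; b2 <- 1.7
  ratio_direct <- direct(b1) / direct(b2)
  ratio_log <- exp(log_marginal_beta(b1, x, hyper) -
                     log_marginal_beta(b2, x, hyper))
  expect_equal(ratio_log, ratio_direct, tolerance = 1e-10)
  # tails fall to -Inf in both directions
  expect_lt(log_marginal_beta(1e-8, x, hyper),
            log_marginal_beta(median(x), x, hyper) - 100)
  # upper tail decays like -(a1 + a2 + 3/2) log(beta): slow but monotone
  expect_lt(log_marginal_beta(1e10, x, hyper),
            log_marginal_beta(median(x), x, hyper) - 25)
  expect_lt(log_marginal_beta(1e12, x, hyper),
            log_marginal_beta(1e10, x, hyper))
  # continuity: no jumps on a fine grid
  grid <- exp(seq(log(0.1 * median(x)), log(100 * median(x)),
                  length.out = 4000))
  lp <- log_marginal_beta(grid, x, hyper)
  expect_true(all(is.finite(lp)))
  expect_lt(max(abs(diff(lp))), 0.1)
})

test_that("ratio-of-uniforms bounds dominate the objectives on a dense grid", {
  x <- make_bs_sample(20, 0.5, 1, seed = 52)
  hyper <- bs_hyper()
  b <- rou_bounds(x, hyper)
  expect_identical(b$b_minus, 0)
  expect_true(is.finite(b$a_r) && is.finite(b$b_plus))
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 5000))
  lp <- log_marginal_beta(grid, x, hyper) - b$log_shift
  a_grid <- exp(lp / (hyper$r + 1))
  bp_grid <- grid * exp(hyper$r * lp / (hyper$r + 1))
  expect_lt(max(a_grid), b$a_r * (1 + 1e-6))
  expect_lt(max(bp_grid), b$b_plus * (1 + 1e-6))
})

test_that("accepted scale draws follow the normalized marginal posterior", {
  x <- make_bs_sample(20, 0.5, 1, seed = 53)
  hyper <- bs_hyper()
  s <- rou_sample_beta(x, hyper, M = 20000, seed = 6)
  expect_length(s$beta, 20000)
  expect_gt(s$acceptance_rate, 0)
  # quadrature-normalized cdf of the kernel as the oracle
  b <- rou_bounds(x, hyper)
  dens <- function(t) exp(log_marginal_beta(t, x, hyper) - b$log_shift)
  Z <- integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  cdf <- function(q) {
    vapply(q, function(qi)
      integrate(dens, 0, qi, rel.tol = 1e-9)$value / Z, numeric(1))
  }
  qs <- quantile(s$beta, seq(0.02, 0.98, by = 0.02), names = FALSE)
  emp <- ecdf(s$beta)(qs)
  expect_lt(max(abs(emp - cdf(qs))), ks_crit_1pct(20000))
  # fixed seed reproduces the draw sequence
  s2 <- rou_sample_beta(x, hyper, M = 20000, seed = 6)
  expect_identical(s2$beta, s$beta)
})

test_that("conditional shape draws match the inverse-gamma closed form", {
  x <- make_bs_sample(15, 0.5, 2, seed = 54)
  hyper <- bs_hyper()
  n <- length(x)
  beta0 <- 2.2
  a <- sample_alpha_given_beta(rep(beta0, 1e5), x, hyper, seed = 8)
  expect_true(all(a > 0))
  shape <- n / 2 + hyper$a2
  scl <- sum(x / beta0 + beta0 / x - 2) / 2 + hyper$b2
  m_theory <- scl / (shape - 1)                    # E[alpha^2]
  v_theory <- m_theory^2 * 2 / (shape - 2)         # Var[alpha^2]
  se <- sqrt(v_theory / 1e5)
  expect_lt(abs(mean(a^2) - m_theory), 3 * se)
  # constant sample at beta = c collapses the data term to b2
  cx <- rep(3, 8)
  ig_scale <- sum(cx / 3 + 3 / cx - 2) / 2 + hyper$b2
  expect_equal(ig_scale, hyper$b2)
})

test_that("posterior percentile draws behave per the closed form", {
  x <- make_bs_sample(40, 0.5, 1, seed = 55)
  post <- bs_posterior(x, M = 800, seed = 10)
  expect_s3_class(post, "bs_posterior")
  # p = 0.5 returns the scale draws exactly
  expect_identical(posterior_theta(post, 0.5), post$beta)
  # increasing p increases every draw
  t6 <- posterior_theta(post, 0.6)
  t9 <- posterior_theta(post, 0.9)
  expect_true(all(t9 > t6))
  # draws reproduce the percentile formula pairwise
  expect_equal(t9, mapply(function(a, b) bs_percentile(a, b, 0.9),
                          post$alpha, post$beta),
               tolerance = 1e-12)
})

test_that("posterior concentrates and the pipeline is scale-equivariant", {
  x <- make_bs_sample(500, 0.5, 1, seed = 56)
  post <- bs_posterior(x, M = 2000, seed = 12)
  expect_lt(abs(mean(post$beta) - 1), 0.05)
  # near-flat priors: scaling the data scales the percentile interval
  y <- make_bs_sample(100, 0.5, 1, seed = 57)
  ci1 <- bayes_interval(y, M = 2000, seed = 14)
  ci10 <- bayes_interval(10 * y, M = 2000, seed = 14)
  expect_equal(c(ci10$lower, ci10$upper) / c(ci1$lower, ci1$upper),
               c(10, 10) / c(1, 1) / 1, tolerance = 1e-2)
})

test_that("interval summaries of draws: equal-tail convention, HPD optimality", {
  expect_equal(credible_interval(1:100, 0.90), c(5.95, 95.05))
  expect_equal(credible_interval(rep(4, 200), 0.95), c(4, 4))
  # nesting
  d <- rlnorm(5000)
  ci95 <- credible_interval(d, 0.95)
  ci99 <- credible_interval(d, 0.99)
  expect_lte(ci99[1], ci95[1])
  expect_gte(ci99[2], ci95[2])
  # HPD never longer than equal-tailed, and shorter on skewed draws
  set.seed(15)
  for (gen in list(function() rlnorm(2000), function() rexp(2000),
                   function() rnorm(2000))) {
    dd <- gen()
    h <- hpd_interval(dd, 0.95)
    e <- credible_interval(dd, 0.95)
    expect_lte(diff(h), diff(e))
  }
  skewed <- rlnorm(5000, sdlog = 1)
  expect_lt(diff(hpd_interval(skewed, 0.95)),
            diff(credible_interval(skewed, 0.95)))
  # symmetric unimodal: HPD matches equal-tailed within MC tolerance
  z <- rnorm(50000)
  expect_equal(hpd_interval(z, 0.95), credible_interval(z, 0.95),
               tolerance = 0.05)
})
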