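test_that("density has the closed-form value at the scale and integrates to 1", {
  for (prm in list(c(0.5, 1), c(1.25, 31.93), c(2, 0.3))) {
    a <- prm[1]; b <- prm[2]
    expect_equal(dbs(b, a, b), 1 / (a * b * sqrt(2 * pi)), tolerance = 1e-12)
  }
  total <- integrate(function(t) dbs(t, 0.5, 1), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # density vanishes at the origin
  expect_lt(dbs(1e-8, 0.5, 1), 1e-12)
  # log form is finite where the density is positive
  expect_true(all(is.finite(dbs(c(1e-6, 1, 1e6), 0.5, 1, log = TRUE))))
})

test_that("distribution function is the normal transform and inverts the percentile", {
  expect_equal(pbs(2, 0.7, 2), 0.5, tolerance = 1e-14)
  # round trip at several probabilities
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(pbs(qbs(p, 0.8, 3), 0.8, 3), p, tolerance = 1e-10)
  }
  # monotone in x
  grid <- seq(0.1, 10, length.out = 200)
  expect_true(all(diff(pbs(grid, 0.5, 1)) > 0))
  # numeric derivative of the cdf matches the density
  h <- 1e-6
  num <- (pbs(grid + h, 0.5, 1) - pbs(grid - h, 0.5, 1)) / (2 * h)
  expect_equal(num, dbs(grid, 0.5, 1), tolerance = 1e-6)
})

test_that("percentile formula: median is the scale, scale equivariance, reciprocal symmetry", {
  expect_identical(bs_percentile(1.25, 31.93, 0.5), 31.93)
  expect_identical(bs_percentile(3, 1, 0.5), 1)
  # strictly increasing in p and equivariant in the scale
  ps <- seq(0.05, 0.95, by = 0.05)
  th <- bs_percentile(0.7, 2.5, ps)
  expect_true(all(diff(th) > 0))
  expect_equal(bs_percentile(0.7, 7 * 2.5, ps), 7 * th, tolerance = 1e-12)
  # theta(p) * theta(1-p) = beta^2
  expect_equal(bs_percentile(0.7, 2.5, ps) * bs_percentile(0.7, 2.5, 1 - ps),
               rep(2.5^2, length(ps)), tolerance = 1e-10)
  # against root-finding on the cdf
  root <- uniroot(function(t) pbs(t, 1, 1) - 0.975, c(1e-6, 1e3),
                  tol = 1e-12)$root
  expect_equal(bs_percentile(1, 1, 0.975), root, tolerance = 1e-8)
})

test_that("random generation matches the distribution", {
  # degenerate transform at z = 0 returns the scale
  expect_equal(bsperc:::bs_from_normal(0, 0.5, 2), 2)
  x <- make_bs_sample(50000, 0.5, 2, seed = 11)
  expect_true(all(x > 0))
  # empirical median near beta (theta(0.5) = beta)
  med <- median(x)
  se <- 1.2533 / (2 * dbs(2, 0.5, 2)) / sqrt(length(x)) # asymptotic median SE
  expect_lt(abs(med - 2), 3 * se)
  expect_lt(ks_distance(x, function(t) pbs(t, 0.5, 2)),
            ks_crit_1pct(length(x)))
  # reproducible under a fixed seed
  expect_identical(make_bs_sample(10, 0.5, 2, seed = 3),
                   make_bs_sample(10, 0.5, 2, seed = 3))
})

test_that("sufficient summaries match hand arithmetic and degenerate cases", {
  st <- bs_stats(toy_sample)
  expect_equal(st$I, 1.5)
  expect_equal(st$J, 0.75)
  expect_equal(st$K, 0.5)
  expect_equal(st$L, 0.125)
  expect_equal(st$S1, 5)
  expect_equal(st$S2, 1.25)
  expect_equal(st$n, 2L)
  cst <- bs_stats(rep(9, 5))
  expect_equal(cst$I, 3)
  expect_equal(cst$J, 1 / 3)
  expect_equal(cst$K, 0, tolerance = 1e-14)
  expect_equal(cst$L, 0, tolerance = 1e-14)
  expect_equal(cst$S1, 45)
  expect_equal(cst$S2, 5 / 9)
  # I*J >= 1 on arbitrary positive samples (AM-GM on sqrt scale)
  for (s in 1:5) {
    z <- exp(rnorm(20, sd = 2))
    stz <- bs_stats(z)
    expect_gte(stz$I * stz$J, 1)
  }
  expect_error(bs_stats(c(1, -2, 3)), "index 2")
  expect_error(bs_stats(5), "at least 2")
})

test_that("maximum-likelihood fit is scale-equivariant and recovers truth", {
  x <- make_bs_sample(300, 0.5, 1, seed = 5)
  f1 <- bs_fit(x)
  f2 <- bs_fit(10 * x)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$beta, 10 * f1$beta, tolerance = 1e-6)
  expect_error(bs_fit(rep(2, 10)), "constant")
  # parameter recovery: 500 replicates at n = 1000
  set.seed(99)
  est <- replicate(500, {
    z <- rbs(1000, 0.5, 1)
    e <- bsperc:::bs_mle_core(z)
    c(e$alpha, e$beta)
  })
  expect_lt(abs(mean(est[1, ]) - 0.5), 0.02)
  expect_lt(abs(mean(est[2, ]) - 1), 0.02)
})

test_that("fit object supports the standard modelling methods", {
  x <- make_bs_sample(200, 0.5, 2, seed = 7)
  fit <- bs_fit(x)
  expect_s3_class(fit, "bs_fit")
  expect_named(coef(fit), c("alpha", "beta"))
  expect_equal(AIC(fit), 4 - 2 * fit$loglik)
  expect_equal(unname(quantile(fit, 0.5)), fit$beta)
  expect_output(print(fit), "alpha")
  expect_output(print(summary(fit)), "percentiles")
  set.seed(1)
  sim <- simulate(fit)
  expect_length(sim, fit$n)
  expect_true(all(sim > 0))
  # quantile residuals are standard normal under the fitted model
  r <- residuals(fit)
  expect_gt(shapiro.test(r)$p.value, 1e-4)
})
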