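# Shared fixtures built in code.

# Tiny hand-checkable sample: sqrt(x) = (1, 2).
toy_sample <- c(1, 4)

# A modest reproducible BS sample for property tests.
make_bs_sample <- function(n, alpha, beta, seed) {
  set.seed(seed)
  rbs(n, alpha, beta)
}

# Kolmogorov-Smirnov distance between draws and a numeric cdf given as a
# function.
ks_distance <- function(draws, cdf) {
  s <- sort(draws)
  n <- length(s)
  u <- cdf(s)
  max(pmax(abs((1:n) / n - u), abs(u - (0:(n - 1)) / n)))
}

# 1% critical value of the one-sample KS statistic (asymptotic).
ks_crit_1pct <- function(n) 1.6276 / sqrt(n)
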