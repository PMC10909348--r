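---
title: "Interval estimation for Birnbaum-Saunders percentiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation for Birnbaum-Saunders percentiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsperc)
```

## The model

The Birnbaum-Saunders (fatigue-life) distribution is a right-skewed model
for positive data with shape $\alpha > 0$ and scale $\beta > 0$ and density

$$f(x;\alpha,\beta) = \frac{1}{2\alpha\beta\sqrt{2\pi}}
\left[\Big(\tfrac{\beta}{x}\Big)^{1/2} + \Big(\tfrac{\beta}{x}\Big)^{3/2}\right]
\exp\left\{-\frac{1}{2\alpha^2}\Big(\frac{x}{\beta}+\frac{\beta}{x}-2\Big)\right\},
\qquad x > 0.$$

It arises from cumulative-damage arguments (failure when accumulated crack
growth crosses a threshold) and fits airborne particulate concentrations
well, which is the application shipped with the package: two daily PM2.5
series (`bs_dataset("maehongson")`, `bs_dataset("lampang")`).

The transform $Z = (\sqrt{x/\beta}-\sqrt{\beta/x})/\alpha$ is standard
normal, giving the closed-form percentile

$$\theta_p = \frac{\beta}{4}\left(\alpha z_p + \sqrt{\alpha^2 z_p^2 + 4}\right)^2,
\qquad z_p = \Phi^{-1}(p),$$

the quantity every interval method here targets. Useful identities the test
suite exercises: $\theta_{0.5} = \beta$ exactly,
$\theta_p\,\theta_{1-p} = \beta^2$, and scale equivariance
$\theta_p(\alpha, c\beta) = c\,\theta_p(\alpha,\beta)$.

For skewed exposure data the percentile is usually the quantity of
interest — a median or an upper percentile describes "typical" and "bad"
days directly, where a mean is dragged by the long right tail.

## Maximum likelihood

`bs_fit()` profiles the likelihood over $\beta$: for fixed scale the shape
MLE is closed-form, $\hat\alpha^2(\beta) = S_1/(n\beta) + \beta S_2/n - 2$
with $S_1 = \sum x_i$, $S_2 = \sum 1/x_i$. The resulting one-dimensional
profile is maximized with `optimize()` over a geometrically widened
`[min(x), max(x)]` bracket. We chose direct profile maximization over a
root search on the profile score because it is derivative-free, the
optimum is provably interior (the scale MLE lies between the harmonic and
arithmetic sample means), and a unimodal 1-D maximization is as robust as
a safeguarded root search while being simpler. Constant samples are
rejected: the fit would degenerate to $\hat\alpha = 0$ and the pivotal
machinery downstream divides by the sample's spread.

## The four interval constructions

**Generalized confidence interval (GCI).** The scale admits a generalized
pivotal quantity $R_\beta$ obtained by solving the quadratic
$A\beta^2 - 2B\beta + C = 0$ whose coefficients mix the sufficient
summaries $I, J, K, L$ of the $\sqrt{x}$ scale with a $t(n-1)$ pivot $T$;
the root choice follows the sign of $T$ (larger root for $T \le 0$,
smaller otherwise). Conditional on $R_\beta$, a $\chi^2(n)$ pivot $V$
yields $R_\alpha$, and substituting both into the percentile formula gives
$R_\theta$. The equal-tailed empirical quantiles of $M$ simulated
$R_\theta$ values form the interval. Draws whose quadratic roots are not
both real and positive carry no valid pivot; they are resimulated, with a
cap of $100M$ total attempts so a pathological sample terminates with an
error instead of looping. The resimulation count is reported on the
returned object because its rate is an informative diagnostic that the
construction itself does not surface.

**Bias-corrected bootstrap.** The MLEs are recomputed on $B$ bootstrap
samples; the twofold bias correction
$\tilde\vartheta_k = \hat\vartheta^*_k - 2(\bar{\vartheta^*}-\hat\vartheta)$
is applied per replicate, each corrected pair is mapped through the
percentile formula, and the equal-tailed quantiles of the replicate
percentiles form the interval. Resampling is *parametric* by default
(samples drawn from the fitted model): the bias correction is defined
against the fitted model, so drawing from it is the coherent choice; a
`resampling = "nonparametric"` flag resamples the data with replacement
for users who prefer the distribution-free variant, and both schemes are
tested. A corrected shape may undershoot zero — the percentile formula
tolerates that, so the replicate is kept; a nonpositive corrected *scale*
makes the percentile meaningless and the replicate is dropped with a
warning counting the drops.

**Bayesian credible interval.** Independent inverse-gamma priors are
placed on $\beta$ (parameters $a_1, b_1$) and $\alpha^2$ ($a_2, b_2$).
Integrating $\alpha^2$ out gives a one-dimensional marginal posterior
kernel for $\beta$, sampled *exactly* by the generalized ratio-of-uniforms
method: $(u, v)$ uniform on $[0, a(r)]\times[0, b^+(r)]$, candidate
$\rho = v/u^r$, accepted when $u \le p(\rho\mid x)^{1/(r+1)}$. Given each
accepted $\beta$, $\alpha^2$ has an inverse-gamma conditional in closed
form. The draws are therefore independent — this is rejection sampling,
not an MCMC chain, so no burn-in or convergence diagnostics apply. The
equal-tailed quantiles of the induced percentile draws form the credible
interval.

**HPD interval.** The same posterior draws, summarized instead by the
shortest window: among all contiguous runs of $\lceil \mathrm{level}\cdot
M\rceil$ sorted draws the narrowest is returned (ties break to the
smallest lower endpoint). For a unimodal posterior this is the highest
posterior density interval; by construction it is never longer than the
equal-tailed interval on the same draws. We use the sorted-window method
rather than density estimation because it is deterministic given the
draws and matches the behaviour of standard HPD utilities on unimodal
posteriors.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `p` | 0.5 | percentile under study (median) |
| `level` | 0.95 | confidence / credible level |
| `M` (GCI) | 5000 | pivotal draws; quantile noise shrinks as $1/\sqrt{M}$ |
| `B` | 500 | bootstrap replicates; each costs one MLE refit |
| `M` (Bayes/HPD) | 5000 (single analysis), 1000 (simulation engine) | posterior draws |
| `a1,b1,a2,b2` | $10^{-4}$ | inverse-gamma prior parameters; the defaults are near-flat so the data dominate |
| `r` | 2 | ratio-of-uniforms constant; $r=2$ keeps both rectangle bounds finite with these priors |

The near-flat defaults make the Bayesian pipeline scale-equivariant in the
data to good approximation (the prior breaks exact equivariance; the test
suite checks agreement to 1% relative at $n = 100$).

## Numerical choices

- **Quantile convention.** All empirical intervals use linear interpolation
  between order statistics (R's type 7). At the draw counts used the
  convention is far below the Monte Carlo noise floor.
- **Log-domain kernel.** The marginal posterior kernel underflows double
  precision at $n \approx 180$; every bound search and acceptance test
  works with the log kernel shifted by its maximum. The accepted-draw
  distribution is invariant to kernel rescaling, so the shift changes
  nothing statistically while making $a(r) = 1$ exactly.
- **Bound search.** $a(r)$ and $b^+(r)$ are maximized over $\log\beta$
  with multistart from sample quantiles; the objectives are unimodal in
  practice but multistart guards against flat stretches, and the test
  suite verifies on a dense grid that neither objective exceeds the
  returned supremum. With near-flat priors the $b^+$ objective decays only
  like $\beta^{-2(a_1+a_2)/3}$ far in the tail, which is why the search
  works on the log scale over a generous bracket.
- **Invalid pivotal draws** are signalled with `NA` rather than exceptions,
  resimulated upstream, and counted.
- **Degenerate inputs.** Nonpositive observations are rejected with the
  offending index; constant samples are rejected outright.

## The simulation engine

`bs_coverage_cell()` reproduces the standard coverage-probability /
average-length experiment: draw a sample from known $(\alpha, \beta)$,
build every requested interval on the *same* sample, record whether the
true $\theta_p$ is covered and how long the interval is, repeat, and
average. Replicate $k$ runs under a child seed derived from the master
seed, which makes cells reproducible, keeps methods paired within a
replicate (a variance-reduction choice — whether the original study paired
methods per replicate is not documented), and lets the Bayesian and HPD
summaries share one posterior sample per replicate.

The engine reports the binomial Monte Carlo standard error
$\sqrt{c(1-c)/\mathrm{reps}}$ next to each coverage estimate, so reduced
runs are honest about their resolution. The test suite runs the full
$n \in \{10,30,50,100\} \times \alpha \in \{0.10,\dots,1.00\}$ grid at
5000 replications for the GCI (cheap: the GPQ simulation vectorizes), and
two representative cells at 500 replications for the bootstrap, Bayesian
and HPD methods, whose per-replicate cost is dominated by $B$ MLE refits
and the rejection sampler respectively; those sizes keep the whole suite
in the minutes range on one core while leaving the coverage resolution
(±0.01 and ±0.03 respectively at 3 SEs) fine enough to be meaningful.

What the generator emulates — and what it does not: samples are i.i.d.
Birnbaum-Saunders draws. Real PM2.5 series are serially correlated,
seasonal, and only approximately stationary, none of which the generator
reproduces; passing coverage under the generator shows the interval
constructions are correct *under the model*, not that a 95% interval on a
real series has 95% frequentist coverage.

## Model screening

`bs_aic_table()` fits seven candidate families and ranks them by
$\mathrm{AIC} = 2k - 2\log L$. Normal, log-normal and exponential MLEs
are closed-form (variances with divisor $n$, so the reported values are
exact likelihood maxima); Weibull, gamma and Cauchy go through
`fitdistrplus::fitdist()`; the Birnbaum-Saunders fit is the package's
own. Parameter counts: 1 for the exponential, 2 for the rest. The AIC is
parameterization-invariant, but the parameterizations are pinned (Weibull
shape/scale, gamma shape/rate, Cauchy location/scale, log-normal
meanlog/sdlog) so numerical results are stable across optimizer starts.

## Known limitations

- Two-parameter model only: no location shift, no censoring, no
  regression structure.
- The GCI machinery is specific to the percentile; pivots for the
  variance or coefficient of variation are out of scope.
- The bootstrap is the plain bias-corrected percentile construction; BCa
  and studentized variants are not implemented.
- At very small $n$ (below ~10) the GPQ quadratic produces invalid draws
  more often and the bootstrap refit can fail on degenerate resamples;
  both paths are guarded, but users should expect the bootstrap interval
  to under-cover there — that is a property of the method, reproduced by
  the simulation engine, not a defect of the implementation.
- The Lampang fixture transcribes its published source verbatim,
  including one abrupt adjacent pair (`16.91, 8.2`) that may be a
  typesetting artifact in the source table.
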