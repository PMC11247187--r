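# sctmm

Scalable continuous-time Markov multistate models with covariates, for
interval-censored panel data.

Longitudinal cohorts in chronic disease — the motivating case is
multiple sclerosis, where disability is scored on the ordinal EDSS
scale at clinic visits every few months — record each subject's state
at visit times only; when the state actually changed is never
observed.  The continuous-time Markov model (CTMM) is the standard
tool for such panels: a generator matrix $Q$ of transition intensities
$q_{ij}$ drives the process, and the probability of the observed move
over a gap of length $\tau$ is an entry of the matrix exponential,
$P(\tau) = \mathrm{Exp}(Q\tau)$.  Covariates act proportionally on
each transition,

$$q_{ij}(z) = q^0_{ij}\exp\Big(\sum_r z_r\,\beta_{ij,r}\Big),$$

so $\exp(z_r\hat\beta_{ij,r})$ is a transition-specific hazard ratio.
The obstacle at scale is that the likelihood, its score and its
Hessian need matrix exponentials for *every* observation interval.
`sctmm` makes this tractable:

* exact score and Hessian from **block-matrix (Padé) Fréchet
  derivatives** of the matrix exponential — an adjoint identity
  collapses the full gradient to *one* block exponential per interval,
  regardless of the number of parameters, with compiled
  (RcppArmadillo) kernels underneath;
* **mini-batch stochastic gradient ascent** with a decaying learning
  rate, random restarts, warmstart and distance-decay initialization
  policies, so cohorts of tens of thousands of subjects are feasible;
* **Wald confidence intervals** from two Hessian constructions — the
  exact block-Padé form (default) and a cheaper truncated power-series
  form for large state spaces — plus transition-specific hazard
  ratios;
* an **exact trajectory simulator** (stationary initialization,
  exponential sojourns, embedded-chain jumps, scheduled assessment
  visits, time-varying covariates) and a **Monte-Carlo harness**
  reporting bias, variance, coverage and rejection rates;
* tidyverse-native surfaces: panels are tibbles, results come back as
  tibbles via `tidy()`/`glance()`, plots via `autoplot()` and
  `plot_*()` helpers, and a thin command-line front end lives in
  `inst/cli/sctmm.R`.

## Worked example

Simulate a four-state birth–death cohort (300 subjects, 15 years,
6-monthly visits) with a true effect of a relapse covariate
($\beta = 0.4$ on every transition) and a null age covariate, then
refit it:

```r
library(sctmm)

ss    <- state_space(0:3)
st    <- all_transitions(ss, max_jump = 1)        # adjacent moves only
truth <- ctmm_params(q0 = rep(0.5, nrow(st)),
                     beta = matrix(c(rep(0.4, 6), rep(0, 6)), 6, 2),
                     st, covariate_names = c("relapse", "age10"))

panel <- simulate_panel(sim_config(M = 300, params = truth), seed = 42)

fit <- ctmm_fit(panel, st, covariates = c("relapse", "age10"),
                control = ctmm_control(batch_size = 75, max_iters = 250,
                                       restarts = 3),
                seed = 1)
fit
#> <ctmm_fit> transition_dependent | M = 300 subjects, 9000 intervals
#> log-likelihood: -6947.9957  (restart 2, 250 iters, converged: FALSE)
#>   0->1   1->0   1->2   2->1   2->3   3->2
#> 0.5064 0.4800 0.5133 0.5303 0.4893 0.4877
```

All six baseline intensities are recovered near the true 0.5 events
per year.  Wald intervals and hazard ratios:

```r
ci <- ctmm_ci(panel, fit)          # block-Pade Hessian, 95% intervals
ci
#> # A tibble: 18 x 10
#>   term          type  transition covariate estimate std.error statistic conf.low
#> 1 q0(0->1)      q0    0->1       <NA>        0.506     0.0252    20.1      0.459
#> 2 beta(0->1,re… beta  0->1       relapse     0.595     0.173      3.45     0.257
#> 3 beta(0->1,ag… beta  0->1       age10       0.0228    0.169      0.135   -0.308
#> ...

hazard_ratios(ci) |> dplyr::filter(covariate == "relapse")
#> # A tibble: 6 x 6
#>   transition covariate    at    hr conf.low conf.high
#> 1 0->1       relapse       1  1.81    1.29       2.54
#> 2 1->0       relapse       1  1.75    1.25       2.45
#> 3 1->2       relapse       1  1.32    0.957      1.83
```

The per-unit hazard ratio on the 0→1 transition is 1.81 (95% CI
1.29–2.54): a one-unit higher relapse covariate nearly doubles the
worsening intensity (the generating truth is $e^{0.4} = 1.49$, inside
every interval).  The null `age10` coefficients sit near zero and are
not rejected.  A quick plausibility check against the raw panel:

```r
round(empirical_transition_matrix(panel), 3)
#>       0     1     2     3
#> 0 0.796 0.180 0.023 0.001
#> 1 0.169 0.650 0.157 0.025
#> 2 0.022 0.164 0.644 0.170
#> 3 0.002 0.023 0.169 0.806
autoplot(fit, tau = 0.5)   # fitted Exp(Q/2) as a heatmap
```

Subjects mostly hold their state between 6-monthly visits and move to
neighbours otherwise — the structure the fitted $\mathrm{Exp}(Q\tau)$
reproduces.  Operating characteristics of the whole pipeline come from
the Monte-Carlo harness:

```r
mc <- run_scenario(mc_scenario(M = 200, S = 4, R = 2, true_beta = 0,
                               n_replicates = 50, seed = 1))
tidy(mc, "aggregate")
```

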