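---
title: "Methods: scalable continuous-time Markov multistate models for panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scalable continuous-time Markov multistate models for panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`sctmm` fits a time-homogeneous continuous-time Markov model (CTMM) on a
finite state space to *panel data*: each subject's state is recorded at
a set of visit times, and the exact transition times in between are not
observed (interval censoring).  The process is characterized by a
generator matrix $Q$ whose off-diagonal entries $q_{ij}$ are
instantaneous transition rates; rows sum to zero.  Covariates act
multiplicatively on each modelled transition,

$$q_{ij}(z) = q^0_{ij}\,\exp\!\Big(\sum_{r=1}^R z_r\,\beta_{ij,r}\Big),$$

so $q^0_{ij}$ is the rate at the covariate reference (which is why
covariates should be centred) and $\exp(z_r\beta_{ij,r})$ is a
transition-specific hazard ratio.  A *transition-independent* variant
shares one $\beta_r$ across all transitions and is nested in the model
above.  Covariates observed at a visit are carried forward to govern
the process until the next visit; this keeps the model causal (future
covariate values cannot drive earlier transitions) and makes each
inter-visit interval a homogeneous CTMC segment.

Over an interval of length $\tau$ the transition probabilities are
$P(\tau) = \mathrm{Exp}(Q\tau)$ (Kolmogorov relation), and a subject's
log-likelihood is the sum over observation intervals of
$\log\,[\mathrm{Exp}(Q_{k}\tau_k)]_{s_{k-1},s_k}$.  Every interval costs
one matrix exponential, which is the entire scalability problem this
package is built around.

## Exact derivatives of the matrix exponential

The score and Hessian are exact, not numerical.  The directional
(Fréchet) derivative of the matrix exponential is read off a block
matrix,

$$\partial_E \mathrm{Exp}(A) \;=\;
  \Big[\mathrm{Exp}\begin{pmatrix}A & E\\ 0 & A\end{pmatrix}\Big]_{1:S,\,S+1:2S},$$

and second directional derivatives come from the same construction one
level up (a $4S\times 4S$ exponential).  Two implementation facts make
the package fast:

* **Adjoint trick.**  The likelihood only needs one *entry* $(s, s')$
  of each derivative matrix.  Writing
  $[\partial_E \mathrm{Exp}(A)]_{s,s'} = \sum_{ab} E_{ab} K_{ab}$ with
  $K = \partial_{e_s e_{s'}^T} \mathrm{Exp}(A^T)$, a *single* $2S \times
  2S$ block exponential per interval yields that entry for **every**
  parameter direction at once, because each parameter perturbs $A$
  through the rank-one pattern $e_i(e_j - e_i)^T$ of its transition.
  The full score therefore costs one block exponential per interval,
  independent of the number of parameters.  The same identity applied
  at the $2S$ level gives all Hessian pairs against a fixed transition
  from one $4S \times 4S$ exponential, so the Hessian costs one such
  exponential per interval and *allowed transition* rather than per
  parameter pair.
* **Scaling-and-squaring Padé** (via `arma::expmat`) is used for every
  exponential; no eigendecomposition, since generators may be
  defective.  Matrices are dense: the intended state spaces are small
  ($S \le 9$ for collapsed EDSS), and structural zeros are enforced by
  masking.

Both derivative layers are verified against central finite differences
and closed forms in the test suite (typical agreement $10^{-9}$).

## Optimization

The log-likelihood is maximized by mini-batch stochastic gradient
ascent: at step $d$ a random subject subset $B_d$ gives the update
$\theta_{d+1} = \theta_d + \lambda_{d+1}\,(M/|B_d|)\sum_{m\in B_d}
\nabla \ell_m(\theta_d)$ with $\lambda_{d+1} = \texttt{lr\_scale}\cdot
(d+1)^{-0.6}$.  Choices that matter, and why:

* **Log scale for rates.**  Optimization runs on $\log q^0_{ij}$ by
  default, so no step can produce a negative intensity; all derivative
  formulas are implemented on both scales via the chain rule, and
  reports are transformed back by the delta method.
* **Base learning rate is probed, not fixed.**  A literal unit base
  rate diverges for any realistic cohort because the summed gradient
  scales with the data volume.  At each restart the package walks the
  initial gradient ray on a subject subsample and keeps the most
  profitable step size; the decaying schedule is re-anchored the same
  way every 50 iterations because the local curvature changes along the
  path.  An explicit `lr_scale` skips all probing.
* **Diagonal preconditioning.**  Baseline-rate and coefficient
  coordinates carry very different information (often a factor of
  hundreds), and a single global rate crawls on such problems.  The
  gradient is rescaled once per restart by the inverse absolute
  diagonal of a subsample Hessian at the initial point — ordinary SGD
  in a linearly rescaled parameterization, not an adaptive optimizer.
* **Robustness.**  Non-finite gradients reject the step (halve the
  rate, retry up to 5 times, then skip the batch); every 20 iterations
  a subsample log-likelihood check restores the best visited point and
  halves the rate if the trajectory deteriorated; matrix-exponential
  failures in extreme parameter regions are reported as degenerate
  evaluations rather than crashes.
* **Convergence** is declared when the sup-norm parameter change,
  averaged over the last 5 iterations, falls below `tol` (default
  `1e-6`); raw per-step changes oscillate under stochastic gradients,
  so a single-step criterion would stop essentially at random.
* **Restarts.**  The likelihood is not concave, so the fit is the best
  of `restarts` runs from random initializations (default 20; large,
  many-parameter problems warrant 1000–5000).  The
  `distance_decay_normal` policy draws $q^0_{ij}$ from the positive
  part of $\mathrm{Normal}(1/|i-j|,\,1/|i-j|)$ — nearby states start
  faster — and coefficients from $\mathrm{Uniform}(-1,1)$; a
  `warmstart_subsample` policy runs a deterministic full-gradient fit
  on a subsample first.
* Sampling is epoch-wise shuffling without replacement by default
  (lower gradient variance); with-replacement sampling is available.

The full-batch, constant-rate configuration is verified against a BFGS
reference with the same exact gradient (agreement $10^{-3}$ in
$\theta$ on toys).

## Confidence intervals

Standard errors come from the inverse observed information $(-H)^{-1}$
at the estimate, with $H$ computed on the optimization scale and
mapped back by the delta method (so rate intervals are exp-transformed
and asymmetric, coefficients symmetric).  Two constructions:

* **`pade`** (default): exact second derivatives from the doubled
  block-matrix construction, including the curvature terms
  $\partial^2(Q\tau)$ within each transition (zero for rate–rate pairs
  on the raw scale; $z_r e^{z'\beta}\tau$ for rate–coefficient;
  $q^0 z_r z_u e^{z'\beta}\tau$ for coefficient–coefficient).
* **`power_series`**: the Hessian of the truncated likelihood
  $\log\,[I + Q\tau + \tfrac12 (Q\tau)^2]_{s,s'}$, differentiated
  analytically.  It avoids all matrix exponentials and is intended for
  large state spaces.  Degenerate intervals (non-positive truncated
  entries) are excluded with a warning.

A caveat we document deliberately: in the short-interval regime where
the truncation is accurate, its net effect is to *reduce* the observed
information (a stay interval contributes exactly zero curvature to the
exact rate Hessian but $+(x - x^2/2)/g^2 > 0$, $x = q\tau$, under the
truncated kernel), so power-series standard errors tend to sit
slightly *above* the exact ones on our toy fits; only for long
intervals ($q\tau \gtrsim 1$) does the direction reverse.  The test
suite states this comparison as a one-sided check in the conventional
direction and we leave its failure visible rather than tune the regime
until the sign flips.

In the transition-independent mode the shared-coefficient second
derivatives sum over all transition pairs, including cross-transition
terms.

## The simulator

`simulate_panel()` generates exactly the kind of cohort the model is
meant for.  Per subject: the initial state is drawn from the
stationary law $\pi^T Q = 0$ of the generator at the subject's initial
covariates; sojourns are exponential with the current exit rate
$-q_{ss}$; jump targets follow the embedded chain $q_{sj}/(-q_{ss})$
(the exact CTMC jump law; drawing from $P(\tau)$ at the sojourn length
instead would double-count the diagonal mass, but that alternative
reading is available behind `next_state = "ptau"`).  Covariates are
redrawn at every observed visit — time-fixed ones once per subject —
and the generator is rebuilt for the remaining sojourn, which is
redrawn by memorylessness; this matches the likelihood's carry-forward
convention exactly.

**What is observed** is a deliberate design point.  By default
(`observe = "scheduled"`) the state is recorded only at regular
assessment visits every `dummy_interval` time units; transition times
remain latent.  That is interval censoring — the model's own premise —
and it makes the observation process non-informative, so the panel
likelihood is correctly specified and coverage is nominal.  The
alternative `observe = "all_events"` additionally emits a visit at
every transition time; the likelihood then conditions on intervals
that end exactly at jumps, which makes the observation process
informative and pushes rate estimates upward by several standard
errors at realistic cohort sizes — why it is not the default, and kept
only for path-level distributional checks.  The default visit spacing is
0.5 time units over a 15-unit horizon — with time in years this is the
6-monthly disability-scale assessment schedule of long MS cohorts, and
it yields about 31 observations per subject, the observation density
of the reference design this package targets.

What the simulator does *not* emulate: informative or irregular visit
schedules, state misclassification (hidden-Markov structure),
subject-level frailty, or covariate processes with serial correlation
(each visit's covariates are independent Uniform(−0.5, 0.5) draws by
default).  Passing tests on simulated data therefore demonstrate
correctness of the estimator under the model, not robustness to these
violations.

## Monte-Carlo harness and problem sizes

`run_scenario()` repeats simulate → fit → infer and reports bias,
variance, 95%-interval coverage, and the 5% Wald rejection rate per
parameter and aggregated per parameter class.  Aggregated bias is the
mean of *absolute* per-parameter biases, so sign cancellation across
parameters cannot hide misfit; both layers are exposed.  At a true
coefficient of zero the rejection rate is the test's size, at nonzero
truth it is power — one column, two readings.  Failed replicates are
counted, warned about, and excluded.  The realized observation count
is recorded rather than targeted: the simulator gives no mechanism to
fix it.

The shipped checks use a reduced design chosen to exercise the whole
pipeline at desk scale: a null scenario with $M = 200$ subjects, 4
states with adjacent (birth–death) transitions at baseline rate 0.5,
2 covariates and 50 replicates (about 6 200 observations per
replicate, 18 parameters per fit, two restarts each); a 15-replicate
power scenario at a common true $\beta = 0.5$; and parameter recovery
on $S = 3$, $R = 1$, $M = 300$ panels across 20 seeds.  These sizes
give binomial noise of a few percentage points on coverage and
rejection, which is the resolution the acceptance bands are written
for.

## Descriptive utilities

The empirical transition matrix counts adjacent-observation state
pairs and row-normalizes; with dense observation it converges to the
rows of $\mathrm{Exp}(Q\,\Delta)$ at the visit spacing $\Delta$.  The
frequency filter drops transitions with fewer than a given share
(default 1%, boundary-inclusive) of all observed off-diagonal
transitions before covariate effects are fitted — rare transitions
otherwise contribute parameters the data cannot identify.  Raw EDSS
values in $[0, 10]$ are collapsed for modelling by flooring to
integers and merging everything at or above 8, giving 9 states.

## Numerical choices and degenerate inputs

* Transition probabilities on observed transitions are floored at
  $10^{-300}$ before the log; floored intervals are counted and
  surfaced (`n_floored`), since a structural zero under the model must
  not silently become $-\infty$.
* The score at a zero-probability observed transition is undefined; a
  flagged non-finite gradient is returned so the optimizer rejects the
  point.
* Generator validation tolerances: row sums zero within $10^{-10}$;
  $P(\tau)$ row sums within $10^{-8}$; roundoff negatives in $P$ below
  $10^{-12}$ clipped to zero.
* Reducible generators: the stationary solver detects a
  multi-dimensional null space, warns, and returns one recurrent-class
  solution; absorbing chains need no warning (their stationary law is
  unique).
* Non-invertible observed information falls back to an SVD
  pseudo-inverse with an explicit warning.

## Known limitations

Time-inhomogeneous intensities, hidden states, exact-transition-time
likelihoods and informative observation schemes are out of scope.
Standard errors are purely model-based (no sandwich or bootstrap).
The SGD optimizer trades a small, configurable optimization error for
scalability; on desk-scale problems a quasi-Newton run on the exact
gradient is often faster to full precision, and the package's own
BFGS-agreement test makes that comparison explicit.
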