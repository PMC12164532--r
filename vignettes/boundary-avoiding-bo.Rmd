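---
title: "Simulating Bayesian optimization of neuromodulation parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Bayesian optimization of neuromodulation parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurobo)
```

## The problem

Closed-loop tuning of neurostimulation devices is a global optimization
problem: a patient generates noisy trial-by-trial responses (reaction times,
physiological readouts, symptom scores) as a function of stimulation
parameters, and an algorithm must locate the parameters producing the best
response within a realistic number of trials. Two features make this setting
much harder than the benchmarks on which Bayesian optimization (BO) is
usually assessed:

* **Tiny effect sizes.** Within-subject effects of stimulation on
  neuro-psychiatric outcomes are typically a small fraction of the trial-to-
  trial noise — Cohen's d between roughly 0.1 and 0.6, with many outcomes
  near 0.2. The signal an optimizer must exploit is far below the noise
  floor of a single observation.
* **Safety constraints.** Charge delivery limits exclude part of the
  parameter space, and the constraint is a curve through the interior of
  the box, not a simple rectangle.

`neurobo` implements a complete simulation framework for studying how
GP-based BO behaves under these conditions, the specific failure mode that
emerges (boundary over-sampling), and its mitigation (a boundary-vanishing
kernel plus a safety-boundary input warp).

## Synthetic patient responses

A simulated patient maps two stimulation parameters — amplitude
$x \in [0, 500]\,\mu A$ and pulse width $y \in [0, 200]\,\mu s$ — to a
response surface built from 10 random sinusoids per axis:

$$f^o(x, y) = \sum_{i=1}^{10} A_{i,x,s} \sin(2\pi F_{i,x}\tilde x)
 + A_{i,x,c} \cos(2\pi F_{i,x}\tilde x)
 + A_{i,y,s} \sin(2\pi F_{i,y}\tilde y)
 + A_{i,y,c} \cos(2\pi F_{i,y}\tilde y)$$

with $A \sim U(-0.5, 0.5)$, $F \sim U(0, 1)$ cycles per normalized axis
length, $\tilde x = x/500$, $\tilde y = y/200$. The surfaces are smooth,
multi-modal, and anatomically plausible (at most 10 oscillations per axis).

A quadratic safety boundary $y_b(x) = (x - h)^2/a + k$ stands in for a
constant-charge tolerability curve, with $h \sim U(500, 1500)$,
$k \sim U(0, 200)$, and the curvature $a$ drawn uniformly over exactly the
interval for which the curve crosses the box, so every problem has a
nontrivial infeasible region in the upper-right (high-charge) corner.

Responses are forced to zero at zero dose and at the tolerability limit:
the surface is multiplied by a sigmoidal ramp $s(d)$ of the normalized
distances to the left edge, bottom edge, and safety curve. We use the
normalized power ramp

$$s(d) = \frac{d^{1.5}}{d^{1.5} + (0.2 - d)^{1.5}}, \quad 0 < d < 0.2,$$

clamped to 0 below and 1 above. The ramp is continuous, reaches exactly 1
at the ramp width 0.2, and equals 1/2 at the midpoint; a ramp of the form
$d^{1.5}/(0.2-d)^{1.5}$ would diverge as $d \to 0.2$ and cannot connect
continuously to the upper clamp, so the normalized form is the only
self-consistent reading of the piecewise definition. Distances are measured
in normalized coordinates (so the unitless ramp width 0.2 applies
isotropically), and the distance to the safety curve is the exact signed
Euclidean point-to-parabola distance, obtained by solving the cubic
stationarity condition of the squared distance in closed form.

Each accepted surface is rescaled so that its minimum equals $-ES$ for a
target effect size $ES$, and observations are drawn as
$N(f^R(x, y), 1)$ — so the problem's Cohen's d *is* the effect size.
Surfaces whose $|\min f^*|$ does not exceed $\max f^*$ are rejected and
resampled (cap: 1000 attempts; by the sign symmetry of the raw surfaces
roughly half of the draws pass), which makes the minimum the dominant
feature the optimizer must find. The study design uses 20 surfaces per effect size for
$ES \in \{0.1, \ldots, 0.6\}$ — 120 problems in the default set (the
per-effect-size count of 20 is the unit over which all medians and
confidence intervals are taken).

```{r problems}
problems <- generate_problem_set(effect_sizes = 0.3, per_es = 2, seed = 1)
problems[[1]]
```

## The GP surrogate and the boundary failure mode

The surrogate is a zero-mean GP with fixed unit observation noise.
Standard runs use a Matérn 5/2 kernel on normalized inputs; lengthscale and
outputscale are refit at session boundaries by maximizing the log marginal
likelihood (multi-start L-BFGS-B in log space, lengthscale bounded to
$[10^{-2}, 10]$, outputscale to $[10^{-4}, 10^2]$). The fit includes the
weakly informative hyperpriors the standard BO software stack places on
these parameters (Gamma(3, 6) on the lengthscale, Gamma(2, 0.15) on the
outputscale): with a handful of near-zero-signal observations and the noise
pinned at 1, the raw likelihood is almost flat and regularly collapses to
degenerate sub-0.05 lengthscales, a pathology the reference implementations
avoid precisely through these priors. A pure MLE fit is available via
`map_priors = FALSE`.

With space-filling training data, stationary kernels concentrate posterior
variance on the boundary of the input space: interior points have neighbors
on all sides, boundary points do not. The package quantifies this with the
**boundary variance ratio** — posterior variance on a discretization of the
boundary relative to a regular grid over the whole space. Two
normalizations are provided:

* `"mean"` (default): mean variance per boundary point over mean per grid
  point. Independent of discretization counts; exactly 1 under the prior.
* `"sum"`: total variance with matched per-axis resolutions, so the ratio
  also carries the boundary's surface-to-volume weight.

The distinction matters for one comparison only. The *growth* of the ratio
with training-set size and lengthscale is identical under both. But the
*dimension* ordering is not: per boundary point, a 1-D design of 256 points
crowds its 2 endpoints far harder than a 3-D design crowds its 6 faces, so
the mean ratio runs *against* dimension at matched $n$. The escalating
total impact of the boundary in higher dimensions — the surface-to-volume
effect that makes boundary over-exploration progressively worse as
parameters are added — is a statement about total variance mass and
appears in the sum normalization. Tests of the dimension trend therefore
use `normalization = "sum"`; everything else uses the mean form.

```{r bvr}
X <- sobol_design(256, 2, seed = 1)
gp <- gp_fit(X, rep(0, 256), kernel_spec("matern52", lengthscale = 0.5))
boundary_variance_ratio(gp, 2)
```

`samples_to_balance()` measures the cost of "fixing" the imbalance naively:
observations are added at the highest-variance boundary location until the
ratio drops below 1. The count grows rapidly with training-set size,
lengthscale, and dimension, which is why post-hoc balancing is not a
practical mitigation.

## Acquisition functions

Five strategies are implemented, all internally maximizing the negated
posterior mean $\tilde\mu = -\mu$ because the simulation goal is the surface
*minimum* while acquisition formulas are conventionally written for
maximization:

* **Maximum variance** — pure exploration; a benchmark for whether an
  exploration/exploitation balance adds anything.
* **UCB** — $\tilde\mu + \sqrt{\beta_t}\,\sigma$ with the zero-regret
  schedule $\beta_t = 2\log(t^3\pi^2/(3p))$, $p = 0.01$. The trial counter
  $t$ runs across sessions (the regret analysis behind the schedule is
  global; nothing in the protocol resets information between sessions).
* **GIBBON** — a max-value entropy-search score: the expected reduction in
  uncertainty about the optimal *value* from observing a point, averaged
  over Gumbel-approximated samples of the posterior maximum (16 by
  default). Scores are nonnegative and vanish where $\sigma^2 = 0$.
* **ε-greedy (Pareto)** — with probability $p = 0.1$ the greedy
  posterior-mean optimum; otherwise a uniform draw from the
  exploration–exploitation Pareto front (nondominated in
  $(\tilde\mu, \sigma^2)$), found by a compact NSGA-II (population 64,
  40 generations, simulated-binary crossover, polynomial mutation). The
  probability semantics follow the protocol definition exactly as stated
  (p is the probability of the *greedy* choice), even though conventional
  ε-greedy uses ε for the random arm.
* **PF-GIBBON** — the same mixture with the GIBBON suggestion taken with
  probability $p = 0.3$.

Acquisition maximization seeds multi-start L-BFGS-B from the best of a
1024-point random feasible pool (8 restarts, first-found tie-breaking); the
returned point is guaranteed feasible and at least as good as the pool. In
standard mode the true quadratic safety bound is the constraint, handled by
a smooth reparametrization $(x, t) \mapsto (x, t \cdot \min(200, y_b(x)))$
that turns the feasible region into a box. In boundary-avoiding mode the
domain is the full warped box and no constraint is needed.

## Boundary avoidance: IBBK and the safety warp

The **iterated Brownian-bridge kernel** replaces the Matérn in
boundary-avoiding runs:

$$k_1(u, v) = \sum_{n=1}^{N} (n^2\pi^2 + \varepsilon^2)^{-\beta}\,
  2\sin(n\pi u)\sin(n\pi v),$$

tensor-product across dimensions, with $\beta = 20$ and $\varepsilon = 50$
held fixed throughout (a deliberately tight kernel able to describe a broad
range of surfaces). The series is truncated at the smallest $N$ whose first
omitted eigenvalue is below $10^{-12}$ of the leading one ($N = 28$ for the
default parameters; $N \le 64$ in general). Because every eigenfunction
vanishes at 0 and 1, both the posterior mean and the posterior variance are
identically zero on the boundary of the unit square — no acquisition
function balancing mean and variance will ever choose a boundary point.
The raw eigen-series at these parameter values has magnitude around
$10^{-68}$, which would be invisible next to unit observation noise, so the
kernel is normalized to make its prior variance at the domain center equal
the outputscale (1, fixed: the kernel's parameters are not refit). Only the
effective outputscale is affected by this choice.

The IBBK protects the box edges but not the safety curve through the
interior. The **input warp** fixes that by mapping the safe region onto the
full box so the curve lands on the top/right edges. From the curve's
crossings with the top edge ($x_1$) and right edge ($y_1$), a split point
$x_o$ is located on the curve where the arc lengths on either side divide
in the ratio $(500 - x_1)/(200 - y_1)$ (closed-form parabola arc length,
bracketed root finding to $10^{-9}$). The warp direction $m$ is the slope
from $(x_o, y_b(x_o))$ to the corner $(500, 200)$. Each safe point is
displaced along the ray of slope $m$ through it by

$$d_w = D_s \cdot \frac{D_o}{D_p},$$

where along the ray $D_o$ is the distance from the bottom/left edge to the
point, $D_p$ the distance to the safety curve, and $D_s$ the remaining gap
from the curve to the outer box edge. This is the unique linear stretch
with the required endpoint behavior: bottom/left-edge points stay fixed
($D_o = 0$) and safety-curve points land exactly on the box edge
($D_o = D_p$). A displacement proportional to $(D_p - D_o)/D_p$ instead
would invert those endpoints — fix the curve and displace the lower edge —
contradicting the warp's purpose, so the endpoint contract was taken as
authoritative over that algebraic variant. Points whose ray crosses the
curve outside the box are left unwarped; the resulting mild discontinuity
at the edge of the ray family is accepted and only affects a region the
optimizer has no reason to visit. The warp is exactly invertible
(`unwarp_point()`), and unwarped points are safe by construction, so
optimizer suggestions in warped space always map to admissible stimulation
parameters.

```{r warp}
b <- safety_boundary(1000, 100, 1e4)
g <- warp_geometry(b)
w <- warp_point(300, boundary_height(b, 300), b, g) # a point on the curve
c(w$x, w$y) # lands on a box edge
```

## The protocol

A run starts from a fixed 6-point low-dose design in the corner of the
space — a 3 × 2 lattice at amplitudes {0, 150, 300} µA and pulse widths
{0, 50} µs — then executes sessions of acquisition-driven trials
(8 sessions × 150 trials at full scale), refitting hyperparameters only at
session boundaries (never for the IBBK, which has none free). Per session
the protocol records:

* **performance** — the ground-truth response at the model's predicted
  best parameters (the safe-region argmax of $\tilde\mu$, unwarped if
  needed), divided by $-ES$: a perfect optimizer scores 1, a zero-response
  boundary point 0, and a positive-response region negative. The predicted
  optimum is always reported from the safe region: a clinician would never
  deliberately set parameters beyond the tolerability limit, and in warped
  mode the inverse warp guarantees this anyway.
* **boundary fraction** — the fraction of all samples so far within 0.01
  normalized units of a box edge or the safety curve (the protocol
  definition leaves the tolerance open; 0.01 is reported with the results).

The **random baseline** is model-free random search: uniform samples from
the safe region, with the learned optimum taken as the location of the best
(lowest) observed value. Scoring the baseline through a GP posterior
instead would make it a strong *model-based* estimator — with 200+ samples
at ES = 0.6 it reaches performance ~0.86 and would beat every acquisition
function, inverting the qualitative relationship the protocol comparison is
designed to expose (an optimizer should outperform not-optimizing). The
model-free reading is also the only one consistent with a baseline that
stays flat and low across sessions.

Session-level analysis uses a percentile bootstrap (1000 resamples) for
median confidence intervals, and ordinary least squares of
logit-transformed final performance on the boundary-sampling percentage
(performances clipped into $(10^{-3}, 1 - 10^{-3})$ before the logit;
negative performances collapse to the lower clip).

```{r protocol}
cfg <- protocol_config(n_sessions = 1, trials_per_session = 10,
                       acquisition = acquisition_config("ucb"))
tr <- run_protocol(problems[[1]], cfg, seed = 42)
tr$per_session
```

## Reproducibility and numerical choices

* Every random source (surface generation, observation noise, acquisition
  coins, optimizer restarts) consumes a named substream derived from the
  run seed; identical seeds give bit-identical traces, problem JSON, and
  CSVs.
* GP linear algebra uses Cholesky factorization with escalating relative
  jitter ($10^{-8}$ to $10^{-4}$); failure after escalation is an error,
  never a silent fix. Posterior variances are clamped at zero against
  roundoff.
* Extrema of each generated surface are located by a 201 × 201 grid scan
  refined with bounded quasi-Newton restarts from the best cell and a 5 × 5
  start lattice — sufficient because surfaces have at most 10 oscillations
  per axis.
* Problem sets, configurations and manifests serialize to JSON at 17
  significant digits, so write → read round trips are exact.

## What the simulations do and do not show

The generator emulates the *statistical* structure of parameter-tuning
experiments — smooth multi-modal response maps, calibrated effect sizes,
i.i.d. Gaussian trial noise, a hard charge-like safety bound, and
session-structured sampling budgets. It does not model drift or
nonstationarity of the patient response across sessions, heteroscedastic or
non-Gaussian noise, discrete parameters (contact selection, waveform),
higher-dimensional parameter spaces, or safety bounds that must be
*learned* rather than given. Passing results here demonstrate the failure
mode and its mitigation under the stated noise model; they do not by
themselves establish clinical performance.

Scaled-down protocol sizes are used in the package's checks so the full
suite runs on a laptop: 5 problems per condition, 4 sessions of 50 trials
for the optimizer-vs-random comparison at ES = 0.6, and 4 sessions of 100
trials for the standard-vs-boundary-avoiding comparison at ES = 0.1 — the
latter sized as large as the budget allows because the tight IBBK needs
several hundred observations before its estimates stabilize. At these
sizes the boundary-fraction contrast between standard and
boundary-avoiding runs is large and stable; performance contrasts at the
smallest effect size are noisier, since a Cohen's d of 0.1 is barely
identifiable from a few hundred unit-variance observations in any mode,
and medians over 5 problems inherit that noise.
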