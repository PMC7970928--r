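---
title: "Evaluating space on the pitch: arrival-time fields, safety and sparsity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating space on the pitch: arrival-time fields, safety and sparsity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchspace)
library(dplyr)
```

## The problem

"Space" is the central but slippery currency of football analysis: a pass
is good because it finds space, a defensive block is good because it denies
it. pitchspace makes the notion quantitative. Every location on the pitch,
at every moment, is scored by how quickly each team can put a player there,
and those two arrival times are rotated into a pair of orthogonal,
interpretable coordinates: *safety* (who gets there first, and by how much)
and *sparsity* (how long before anyone gets there at all).

## The motion model

Players are modelled by a damped-acceleration equation of motion: a player
of mass $m$ pushes with constant force $F$ along a chosen unit direction
$\vec n$ against a drag proportional to velocity,

$$m\,\ddot{\vec x} = F\vec n - k\,\dot{\vec x}.$$

With $V_\max = F/m$ (terminal sprint speed) and $\alpha = k/m$ (inverse
relaxation time) the solution from initial state $(\vec x_0, \vec v_0)$ is

$$\vec x(t) = \vec x_0 + s(t)\,\vec v_0 + V_\max\,\bigl(t - s(t)\bigr)\vec n,
\qquad s(t) = \frac{1 - e^{-\alpha t}}{\alpha}.$$

The defaults `motion_params(v_max = 7.8, alpha = 1.3)` are the standard
sprint values from the arrival-time literature and are shared by all
players; snapshots may carry per-player `v_max`/`alpha` columns when
player-specific estimates are available. Both parameters have physical
units (m/s and 1/s) and physical meaning, which keeps every downstream
quantity interpretable in seconds.

The set of positions reachable at time $t$ is a disc: a drift point
$\vec c(t) = \vec x_0 + s(t)\vec v_0$ (where the player coasts if they stop
pushing) plus an isotropic sprint radius $r(t) = V_\max(t - s(t))$
(`reach_state()`). The minimum arrival time to a target $\vec x$ is the
first root of

$$g(t) = \lVert \vec x - \vec c(t)\rVert - r(t).$$

### Root finding

`min_arrival_time()` locates the *first* crossing by a forward scan with
step 0.01 s up to 60 s, refined by bisection to $10^{-6}$ s. The scan is
essential: when $\vec v_0$ points away from the target, $g$ first rises and
need not be monotone, so a bracketing solver started blindly from $t = 0$
can skip an early tangency. Two numerical details:

* targets closer than $10^{-6}$ m to the player return exactly 0;
* the scan skips the interval where a crossing is provably impossible
  ($r(t) \le V_\max t$ and the drift point moves at most
  $|\vec v_0|/\alpha$ metres, so $g > 0$ while
  $V_\max t < d_0 - |\vec v_0|/\alpha$). This is a pure speed-up with
  identical first-crossing semantics; it makes a full-pitch evaluation
  (28,907 cells $\times$ 22 players) run in about a second.

The scan/bisection kernel is compiled (Rcpp) because it is the innermost
loop of every field evaluation; an independent dense-scan oracle
($\Delta t = 10^{-4}$ s) in the test suite checks it to $10^{-3}$ s on
1,000 random instances.

## Safety and sparsity

With $\tau_{of}$ and $\tau_{df}$ the minimum arrival times of the
ball-possessing (offense) and defending teams — each a minimum over that
side's 11 players — the two coordinates are the $45^\circ$ rotation

$$z_1 = \frac{\tau_{df} - \tau_{of}}{\sqrt 2}, \qquad
  z_2 = \frac{\tau_{df} + \tau_{of}}{\sqrt 2}.$$

$z_1$ is the signed distance from the equal-arrival axis: positive where
the offense arrives first (safe), negative where the defense does (risky).
$z_2$ grows with the total time either team needs: a sparsity measure.
Because the map is a rotation, $z_1^2 + z_2^2 = \tau_{of}^2 + \tau_{df}^2$
at every cell — an identity the tests assert to $10^{-9}$ over the full
grid — and $z_2 \ge |z_1|$ always.

Thresholding both axes divides the pitch into four regions
(`classify_region()`): A safe/dense, B safe/sparse, C risky/sparse,
D risky/dense. The safety boundary is $z_1 = 0$ by construction; the
sparsity boundary $z_2 = 2$ is the empirical value at which pass end
points sit at the edge of the joint formation (below). Boundaries
themselves are classified conservatively: $z_1 = 0$ counts as risky,
$z_2 = 2$ as dense, so exactly one label applies everywhere.

In the zero-velocity, equal-parameter limit, arrival time is a monotone
function of distance and the sign of $z_1$ reduces to the classical
Voronoi/dominant-region partition; the test suite checks that the
$z_1 = 0$ locus of a two-player field lies on the perpendicular bisector
to within one grid cell.

```{r field-example}
snap <- sim_snapshot(seed = 1)
field <- compute_space_field(snap, grid = pitch_grid(resolution = 2))
count(as_tibble(field), region)
```

`autoplot(field)`, `autoplot(field, what = "region")` and
`autoplot(field, what = "tau_df", cap = 2)` render the classic field
views. The default grid is 0.5 m (211 $\times$ 137 cell centres on the
105 m $\times$ 68 m pitch); the resolution trades smoothness of the
$z_1 = 0$ contour against compute time and is freely configurable.

Goalkeepers are *included* in the team arrival minima by default (they are
players too, and near the goal they dominate the defensive field); they
are excluded only from the formation summary below. `include_gk = FALSE`
is available for sensitivity analysis.

## The formation and $\tilde R$

The joint formation of the 20 outfield players is summarised by its
centroid and root-mean-square spread,

$$\vec x_c = \frac{1}{20}\sum_{j=1}^{20} \vec x_j, \qquad
  \sigma = \sqrt{\frac{1}{20}\sum_{j=1}^{20}
  \lVert \vec x_c - \vec x_j \rVert^2},$$

and a pass ending at $\vec x_e$ gets the formation-relative distance
$\tilde R = \lVert \vec x_e - \vec x_c \rVert / \sigma$: below 1 means
roughly inside the formation. Binning $\tilde R$ against $z_2$
(`r_tilde_vs_z2_curve()`, default bin width 0.25) locates the $z_2$ value
at which the mean $\tilde R$ crosses 1 — the sparsity threshold used for
the region labels, empirically $\approx 2$, i.e.
$\tau_{of} + \tau_{df} \approx 2\sqrt 2$ s.

## Pass-outcome statistics

A pass record is $[t_o, \vec x_o, t_e, \vec x_e, q]$ with outcome
$q \in \{0, 1\}$. `evaluate_passes()` scores the *end point at the moment
the pass is made* — $z_1(\vec x_e, t_o)$, $z_2(\vec x_e, t_o)$ — using the
tracking frame nearest to $t_o$ (within one 0.04 s frame at the default
25 Hz). Three estimators then summarise the outcome structure:

* `fit_class_normals()` — per-class normal fits of $z_1$ for successful
  and failed passes, maximum-likelihood (divisor $n$, i.e. ddof = 0);
* `empirical_success_curve()` — mean of $q$ in $z_1$ bins (default width
  0.1, bins with fewer than 30 passes suppressed);
* `fit_sigmoid()` — the logistic model
  $P(q = 1 \mid z_1) = 1/(1 + e^{-(a z_1 + b)})$, fitted by
  maximum-likelihood logistic regression (IRLS to machine precision).
  Whether the historical curve fits were done on raw outcomes or binned
  fractions is not documented anywhere we know of, so a binned
  least-squares variant (`method = "binned"`) is provided for comparison;
  the MLE is the default because it uses every pass and yields standard
  errors.

Perfect (or quasi-complete) separation makes the logistic MLE diverge;
`fit_sigmoid()` detects non-overlapping class ranges and refuses with a
diagnostic rather than returning a runaway estimate.

`bayes_sigmoid_from_normals()` closes the loop between the first and third
estimator: by Bayes' rule the posterior success probability implied by the
two class normals has log-odds linear in $z_1$ — exactly the sigmoid, with
$a = (\mu_1 - \mu_0)/\sigma^2$ and
$b = -(\mu_1^2 - \mu_0^2)/(2\sigma^2) + \log\frac{p_1}{1 - p_1}$ — *iff*
the class standard deviations are equal. With unequal SDs (the empirically
typical case: successful passes are more dispersed in $z_1$ than failed
ones) the log-odds are quadratic, the linear reduction is flagged
inapplicable, and the quadratic-discriminant posterior is returned
instead. That curvature is the model's own explanation for the empirical
success curve bending away from the fitted sigmoid at negative $z_1$.

```{r pass-example}
passes <- sim_outcome_passes(20000, seed = 2)
fit <- fit_sigmoid(passes)
tidy(fit)
```

Pre-shot passes (the `pre_shot` flag, `filter_pre_shot()`) can be run
through the same estimators unchanged; shot-preparing passes concentrate
at lower $z_1$, which quantifies how much risk teams accept to create
shots.

## The synthetic generators

Real tracking feeds are proprietary, so the package carries seeded
generators reproducing the statistical structure each estimator assumes:

* `sim_snapshot()` / `sim_tracking()` — 22 players on mirrored 4-4-2
  templates with 3 m Gaussian jitter, speeds uniform on [0, 8] m/s with
  uniform directions, goalkeepers held near their lines; tracks advance
  with constant velocities so finite-difference velocity estimation is
  exactly checkable. The template is an arbitrary but documented choice; a
  realistic but conventional formation keeps the player-density scale
  (and hence the $z_2$ scale) plausible.
* `sim_labeled_z1()` — $q \sim \text{Bernoulli}(p_1)$,
  $z_1 \mid q \sim N(\mu_q, \sigma_q)$, defaulting to the fitted class
  parameters $\mu_1 = 0.69$, $\sigma_1 = 0.54$, $\mu_0 = -0.25$,
  $\sigma_0 = 0.38$.
* `sim_outcome_passes()` — $z_1 \sim U(-2, 3)$ (spanning the observed
  support of real pass evaluations), $q$ Bernoulli from the sigmoid at the
  fitted coefficients $a = 4.68$, $b = 0.48$, and
  $z_2 \sim U(|z_1|, |z_1| + 4)$ so the rotation constraint holds by
  construction.
* `sim_passes_with_tracking()` — full (snapshot, pass) pairs whose
  ground-truth evaluation is recomputable from the emitted snapshot;
  outcomes are generated from the true $z_1$ of the end point, so the
  whole pipeline from CSV to fitted sigmoid is exercised end to end.

What these generators deliberately do *not* emulate: real match dynamics
(players move ballistically, not tactically), correlated team shapes over
time, measurement noise, or any relation between $z_1$ and pitch location.
Passing tests therefore demonstrate that the estimators recover what the
generators put in — parameter recovery and algebraic consistency — not
that any particular football claim holds in new data.

## Problem sizes and test design

The test suite fixes every seed and uses problem sizes chosen so each
recovery check is sharp relative to its 3-standard-error criterion:
200,000 passes for the sigmoid fit (slope SE $\approx$ 0.03), 100,000
draws per class for the normal fits, 1,000 random instances for the
solver-vs-oracle comparison, and one full 0.5 m field for the rotation
identity. The whole suite runs in under a minute on one core.

## Limitations

* The motion model is isotropic and reaction-free: no turning costs, no
  acceleration asymmetry, no delay before a player reacts to the pass.
* One parameter pair for all players by default; per-player estimation is
  supported in the data model but not performed by the package.
* Ball flight is not modelled: a location's safety is assessed as if the
  ball arrived instantaneously; $t_e$ is carried through but unused by the
  evaluators.
* Frames are evaluated independently; there is no interpolation between
  snapshots beyond nearest-frame matching.
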