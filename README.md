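# pitchspace

Quantitative space evaluation for football (soccer) tracking data.

Every location on the pitch, at every tracked moment, is scored by how
fast each team can put a player there. A player starting at position
`x0` with velocity `v0` and sprinting along a unit direction `n` follows
the damped-acceleration motion model

    x(t) = x0 + s(t) v0 + V_max (t - s(t)) n,    s(t) = (1 - exp(-alpha t)) / alpha

with terminal sprint speed `V_max = 7.8` m/s and inverse relaxation time
`alpha = 1.3` 1/s by default. The minimum arrival time `tau` of a player
to a target is the first crossing of the reachable disc with the target;
minimising over each team gives the offense and defense fields
`tau_of(x, t)` and `tau_df(x, t)`, which a 45-degree rotation turns into
two orthogonal, interpretable coordinates:

    z1 = (tau_df - tau_of) / sqrt(2)    # safety: > 0 where the offense arrives first
    z2 = (tau_df + tau_of) / sqrt(2)    # sparsity: large where nobody is close

Thresholding at `z1 = 0` and `z2 = 2` divides the pitch into four
regions — (A) safe dense, (B) safe sparse, (C) risky sparse, (D) risky
dense. Pass end points evaluated this way are strongly predictive of
outcome: the success probability follows the sigmoid
`P(q = 1 | z1) = 1 / (1 + exp(-(a z1 + b)))`, and the per-class `z1`
distributions are near-normal, which connects both views through Bayes'
rule. The package implements the full chain — motion model, arrival-time
solver (Rcpp kernel), field evaluation, formation centroid/spread and the
formation-relative pass distance `R~`, class-normal / empirical-curve /
logistic estimators, the Bayes closed form — plus seeded synthetic
generators, CSV IO for simple tracking and pass schemas, ggplot2
`autoplot()` views, and broom-style `tidy()`/`glance()` methods.

It is aimed at sports-analytics researchers and practitioners who have
(or simulate) player-tracking data and want a physically interpretable
space metric rather than a black-box pitch-control model.

## Worked example

```r
library(pitchspace)

# simulated match moments: one 22-player snapshot per pass
sim   <- sim_passes_with_tracking(200, seed = 42)
feats <- evaluate_passes(sim$passes, sim$tracking)
head(dplyr::select(feats, t_o_s, x_e_m, y_e_m, q, z1, z2, r_tilde), 3)
#>   t_o_s x_e_m  y_e_m     q    z1    z2 r_tilde
#> 1  0     36.8   5.43     0 -3.26  5.05    1.39
#> 2  0.04  40.4 -11.1      0 -3.70  5.81    1.49
#> 3  0.08 -27.3  15.1      1  2.20  5.12    1.06
```

A defender reaches pass 1's end point about `3.26 * sqrt(2) = 4.6` s
before any attacker (`z1 = -3.26`): a very risky ball, and indeed it
failed (`q = 0`). Pass 3 ends in space the offense controls (`z1 > 0`)
just outside the formation edge (`r_tilde` slightly above 1).

Fitting the outcome models on synthetic passes generated at the
defaults:

```r
fit_sigmoid(sim_outcome_passes(20000, seed = 43))
#> <sigmoid_fit> P(q=1|z1) = 1/(1 + exp(-(a z1 + b)))  [mle]
#>   a = 4.7256 (se 0.0902), b = 0.5031 (se 0.0357), n = 20000

glance(fit_class_normals(sim_labeled_z1(50000, seed = 44)))
#>     mu1 sigma1    n1    mu0 sigma0    n0 success_fraction
#> 1 0.690  0.541 24927 -0.251  0.380 25073            0.499
```

The slope/intercept and class means/SDs recover the generating values
(4.68, 0.48; 0.69/0.54, -0.25/0.38) within sampling error. A full field
for one snapshot, and its four-way division:

```r
snap  <- sim_snapshot(seed = 1)
field <- compute_space_field(snap, grid = pitch_grid(resolution = 1))
dplyr::count(tibble::as_tibble(field), region)
#>   region    n
#> 1      A   91
#> 2      B 3708
#> 3      C 3438
#> 4      D   77
autoplot(field)                  # z1 raster with players overlaid
autoplot(field, what = "region") # A-D division
```

Most of the pitch far from the players is sparse (B/C); the dense
safe/risky cells (A/D) hug the two formations.

A thin command-line interface wraps the same functions
(`inst/cli/pitchspace.R`; commands `simulate`, `field`, `passes`, `fit`;
exit codes 0/2/3 for success/validation/numerical failure).

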