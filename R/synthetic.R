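# Seeded synthetic-data generators. Real tracking feeds are proprietary,
# so these emulate the statistical structure the analysis assumes:
# 22-player snapshots on a 4-4-2 template, class-conditional normal safety
# values, Bernoulli outcomes from the sigmoid success model, and
# (snapshot, pass) pairs whose ground-truth evaluation is recomputable.

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# 4-4-2 template for one side defending the left goal (home); the away
# side is the mirror image. x fractions of half-length, y fractions of
# half-width.
formation_template <- function(pitch) {
  hx <- pitch$length / 2
  hy <- pitch$width / 2
  rows <- rbind(
    c(-0.95, 0.00),                                       # goalkeeper
    cbind(rep(-0.65, 4), c(-0.60, -0.20, 0.20, 0.60)),    # defenders
    cbind(rep(-0.30, 4), c(-0.65, -0.25, 0.25, 0.65)),    # midfielders
    cbind(rep(-0.05, 2), c(-0.20, 0.20))                  # forwards
  )
  cbind(rows[, 1] * hx, rows[, 2] * hy)
}

#' Simulate one tracking snapshot
#'
#' 22 players on mirrored 4-4-2 templates with Gaussian positional jitter
#' (goalkeepers stay near their goal lines), velocities with uniform random
#' direction and speed ~ Uniform(0, `speed_max`) m/s. Deterministic under a
#' fixed `seed`.
#'
#' @param seed Optional integer seed; when given, the snapshot is a pure
#'   function of it (the global RNG state is untouched).
#' @param time Frame time in seconds.
#' @param possession Side in possession (stored as an attribute).
#' @param jitter_sd SD of the positional jitter, metres (outfield players).
#' @param speed_max Upper bound of the uniform speed distribution, m/s.
#' @param pitch A [pitch_dims()] object.
#' @return A one-frame tracking tibble with a `possession` attribute.
#' @export
sim_snapshot <- function(seed = NULL, time = 0, possession = "home",
                         jitter_sd = 3, speed_max = 8,
                         pitch = pitch_dims()) {
  if (!possession %in% c("home", "away")) {
    abort_validation("`possession` must be 'home' or 'away'.")
  }
  with_optional_seed(seed, {
    tmpl <- formation_template(pitch)
    one_side <- function(side, sgn) {
      pos <- tmpl * sgn
      jit <- cbind(rnorm(11, 0, jitter_sd), rnorm(11, 0, jitter_sd))
      jit[1, ] <- jit[1, ] / 6                    # keep the GK near the line
      pos <- pos + jit
      pos[, 1] <- pmin(pmax(pos[, 1], -pitch$length / 2), pitch$length / 2)
      pos[, 2] <- pmin(pmax(pos[, 2], -pitch$width / 2), pitch$width / 2)
      ang <- runif(11, 0, 2 * pi)
      spd <- runif(11, 0, speed_max)
      tibble::tibble(
        frame = 1L, time_s = time, team = side,
        player_id = sprintf("%s%02d", substr(side, 1, 1), 1:11),
        x_m = pos[, 1], y_m = pos[, 2],
        is_gk = c(TRUE, rep(FALSE, 10)),
        vx_mps = spd * cos(ang), vy_mps = spd * sin(ang))
    }
    snap <- dplyr::bind_rows(one_side("home", 1), one_side("away", -1))
    attr(snap, "possession") <- possession
    snap
  })
}

#' Simulate a short tracking sequence
#'
#' A [sim_snapshot()] start frame advanced with constant per-player
#' velocities, giving a multi-frame track whose velocities are exactly
#' recoverable by finite differences.
#'
#' @param n_frames Number of frames.
#' @param dt Sampling interval, seconds (default 0.04, i.e. 25 Hz).
#' @inheritParams sim_snapshot
#' @return A tracking tibble with `n_frames` frames.
#' @export
sim_tracking <- function(n_frames = 25, dt = 0.04, seed = NULL,
                         possession = "home", pitch = pitch_dims()) {
  check_number(n_frames, "n_frames", lower = 1)
  base <- sim_snapshot(seed = seed, possession = possession, pitch = pitch)
  frames <- lapply(seq_len(n_frames), function(i) {
    dplyr::mutate(base,
      frame = as.integer(i),
      time_s = (i - 1) * dt,
      x_m = .data$x_m + (i - 1) * dt * .data$vx_mps,
      y_m = .data$y_m + (i - 1) * dt * .data$vy_mps)
  })
  out <- dplyr::bind_rows(frames)
  attr(out, "possession") <- possession
  out
}

#' Simulate class-labelled safety values
#'
#' Draws pass outcomes `q ~ Bernoulli(prior1)` and safety values
#' `z1 | q ~ Normal(mu_q, sigma_q)` — the class-conditional structure the
#' normal-fit estimator assumes. Defaults are the study's fitted class
#' parameters.
#'
#' @param n Number of passes.
#' @param mu1,sigma1 Successful-class normal parameters.
#' @param mu0,sigma0 Failed-class normal parameters.
#' @param prior1 Success prior `P(q = 1)` in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `z1`, `q`.
#' @export
sim_labeled_z1 <- function(n, mu1 = 0.69, sigma1 = 0.54,
                           mu0 = -0.25, sigma0 = 0.38,
                           prior1 = 0.5, seed = NULL) {
  check_number(n, "n", lower = 1)
  check_number(prior1, "prior1", lower = 0, upper = 1)
  check_number(sigma1, "sigma1", lower = 0)
  check_number(sigma0, "sigma0", lower = 0)
  with_optional_seed(seed, {
    q <- rbinom(n, 1L, prior1)
    z1 <- ifelse(q == 1L, rnorm(n, mu1, sigma1), rnorm(n, mu0, sigma0))
    tibble::tibble(z1 = z1, q = as.integer(q))
  })
}

#' Simulate pass features with sigmoid outcomes
#'
#' Draws `z1 ~ Uniform(z1_range)`, outcomes
#' `q ~ Bernoulli(plogis(a z1 + b))`, and a sparsity coordinate
#' `z2 ~ Uniform(|z1|, |z1| + 4)` (so the rotation constraint
#' `z2 >= |z1|` holds by construction). Defaults are the study's fitted
#' sigmoid coefficients.
#'
#' @param n Number of passes.
#' @param a,b Sigmoid slope and intercept.
#' @param z1_range Support of the uniform `z1` design distribution.
#' @param seed Optional integer seed.
#' @return A tibble with columns `z1`, `z2`, `r_tilde` (NA: not modelled
#'   by this generator), `q`, `pre_shot` (FALSE).
#' @export
sim_outcome_passes <- function(n, a = 4.68, b = 0.48,
                               z1_range = c(-2, 3), seed = NULL) {
  check_number(n, "n", lower = 1)
  with_optional_seed(seed, {
    z1 <- runif(n, z1_range[1], z1_range[2])
    q <- rbinom(n, 1L, plogis(a * z1 + b))
    tibble::tibble(
      z1 = z1,
      z2 = abs(z1) + runif(n, 0, 4),
      r_tilde = NA_real_,
      q = as.integer(q),
      pre_shot = FALSE)
  })
}

#' Simulate (snapshot, pass) pairs with recomputable ground truth
#'
#' One snapshot per pass: the pass originates at a randomly chosen outfield
#' player of the possessing side, the end point is uniform on the pitch,
#' and the outcome is Bernoulli with success probability given by the
#' sigmoid model evaluated at the true safety coordinate of the end point
#' (recomputed from the emitted snapshot). End-to-end fixture for
#' [evaluate_passes()].
#'
#' @param n_passes Number of pairs.
#' @param dt Frame spacing, seconds; pass i originates at `(i - 1) * dt`.
#' @param a,b Sigmoid coefficients used for the outcomes.
#' @param pre_shot_prob Probability a pass is flagged pre-shot.
#' @param params A [motion_params()] object.
#' @param seed Optional integer seed.
#' @param pitch A [pitch_dims()] object.
#' @return A list with elements `tracking` (one frame per pass) and
#'   `passes` (one row per pass).
#' @export
sim_passes_with_tracking <- function(n_passes = 100, dt = 0.04,
                                     a = 4.68, b = 0.48,
                                     pre_shot_prob = 0.1,
                                     params = motion_params(),
                                     seed = NULL, pitch = pitch_dims()) {
  check_number(n_passes, "n_passes", lower = 1)
  with_optional_seed(seed, {
    tracking <- vector("list", n_passes)
    passes <- vector("list", n_passes)
    for (i in seq_len(n_passes)) {
      possession <- sample(c("home", "away"), 1)
      snap <- sim_snapshot(time = (i - 1) * dt, possession = possession,
                           pitch = pitch)
      snap$frame <- as.integer(i)
      passer <- dplyr::slice_sample(
        dplyr::filter(snap, .data$team == possession, !.data$is_gk), n = 1)
      x_e <- c(runif(1, -pitch$length / 2, pitch$length / 2),
               runif(1, -pitch$width / 2, pitch$width / 2))
      defense <- setdiff(c("home", "away"), possession)
      tau_of <- team_min_arrival(snap, possession, x_e, params)
      tau_df <- team_min_arrival(snap, defense, x_e, params)
      z1 <- (tau_df - tau_of) / sqrt(2)
      t_o <- (i - 1) * dt
      dist <- sqrt(sum((x_e - c(passer$x_m, passer$y_m))^2))
      tracking[[i]] <- snap
      passes[[i]] <- tibble::tibble(
        t_o_s = t_o, x_o_m = passer$x_m, y_o_m = passer$y_m,
        t_e_s = t_o + dist / 15, x_e_m = x_e[1], y_e_m = x_e[2],
        q = rbinom(1, 1L, plogis(a * z1 + b)),
        pre_shot = runif(1) < pre_shot_prob,
        possession = possession)
    }
    list(tracking = dplyr::bind_rows(tracking),
         passes = dplyr::bind_rows(passes))
  })
}
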