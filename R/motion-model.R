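#' Motion-model parameters
#'
#' Parameters of the damped-acceleration equation of motion used to compute
#' player trajectories and minimum arrival times. A player accelerates with
#' constant force along a chosen unit direction and experiences a drag
#' proportional to velocity, so speed relaxes towards the terminal sprint
#' speed `v_max` at rate `alpha`.
#'
#' The closed-form trajectory from initial position \eqn{x_0} and velocity
#' \eqn{v_0} along unit direction \eqn{n} is
#' \deqn{x(t) = x_0 + s(t)\,v_0 + V_{max}\,(t - s(t))\,n, \quad
#'       s(t) = (1 - e^{-\alpha t})/\alpha.}
#'
#' The defaults, 7.8 m/s and 1.3 1/s, are the standard sprint values used
#' in the arrival-time literature; they are applied to all players unless a
#' snapshot carries per-player `v_max`/`alpha` columns.
#'
#' @param v_max Terminal sprint speed, metres/second. Must be positive.
#' @param alpha Inverse relaxation time, 1/second. Must be positive.
#' @return An object of class `motion_params`.
#' @examples
#' motion_params()
#' motion_params(v_max = 8.5, alpha = 1.5)
#' @export
motion_params <- function(v_max = 7.8, alpha = 1.3) {
  check_number(v_max, "v_max", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  structure(list(v_max = v_max, alpha = alpha), class = "motion_params")
}

#' @export
print.motion_params <- function(x, ...) {
  cat(sprintf("<motion_params> v_max = %g m/s, alpha = %g 1/s\n",
              x$v_max, x$alpha))
  invisible(x)
}

# drift fraction s(t) = (1 - exp(-alpha t)) / alpha
drift_fraction <- function(t, alpha) (1 - exp(-alpha * t)) / alpha

#' Trajectory position under the motion model
#'
#' Evaluates the closed-form trajectory of a player who starts at `x0` with
#' velocity `v0` and sprints along the fixed unit direction `direction`.
#'
#' @param x0 Initial position, length-2 numeric (metres).
#' @param v0 Initial velocity, length-2 numeric (metres/second).
#' @param direction Unit 2-vector giving the sprint direction; its norm
#'   must equal 1 within 1e-9.
#' @param t Times in seconds (vectorised); all must be >= 0.
#' @param params A [motion_params()] object.
#' @return A tibble with columns `time_s`, `x_m`, `y_m`.
#' @examples
#' position_at(c(0, 0), c(0, 0), c(1, 0), t = 1)
#' @export
position_at <- function(x0, v0, direction, t, params = motion_params()) {
  x0 <- drop(as_xy(x0, "x0"))
  v0 <- drop(as_xy(v0, "v0"))
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    abort_validation("`direction` must be a unit vector (|n| = 1 within 1e-9).")
  }
  if (any(t < 0)) abort_validation("`t` must be non-negative.")
  s <- drift_fraction(t, params$alpha)
  sprint <- params$v_max * (t - s)
  tibble::tibble(
    time_s = t,
    x_m = x0[1] + s * v0[1] + sprint * direction[1],
    y_m = x0[2] + s * v0[2] + sprint * direction[2]
  )
}

#' Reachable set of a player at time t
#'
#' Decomposes the motion-model trajectory into a direction-independent
#' drift point plus an isotropic sprint radius: every position reachable at
#' time `t` lies on the circle `center + radius * n` over unit directions
#' `n`. This is the geometry the arrival-time solver roots on.
#'
#' @inheritParams position_at
#' @return A tibble with columns `time_s`, `center_x`, `center_y`, `radius`.
#' @examples
#' reach_state(c(0, 0), c(2, 0), t = c(0, 1, 2))
#' @export
reach_state <- function(x0, v0, t, params = motion_params()) {
  x0 <- drop(as_xy(x0, "x0"))
  v0 <- drop(as_xy(v0, "v0"))
  if (any(t < 0)) abort_validation("`t` must be non-negative.")
  s <- drift_fraction(t, params$alpha)
  tibble::tibble(
    time_s = t,
    center_x = x0[1] + s * v0[1],
    center_y = x0[2] + s * v0[2],
    radius = params$v_max * (t - s)
  )
}

#' Minimum arrival time to target locations
#'
#' Smallest `t >= 0` at which a player starting at `x0` with velocity `v0`
#' can be at `target`, i.e. the first root of
#' \eqn{g(t) = \lVert target - c(t)\rVert - r(t)} where `c` and `r` are the
#' drift point and sprint radius of [reach_state()]. The root is located by
#' a forward scan (step `dt`) followed by bisection; the first crossing is
#' what matters because `g` need not be monotone when the initial velocity
#' points away from the target.
#'
#' @inheritParams position_at
#' @param target Length-2 numeric, n x 2 matrix, or data frame with
#'   `x_m`/`y_m` columns: the location(s) to reach.
#' @param t_max Scan horizon in seconds; no crossing before `t_max` is an
#'   error (it signals absurd inputs).
#' @param dt Scan step, seconds.
#' @param tol Bisection tolerance, seconds.
#' @param pos_tol Positions closer than this to `x0` return exactly 0.
#' @return Numeric vector of arrival times, seconds (one per target row).
#' @examples
#' # at rest 7.8 m from the target: slower than 1 s because speed must build
#' min_arrival_time(c(0, 0), c(0, 0), c(7.8, 0))
#' @export
min_arrival_time <- function(x0, v0, target, params = motion_params(),
                             t_max = 60, dt = 0.01, tol = 1e-6,
                             pos_tol = 1e-6) {
  x0 <- drop(as_xy(x0, "x0"))
  v0 <- drop(as_xy(v0, "v0"))
  tgt <- as_xy(target, "target")
  speed0 <- sqrt(sum(v0^2))
  if (speed0 > 12) {
    warn(sprintf("initial speed %.1f m/s exceeds 12 m/s; check tracking noise.",
                 speed0))
  }
  tau <- arrival_times_cpp(x0[1], x0[2], v0[1], v0[2],
                           tgt[, 1], tgt[, 2],
                           params$v_max, params$alpha,
                           dt, t_max, tol, pos_tol)[1, ]
  if (anyNA(tau)) {
    bad <- which(is.na(tau))[1]
    abort_numerical(sprintf(
      "no arrival before t_max = %g s for target (%.2f, %.2f).",
      t_max, tgt[bad, 1], tgt[bad, 2]))
  }
  tau
}

# Arrival-time matrix for a set of players (rows of a snapshot tibble) to a
# set of targets (n x 2 matrix). Per-player v_max/alpha columns override
# `params` when present. Returns players x targets matrix of seconds.
arrival_matrix <- function(players, targets, params = motion_params(),
                           t_max = 60, dt = 0.01, tol = 1e-6,
                           pos_tol = 1e-6) {
  vmax <- if ("v_max" %in% names(players)) players$v_max else
    rep(params$v_max, nrow(players))
  alpha <- if ("alpha" %in% names(players)) players$alpha else
    rep(params$alpha, nrow(players))
  arrival_times_cpp(players$x_m, players$y_m,
                    players$vx_mps, players$vy_mps,
                    targets[, 1], targets[, 2],
                    vmax, alpha, dt, t_max, tol, pos_tol)
}
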