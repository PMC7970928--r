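# Team arrival-time fields, the z1/z2 rotation, and the four-way field
# division.

#' Minimum team arrival time to target locations
#'
#' Minimum over one side's players of the per-player minimum arrival time
#' ([min_arrival_time()]): the earliest any player of that side can be at
#' each target.
#'
#' @param snapshot One-frame tracking tibble (columns `team`, `x_m`, `y_m`,
#'   `vx_mps`, `vy_mps`, `is_gk`).
#' @param side `"home"` or `"away"`.
#' @param target Length-2 numeric, n x 2 matrix, or data frame with
#'   `x_m`/`y_m` columns.
#' @param params A [motion_params()] object; per-player `v_max`/`alpha`
#'   columns in `snapshot`, if present, override it.
#' @param include_gk Include goalkeepers in the minimum (default TRUE).
#' @param t_max,dt,tol Solver settings, see [min_arrival_time()].
#' @return Numeric vector of seconds, one per target row.
#' @export
team_min_arrival <- function(snapshot, side, target,
                             params = motion_params(), include_gk = TRUE,
                             t_max = 60, dt = 0.01, tol = 1e-6) {
  players <- dplyr::filter(snapshot, .data$team == side)
  if (!include_gk) players <- dplyr::filter(players, !.data$is_gk)
  if (nrow(players) == 0L) {
    abort_validation(sprintf("no players on side '%s'%s.", side,
                             if (include_gk) "" else " (goalkeepers excluded)"))
  }
  tgt <- as_xy(target, "target")
  m <- arrival_matrix(players, tgt, params, t_max = t_max, dt = dt, tol = tol)
  tau <- m[1, ]
  if (nrow(m) > 1L) {
    for (r in 2:nrow(m)) tau <- pmin(tau, m[r, ])
  }
  if (anyNA(tau)) {
    bad <- which(is.na(tau))[1]
    abort_numerical(sprintf(
      "no arrival before t_max = %g s at cell (%.2f, %.2f).",
      t_max, tgt[bad, 1], tgt[bad, 2]))
  }
  tau
}

#' Rotate arrival times into safety and sparsity coordinates
#'
#' A 45-degree rotation of the (offense, defense) arrival-time plane:
#' \deqn{z_1 = (\tau_{df} - \tau_{of})/\sqrt{2}, \qquad
#'       z_2 = (\tau_{df} + \tau_{of})/\sqrt{2}.}
#' `z1` is the signed distance from the equal-arrival axis (positive where
#' the offense arrives first: safe space); `z2` grows with the total time
#' both teams need, i.e. with the sparsity of the location. Being a
#' rotation, it preserves the norm: `z1^2 + z2^2 = tau_of^2 + tau_df^2`.
#'
#' @param tau_of,tau_df Offense / defense minimum arrival times, seconds
#'   (vectorised, all >= 0).
#' @return A tibble with columns `z1`, `z2`.
#' @examples
#' z_transform(1, 2)
#' @export
z_transform <- function(tau_of, tau_df) {
  if (any(tau_of < 0) || any(tau_df < 0)) {
    abort_validation("arrival times must be non-negative.")
  }
  tibble::tibble(z1 = (tau_df - tau_of) / sqrt(2),
                 z2 = (tau_df + tau_of) / sqrt(2))
}

#' Four-way field division from (z1, z2)
#'
#' Labels each location by the signs of `z1` and `z2 - z2_threshold`:
#' A = safe dense (`z1 > 0`, `z2 < 2`), B = safe sparse (`z1 > 0`,
#' `z2 > 2`), C = risky sparse (`z1 < 0`, `z2 > 2`), D = risky dense
#' (`z1 < 0`, `z2 < 2`). Boundaries use the convention that `z1 = 0` is
#' risky and `z2 = 2` is dense, so `(0, 2)` is labelled D.
#'
#' @param z1,z2 Safety / sparsity coordinates (vectorised).
#' @param z1_threshold Safety boundary (default 0).
#' @param z2_threshold Sparsity boundary (default 2, the empirical
#'   inside/outside-formation threshold).
#' @return Factor with levels `A`, `B`, `C`, `D`.
#' @examples
#' classify_region(c(0.5, 0.5, -0.5, -0.5), c(1, 3, 3, 1))
#' @export
classify_region <- function(z1, z2, z1_threshold = 0, z2_threshold = 2) {
  safe <- z1 > z1_threshold
  sparse <- z2 > z2_threshold
  lab <- dplyr::case_when(
    safe & !sparse ~ "A",
    safe & sparse ~ "B",
    !safe & sparse ~ "C",
    .default = "D"
  )
  factor(lab, levels = c("A", "B", "C", "D"))
}

#' Evaluate the space field over a pitch grid
#'
#' Computes per-cell offense and defense minimum arrival times, the
#' safety/sparsity coordinates `z1`/`z2`, and the A-D region label for one
#' tracking snapshot. The offense is the side in possession.
#'
#' @param snapshot One-frame tracking tibble; both sides must be present.
#' @param possession `"home"` or `"away"`; defaults to the snapshot's
#'   `possession` attribute (simulated snapshots carry one).
#' @param grid Evaluation lattice from [pitch_grid()].
#' @param params A [motion_params()] object.
#' @param include_gk Include goalkeepers in the team arrival minima
#'   (default TRUE; set FALSE for sensitivity analysis).
#' @param z1_threshold,z2_threshold Region boundaries, see
#'   [classify_region()].
#' @return A `space_field` tibble: `x_m`, `y_m`, `tau_of_s`, `tau_df_s`,
#'   `z1`, `z2`, `region`, with the snapshot, possession, time and grid
#'   resolution stored as attributes.
#' @export
compute_space_field <- function(snapshot, possession = NULL,
                                grid = pitch_grid(),
                                params = motion_params(),
                                include_gk = TRUE,
                                z1_threshold = 0, z2_threshold = 2) {
  possession <- possession %||% attr(snapshot, "possession", exact = TRUE)
  if (is.null(possession) || !possession %in% c("home", "away")) {
    abort_validation("`possession` must be 'home' or 'away'.")
  }
  defense <- setdiff(c("home", "away"), possession)
  tgt <- cbind(grid$x_m, grid$y_m)
  tau_of <- team_min_arrival(snapshot, possession, tgt, params,
                             include_gk = include_gk)
  tau_df <- team_min_arrival(snapshot, defense, tgt, params,
                             include_gk = include_gk)
  z <- z_transform(tau_of, tau_df)
  field <- tibble::tibble(
    x_m = grid$x_m, y_m = grid$y_m,
    tau_of_s = tau_of, tau_df_s = tau_df,
    z1 = z$z1, z2 = z$z2,
    region = classify_region(z$z1, z$z2, z1_threshold, z2_threshold)
  )
  class(field) <- c("space_field", class(field))
  attr(field, "snapshot") <- snapshot
  attr(field, "possession") <- possession
  attr(field, "time_s") <- if (nrow(snapshot)) snapshot$time_s[1] else NA_real_
  attr(field, "resolution") <- attr(grid, "resolution", exact = TRUE)
  field
}

#' Write a space field to CSV (long format, one row per cell)
#'
#' @param field A `space_field` tibble from [compute_space_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  out <- dplyr::select(field, dplyr::all_of(c(
    "x_m", "y_m", "tau_of_s", "tau_df_s", "z1", "z2", "region")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
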