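# Reading, validating and writing tracking and pass-event tables.
#
# Tracking CSV schema (header required):
#   frame:int, time_s:float, team:{home,away}, player_id:str,
#   x_m:float, y_m:float, is_gk:{0,1}; optional vx_mps, vy_mps.
# Pass CSV schema:
#   t_o_s, x_o_m, y_o_m, t_e_s, x_e_m, y_e_m, q:{0,1},
#   pre_shot:{0,1} (optional, default 0), possession:{home,away}.

tracking_required_cols <- c("frame", "time_s", "team", "player_id",
                            "x_m", "y_m", "is_gk")
pass_required_cols <- c("t_o_s", "x_o_m", "y_o_m", "t_e_s", "x_e_m",
                        "y_e_m", "q", "possession")
# canonical column order used by the readers and writers
pass_canonical_cols <- c("t_o_s", "x_o_m", "y_o_m", "t_e_s", "x_e_m",
                         "y_e_m", "q", "pre_shot", "possession")

#' Read a tracking CSV
#'
#' Reads a tracking table (one row per player per frame), validates the
#' snapshot invariants (22 players per frame, 11 per side, exactly one
#' goalkeeper per side, positions on the padded pitch), and estimates
#' velocities by finite differences when the file does not provide them.
#'
#' @param path Path to a tracking CSV (schema in the package vignette).
#' @param velocity_window Odd number of frames for the central-difference
#'   velocity estimate; used only when `vx_mps`/`vy_mps` are absent.
#' @param pitch A [pitch_dims()] object for the bounds check.
#' @return A tibble sorted by `time_s` with logical `is_gk` and velocity
#'   columns always present.
#' @export
read_tracking <- function(path, velocity_window = 5, pitch = pitch_dims()) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(tracking_required_cols, names(df))
  if (length(missing)) {
    abort_schema(sprintf("tracking file is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- dplyr::mutate(df,
    frame = as.integer(.data$frame),
    team = as.character(.data$team),
    player_id = as.character(.data$player_id),
    is_gk = as.integer(.data$is_gk)
  )
  validate_tracking(df, pitch)
  df$is_gk <- df$is_gk == 1L
  df <- dplyr::arrange(df, .data$time_s, .data$team, .data$player_id)
  if (!all(c("vx_mps", "vy_mps") %in% names(df))) {
    df <- add_velocities(df, window = velocity_window)
  }
  bad_v <- sqrt(df$vx_mps^2 + df$vy_mps^2) >= 15
  if (any(bad_v)) {
    warn(sprintf("%d player-frame(s) have velocity magnitude >= 15 m/s.",
                 sum(bad_v)))
  }
  tibble::as_tibble(df)
}

validate_tracking <- function(df, pitch = pitch_dims()) {
  if (!all(df$team %in% c("home", "away"))) {
    abort_validation("`team` must be 'home' or 'away'.")
  }
  if (!all(df$is_gk %in% c(0L, 1L))) {
    abort_validation("`is_gk` must be 0 or 1.")
  }
  if (any(df$time_s < 0)) abort_validation("`time_s` must be >= 0.")
  pad_x <- pitch$length / 2 + 5
  pad_y <- pitch$width / 2 + 5
  off <- abs(df$x_m) > pad_x | abs(df$y_m) > pad_y
  if (any(off)) {
    abort_validation(sprintf(
      "frame %d: position (%.1f, %.1f) outside the padded pitch.",
      df$frame[which(off)[1]], df$x_m[which(off)[1]], df$y_m[which(off)[1]]))
  }
  by_frame <- dplyr::summarise(dplyr::group_by(df, .data$frame),
    n = dplyr::n(),
    n_home = sum(.data$team == "home"),
    n_away = sum(.data$team == "away"),
    gk_home = sum(.data$is_gk == 1L & .data$team == "home"),
    gk_away = sum(.data$is_gk == 1L & .data$team == "away"),
    .groups = "drop")
  bad <- by_frame$n != 22L
  if (any(bad)) {
    f <- by_frame$frame[which(bad)[1]]
    abort_validation(sprintf("frame %d has %d players; expected 22.",
                             f, by_frame$n[which(bad)[1]]))
  }
  bad <- by_frame$n_home != 11L | by_frame$n_away != 11L
  if (any(bad)) {
    abort_validation(sprintf("frame %d does not have 11 players per side.",
                             by_frame$frame[which(bad)[1]]))
  }
  bad <- by_frame$gk_home != 1L | by_frame$gk_away != 1L
  if (any(bad)) {
    abort_validation(sprintf(
      "frame %d does not have exactly one goalkeeper per side.",
      by_frame$frame[which(bad)[1]]))
  }
  invisible(df)
}

#' Write a tracking table to CSV
#'
#' Inverse of [read_tracking()]: writes the schema columns (plus velocities)
#' so that a write/read round trip reproduces all values.
#'
#' @param tracking Tracking tibble as returned by [read_tracking()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracking, path) {
  out <- dplyr::select(tracking, dplyr::all_of(c(
    "frame", "time_s", "team", "player_id", "x_m", "y_m", "is_gk",
    "vx_mps", "vy_mps")))
  out$is_gk <- as.integer(out$is_gk)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Estimate velocities from a position time series
#'
#' Central finite difference over a symmetric window at interior frames and
#' one-sided differences at the endpoints. Exact (to floating point) for
#' affine trajectories regardless of the window.
#'
#' @param xy An n x 2 matrix (or data frame) of positions at a fixed
#'   sampling interval.
#' @param dt Sampling interval, seconds.
#' @param window Odd window length in frames, >= 3; the central difference
#'   spans `(window - 1) / 2` frames on each side.
#' @return An n x 2 matrix of velocities (metres/second).
#' @export
estimate_velocities <- function(xy, dt, window = 5) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (window < 3 || window %% 2 != 1) {
    abort_validation("`window` must be an odd integer >= 3.")
  }
  xy <- as_xy(xy, "xy")
  n <- nrow(xy)
  if (n < window) {
    abort_validation(sprintf(
      "position series has %d frames; at least %d (the window) required.",
      n, window))
  }
  k <- (window - 1L) / 2L
  v <- matrix(0, n, 2)
  idx <- (k + 1L):(n - k)
  v[idx, ] <- (xy[idx + k, , drop = FALSE] - xy[idx - k, , drop = FALSE]) /
    (2 * k * dt)
  for (i in seq_len(k)) {                      # one-sided at the ends
    v[i, ] <- (xy[i + k, ] - xy[i, ]) / (k * dt)
    v[n - i + 1L, ] <- (xy[n - i + 1L, ] - xy[n - i + 1L - k, ]) / (k * dt)
  }
  v
}

# Fill vx_mps/vy_mps for every player track in a tracking tibble.
# Degenerate tracks: a single isolated frame gets zero velocity with a
# warning; two frames use a plain first difference; short tracks shrink the
# window to the largest odd length available.
add_velocities <- function(tracking, window = 5) {
  times <- sort(unique(tracking$time_s))
  dt <- if (length(times) > 1) stats::median(diff(times)) else 0.04
  out <- dplyr::group_modify(
    dplyr::group_by(tracking, .data$player_id),
    function(d, key) {
      d <- dplyr::arrange(d, .data$time_s)
      n <- nrow(d)
      if (n == 1L) {
        warn(sprintf("player %s has a single isolated frame; velocity set to 0.",
                     key$player_id))
        v <- matrix(0, 1, 2)
      } else if (n == 2L) {
        v1 <- c(d$x_m[2] - d$x_m[1], d$y_m[2] - d$y_m[1]) / dt
        v <- rbind(v1, v1)
      } else {
        w <- min(window, if (n %% 2 == 1L) n else n - 1L)
        v <- estimate_velocities(cbind(d$x_m, d$y_m), dt = dt, window = w)
      }
      d$vx_mps <- v[, 1]
      d$vy_mps <- v[, 2]
      d
    })
  dplyr::arrange(dplyr::ungroup(out), .data$time_s, .data$team,
                 .data$player_id)
}

#' Read a pass-event CSV
#'
#' @param path Path to a pass CSV (schema in the package vignette).
#' @return A tibble of pass events with logical `pre_shot`.
#' @export
read_passes <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(pass_required_cols, names(df))
  if (length(missing)) {
    abort_schema(sprintf("pass file is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!("pre_shot" %in% names(df))) df$pre_shot <- 0L
  if (!all(df$q %in% c(0, 1))) {
    abort_validation(sprintf("`q` must be 0 or 1; found %s.",
                             paste(unique(df$q[!df$q %in% c(0, 1)]),
                                   collapse = ", ")))
  }
  if (!all(df$pre_shot %in% c(0, 1))) {
    abort_validation("`pre_shot` must be 0 or 1.")
  }
  if (!all(df$possession %in% c("home", "away"))) {
    abort_validation("`possession` must be 'home' or 'away'.")
  }
  if (any(df$t_e_s < df$t_o_s)) {
    abort_validation("pass end time t_e_s precedes origin time t_o_s.")
  }
  df$q <- as.integer(df$q)
  df$pre_shot <- df$pre_shot == 1
  df <- dplyr::relocate(df, dplyr::all_of(pass_canonical_cols))
  tibble::as_tibble(df)
}

#' Write pass events or pass features to CSV
#'
#' `write_passes()` writes the raw pass schema; `write_features()` writes
#' the same columns plus the derived `z1`, `z2`, `r_tilde` evaluation.
#'
#' @param passes,features Tibbles as returned by [read_passes()] /
#'   [evaluate_passes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_passes <- function(passes, path) {
  out <- dplyr::select(passes, dplyr::all_of(pass_canonical_cols))
  out$pre_shot <- as.integer(out$pre_shot)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_passes
#' @export
write_features <- function(features, path) {
  cols <- c(pass_canonical_cols, "z1", "z2", "r_tilde")
  cols <- intersect(cols, names(features))
  out <- dplyr::select(features, dplyr::all_of(cols))
  if ("pre_shot" %in% names(out)) out$pre_shot <- as.integer(out$pre_shot)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pass-feature CSV written by [write_features()]
#'
#' @param path Path to a features CSV.
#' @return A tibble with pass columns plus `z1`, `z2`, `r_tilde`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("z1", "q")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_schema(sprintf("features file is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!all(df$q %in% c(0, 1))) abort_validation("`q` must be 0 or 1.")
  if ("pre_shot" %in% names(df)) df$pre_shot <- df$pre_shot == 1
  df$q <- as.integer(df$q)
  tibble::as_tibble(df)
}

#' Extract the snapshot nearest to a time
#'
#' @param tracking Tracking tibble.
#' @param time Time in seconds.
#' @param tol Maximum |frame time - `time`| accepted, seconds (one frame at
#'   25 Hz by default).
#' @return One-frame tibble (22 players).
#' @export
snapshot_at <- function(tracking, time, tol = 0.04) {
  times <- unique(tracking$time_s)
  i <- which.min(abs(times - time))
  if (abs(times[i] - time) > tol + 1e-9) {
    abort_validation(sprintf(
      "no tracking frame within %g s of t = %g s (nearest: %g s).",
      tol, time, times[i]))
  }
  dplyr::filter(tracking, .data$time_s == times[i])
}
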