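# Formation centroid, spread, and the formation-relative pass distance.

#' Formation centroid and spread
#'
#' Centroid \eqn{x_c} and root-mean-square spread \eqn{\sigma} of the 20
#' outfield players (goalkeepers excluded):
#' \deqn{x_c = \frac{1}{20}\sum_{j=1}^{20} x_j, \qquad
#'       \sigma = \sqrt{\frac{1}{20}\sum_{j=1}^{20} \lVert x_c - x_j \rVert^2}.}
#' The spread measures the size of the joint formation of both teams.
#'
#' @param snapshot One-frame tracking tibble containing exactly 20
#'   non-goalkeeper players (plus any goalkeepers, which are ignored).
#' @return A one-row tibble: `time_s`, `x_c`, `y_c`, `spread`, `n`.
#' @export
formation_summary <- function(snapshot) {
  fp <- dplyr::filter(snapshot, !.data$is_gk)
  if (nrow(fp) != 20L) {
    abort_validation(sprintf(
      "formation summary needs exactly 20 outfield players; found %d.",
      nrow(fp)))
  }
  xc <- mean(fp$x_m)
  yc <- mean(fp$y_m)
  spread <- sqrt(mean((fp$x_m - xc)^2 + (fp$y_m - yc)^2))
  tibble::tibble(
    time_s = if ("time_s" %in% names(fp)) fp$time_s[1] else NA_real_,
    x_c = xc, y_c = yc, spread = spread, n = 20L)
}

#' Formation-relative pass distance
#'
#' Distance of a pass end point from the outfield-player centroid in units
#' of the formation spread:
#' \deqn{\tilde{R} = \lVert x_e - x_c \rVert / \sigma.}
#' Values below 1 place the end point roughly inside the formation.
#'
#' @param snapshot One-frame tracking tibble at the moment the pass is
#'   made (see [formation_summary()]).
#' @param x_e Pass end point(s): length-2 numeric, n x 2 matrix, or data
#'   frame with `x_m`/`y_m` (or `x_e_m`/`y_e_m`) columns.
#' @return Numeric vector of dimensionless distances.
#' @export
r_tilde <- function(snapshot, x_e) {
  if (is.data.frame(x_e) && all(c("x_e_m", "y_e_m") %in% names(x_e))) {
    x_e <- cbind(x_e$x_e_m, x_e$y_e_m)
  }
  xe <- as_xy(x_e, "x_e")
  fs <- formation_summary(snapshot)
  if (fs$spread <= 0) {
    abort_validation("formation spread is zero; r_tilde is undefined.")
  }
  sqrt((xe[, 1] - fs$x_c)^2 + (xe[, 2] - fs$y_c)^2) / fs$spread
}

#' Binned mean of the formation-relative distance against sparsity
#'
#' Bins pass features by their sparsity coordinate `z2` and averages the
#' formation-relative distance `r_tilde` per bin. The `z2` value at which
#' the mean crosses 1 estimates the inside/outside-formation threshold
#' (empirically close to 2).
#'
#' @param features Tibble with columns `z2` and `r_tilde` (e.g. from
#'   [evaluate_passes()]).
#' @param bin_width Bin width in `z2` (default 0.25).
#' @param min_count Bins with fewer passes are omitted.
#' @return A tibble `z2_bin_center`, `mean_r_tilde`, `n`, sorted by bin.
#' @export
r_tilde_vs_z2_curve <- function(features, bin_width = 0.25, min_count = 1) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  check_number(min_count, "min_count", lower = 0)
  if (!all(c("z2", "r_tilde") %in% names(features))) {
    abort_schema("`features` must have columns z2 and r_tilde.")
  }
  if (nrow(features) == 0L) abort_validation("`features` is empty.")
  dplyr::arrange(dplyr::summarise(
    dplyr::group_by(features,
                    z2_bin_center = (floor(.data$z2 / bin_width) + 0.5) * bin_width),
    mean_r_tilde = mean(.data$r_tilde),
    n = dplyr::n(),
    .groups = "drop"
  ), .data$z2_bin_center) |>
    dplyr::filter(.data$n >= min_count)
}
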