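# ggplot2 views of the result types.

#' Plot a space field
#'
#' Raster of one field quantity over the pitch with the players overlaid
#' (offense as leftward-pointing triangles, defense rightward).
#'
#' @param object A `space_field` from [compute_space_field()].
#' @param what One of `"z1"`, `"z2"`, `"tau_of"`, `"tau_df"`, `"region"`.
#' @param cap Optional display cap, in seconds, applied to arrival-time
#'   rasters (e.g. `cap = 2` renders the classic 2 s contour range).
#' @param show_players Overlay the snapshot's players.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.space_field <- function(object, what = c("z1", "z2", "tau_of",
                                                  "tau_df", "region"),
                                 cap = NULL, show_players = TRUE, ...) {
  what <- match.arg(what)
  col <- switch(what, tau_of = "tau_of_s", tau_df = "tau_df_s", what)
  df <- tibble::as_tibble(object)
  if (!is.null(cap) && col %in% c("tau_of_s", "tau_df_s")) {
    df[[col]] <- pmin(df[[col]], cap)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x_m, y = .data$y_m)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[col]])) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = what)
  p <- if (what == "region") {
    p + ggplot2::scale_fill_brewer(palette = "RdYlBu", drop = FALSE)
  } else if (what == "z1") {
    p + ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                      high = "#2166ac", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
  snap <- attr(object, "snapshot", exact = TRUE)
  possession <- attr(object, "possession", exact = TRUE)
  if (show_players && !is.null(snap)) {
    snap <- dplyr::mutate(snap,
      role = ifelse(.data$team == possession, "offense", "defense"))
    p <- p + ggplot2::geom_point(
      data = snap,
      ggplot2::aes(shape = .data$role),
      size = 2.5, stroke = 1, colour = "black") +
      ggplot2::scale_shape_manual(values = c(offense = 17, defense = 25))
  }
  p
}

#' Plot class-conditional normal fits of z1
#'
#' Fitted per-class normal densities; when the underlying features are
#' supplied, per-class histograms are drawn behind the curves.
#'
#' @param object A [fit_class_normals()] object.
#' @param features Optional tibble with `z1`, `q` used for the histograms.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_normal_fit <- function(object, features = NULL,
                                      binwidth = 0.1, ...) {
  lim <- range(object$mu1 + c(-4, 4) * object$sigma1,
               object$mu0 + c(-4, 4) * object$sigma0)
  zs <- seq(lim[1], lim[2], length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(z1 = zs, density = dnorm(zs, object$mu1, object$sigma1),
                   class = "successful"),
    tibble::tibble(z1 = zs, density = dnorm(zs, object$mu0, object$sigma0),
                   class = "failed"))
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$z1))
  if (!is.null(features)) {
    hist_df <- dplyr::mutate(features,
      class = ifelse(.data$q == 1, "successful", "failed"))
    p <- p + ggplot2::geom_histogram(
      data = hist_df,
      ggplot2::aes(y = ggplot2::after_stat(.data$density),
                   fill = .data$class),
      binwidth = binwidth, alpha = 0.35, position = "identity")
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$density,
                                    colour = .data$class),
                       linetype = "dashed", linewidth = 0.8) +
    ggplot2::labs(x = "z1 (safety)", y = "density")
}

#' Plot a sigmoid pass-success fit
#'
#' Fitted success-probability curve; when an empirical curve from
#' [empirical_success_curve()] is supplied, its binned fractions are drawn
#' as points sized by bin count.
#'
#' @param object A [fit_sigmoid()] object.
#' @param curve Optional tibble from [empirical_success_curve()].
#' @param z1_range Range of `z1` for the fitted line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigmoid_fit <- function(object, curve = NULL,
                                 z1_range = c(-2, 3), ...) {
  zs <- seq(z1_range[1], z1_range[2], length.out = 400)
  line <- tibble::tibble(z1 = zs, p = predict(object, zs))
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$z1, y = .data$p)) +
    ggplot2::geom_line(linetype = "dashed", colour = "#2166ac") +
    ggplot2::labs(x = "z1 (safety)", y = "P(q = 1 | z1)") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_point(
      data = curve,
      ggplot2::aes(x = .data$z1_bin_center, y = .data$success_fraction,
                   size = .data$n),
      alpha = 0.6)
  }
  p
}
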