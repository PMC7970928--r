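#' Pitch dimensions
#'
#' Pitch-centred coordinate convention: the origin is the centre spot,
#' x runs along the long axis in `[-length/2, length/2]`, y along the short
#' axis in `[-width/2, width/2]`. The default is the regulation
#' 105 m x 68 m pitch.
#'
#' @param length Pitch length in metres (x extent).
#' @param width Pitch width in metres (y extent).
#' @return An object of class `pitch_dims`.
#' @export
pitch_dims <- function(length = 105, width = 68) {
  check_number(length, "length", lower = 0, strict_lower = TRUE)
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  structure(list(length = length, width = width), class = "pitch_dims")
}

#' @export
print.pitch_dims <- function(x, ...) {
  cat(sprintf("<pitch_dims> %g m x %g m, centred at the origin\n",
              x$length, x$width))
  invisible(x)
}

#' Regular grid of evaluation points over the pitch
#'
#' Cell centres on a uniform lattice covering the pitch, used to evaluate
#' arrival-time fields. At the default 0.5 m resolution on a 105 x 68 m
#' pitch this is a 211 x 137 lattice (boundaries included).
#'
#' @param resolution Grid spacing in metres.
#' @param pitch A [pitch_dims()] object.
#' @return A tibble with columns `x_m`, `y_m`; attributes `resolution` and
#'   `pitch`.
#' @export
pitch_grid <- function(resolution = 0.5, pitch = pitch_dims()) {
  check_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  xs <- seq(-pitch$length / 2, pitch$length / 2, by = resolution)
  ys <- seq(-pitch$width / 2, pitch$width / 2, by = resolution)
  g <- tidyr::expand_grid(x_m = xs, y_m = ys)
  attr(g, "resolution") <- resolution
  attr(g, "pitch") <- pitch
  g
}
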