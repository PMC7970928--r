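# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a class-conditional normal fit
#'
#' @param x A [fit_class_normals()] object.
#' @param ... Unused.
#' @return One row per outcome class with `class`, `mean`, `sd`, `n`.
#' @export
tidy.class_normal_fit <- function(x, ...) {
  tibble::tibble(
    class = c("successful", "failed"),
    mean = c(x$mu1, x$mu0),
    sd = c(x$sigma1, x$sigma0),
    n = c(x$n1, x$n0))
}

#' @rdname tidy.class_normal_fit
#' @return `glance()`: a one-row summary with both classes' parameters and
#'   the empirical success fraction.
#' @export
glance.class_normal_fit <- function(x, ...) {
  tibble::tibble(
    mu1 = x$mu1, sigma1 = x$sigma1, n1 = x$n1,
    mu0 = x$mu0, sigma0 = x$sigma0, n0 = x$n0,
    success_fraction = x$n1 / (x$n1 + x$n0))
}

#' Tidy a sigmoid pass-success fit
#'
#' @param x A [fit_sigmoid()] object.
#' @param ... Unused.
#' @return One row per coefficient with `term`, `estimate`, `std.error`.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$a, x$b),
    std.error = c(x$se_a, x$se_b))
}

#' @rdname tidy.sigmoid_fit
#' @return `glance()`: a one-row summary with `a`, `b`, `n`, `logLik`,
#'   `method`.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, n = x$n, logLik = x$loglik,
                 method = x$method)
}
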