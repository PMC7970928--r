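# Internal helpers: error classes and coordinate coercion.

abort_schema <- function(msg) {
  abort(msg, class = c("pitchspace_schema_error", "pitchspace_error"))
}

abort_validation <- function(msg) {
  abort(msg, class = c("pitchspace_validation_error", "pitchspace_error"))
}

abort_numerical <- function(msg) {
  abort(msg, class = c("pitchspace_numerical_error", "pitchspace_error"))
}

# Coerce a target location argument to an n x 2 matrix of metres.
# Accepts a length-2 numeric, an n x 2 matrix, or a data frame with two
# coordinate columns (x_m/y_m or x/y).
as_xy <- function(x, arg = "target") {
  if (is.data.frame(x)) {
    nm <- names(x)
    if (all(c("x_m", "y_m") %in% nm)) {
      x <- cbind(x$x_m, x$y_m)
    } else if (all(c("x", "y") %in% nm)) {
      x <- cbind(x$x, x$y)
    } else {
      abort_validation(sprintf(
        "`%s` data frame must have columns x_m/y_m (or x/y).", arg))
    }
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 2L) {
      abort_validation(sprintf("`%s` must be a length-2 numeric or an n x 2 matrix.", arg))
    }
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
  }
  if (ncol(x) != 2L || !is.numeric(x)) {
    abort_validation(sprintf("`%s` must have two numeric columns.", arg))
  }
  if (any(!is.finite(x))) {
    abort_validation(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  unname(x)
}

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", arg))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort_validation(sprintf("`%s` = %g is outside its allowed range.", arg, x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
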