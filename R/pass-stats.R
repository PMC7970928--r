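# Per-pass space evaluation and pass-outcome statistics: class-conditional
# normal fits, the empirical success curve, the logistic (sigmoid) success
# model, and its Bayes closed form.

#' Evaluate passes in safety/sparsity coordinates
#'
#' For each pass, finds the tracking frame nearest to the pass origin time
#' `t_o_s`, computes the offense and defense minimum arrival times to the
#' end point `(x_e_m, y_e_m)` at that moment, rotates them into `(z1, z2)`,
#' and attaches the formation-relative distance `r_tilde`.
#'
#' @param passes Pass-event tibble (see [read_passes()]).
#' @param tracking Tracking tibble (see [read_tracking()]).
#' @param params A [motion_params()] object.
#' @param include_gk Include goalkeepers in the team arrival minima.
#' @param frame_tol Maximum |frame time - t_o| accepted, seconds.
#' @return The input passes with columns `z1`, `z2`, `r_tilde` appended
#'   (original row order preserved).
#' @export
evaluate_passes <- function(passes, tracking, params = motion_params(),
                            include_gk = TRUE, frame_tol = 0.04) {
  if (nrow(passes) == 0L) abort_validation("`passes` is empty.")
  times <- sort(unique(tracking$time_s))
  nearest <- vapply(passes$t_o_s, function(t) {
    i <- which.min(abs(times - t))
    if (abs(times[i] - t) > frame_tol + 1e-9) {
      abort_validation(sprintf(
        "no tracking frame within %g s of pass origin t_o = %g s.",
        frame_tol, t))
    }
    times[i]
  }, numeric(1))
  passes$.row <- seq_len(nrow(passes))
  passes$.frame_time <- nearest
  out <- dplyr::group_modify(
    dplyr::group_by(passes, .data$.frame_time, .data$possession),
    function(d, key) {
      snap <- dplyr::filter(tracking, .data$time_s == key$.frame_time)
      defense <- setdiff(c("home", "away"), key$possession)
      xe <- cbind(d$x_e_m, d$y_e_m)
      tau_of <- team_min_arrival(snap, key$possession, xe, params,
                                 include_gk = include_gk)
      tau_df <- team_min_arrival(snap, defense, xe, params,
                                 include_gk = include_gk)
      z <- z_transform(tau_of, tau_df)
      d$z1 <- z$z1
      d$z2 <- z$z2
      d$r_tilde <- r_tilde(snap, xe)
      d
    })
  out <- dplyr::arrange(dplyr::ungroup(out), .data$.row)
  dplyr::select(out, -".row", -".frame_time")
}

#' Subset pass features to pre-shot passes
#'
#' Passes flagged as immediately preceding a shot, analysed separately
#' because they tend to be riskier (lower `z1`) than passes overall.
#'
#' @param features Tibble with a logical `pre_shot` column.
#' @return The flagged subset (possibly empty).
#' @export
filter_pre_shot <- function(features) {
  if (!"pre_shot" %in% names(features)) {
    abort_schema("`features` must have a pre_shot column.")
  }
  dplyr::filter(features, .data$pre_shot)
}

#' Class-conditional normal fits of the safety coordinate
#'
#' Maximum-likelihood normal fits of `z1` separately for successful
#' (`q = 1`) and failed (`q = 0`) passes: per-class sample mean and
#' standard deviation with divisor n (ddof = 0).
#'
#' @param features Tibble with columns `z1` and `q` in {0, 1}.
#' @return An object of class `class_normal_fit` with elements `mu1`,
#'   `sigma1`, `n1` (successful class), `mu0`, `sigma0`, `n0` (failed
#'   class).
#' @export
fit_class_normals <- function(features) {
  if (!all(c("z1", "q") %in% names(features))) {
    abort_schema("`features` must have columns z1 and q.")
  }
  fit_one <- function(x, label) {
    if (length(x) < 2L) {
      abort_validation(sprintf(
        "class '%s' has %d sample(s); at least 2 required.", label, length(x)))
    }
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma <= 0) {
      abort_validation(sprintf("class '%s' has zero variance.", label))
    }
    list(mu = mu, sigma = sigma, n = length(x))
  }
  s <- fit_one(features$z1[features$q == 1], "successful")
  f <- fit_one(features$z1[features$q == 0], "failed")
  structure(list(mu1 = s$mu, sigma1 = s$sigma, n1 = s$n,
                 mu0 = f$mu, sigma0 = f$sigma, n0 = f$n),
            class = "class_normal_fit")
}

#' @export
print.class_normal_fit <- function(x, ...) {
  cat("<class_normal_fit>\n")
  cat(sprintf("  successful: mu1 = %.4f, sigma1 = %.4f (n = %d)\n",
              x$mu1, x$sigma1, x$n1))
  cat(sprintf("  failed:     mu0 = %.4f, sigma0 = %.4f (n = %d)\n",
              x$mu0, x$sigma0, x$n0))
  invisible(x)
}

#' Empirical pass-success curve
#'
#' Success fraction (mean of `q`) in bins of the safety coordinate `z1`.
#'
#' @param features Tibble with columns `z1` and `q`.
#' @param bin_width Bin width in `z1` (default 0.1).
#' @param min_count Bins with fewer passes are omitted (default 30).
#' @return A tibble `z1_bin_center`, `success_fraction`, `n`.
#' @export
empirical_success_curve <- function(features, bin_width = 0.1,
                                    min_count = 30) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  check_number(min_count, "min_count", lower = 0)
  if (!all(c("z1", "q") %in% names(features))) {
    abort_schema("`features` must have columns z1 and q.")
  }
  if (nrow(features) == 0L) abort_validation("`features` is empty.")
  dplyr::filter(dplyr::arrange(dplyr::summarise(
    dplyr::group_by(features,
                    z1_bin_center = (floor(.data$z1 / bin_width) + 0.5) * bin_width),
    success_fraction = mean(.data$q),
    n = dplyr::n(),
    .groups = "drop"
  ), .data$z1_bin_center), .data$n >= min_count)
}

#' Logistic (sigmoid) pass-success model
#'
#' Fits the success probability
#' \deqn{P(q = 1 \mid z_1) = \frac{1}{1 + e^{-(a z_1 + b)}}}
#' by maximum-likelihood logistic regression of `q` on `z1` (the default),
#' or by least squares on the binned empirical success curve
#' (`method = "binned"`, for comparison).
#'
#' @param features Tibble with columns `z1` and `q`; both outcome classes
#'   must be present and not perfectly separated in `z1`.
#' @param method `"mle"` (logistic regression) or `"binned"`.
#' @param bin_width,min_count Binning settings for `method = "binned"`.
#' @return An object of class `sigmoid_fit` with slope `a`, intercept `b`,
#'   standard errors `se_a`, `se_b` (NA for the binned method), sample size
#'   `n`, the log-likelihood, and `method`.
#' @export
fit_sigmoid <- function(features, method = c("mle", "binned"),
                        bin_width = 0.1, min_count = 30) {
  method <- match.arg(method)
  if (!all(c("z1", "q") %in% names(features))) {
    abort_schema("`features` must have columns z1 and q.")
  }
  z1 <- features$z1
  q <- features$q
  if (length(unique(q)) < 2L) {
    abort_validation("both outcome classes (q = 0 and q = 1) must be present.")
  }
  if (max(z1[q == 0]) < min(z1[q == 1]) || min(z1[q == 0]) > max(z1[q == 1])) {
    abort_numerical(sprintf(
      paste0("perfect separation: z1 ranges of the classes do not overlap ",
             "(failed: [%.3f, %.3f], successful: [%.3f, %.3f]); ",
             "the logistic MLE diverges."),
      min(z1[q == 0]), max(z1[q == 0]), min(z1[q == 1]), max(z1[q == 1])))
  }
  fit <- suppressWarnings(
    glm(q ~ z1, family = binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  se <- sqrt(diag(vcov(fit)))
  ll <- as.numeric(logLik(fit))
  if (method == "binned") {
    curve <- empirical_success_curve(features, bin_width, min_count)
    if (nrow(curve) < 2L) {
      abort_validation("too few populated bins for the binned sigmoid fit.")
    }
    sse <- function(par) {
      p <- plogis(par[1] * curve$z1_bin_center + par[2])
      sum((curve$success_fraction - p)^2)
    }
    opt <- optim(c(a, b), sse, method = "BFGS",
                 control = list(reltol = 1e-12))
    a <- opt$par[1]
    b <- opt$par[2]
    se <- c(NA_real_, NA_real_)
    ll <- sum(stats::dbinom(q, 1, plogis(a * z1 + b), log = TRUE))
  }
  structure(list(a = a, b = b,
                 se_a = unname(se[2]), se_b = unname(se[1]),
                 n = length(q), loglik = ll, method = method),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> P(q=1|z1) = 1/(1 + exp(-(a z1 + b)))  [%s]\n",
              x$method))
  cat(sprintf("  a = %.4f (se %.4f), b = %.4f (se %.4f), n = %d\n",
              x$a, x$se_a, x$b, x$se_b, x$n))
  invisible(x)
}

#' Predicted success probability from a sigmoid fit
#'
#' @param object A `sigmoid_fit`.
#' @param z1 Safety-coordinate values.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.sigmoid_fit <- function(object, z1, ...) {
  plogis(object$a * z1 + object$b)
}

#' Sigmoid coefficients implied by the class-conditional normals
#'
#' By Bayes' rule the success posterior is
#' \deqn{P(q=1 \mid z_1) = \left[1 + \exp\left(-\log
#'   \frac{P(z_1 \mid q=1)\,P(q=1)}{P(z_1 \mid q=0)\,P(q=0)}\right)\right]^{-1},}
#' which reduces to the logistic model with
#' \eqn{a = (\mu_1 - \mu_0)/\sigma^2} and
#' \eqn{b = -(\mu_1^2 - \mu_0^2)/(2\sigma^2) + \log(p_1/(1-p_1))}
#' exactly when the two class-conditional normals share a standard
#' deviation. When they do not (the empirically typical case), the
#' log-odds are quadratic in `z1`; the returned object then flags the
#' linear reduction as inapplicable and carries the quadratic-discriminant
#' posterior function instead. That curvature is what bends the empirical
#' success curve away from a pure sigmoid at negative `z1`.
#'
#' @param fit A [fit_class_normals()] object.
#' @param prior1 Prior success probability `P(q = 1)`, in (0, 1); defaults
#'   to the empirical fraction `n1 / (n1 + n0)`.
#' @param sd_rel_tol Relative tolerance for treating the class standard
#'   deviations as equal.
#' @return An object of class `bayes_sigmoid` with fields `applicable`
#'   (TRUE when the linear reduction holds), `a`, `b` (NA when not
#'   applicable), `posterior` (function of `z1`, always available),
#'   `prior1`, `sigma1`, `sigma0`.
#' @export
bayes_sigmoid_from_normals <- function(fit, prior1 = NULL,
                                       sd_rel_tol = 1e-6) {
  prior1 <- prior1 %||% (fit$n1 / (fit$n1 + fit$n0))
  if (!is.numeric(prior1) || length(prior1) != 1L ||
      prior1 <= 0 || prior1 >= 1) {
    abort_validation("`prior1` must lie strictly between 0 and 1.")
  }
  log_prior_odds <- log(prior1 / (1 - prior1))
  equal_sd <- abs(fit$sigma1 - fit$sigma0) <=
    sd_rel_tol * max(fit$sigma1, fit$sigma0)
  if (equal_sd) {
    sigma <- (fit$sigma1 + fit$sigma0) / 2
    a <- (fit$mu1 - fit$mu0) / sigma^2
    b <- -(fit$mu1^2 - fit$mu0^2) / (2 * sigma^2) + log_prior_odds
    posterior <- function(z1) plogis(a * z1 + b)
  } else {
    a <- NA_real_
    b <- NA_real_
    mu1 <- fit$mu1; mu0 <- fit$mu0
    s1 <- fit$sigma1; s0 <- fit$sigma0
    posterior <- function(z1) {
      plogis(log(s0 / s1) - (z1 - mu1)^2 / (2 * s1^2) +
               (z1 - mu0)^2 / (2 * s0^2) + log_prior_odds)
    }
  }
  structure(list(applicable = equal_sd, a = a, b = b, posterior = posterior,
                 prior1 = prior1, sigma1 = fit$sigma1, sigma0 = fit$sigma0),
            class = "bayes_sigmoid")
}

#' @export
print.bayes_sigmoid <- function(x, ...) {
  cat("<bayes_sigmoid>\n")
  if (x$applicable) {
    cat(sprintf("  equal class SDs: linear log-odds with a = %.4f, b = %.4f\n",
                x$a, x$b))
  } else {
    cat(sprintf(paste0("  sigma1 = %.4f != sigma0 = %.4f: log-odds are ",
                       "quadratic in z1;\n  the pure sigmoid reduction does ",
                       "not apply (use $posterior).\n"),
                x$sigma1, x$sigma0))
  }
  invisible(x)
}
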