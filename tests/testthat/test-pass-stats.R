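test_that("evaluate_passes composes the public field operations", {
  sim <- sim_passes_with_tracking(20, seed = 42)
  feat <- evaluate_passes(sim$passes, sim$tracking)
  expect_equal(nrow(feat), 20L)
  expect_true(all(feat$z2 >= abs(feat$z1) - 1e-12))

  for (i in c(1, 7, 20)) {
    p <- sim$passes[i, ]
    snap <- snapshot_at(sim$tracking, p$t_o_s)
    defense <- setdiff(c("home", "away"), p$possession)
    x_e <- c(p$x_e_m, p$y_e_m)
    tau_of <- team_min_arrival(snap, p$possession, x_e)
    tau_df <- team_min_arrival(snap, defense, x_e)
    z <- z_transform(tau_of, tau_df)
    expect_equal(feat$z1[i], z$z1, tolerance = 1e-9)
    expect_equal(feat$z2[i], z$z2, tolerance = 1e-9)
    expect_equal(feat$r_tilde[i], r_tilde(snap, x_e), tolerance = 1e-9)
  }

  # an offense player standing at the end point makes it safe
  snap <- make_snapshot(home_xy = rbind(c(10, 5), matrix(0, 10, 2)),
                        away_xy = cbind(rep(30, 11), seq(-25, 25, 5)))
  tau_df <- team_min_arrival(snap, "away", c(10, 5))
  z <- z_transform(0, tau_df)
  expect_gt(z$z1, 0)
  expect_equal(z$z1, z$z2)

  # a defender at the end point makes z1 negative
  z2 <- z_transform(team_min_arrival(snap, "home", c(30, 0)), 0)
  expect_lt(z2$z1, 0)

  # a pass with no frame nearby is refused, naming the time
  bad <- dplyr::mutate(sim$passes[1, ], t_o_s = 99)
  err <- expect_error(evaluate_passes(bad, sim$tracking),
                      class = "pitchspace_validation_error")
  expect_match(conditionMessage(err), "99")
})

test_that("class-conditional normal fits are per-class MLE statistics", {
  f <- tibble::tibble(z1 = c(0, 2, 5, 7), q = c(1L, 1L, 0L, 0L))
  fit <- fit_class_normals(f)
  expect_equal(fit$mu1, 1)
  expect_equal(fit$sigma1, 1)   # ddof = 0: sqrt(mean((x - mean)^2))
  expect_equal(fit$mu0, 6)
  expect_equal(fit$sigma0, 1)
  expect_equal(c(fit$n1, fit$n0), c(2L, 2L))

  # split-then-average oracle on mixed synthetic classes
  d <- sim_labeled_z1(5000, seed = 77)
  fit <- fit_class_normals(d)
  for (cls in c(0L, 1L)) {
    x <- d$z1[d$q == cls]
    expect_equal(if (cls == 1L) fit$mu1 else fit$mu0, mean(x))
    expect_equal(if (cls == 1L) fit$sigma1 else fit$sigma0,
                 sqrt(mean((x - mean(x))^2)))
  }

  expect_error(fit_class_normals(tibble::tibble(z1 = c(1, 2, 3),
                                                q = c(1L, 1L, 0L))),
               "failed", class = "pitchspace_validation_error")
  expect_error(fit_class_normals(tibble::tibble(z1 = c(1, 1, 0, 2),
                                                q = c(1L, 1L, 0L, 0L))),
               "variance", class = "pitchspace_validation_error")
})

test_that("empirical success curve counts outcomes per bin", {
  f <- tibble::tibble(z1 = c(0.01, 0.03, 0.05, 0.52, 0.57),
                      q = c(1L, 1L, 0L, 0L, 0L))
  curve <- empirical_success_curve(f, bin_width = 0.1, min_count = 1)
  expect_equal(curve$success_fraction, c(2 / 3, 0))
  expect_equal(curve$n, c(3L, 2L))
  expect_equal(curve$z1_bin_center, c(0.05, 0.55))

  all_success <- tibble::tibble(z1 = runif(50), q = rep(1L, 50))
  expect_true(all(empirical_success_curve(all_success, min_count = 1)
                  $success_fraction == 1))

  # binned fractions track the generating sigmoid within binomial bands
  d <- sim_outcome_passes(20000, seed = 15)
  curve <- empirical_success_curve(d, bin_width = 0.25, min_count = 50)
  p <- plogis(4.68 * curve$z1_bin_center + 0.48)
  band <- 1.96 * sqrt(p * (1 - p) / curve$n) + 0.02  # + bin-curvature slack
  expect_gte(mean(abs(curve$success_fraction - p) <= band), 0.9)

  expect_error(empirical_success_curve(f[0, ]),
               class = "pitchspace_validation_error")
})

test_that("sigmoid MLE agrees with independent maximisers", {
  # outcome independent of z1: slope ~ 0, intercept ~ logit of the rate
  d0 <- withr::with_seed(3, tibble::tibble(z1 = runif(20000, -2, 3),
                                           q = rbinom(20000, 1L, 0.7)))
  fit0 <- fit_sigmoid(d0)
  expect_lt(abs(fit0$a - 0), 3 * fit0$se_a)
  expect_lt(abs(fit0$b - qlogis(0.7)), 3 * fit0$se_b)

  # tiny data set: matches a grid-search maximiser of the log-likelihood
  tiny <- tibble::tibble(z1 = c(-1, -1, -1, 1, 1, 1),
                         q = c(0L, 0L, 1L, 1L, 1L, 0L))
  fit <- fit_sigmoid(tiny)
  gs <- grid_search_logistic(tiny$z1, tiny$q)
  expect_equal(fit$a, gs$a, tolerance = 1e-3)
  expect_equal(fit$b, gs$b, tolerance = 1e-3)

  # the returned optimum beats every point of a surrounding coarse grid
  ll <- function(a, b) sum(dbinom(tiny$q, 1, plogis(a * tiny$z1 + b),
                                  log = TRUE))
  grid <- expand.grid(a = fit$a + seq(-1, 1, 0.2),
                      b = fit$b + seq(-1, 1, 0.2))
  expect_true(all(fit$loglik + 1e-8 >=
                    mapply(ll, grid$a, grid$b)))

  # positive slope gives a strictly increasing success probability
  zs <- seq(-3, 3, 0.1)
  d1 <- sim_outcome_passes(5000, seed = 16)
  fit1 <- fit_sigmoid(d1)
  expect_true(all(diff(predict(fit1, zs)) > 0))

  # perfect separation is refused with a diagnostic
  sep <- tibble::tibble(z1 = c(-2, -1, 1, 2), q = c(0L, 0L, 1L, 1L))
  err <- expect_error(fit_sigmoid(sep), class = "pitchspace_numerical_error")
  expect_match(conditionMessage(err), "separation")
  expect_error(fit_sigmoid(tibble::tibble(z1 = 1:4, q = rep(1L, 4))),
               class = "pitchspace_validation_error")
})

test_that("binned least-squares sigmoid is close to the MLE on clean data", {
  d <- sim_outcome_passes(30000, seed = 17)
  mle <- fit_sigmoid(d)
  binned <- fit_sigmoid(d, method = "binned", bin_width = 0.2)
  expect_equal(binned$a, mle$a, tolerance = 0.15)
  expect_equal(binned$b, mle$b, tolerance = 0.1)
  expect_true(is.na(binned$se_a))
})

test_that("sigmoid parameter recovery holds across the design space", {
  withr::with_seed(19, {
    ok <- 0L
    reps <- 10L
    for (r in seq_len(reps)) {
      a <- runif(1, 0.5, 8)
      b <- runif(1, -2, 2)
      d <- sim_outcome_passes(20000, a = a, b = b)
      fit <- fit_sigmoid(d)
      if (abs(fit$a - a) <= 3 * fit$se_a && abs(fit$b - b) <= 3 * fit$se_b) {
        ok <- ok + 1L
      }
    }
    expect_gte(ok, reps - 1L)
  })
})

test_that("Bayes identity reduces to the sigmoid when the SDs are equal", {
  fit <- structure(list(mu1 = 1, sigma1 = 1, n1 = 100,
                        mu0 = -1, sigma0 = 1, n0 = 100),
                   class = "class_normal_fit")
  bs <- bayes_sigmoid_from_normals(fit, prior1 = 0.5)
  expect_true(bs$applicable)
  expect_equal(bs$a, 2)
  expect_equal(bs$b, 0)
  expect_equal(bs$posterior(0.5), plogis(2 * 0.5))

  # equal-sigma synthetic data: closed form matches the fitted logistic
  d <- sim_labeled_z1(200000, mu1 = 0.7, sigma1 = 0.5,
                      mu0 = -0.3, sigma0 = 0.5, prior1 = 0.55, seed = 23)
  closed <- bayes_sigmoid_from_normals(
    structure(list(mu1 = 0.7, sigma1 = 0.5, n1 = 1, mu0 = -0.3,
                   sigma0 = 0.5, n0 = 1), class = "class_normal_fit"),
    prior1 = 0.55)
  mle <- fit_sigmoid(d)
  expect_lt(abs(mle$a - closed$a), 3 * mle$se_a)
  expect_lt(abs(mle$b - closed$b), 3 * mle$se_b)

  # unequal SDs: the linear reduction is flagged inapplicable and the
  # quadratic posterior takes over
  uneq <- structure(list(mu1 = 0.69, sigma1 = 0.54, n1 = 100,
                         mu0 = -0.25, sigma0 = 0.38, n0 = 100),
                    class = "class_normal_fit")
  bq <- bayes_sigmoid_from_normals(uneq, prior1 = 0.5)
  expect_false(bq$applicable)
  expect_true(is.na(bq$a))
  # the quadratic posterior still reproduces Bayes' rule pointwise
  z <- c(-1, 0, 0.5, 1.5)
  num <- dnorm(z, 0.69, 0.54) * 0.5
  den <- num + dnorm(z, -0.25, 0.38) * 0.5
  expect_equal(bq$posterior(z), num / den, tolerance = 1e-12)

  expect_error(bayes_sigmoid_from_normals(uneq, prior1 = 1.2),
               class = "pitchspace_validation_error")
})

test_that("pre-shot filtering selects the flagged subset", {
  f <- tibble::tibble(z1 = rnorm(10), q = rep(0:1, 5),
                      pre_shot = rep(c(TRUE, FALSE), 5))
  expect_equal(nrow(filter_pre_shot(f)), 5L)
  expect_true(all(filter_pre_shot(f)$pre_shot))
  none <- dplyr::mutate(f, pre_shot = FALSE)
  expect_equal(nrow(filter_pre_shot(none)), 0L)

  # a pre-shot class generated with lower mean z1 shows up in the fits
  all_passes <- sim_labeled_z1(4000, mu1 = 0.69, seed = 29)
  pre <- dplyr::mutate(sim_labeled_z1(1000, mu1 = 0.05, mu0 = -0.4,
                                      seed = 30), pre_shot = TRUE)
  mixed <- dplyr::bind_rows(dplyr::mutate(all_passes, pre_shot = FALSE), pre)
  fit_pre <- fit_class_normals(filter_pre_shot(mixed))
  fit_all <- fit_class_normals(mixed)
  expect_lt(fit_pre$mu1, fit_all$mu1)
})

test_that("tidiers expose the fits in broom shape", {
  d <- sim_labeled_z1(2000, seed = 31)
  cn <- fit_class_normals(d)
  td <- tidy(cn)
  expect_equal(td$class, c("successful", "failed"))
  expect_equal(td$mean, c(cn$mu1, cn$mu0))
  gl <- glance(cn)
  expect_equal(gl$success_fraction, cn$n1 / (cn$n1 + cn$n0))

  sf <- fit_sigmoid(sim_outcome_passes(2000, seed = 32))
  ts <- tidy(sf)
  expect_equal(ts$term, c("slope", "intercept"))
  expect_equal(ts$estimate, c(sf$a, sf$b))
  expect_equal(glance(sf)$n, 2000L)
})
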