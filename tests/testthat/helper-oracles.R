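# Independent oracles and fixture builders shared across the test files.

# Dense-scan arrival-time oracle, written directly from the reachable-set
# geometry and independent of the package's solver: evaluate
# g(t) = ||target - c(t)|| - r(t) on a fine time grid and return the first
# time at which it is non-positive.
dense_scan_tau <- function(x0, v0, target, v_max = 7.8, alpha = 1.3,
                           dt = 1e-4, t_max = NULL) {
  d0 <- sqrt(sum((target - x0)^2))
  if (is.null(t_max)) {
    t_max <- (d0 + sqrt(sum(v0^2)) / alpha) / v_max + 2 / alpha + 0.5
  }
  ts <- seq(0, t_max, by = dt)
  s <- (1 - exp(-alpha * ts)) / alpha
  cx <- x0[1] + s * v0[1]
  cy <- x0[2] + s * v0[2]
  g <- sqrt((target[1] - cx)^2 + (target[2] - cy)^2) - v_max * (ts - s)
  i <- which(g <= 0)[1]
  if (is.na(i)) stop("oracle: no crossing before t_max")
  ts[i]
}

# Build a one-frame snapshot tibble from position matrices (one row per
# player). Velocities default to zero; is_gk marks the first player of a
# side when gk = TRUE.
make_snapshot <- function(home_xy, away_xy, home_v = NULL, away_v = NULL,
                          gk = FALSE, time = 0) {
  one <- function(xy, v, side) {
    xy <- matrix(xy, ncol = 2)
    if (is.null(v)) v <- matrix(0, nrow(xy), 2) else v <- matrix(v, ncol = 2)
    tibble::tibble(
      frame = 1L, time_s = time, team = side,
      player_id = sprintf("%s%02d", substr(side, 1, 1), seq_len(nrow(xy))),
      x_m = xy[, 1], y_m = xy[, 2],
      is_gk = if (gk) c(TRUE, rep(FALSE, nrow(xy) - 1L)) else
        rep(FALSE, nrow(xy)),
      vx_mps = v[, 1], vy_mps = v[, 2])
  }
  dplyr::bind_rows(one(home_xy, home_v, "home"), one(away_xy, away_v, "away"))
}

# 22-player fixture: 20 outfield players on the corners of a 2w x 2h
# rectangle (5 per corner) plus one goalkeeper per side outside the count.
rect_formation_snapshot <- function(w = 20, h = 10) {
  corners <- rbind(c(-w, -h), c(-w, h), c(w, -h), c(w, h))
  field <- corners[rep(1:4, each = 5), ]
  home <- rbind(c(-50, 0), field[1:10, ])   # first row is the goalkeeper
  away <- rbind(c(50, 0), field[11:20, ])
  make_snapshot(home, away, gk = TRUE)
}

# Brute-force log-likelihood grid search for the logistic model: coarse
# grid refined around the best cell, independent of glm.
grid_search_logistic <- function(z1, q, a_range = c(-6, 6),
                                 b_range = c(-6, 6)) {
  ll <- function(a, b) sum(stats::dbinom(q, 1, stats::plogis(a * z1 + b),
                                         log = TRUE))
  best <- c(0, 0)
  step <- 0.1
  grid_best <- function(ar, br, step) {
    as <- seq(ar[1], ar[2], by = step)
    bs <- seq(br[1], br[2], by = step)
    m <- outer(as, bs, Vectorize(ll))
    i <- which(m == max(m), arr.ind = TRUE)[1, ]
    c(as[i[1]], bs[i[2]])
  }
  best <- grid_best(a_range, b_range, 0.1)
  for (step in c(0.01, 0.001, 1e-4)) {
    best <- grid_best(best[1] + c(-15, 15) * step,
                      best[2] + c(-15, 15) * step, step)
  }
  list(a = best[1], b = best[2], loglik = ll(best[1], best[2]))
}

csv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
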