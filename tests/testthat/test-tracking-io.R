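tracking_header <- "frame,time_s,team,player_id,x_m,y_m,is_gk,vx_mps,vy_mps"

tracking_lines <- function(n_frames = 2, dt = 0.04) {
  snap <- sim_snapshot(seed = 99)
  rows <- character(0)
  for (i in seq_len(n_frames)) {
    d <- dplyr::mutate(snap, frame = i, time_s = (i - 1) * dt,
                       x_m = x_m + (i - 1) * dt * vx_mps,
                       y_m = y_m + (i - 1) * dt * vy_mps)
    rows <- c(rows, sprintf("%d,%.10g,%s,%s,%.10g,%.10g,%d,%.10g,%.10g",
                            d$frame, d$time_s, d$team, d$player_id,
                            d$x_m, d$y_m, as.integer(d$is_gk),
                            d$vx_mps, d$vy_mps))
  }
  c(tracking_header, rows)
}

test_that("well-formed tracking files round-trip through write/read", {
  path <- csv_tmp(tracking_lines(n_frames = 3))
  trk <- read_tracking(path)
  expect_equal(length(unique(trk$time_s)), 3L)
  expect_true(all(c("vx_mps", "vy_mps") %in% names(trk)))
  expect_s3_class(trk, "tbl_df")

  out <- withr::local_tempfile(fileext = ".csv")
  write_tracking(trk, out)
  trk2 <- read_tracking(out)
  for (col in c("time_s", "x_m", "y_m", "vx_mps", "vy_mps")) {
    expect_equal(trk2[[col]], trk[[col]], tolerance = 1e-9)
  }
  expect_identical(trk2$player_id, trk$player_id)
  expect_identical(trk2$is_gk, trk$is_gk)
})

test_that("schema and invariant violations are reported with context", {
  lines <- tracking_lines()
  # missing column
  bad <- gsub("^frame,", "idx,", lines[1])
  expect_error(read_tracking(csv_tmp(c(bad, lines[-1]))),
               "frame", class = "pitchspace_schema_error")
  # frame 2 listing 21 players
  drop_one <- lines[-length(lines)]
  err <- expect_error(read_tracking(csv_tmp(drop_one)),
                      class = "pitchspace_validation_error")
  expect_match(conditionMessage(err), "frame 2")
  expect_match(conditionMessage(err), "21")
  # two goalkeepers on one side (is_gk is the 7th field)
  lines2 <- tracking_lines(n_frames = 1)
  f <- strsplit(lines2[3], ",")[[1]]
  f[7] <- "1"
  lines2[3] <- paste(f, collapse = ",")
  expect_error(read_tracking(csv_tmp(lines2)), "goalkeeper",
               class = "pitchspace_validation_error")
})

test_that("velocity estimation is exact for affine motion and second order
           for smooth motion", {
  dt <- 0.04
  n <- 51
  t <- (seq_len(n) - 1) * dt

  # constant position: zero velocity everywhere
  v <- estimate_velocities(cbind(rep(2, n), rep(-1, n)), dt)
  expect_equal(v, matrix(0, n, 2))

  # linear motion x(t) = (2t, 0): exact at every frame, any window
  for (w in c(3, 5, 9)) {
    v <- estimate_velocities(cbind(2 * t, 0 * t), dt, window = w)
    expect_equal(v[, 1], rep(2, n), tolerance = 1e-12)
    expect_equal(v[, 2], rep(0, n), tolerance = 1e-12)
  }

  # quadratic motion x(t) = t^2: central difference error O(dt^2)
  v <- estimate_velocities(cbind(t^2, 0 * t), dt, window = 5)
  interior <- 3:(n - 2)
  expect_lt(max(abs(v[interior, 1] - 2 * t[interior])), 1e-3)

  expect_error(estimate_velocities(cbind(1:3, 1:3), dt, window = 5),
               "at least 5", class = "pitchspace_validation_error")
  expect_error(estimate_velocities(cbind(t, t), dt, window = 4),
               class = "pitchspace_validation_error")
})

test_that("velocities are estimated when the file has none", {
  lines <- tracking_lines(n_frames = 9)
  no_v <- sub(",vx_mps,vy_mps$", "", lines[1])
  body <- sapply(strsplit(lines[-1], ","), function(x)
    paste(x[1:7], collapse = ","))
  trk <- read_tracking(csv_tmp(c(no_v, body)))
  # base snapshot moved with constant velocity, so estimates recover it
  snap0 <- sim_snapshot(seed = 99)
  est <- dplyr::arrange(dplyr::filter(trk, frame == 5), player_id)
  truth <- dplyr::arrange(snap0, player_id)
  expect_equal(est$vx_mps, truth$vx_mps, tolerance = 1e-6)
  expect_equal(est$vy_mps, truth$vy_mps, tolerance = 1e-6)
})

test_that("pass files parse strictly and round-trip", {
  header <- "t_o_s,x_o_m,y_o_m,t_e_s,x_e_m,y_e_m,q,pre_shot,possession"
  path <- csv_tmp(c(header, "12.0,10,5,13.2,30,8,1,0,home"))
  p <- read_passes(path)
  expect_identical(p$q, 1L)
  expect_identical(p$pre_shot, FALSE)
  expect_equal(p$t_o_s, 12)
  expect_equal(p$x_e_m, 30)

  # q outside {0, 1}
  expect_error(read_passes(csv_tmp(c(header, "12.0,10,5,13.2,30,8,2,0,home"))),
               "q", class = "pitchspace_validation_error")
  # end before origin
  expect_error(read_passes(csv_tmp(c(header, "12.0,10,5,11.0,30,8,1,0,home"))),
               class = "pitchspace_validation_error")
  # pre_shot optional, defaults to FALSE
  h2 <- "t_o_s,x_o_m,y_o_m,t_e_s,x_e_m,y_e_m,q,possession"
  p2 <- read_passes(csv_tmp(c(h2, "0.0,0,0,1.0,5,5,0,away")))
  expect_identical(p2$pre_shot, FALSE)

  out <- withr::local_tempfile(fileext = ".csv")
  write_passes(p, out)
  expect_equal(as.data.frame(read_passes(out)), as.data.frame(p),
               tolerance = 1e-9)
})

test_that("features round-trip through write_features/read_features", {
  sim <- sim_passes_with_tracking(5, seed = 3)
  feat <- evaluate_passes(sim$passes, sim$tracking)
  out <- withr::local_tempfile(fileext = ".csv")
  write_features(feat, out)
  feat2 <- read_features(out)
  for (col in c("z1", "z2", "r_tilde", "q")) {
    expect_equal(feat2[[col]], feat[[col]], tolerance = 1e-9)
  }
  expect_identical(feat2$pre_shot, feat$pre_shot)
})

test_that("snapshot_at picks the nearest frame within tolerance", {
  trk <- sim_tracking(n_frames = 5, seed = 4)
  snap <- snapshot_at(trk, 0.081)
  expect_equal(unique(snap$time_s), 0.08)
  expect_equal(nrow(snap), 22L)
  expect_error(snapshot_at(trk, 3), "no tracking frame",
               class = "pitchspace_validation_error")
})
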