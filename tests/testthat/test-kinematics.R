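mk_traj <- function(x, y, rate = 10) {
  tibble::tibble(time = (seq_along(x) - 1) / rate, x = x, y = y)
}

test_that("centred moving average behaves on canonical inputs", {
  # constant trajectory is a fixed point
  tr <- mk_traj(rep(3, 30), rep(-1, 30))
  sm <- smooth_centroid(tr, 0.5)
  expect_equal(sm$x, tr$x)
  expect_equal(sm$y, tr$y)

  # single impulse of height h with a 5-frame window becomes a h/5 plateau
  x <- rep(0, 21); x[11] <- 5
  sm <- smooth_centroid(mk_traj(x, x * 0), 0.5)
  expect_equal(sm$x[9:13], rep(1, 5))
  expect_equal(sm$x[7], 0)

  # a linear ramp is unchanged away from the edges
  x <- seq(0, 2, length.out = 21)
  sm <- smooth_centroid(mk_traj(x, x * 0), 0.5)
  expect_equal(sm$x[3:19], x[3:19])

  expect_error(smooth_centroid(mk_traj(1:3 * 1.0, rep(0, 3)), 1), "longer")
})

test_that("speed and signed acceleration match finite-difference arithmetic", {
  # constant velocity 4 cm/s
  tr <- compute_kinematics(mk_traj(seq(0, 4, by = 0.4), rep(0, 11)))
  expect_equal(tr$speed[-1], rep(4, 10))
  expect_equal(tr$accel[-(1:2)], rep(0, 9))

  # speed ramp 0 -> 10 cm/s over 2 s gives 5 cm/s^2
  v <- seq(0, 10, length.out = 21)            # speed at each frame
  x <- cumsum(c(0, v[-1] * 0.1))
  tr <- compute_kinematics(mk_traj(x, rep(0, 21)))
  expect_equal(tr$accel[3:21], rep(5, 19), tolerance = 1e-10)

  # stationary
  tr <- compute_kinematics(mk_traj(rep(1, 10), rep(1, 10)))
  expect_equal(tr$speed[-1], rep(0, 9))

  # time-origin shift leaves speed unchanged; spatial scaling is linear
  tr1 <- compute_kinematics(mk_traj(cumsum(runif(30)), rep(0, 30)))
  tr2 <- tr1
  tr2$time <- tr2$time + 100
  tr2 <- compute_kinematics(tr2[, c("time", "x", "y")])
  expect_equal(tr2$speed, tr1$speed)
  tr3 <- compute_kinematics(mk_traj(3 * tr1$x, rep(0, 30)))
  expect_equal(tr3$speed, 3 * tr1$speed)
})

test_that("tortuosity is 1 on straight paths and matches the arc/chord form on circles", {
  # straight line at constant speed
  tr <- compute_kinematics(mk_traj(seq(0, 30, by = 0.3), rep(0, 101)))
  tor <- compute_tortuosity(tr, speed_threshold = 1)
  mid <- !is.na(tor$tortuosity)
  expect_true(any(mid))
  expect_equal(tor$tortuosity[mid], rep(1, sum(mid)), tolerance = 1e-6)
  expect_equal(as.numeric(attr(tor, "tortuosity_summary")), 1, tolerance = 1e-6)

  # circle r = 10 cm at 4 cm/s sampled at 100 Hz: window arc 10 cm (1 rad),
  # closed form arc/chord = 10 / (2 * 10 * sin(0.5))
  rate <- 100
  t <- seq(0, 60, by = 1 / rate)
  th <- 4 * t / 10
  tr <- tibble::tibble(time = t, x = 10 * cos(th), y = 10 * sin(th))
  tor <- compute_tortuosity(compute_kinematics(tr))
  closed <- 10 / (2 * 10 * sin(0.5))
  mid <- which(!is.na(tor$tortuosity))
  expect_equal(mean(tor$tortuosity[mid]), closed, tolerance = 1e-3)

  # independent dense-polyline oracle for the circular case
  w <- round(1.25 * rate)
  i <- 3000
  L_or <- sum(sqrt(diff(tr$x[(i - w):(i + w)])^2 + diff(tr$y[(i - w):(i + w)])^2))
  D_or <- sqrt((tr$x[i + w] - tr$x[i - w])^2 + (tr$y[i + w] - tr$y[i - w])^2)
  expect_equal(tor$tortuosity[i], L_or / D_or, tolerance = 1e-12)

  # out-and-back: window endpoints coincide -> undefined, not infinite
  x <- c(seq(0, 10, by = 0.5), seq(9.5, 0, by = -0.5))
  tr <- compute_kinematics(mk_traj(x, rep(0, length(x))))
  tor <- compute_tortuosity(tr, half_window = 1)
  turn <- 21                                   # symmetric about the turn
  expect_true(is.na(tor$tortuosity[turn]))

  # no frame exceeds the speed threshold -> summary undefined with flag
  tr <- compute_kinematics(mk_traj(seq(0, 3, by = 0.03), rep(0, 101)))
  tor <- compute_tortuosity(tr, speed_threshold = 50)
  expect_true(is.na(attr(tor, "tortuosity_summary")))
  expect_false(attr(attr(tor, "tortuosity_summary"), "defined"))
})

test_that("turn angles follow the three-point construction and its invariances", {
  tr <- compute_turn_angles(mk_traj(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(tr$turn_angle[2], 0)
  tr <- compute_turn_angles(mk_traj(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(tr$turn_angle[2], 90)
  tr <- compute_turn_angles(mk_traj(c(0, 1, 0), c(0, 0, 0)))
  expect_equal(tr$turn_angle[2], 180)

  # sub-threshold steps are excluded
  tr <- compute_turn_angles(mk_traj(c(0, 0.01, 1), c(0, 0, 0)))
  expect_true(is.na(tr$turn_angle[2]))

  # invariance under global rotation + translation
  set.seed(9)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  a0 <- compute_turn_angles(mk_traj(x, y))$turn_angle
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 12
  yr <- sin(th) * x + cos(th) * y - 3
  a1 <- compute_turn_angles(mk_traj(xr, yr))$turn_angle
  expect_equal(a1, a0, tolerance = 1e-10)

  h <- turn_angle_histogram(compute_turn_angles(mk_traj(x, y)))
  expect_equal(sum(h$count), sum(!is.na(a0)))
})

test_that("immobility bouts respect the duration threshold", {
  rate <- 10
  mkk <- function(speed) tibble::tibble(time = (seq_along(speed) - 1) / rate,
                                        speed = speed)
  # 10 s at zero speed: one bout spanning every measured frame
  b <- label_immobility(mkk(rep(0, 100)))
  expect_equal(nrow(b), 1)
  expect_equal(b$end_frame - b$start_frame, 100)

  # a 0.9 s dip does not qualify
  sp <- c(rep(10, 20), rep(0, 9), rep(10, 20))
  expect_equal(nrow(label_immobility(mkk(sp))), 0)

  # two separated 2-s dips give two bouts
  sp <- c(rep(10, 10), rep(0, 20), rep(10, 10), rep(1, 20), rep(10, 10))
  b <- label_immobility(mkk(sp))
  expect_equal(nrow(b), 2)
  expect_equal(b$start_frame, c(10L, 40L))
  expect_equal(b$end_frame, c(30L, 60L))
})

test_that("trial extraction recovers scripted traversals exactly", {
  sc <- scripted_session()
  trials <- sc$session$trials
  expect_equal(nrow(trials), nrow(sc$expected))
  expect_equal(trials$direction, sc$expected$direction)
  expect_true(all(abs(trials$start_frame - sc$expected$start_frame) <= 1))
  expect_true(all(abs(trials$end_frame - sc$expected$end_frame) <= 1))
  expect_true(all(trials$qualified))
  # directions strictly alternate
  expect_true(all(trials$direction[-1] != trials$direction[-nrow(trials)]))
  # the water-delivery frame itself is never inside a trial
  wd <- sc$session$events$frame[sc$session$events$kind == "water_delivery"]
  for (i in seq_len(nrow(trials))) {
    expect_false(any(wd >= trials$start_frame[i] & wd < trials$end_frame[i]))
  }
})

test_that("trials spending too long in arm 3 are kept but disqualified", {
  ses <- decoder_session()
  tr_strict <- extract_navigation_trials(ses$frames, ses$events, arm3_frac = 0.02)
  tr_loose <- extract_navigation_trials(ses$frames, ses$events, arm3_frac = 0.9)
  expect_equal(nrow(tr_strict), nrow(tr_loose))
  expect_true(sum(tr_strict$qualified) < sum(tr_loose$qualified))
  detoured <- tr_strict$arm3_fraction > 0.02
  expect_false(any(tr_strict$qualified[detoured]))
})

test_that("learning metrics count valid licks and arm entries", {
  # 30 valid licks at t = 10, 20, ..., 300 s
  times <- seq(10, 300, by = 10)
  ev <- event_log(dplyr::bind_rows(
    tibble::tibble(time = times, kind = "lick", spout = rep(c(1L, 2L), 15)),
    tibble::tibble(time = times, kind = "water_delivery", spout = rep(c(1L, 2L), 15))
  ))
  df <- tibble::tibble(time = seq(0, 310, by = 0.1), region = "arm1")
  m <- learning_metrics(ev, df)
  expect_true(m$defined)
  expect_equal(m$time_to_valid_licks, 300)
  expect_equal(m$error_lick_rate, 0)

  # scripted region sequence: 10 arm1, 10 arm2, 4 arm3 entries -> ratio 5
  regs <- c("center")
  for (i in 1:10) regs <- c(regs, "arm1", "center")
  for (i in 1:10) regs <- c(regs, "arm2", "center")
  for (i in 1:4) regs <- c(regs, "arm3", "center")
  df2 <- tibble::tibble(time = seq_along(regs) * 0.1, region = regs)
  t_last <- max(df2$time)
  ev2 <- event_log(dplyr::bind_rows(
    tibble::tibble(time = c(t_last - 0.5, t_last), kind = "lick", spout = 1L),
    tibble::tibble(time = t_last, kind = "water_delivery", spout = 1L)
  ))
  m2 <- learning_metrics(ev2, df2, n_licks = 1)
  expect_equal(m2$reward_arm_entry_ratio, 5)
  expect_equal(m2$error_lick_rate, 0.5)  # one dry lick of two in the window
})

test_that("open-field metrics integrate the standard battery", {
  # stationary mouse: zero accumulated distance
  n <- 3200
  still <- tibble::tibble(time = (seq_len(n) - 1) / 10,
                          x = rep(5, n), y = rep(5, n))
  m <- openfield_metrics(still)
  expect_equal(m$accumulated_distance, 0)
  expect_equal(m$center_entries, 1)      # starts inside, counted once

  # five square laps of side 30 cm (inside the walls): distance = 5 * perimeter
  side_pts <- function(a, b, k = 150) cbind(seq(a[1], b[1], length.out = k + 1),
                                            seq(a[2], b[2], length.out = k + 1))[-1, ]
  corners <- list(c(-15, -15), c(15, -15), c(15, 15), c(-15, 15))
  lap <- do.call(rbind, lapply(1:4, function(i) {
    side_pts(corners[[i]], corners[[if (i == 4) 1 else i + 1]])
  }))
  laps <- do.call(rbind, replicate(5, lap, simplify = FALSE))
  warm <- matrix(rep(c(-15, -15), 350), ncol = 2, byrow = TRUE)  # adaption padding
  pts <- rbind(warm, laps)
  tr <- tibble::tibble(time = (seq_len(nrow(pts)) - 1) / 10,
                       x = pts[, 1], y = pts[, 2])
  m <- openfield_metrics(tr, smooth_window = 0)
  expect_equal(m$accumulated_distance, 5 * 4 * 30, tolerance = 1e-6)

  # a path hugging the walls never enters the 20 x 20 center zone
  th <- seq(0, 20 * pi, length.out = 4000)
  ring <- tibble::tibble(time = (seq_along(th) - 1) / 10,
                         x = 18 * cos(th), y = 18 * sin(th))
  m <- openfield_metrics(ring)
  expect_equal(m$center_entries, 0)

  expect_error(openfield_metrics(still[1:100, ]), "adaption")
})
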