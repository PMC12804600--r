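test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_traversals = 6, n_neurons = 10, n_position = 3,
                    n_path = 2, n_accel = 2, n_conj_accel_position = 1,
                    n_conj_accel_path = 1)
  a <- simulate_ymaze_session(cfg)
  b <- simulate_ymaze_session(cfg)
  expect_identical(a$traj$x, b$traj$x)
  expect_identical(a$events$time, b$events$time)

  s1 <- suppressWarnings(simulate_session(cfg))
  s2 <- suppressWarnings(simulate_session(cfg))
  expect_identical(s1$traces$mat, s2$traces$mat)
  expect_identical(s1$ground_truth$preferred, s2$ground_truth$preferred)

  o1 <- simulate_openfield_trajectory(sim_config(seed = 4, duration = 30, behavior_rate = 10))
  o2 <- simulate_openfield_trajectory(sim_config(seed = 4, duration = 30, behavior_rate = 10))
  expect_identical(o1$x, o2$x)
})

test_that("the alternation task produces the requested traversals and dry licks", {
  cfg <- sim_config(seed = 5, n_traversals = 10, p_arm3 = 0, p_revisit = 0.5,
                    n_neurons = 2, n_position = 0, n_path = 0, n_accel = 0,
                    n_conj_accel_position = 0, n_conj_accel_path = 0)
  beh <- simulate_ymaze_session(cfg)
  expect_equal(nrow(beh$itinerary), 10)
  expect_true(all(beh$itinerary$from[-1] == beh$itinerary$to[-10]))
  expect_false(any(beh$itinerary$arm3_detour))

  # consecutive licks at the same spout: only the alternation-valid bout is
  # rewarded, so revisit bouts are entirely dry
  ev <- beh$events
  licks <- ev[ev$kind == "lick", ]
  wd_times <- ev$time[ev$kind == "water_delivery"]
  lick_valid <- vapply(licks$time, function(t) any(abs(wd_times - t) < 1e-6), logical(1))
  # dry licks exist (p_revisit = 0.5) and occur at the same spout as the
  # previous rewarded bout
  expect_true(any(!lick_valid))
  # every delivery coincides with a lick
  expect_true(all(vapply(wd_times, function(t) any(abs(licks$time - t) < 1e-6), logical(1))))

  expect_error(simulate_ymaze_session(sim_config(seed = 1, duration = 3)),
               "two traversals")
})

test_that("open-field walks stay confined and straighten without turning noise", {
  cfg <- sim_config(seed = 8, duration = 120, behavior_rate = 10)
  tr <- simulate_openfield_trajectory(cfg)
  expect_true(all(abs(tr$x) <= 20 + 1e-9))
  expect_true(all(abs(tr$y) <= 20 + 1e-9))

  straight <- simulate_openfield_trajectory(
    sim_config(seed = 8, duration = 20, behavior_rate = 10),
    turning_noise = 0, wall_bias = 0
  )
  # the heading only ever changes at a wall reflection
  a <- compute_turn_angles(straight)$turn_angle
  turns <- which(!is.na(a) & a > 0.001)
  if (length(turns) > 0) {
    near_wall <- abs(straight$x[turns]) > 17 | abs(straight$y[turns]) > 17
    expect_true(all(near_wall))
    pre <- a[2:(turns[1] - 1)]
    expect_true(all(pre[!is.na(pre)] < 0.001))
  } else {
    expect_true(all(a[!is.na(a)] < 0.001))
  }
})

test_that("planted traces follow the stated forward model", {
  ses <- small_session()
  frames <- ses$frames

  # noiseless, baseline-free position neuron: appreciable signal only in
  # (and within 5 tau after) its preferred region
  cfg0 <- sim_config(seed = 13, n_neurons = 1, n_position = 1, n_path = 0,
                     n_accel = 0, n_conj_accel_position = 0, n_conj_accel_path = 0,
                     noise_sigma = 0, tuning_gain = 10, baseline_rate = 0)
  pl <- plant_traces(frames, cfg0)
  gt <- pl$ground_truth
  tr <- pl$traces$mat[1, ]
  expect_gt(max(tr), 0)
  inregion <- !is.na(frames$region) & frames$region == gt$preferred[1]
  near <- which(inregion)
  ok <- rep(FALSE, length(tr))
  for (d in 0:20) ok[pmin(near + d, length(tr))] <- TRUE   # + 5 tau = 2 s
  # outside the extended support the trace is below the 5-tau residual
  expect_true(all(tr[!ok] <= exp(-5) * max(tr) + 1e-9))

  # doubling the gain increases the condition-mean contrast monotonically
  contrast <- function(gain, seed) {
    cfgg <- sim_config(seed = seed, n_neurons = 1, n_position = 1, n_path = 0,
                       n_accel = 0, n_conj_accel_position = 0,
                       n_conj_accel_path = 0, tuning_gain = gain)
    p <- plant_traces(frames, cfgg)
    reg <- p$ground_truth$preferred[1]
    mean(p$traces$mat[1, frames$region == reg]) -
      mean(p$traces$mat[1, frames$region != reg & frames$region != "none"])
  }
  wins <- vapply(1:20, function(s) contrast(4, s) < contrast(8, s), logical(1))
  expect_true(mean(wins) > 0.9)
})

test_that("default sessions populate both acceleration analysis bins", {
  ses <- memo("default_bins", suppressWarnings(simulate_session(sim_config(seed = 2))))
  bins <- table(bin_acceleration(ses$frames)$accel_bin)
  expect_gte(bins[["low"]], 100)
  expect_gte(bins[["high"]], 100)
})

test_that("the encoding-model generator is exact and identifiable", {
  d <- simulate_glm_session(0.5, 2, -1, noise_sd = 0, n_frames = 200, seed = 3)
  expect_identical(d$x, 0.5 + 2 * d$position - 1 * d$acceleration)
  fit <- fit_trajectory_glm(d$x, d$position, d$acceleration)
  expect_equal(unname(fit$beta), c(0.5, 2, -1), tolerance = 1e-8)
  expect_error(simulate_glm_session(0, 1, 1, 1, n_frames = 5), "at least 10")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- sim_config(seed = 9, duration = 120, n_neurons = 50, n_position = 5,
                    n_path = 5, n_accel = 5, n_conj_accel_position = 0,
                    n_conj_accel_path = 0, tuning_gain = 6)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2[order(names(cfg2))], cfg[order(names(cfg))],
               ignore_attr = TRUE)
  writeLines("nonsense_field: 3", f)
  expect_error(read_sim_config(f), "unknown config field")
})
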