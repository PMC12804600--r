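test_that("trajectory CSV loading enforces the contract", {
  f <- tempfile(fileext = ".csv")

  # identity load
  write.csv(data.frame(time = c(0, 0.1, 0.2), x = 0:2, y = 0), f, row.names = FALSE)
  tr <- load_trajectory(f)
  expect_s3_class(tr, "nav_trajectory")
  expect_equal(nrow(tr), 3)
  expect_equal(frame_rate(tr), 10)
  expect_equal(tr$x, c(0, 1, 2))

  # single missing row is linearly interpolated, length preserved
  write.csv(data.frame(time = c(0, 0.1, 0.2, 0.3, 0.4),
                       x = c(0, NA, 4, 6, 8), y = c(0, NA, 2, 3, 4)),
            f, row.names = FALSE)
  tr <- load_trajectory(f)
  expect_equal(nrow(tr), 5)
  expect_equal(tr$x[2], 2)   # midpoint of 0 and 4
  expect_equal(tr$y[2], 1)
  expect_true(all(tr$valid))

  # a gap longer than max_gap stays invalid and is recorded
  df <- data.frame(time = seq(0, 2.4, by = 0.1), x = 1, y = 1)
  df$x[4:8] <- NA
  write.csv(df, f, row.names = FALSE)
  tr <- load_trajectory(f)
  expect_false(any(tr$valid[4:8]))
  expect_true(all(tr$valid[-(4:8)]))
  expect_length(attr(tr, "gaps"), 1)

  # non-monotone time names the offending row
  write.csv(data.frame(time = c(0, 0.1, 0.2, 0.15, 0.3), x = 0, y = 0),
            f, row.names = FALSE)
  expect_error(load_trajectory(f), "row 4")

  # too many missing coordinates
  df <- data.frame(time = seq(0, 0.9, by = 0.1), x = NA_real_, y = NA_real_)
  df$x[1:7] <- 1; df$y[1:7] <- 1
  write.csv(df, f, row.names = FALSE)
  expect_error(load_trajectory(f), "limit 20%")
})

test_that("event logs require lick/delivery co-occurrence", {
  ok <- event_log(data.frame(time = c(1, 1, 2), kind = c("lick", "water_delivery", "lick"),
                             spout = c(1, 1, 2)))
  expect_s3_class(ok, "nav_events")
  expect_error(
    event_log(data.frame(time = c(1, 5), kind = c("lick", "water_delivery"),
                         spout = c(1, 1))),
    "co-occurring"
  )
  expect_error(
    event_log(data.frame(time = 1, kind = "nibble", spout = 1)),
    "unknown event kind"
  )
})

test_that("behavior resamples exactly onto the neural clock", {
  # 20 Hz behavior at constant velocity -> resampled x is every other sample
  tr <- trajectory(tibble::tibble(time = seq(0, 2, by = 0.05), x = seq(0, 2, by = 0.05) * 4, y = 0),
                   frame_rate = 20)
  traces <- neural_traces(matrix(0, 1, 21), sample_rate = 10)
  al <- align_behavior_to_neural(tr, traces)
  expect_equal(al$frames$x, tr$x[seq(1, 41, by = 2)])
  expect_equal(al$frames$time, traces$time)

  # identical clocks: identity
  tr10 <- trajectory(tibble::tibble(time = traces$time, x = sin(traces$time), y = 0),
                     frame_rate = 10)
  al2 <- align_behavior_to_neural(tr10, traces)
  expect_equal(al2$frames$x, tr10$x)

  # event at t = 1.04 s on a 10 Hz clock snaps to frame 10 (0-based)
  ev <- event_log(data.frame(time = 1.04, kind = "lick", spout = 1))
  al3 <- align_behavior_to_neural(tr10, traces, ev)
  expect_identical(al3$events$frame, 10L)

  # ties round toward the earlier frame
  ev2 <- event_log(data.frame(time = 0.15, kind = "lick", spout = 1))
  al4 <- align_behavior_to_neural(tr10, traces, ev2)
  expect_identical(al4$events$frame, 1L)

  # insufficient overlap is rejected with the fraction
  short <- trajectory(tibble::tibble(time = seq(0, 0.9, by = 0.05), x = 0, y = 0),
                      frame_rate = 20)
  expect_error(align_behavior_to_neural(short, traces), "%")
})

test_that("alignment is idempotent and preserves coinciding samples", {
  ses <- small_session()
  tr <- trajectory(ses$frames[, c("time", "x", "y", "valid")],
                   frame_rate = ses$traces$sample_rate)
  ev <- event_log(as.data.frame(ses$events[, c("time", "kind", "spout")]))
  al <- align_behavior_to_neural(tr, ses$traces, ev)
  expect_equal(al$frames$x, ses$frames$x)
  expect_equal(al$frames$y, ses$frames$y)
})

test_that("results round-trip losslessly through the JSON envelope", {
  ses <- small_session()
  res <- classify_neurons(ses$traces, ses$frames, n_permutations = 50, seed = 2)
  f <- tempfile(fileext = ".json")
  save_results(res, f)
  res2 <- load_results(f)
  for (nm in names(res)) {
    expect_equal(res2[[nm]], res[[nm]], tolerance = NULL, info = nm)
  }
  expect_s3_class(res2, "tuning_result")
  expect_equal(attr(res2, "metadata")$n_permutations,
               attr(res, "metadata")$n_permutations, ignore_attr = TRUE)

  rep <- decoding_report(c("a", "b", "a", "b"), c("a", "b", "b", "b"))
  save_results(rep, f)
  rep2 <- load_results(f)
  expect_equal(rep2$confusion, rep$confusion)
  expect_identical(rep2$accuracy, rep$accuracy)

  # corrupt file errors rather than partially loading
  writeLines("{not json", f)
  expect_error(load_results(f), "corrupt")

  # version mismatch is explicit
  good <- tempfile(fileext = ".json")
  save_results(rep, good)
  env <- jsonlite::read_json(good)
  env$format_version <- "999"
  jsonlite::write_json(env, good, auto_unbox = TRUE)
  expect_error(load_results(good), "version")
})

test_that("session directories round-trip all components", {
  ses <- small_session()
  cfg <- sim_config(seed = 3, n_traversals = 4, n_neurons = 4, n_position = 1,
                    n_path = 1, n_accel = 1, n_conj_accel_position = 0,
                    n_conj_accel_path = 0)
  beh <- simulate_ymaze_session(cfg)
  d <- file.path(tempdir(), "ses-roundtrip")
  write_session(d, traj = beh$traj, events = beh$events, traces = ses$traces,
                geometry = ymaze_geometry(), ground_truth = ses$ground_truth)
  l <- load_session(d)
  expect_equal(l$traj$x, beh$traj$x)
  expect_equal(l$traj$time, beh$traj$time)
  expect_equal(l$events$time, beh$events$time)
  expect_equal(l$traces$mat, ses$traces$mat, ignore_attr = TRUE)
  expect_equal(l$traces$neuron_ids, ses$traces$neuron_ids)
  expect_equal(l$geometry$regions$arm1, ymaze_geometry()$regions$arm1,
               ignore_attr = TRUE)
  expect_equal(l$ground_truth$class, ses$ground_truth$class)
})
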