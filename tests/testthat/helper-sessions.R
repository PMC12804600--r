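# Shared synthetic sessions, memoised so several test files can reuse them
# within one test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

small_session <- function(seed = 3) {
  memo(paste0("small", seed), {
    cfg <- sim_config(
      seed = seed, n_traversals = 20, n_neurons = 24, n_position = 6,
      n_path = 4, n_accel = 4, n_conj_accel_position = 2, n_conj_accel_path = 2
    )
    suppressWarnings(simulate_session(cfg))
  })
}

# session conditions for the decoder evaluations: strong planted coding
# (high gain, fast event rate, low noise), slowed locomotion and long
# dwells so windows rarely straddle a region boundary, and frequent
# arm-3 visits so all four position classes are populated
decoder_session_config <- function(seed, duration = 1500) {
  sim_config(
    seed = seed, duration = duration, p_arm3 = 0.3, tuning_gain = 12,
    noise_sigma = 0.03, n_neurons = 80, n_position = 40, n_path = 10,
    n_accel = 10, n_conj_accel_position = 5, n_conj_accel_path = 5,
    dwell_time = 5, center_speed = 5, vmax_range = c(10, 25),
    baseline_rate = 0.8
  )
}

decoder_session <- function(seed = 31, duration = 1500) {
  memo(paste0("dec", seed, "_", duration),
       suppressWarnings(simulate_session(decoder_session_config(seed, duration))))
}

# trial-rich session for the path transformer
tf_session <- function(seed = 21) {
  memo(paste0("tf", seed), {
    cfg <- sim_config(
      seed = seed, n_traversals = 80, tuning_gain = 8, noise_sigma = 0.05,
      n_neurons = 120, n_position = 30, n_path = 30, n_accel = 20,
      n_conj_accel_position = 5, n_conj_accel_path = 5
    )
    suppressWarnings(simulate_session(cfg))
  })
}

# session in which the only informative neurons are acceleration-tuned
# (conjunctive acceleration x position); short dwells keep acceleration
# episodes inside most decoding windows
ablation_session <- function(seed = 41) {
  memo(paste0("abl", seed), {
    cfg <- sim_config(
      seed = seed, duration = 1200, p_arm3 = 0.3, tuning_gain = 12,
      noise_sigma = 0.05, n_neurons = 60, n_position = 0, n_path = 0,
      n_accel = 0, n_conj_accel_position = 30, n_conj_accel_path = 0,
      dwell_time = 1, center_speed = 5, vmax_range = c(10, 25),
      baseline_rate = 0.8
    )
    suppressWarnings(simulate_session(cfg))
  })
}

# desk-scale decoder configurations (architecture sizes chosen for
# single-CPU test runs; the printed-recipe defaults stay in decoder_config)
tf_desk_cfg <- function(...) {
  decoder_config("path_transformer",
    n_components = 32, d_model = 32, n_heads = 2, n_layers = 2, d_ff = 64,
    d_head_mlp = 32, lr = 1e-3, max_len = 64, epochs = 45, ...
  )
}

pos_desk_cfg <- function(...) {
  decoder_config("position_lstm",
    d_embed = 32, d_hidden = 32, dropout = 0.3, epochs = 35, ...
  )
}

# hand-scripted session on the neural clock with exactly known trial
# endpoints: the mouse dwells at a spout, departs at a known frame at
# constant speed along the arm centerlines, arrives, and repeats.
# Returns the session plus the expected trial table.
scripted_session <- function(n_trials = 6, rate = 10, speed = 20,
                             dwell_frames = 20, geom = ymaze_geometry()) {
  memo(paste0("script", n_trials, rate, speed, dwell_frames), {
    sp <- lapply(geom$spouts, function(p) p * (1 - 1.5 / sqrt(sum(p^2))))
    path12 <- rbind(sp$arm1, c(0, 0), sp$arm2)
    seg <- function(wp) {
      len <- sum(sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2))
      s <- seq(0, len, by = speed / rate)
      cortexnav:::.polyline_point(wp, s)
    }
    xs <- c(); ys <- c(); ev <- list()
    expected <- list()
    cur <- "arm1"
    add_dwell <- function(arm, rewarded) {
      p <- sp[[arm]]
      xs <<- c(xs, rep(p[1], dwell_frames))
      ys <<- c(ys, rep(p[2], dwell_frames))
      t0 <- (length(xs) - dwell_frames) / rate
      ev[[length(ev) + 1]] <<- tibble::tibble(
        time = t0 + 0.2, kind = "lick", spout = as.integer(sub("arm", "", arm))
      )
      if (rewarded) {
        ev[[length(ev) + 1]] <<- tibble::tibble(
          time = t0 + 0.2, kind = "water_delivery",
          spout = as.integer(sub("arm", "", arm))
        )
      }
    }
    add_dwell("arm1", TRUE)
    for (i in seq_len(n_trials)) {
      nxt <- if (cur == "arm1") "arm2" else "arm1"
      depart_frame <- length(xs)              # 0-based frame of first move
      wp <- if (cur == "arm1") path12 else path12[3:1, ]
      p <- seg(wp)
      # the first point duplicates the dwell position; drop it
      p <- p[-1, , drop = FALSE]
      xs <- c(xs, p[, 1]); ys <- c(ys, p[, 2])
      # first frame inside the destination reward zone (distal 5 cm)
      rz <- geom$reward_zones[[nxt]]
      inr <- cortexnav:::.pip(p[, 1], p[, 2], rz)
      arrive_frame <- depart_frame + which(inr)[1] - 1L
      expected[[i]] <- tibble::tibble(
        start_frame = depart_frame, end_frame = arrive_frame,
        direction = sprintf("%s→%s", cur, nxt)
      )
      cur <- nxt
      add_dwell(cur, TRUE)
    }
    n <- length(xs)
    traj <- trajectory(
      tibble::tibble(time = (seq_len(n) - 1) / rate, x = xs, y = ys),
      frame_rate = rate
    )
    events <- event_log(dplyr::bind_rows(ev))
    traces <- neural_traces(matrix(0, 2, n), sample_rate = rate)
    ses <- align_behavior_to_neural(traj, traces, events)
    ses <- annotate_session(ses, geom)
    list(session = ses, expected = dplyr::bind_rows(expected))
  })
}
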