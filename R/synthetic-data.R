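#' @importFrom stats rnorm runif rpois rexp filter
NULL

#' Simulation configuration
#'
#' Bundles every knob of the synthetic session generator. Defaults emulate
#' a trained mouse in the alternating-reward Y-maze under GCaMP6f imaging:
#' 10 Hz neural sampling, 19 frames/s behavior camera, 500 neurons of which
#' 20 are position-tuned, 20 path-tuned, 40 acceleration-tuned, 5
#' conjunctive acceleration-and-position, 5 conjunctive
#' acceleration-and-path and the rest untuned. Peak accelerations are drawn
#' across 5-45 cm/s^2 so both analysis bins ([5,25) and [25,50]) are
#' populated, and speed is re-modulated repeatedly along each traversal so
#' acceleration episodes occur in every maze region rather than only at
#' departure and arrival.
#'
#' @param seed RNG seed recorded in every output.
#' @param duration session length, seconds (ignored when `n_traversals`
#'   is given).
#' @param n_traversals exact number of reward-to-reward traversals, or NULL.
#' @param neural_rate Hz.
#' @param behavior_rate behavior camera frames/s (19 Y-maze, 10 open field).
#' @param n_neurons total neurons.
#' @param n_position,n_path,n_accel,n_conj_accel_position,n_conj_accel_path
#'   planted counts per tuned class; the remainder is untuned.
#' @param tuning_gain multiplicative rate gain when the preferred condition
#'   is active.
#' @param conj_gain_multiplier extra gain factor for conjunctive neurons,
#'   whose preferred conjunction is active in far fewer frames.
#' @param baseline_rate calcium-event rate, events/s.
#' @param calcium_decay_tau exponential decay of the event kernel, s
#'   (0.4 s, GCaMP6f-like).
#' @param noise_sigma additive white noise on dF/F.
#' @param vmax_range cruise-speed draw range, cm/s.
#' @param accel_range peak-acceleration draw range, cm/s^2.
#' @param center_speed speed cap while crossing the maze center, cm/s
#'   (choice-point hesitation).
#' @param dwell_time mean dwell at a spout, s.
#' @param p_arm3 probability a traversal detours into arm 3.
#' @param p_revisit probability of a dry same-spout revisit after a reward.
#' @param licks_per_bout licks per drinking bout.
#' @param jitter_sd lateral centroid jitter, cm.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, duration = 600, n_traversals = NULL,
                       neural_rate = 10, behavior_rate = 19,
                       n_neurons = 500, n_position = 20, n_path = 20,
                       n_accel = 40, n_conj_accel_position = 5,
                       n_conj_accel_path = 5, tuning_gain = 4,
                       conj_gain_multiplier = 3, baseline_rate = 0.2,
                       calcium_decay_tau = 0.4, noise_sigma = 0.1,
                       vmax_range = c(10, 32), accel_range = c(5, 45),
                       center_speed = 7, dwell_time = 2, p_arm3 = 0.1,
                       p_revisit = 0.1, licks_per_bout = 3, jitter_sd = 0.15) {
  cfg <- as.list(environment())
  n_tuned <- n_position + n_path + n_accel + n_conj_accel_position + n_conj_accel_path
  if (n_tuned > n_neurons) rlang::abort("planted counts exceed n_neurons.")
  cfg$n_untuned <- n_neurons - n_tuned
  stopifnot(neural_rate > 0, behavior_rate > 0, baseline_rate >= 0,
            calcium_decay_tau > 0, noise_sigma >= 0)
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(cfg[names(cfg) != "n_untuned"], path)
  invisible(path)
}

# point at arc distance s (vector) along polyline wp
.polyline_point <- function(wp, s) {
  seg <- sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  f <- (s - cs[i]) / seg[i]
  cbind(wp[i, 1] + f * (wp[i + 1, 1] - wp[i, 1]),
        wp[i, 2] + f * (wp[i + 1, 2] - wp[i, 2]))
}

# speed trace covering dist_total; repeated accelerate/hold episodes, a
# slow-down inside `slow_zones` (arc intervals, e.g. the maze center,
# where mice hesitate at the choice point), then a final deceleration
# into the target. Returns arc positions per frame.
.speed_profile <- function(dist_total, dt, cfg, slow_zones = NULL) {
  a_stop <- runif(1, max(15, cfg$accel_range[1]), cfg$accel_range[2])
  target <- runif(1, cfg$vmax_range[1], cfg$vmax_range[2])
  a <- runif(1, cfg$accel_range[1], cfg$accel_range[2])
  in_zone <- function(s) {
    !is.null(slow_zones) && nrow(slow_zones) > 0 &&
      any(s >= slow_zones[, 1] & s <= slow_zones[, 2])
  }
  hold <- 0
  v <- 0
  s <- 0
  out <- numeric(0)
  while (dist_total - s > v^2 / (2 * a_stop) + v * dt) {
    eff <- if (in_zone(s)) min(target, cfg$center_speed) else target
    if (v < eff - 1e-9) {
      v <- min(eff, v + a * dt)
    } else if (v > eff + 1e-9) {
      v <- max(eff, v - a * dt)
    } else if (hold > 0) {
      hold <- hold - dt
    } else {
      target <- runif(1, cfg$vmax_range[1], cfg$vmax_range[2])
      a <- runif(1, cfg$accel_range[1], cfg$accel_range[2])
      hold <- runif(1, 0.2, 0.8)
    }
    s <- s + v * dt
    out <- c(out, s)
    if (length(out) > 1e6) rlang::abort("runaway speed profile.")
  }
  while (v > 0.3) {
    v <- max(0, v - a_stop * dt)
    s <- min(s + v * dt, dist_total)
    out <- c(out, s)
  }
  out
}

# arc intervals of a polyline lying within `radius` of the origin
.center_zones <- function(wp, radius) {
  seg <- sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)
  total <- sum(seg)
  grid <- seq(0, total, by = 0.25)
  p <- .polyline_point(wp, grid)
  inz <- sqrt(p[, 1]^2 + p[, 2]^2) < radius
  if (!any(inz)) return(NULL)
  r <- rle(inz)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  cbind(grid[begins[r$values]], grid[ends[r$values]])
}

.smooth_noise <- function(n, sd, k = 9) {
  if (n == 0) return(numeric(0))
  z <- rnorm(n + 2 * k, 0, sd)
  f <- as.numeric(stats::filter(z, rep(1 / k, k), sides = 2))
  f[(k + 1):(k + n)] * sqrt(k)
}

#' Simulate a Y-maze alternation session
#'
#' Builds a behavioral session for the alternating-reward task: the mouse
#' dwells and licks at a spout, traverses to the opposite reward arm along
#' the arm centerlines with a piecewise-constant-acceleration speed
#' profile, occasionally detours into arm 3 or revisits the same spout (a
#' dry bout), and repeats. Water delivery accompanies licks only on
#' alternation-valid visits, so same-spout licks are dry.
#'
#' @param cfg a [sim_config()].
#' @param geom a [ymaze_geometry()].
#' @return list with `traj` (a [trajectory()]), `events` (an
#'   [event_log()]), and `itinerary` (the scripted traversals:
#'   `from`, `to`, `t_depart`, `t_arrive`, `arm3_detour`).
#' @export
simulate_ymaze_session <- function(cfg = sim_config(), geom = ymaze_geometry()) {
  set.seed(cfg$seed)
  dt <- 1 / cfg$behavior_rate
  sp <- lapply(geom$spouts, function(p) p * (1 - 1.5 / sqrt(sum(p^2)))) # 1.5 cm in
  ctr <- c(0, 0)
  a3dir <- c(cos(pi / 2 - 2 * pi / 3), sin(pi / 2 - 2 * pi / 3))

  xs <- numeric(0); ys <- numeric(0)
  ev <- list()
  itin <- list()
  t_now <- 0
  cur <- 1L # start dwelling at spout 1 (first visit rewarded)
  n_trav <- 0L

  emit_dwell <- function(spout, rewarded) {
    nd <- max(3L, round((cfg$dwell_time + rexp(1, 2)) / dt))
    px <- sp[[paste0("arm", spout)]][1] + .smooth_noise(nd, 0.02)
    py <- sp[[paste0("arm", spout)]][2] + .smooth_noise(nd, 0.02)
    lt <- t_now + seq(0.2, by = 1 / 7, length.out = cfg$licks_per_bout)
    lt <- lt[lt < t_now + nd * dt]
    for (t in lt) {
      ev[[length(ev) + 1]] <<- list(time = t, kind = "lick", spout = spout)
      if (rewarded) {
        ev[[length(ev) + 1]] <<- list(time = t, kind = "water_delivery", spout = spout)
      }
    }
    if (rewarded && length(lt) > 0) {
      ev[[length(ev) + 1]] <<- list(time = lt[1] - 0.05, kind = "ir_trigger", spout = spout)
    }
    xs <<- c(xs, px); ys <<- c(ys, py)
    t_now <<- t_now + nd * dt
  }

  emit_path <- function(wp) {
    zones <- .center_zones(wp, 7)
    s <- .speed_profile(sum(sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)), dt, cfg, zones)
    p <- .polyline_point(wp, s)
    n <- nrow(p)
    # lateral jitter orthogonal to local heading
    hx <- c(diff(p[, 1]), 0); hy <- c(diff(p[, 2]), 0)
    hn <- sqrt(hx^2 + hy^2); hn[hn == 0] <- 1
    j <- .smooth_noise(n, cfg$jitter_sd)
    xs <<- c(xs, p[, 1] - j * hy / hn)
    ys <<- c(ys, p[, 2] + j * hx / hn)
    t_now <<- t_now + n * dt
  }

  done <- function() {
    if (!is.null(cfg$n_traversals)) n_trav >= cfg$n_traversals else t_now >= cfg$duration
  }

  emit_dwell(cur, rewarded = TRUE)
  while (!done()) {
    if (runif(1) < cfg$p_revisit) {            # dry same-spout revisit
      depth <- runif(1, 5, 12)
      a <- sp[[paste0("arm", cur)]]
      inward <- ctr - a
      inward <- inward / sqrt(sum(inward^2))
      emit_path(rbind(a, a + depth * inward, a))
      emit_dwell(cur, rewarded = FALSE)
    }
    nxt <- 3L - cur
    t_dep <- t_now
    detour <- runif(1) < cfg$p_arm3
    wp <- if (detour) {
      d3 <- runif(1, 12, 25)
      rbind(sp[[paste0("arm", cur)]], ctr, ctr + d3 * a3dir, ctr,
            sp[[paste0("arm", nxt)]])
    } else {
      rbind(sp[[paste0("arm", cur)]], ctr, sp[[paste0("arm", nxt)]])
    }
    emit_path(wp)
    itin[[length(itin) + 1]] <- list(
      from = paste0("arm", cur), to = paste0("arm", nxt),
      t_depart = t_dep, t_arrive = t_now, arm3_detour = detour
    )
    n_trav <- n_trav + 1L
    cur <- nxt
    emit_dwell(cur, rewarded = TRUE)
  }
  if (n_trav < 2) rlang::abort("session too short for two traversals; increase duration.")

  traj <- trajectory(
    tibble::tibble(time = (seq_along(xs) - 1) * dt, x = unname(xs), y = unname(ys)),
    frame_rate = cfg$behavior_rate, arena = "ymaze"
  )
  events <- event_log(dplyr::bind_rows(lapply(ev, tibble::as_tibble)))
  list(
    traj = traj, events = events,
    itinerary = dplyr::bind_rows(lapply(itin, tibble::as_tibble)),
    seed = cfg$seed
  )
}

#' Simulate an open-field trajectory
#'
#' Smoothed random walk in a square arena with reflective walls: speed is
#' an Ornstein-Uhlenbeck process, heading a random walk, and an optional
#' thigmotaxis drift biases movement toward the walls so that center
#' entries are occasional rather than constant.
#'
#' @param cfg a [sim_config()] (behavior_rate 10 for the open-field
#'   camera).
#' @param side arena side, cm.
#' @param turning_noise heading random-walk SD, rad per step.
#' @param wall_bias thigmotaxis drift weight (0 disables).
#' @param mean_speed OU mean speed, cm/s.
#' @return a [trajectory()] in arena-centred coordinates.
#' @export
simulate_openfield_trajectory <- function(cfg = sim_config(behavior_rate = 10),
                                          side = 40, turning_noise = 0.4,
                                          wall_bias = 0.1, mean_speed = 8) {
  set.seed(cfg$seed)
  dt <- 1 / cfg$behavior_rate
  n <- round(cfg$duration * cfg$behavior_rate)
  h <- side / 2 - 1e-6
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, -h / 2, h / 2); y[1] <- runif(1, -h / 2, h / 2)
  th <- runif(1, 0, 2 * pi)
  v <- mean_speed
  for (i in 2:n) {
    v <- max(0, v + 0.5 * (mean_speed - v) * dt + rnorm(1, 0, 1.5) * sqrt(dt))
    th <- th + rnorm(1, 0, turning_noise)
    if (wall_bias > 0) {
      r <- sqrt(x[i - 1]^2 + y[i - 1]^2)
      if (r > 1e-6) {
        out_ang <- atan2(y[i - 1], x[i - 1])
        d <- out_ang - th
        th <- th + wall_bias * atan2(sin(d), cos(d)) * (1 - r / h)
      }
    }
    xi <- x[i - 1] + v * cos(th) * dt
    yi <- y[i - 1] + v * sin(th) * dt
    if (xi > h) { xi <- 2 * h - xi; th <- pi - th }
    if (xi < -h) { xi <- -2 * h - xi; th <- pi - th }
    if (yi > h) { yi <- 2 * h - yi; th <- -th }
    if (yi < -h) { yi <- -2 * h - yi; th <- -th }
    x[i] <- xi; y[i] <- yi
  }
  trajectory(tibble::tibble(time = (seq_len(n) - 1) * dt, x = x, y = y),
             frame_rate = cfg$behavior_rate, arena = "open_field")
}

.gt_classes <- function(cfg) {
  c(rep("position", cfg$n_position), rep("path", cfg$n_path),
    rep("acceleration", cfg$n_accel),
    rep("conjunctive_accel_position", cfg$n_conj_accel_position),
    rep("conjunctive_accel_path", cfg$n_conj_accel_path),
    rep("untuned", cfg$n_untuned))
}

#' Plant GCaMP-like traces with known tuning
#'
#' Forward model: each neuron emits calcium events from an inhomogeneous
#' Poisson process with instantaneous rate
#' `baseline_rate * (1 + gain * indicator(preferred condition))`; events
#' are convolved with a causal exponential kernel (decay
#' `calcium_decay_tau`) of unit amplitude and white Gaussian noise
#' (`noise_sigma`) is added. Conjunctive neurons multiply two indicators;
#' untuned neurons run at baseline. Image-plane centroids are drawn
#' uniformly, making the planted functional map salt-and-pepper by
#' construction.
#'
#' Position indicators are absolute maze regions (arm1/center/arm2), path
#' indicators are trial-relative phases (starting/central/terminal), and
#' acceleration indicators the low/high analysis bins, so path and
#' position tuning are dissociable by design in direction-balanced
#' sessions.
#'
#' @param frames aligned frame tibble on the neural clock carrying
#'   `region`, `phase`, and `accel` columns (see [annotate_frames()]).
#' @param cfg a [sim_config()].
#' @return list with `traces` (a [neural_traces()]) and `ground_truth`
#'   (tibble: `neuron_id`, `class`, `preferred`, `gain`, `active`).
#' @export
plant_traces <- function(frames, cfg = sim_config()) {
  set.seed(cfg$seed + 1937L)
  n <- nrow(frames)
  dt <- median(diff(frames$time))
  bins <- bin_acceleration(frames)$accel_bin
  ind_of <- function(class, pref) {
    switch(class,
      position = !is.na(frames$region) & frames$region == pref,
      path = frames$phase == pref,
      acceleration = bins == pref,
      conjunctive_accel_position = {
        p <- strsplit(pref, "&", fixed = TRUE)[[1]]
        bins == p[1] & frames$region == p[2]
      },
      conjunctive_accel_path = {
        p <- strsplit(pref, "&", fixed = TRUE)[[1]]
        bins == p[1] & frames$phase == p[2]
      },
      untuned = rep(FALSE, n)
    )
  }
  classes <- .gt_classes(cfg)
  # conjunctive preferences are drawn among combinations that actually
  # occur often enough in this session to constitute a condition
  conj_pool <- function(class, min_active = 50) {
    parts <- if (class == "conjunctive_accel_position") {
      expand.grid(c("low", "high"), c("arm1", "center", "arm2"))
    } else {
      expand.grid(c("low", "high"), c("starting", "terminal"))
    }
    combos <- paste(parts[, 1], parts[, 2], sep = "&")
    nact <- vapply(combos, function(pf) sum(ind_of(class, pf), na.rm = TRUE), numeric(1))
    pool <- combos[nact >= min_active]
    if (length(pool) == 0) pool <- combos[which.max(nact)]
    pool
  }
  pools <- list(
    conjunctive_accel_position = conj_pool("conjunctive_accel_position"),
    conjunctive_accel_path = conj_pool("conjunctive_accel_path")
  )
  pick <- function(class) {
    switch(class,
      position = sample(c("arm1", "center", "arm2"), 1),
      path = sample(c("starting", "terminal"), 1),
      acceleration = sample(c("low", "high"), 1),
      conjunctive_accel_position = sample(pools[[class]], 1),
      conjunctive_accel_path = sample(pools[[class]], 1),
      untuned = NA_character_
    )
  }
  decay <- exp(-dt / cfg$calcium_decay_tau)
  mat <- matrix(0, nrow = cfg$n_neurons, ncol = n)
  gt <- vector("list", cfg$n_neurons)
  for (i in seq_len(cfg$n_neurons)) {
    cls <- classes[i]
    pref <- pick(cls)
    gain <- if (cls == "untuned") 0 else if (startsWith(cls, "conjunctive")) {
      cfg$tuning_gain * cfg$conj_gain_multiplier
    } else cfg$tuning_gain
    ind <- if (cls == "untuned") rep(FALSE, n) else ind_of(cls, pref)
    ind[is.na(ind)] <- FALSE
    active <- cls == "untuned" || any(ind)
    if (!active) {
      rlang::warn(sprintf("neuron %d: preferred condition '%s' never active.", i, pref))
    }
    # baseline-free limit: a purely conditional responder at `gain` events/s
    rate <- if (cfg$baseline_rate > 0) {
      cfg$baseline_rate * (1 + gain * ind)
    } else {
      gain * ind
    }
    ev <- rpois(n, rate * dt)
    tr <- as.numeric(stats::filter(ev, decay, method = "recursive"))
    if (cfg$noise_sigma > 0) tr <- tr + rnorm(n, 0, cfg$noise_sigma)
    mat[i, ] <- tr
    gt[[i]] <- list(neuron_id = paste0("n", i), class = cls,
                    preferred = pref, gain = gain, active = active)
  }
  ids <- paste0("n", seq_len(cfg$n_neurons))
  centroids <- tibble::tibble(
    neuron_id = ids,
    cx = runif(cfg$n_neurons, 0, 1000),
    cy = runif(cfg$n_neurons, 0, 1000)
  )
  traces <- neural_traces(mat, sample_rate = 1 / dt, time = frames$time,
                          neuron_ids = ids, centroids = centroids)
  list(traces = traces,
       ground_truth = dplyr::bind_rows(lapply(gt, tibble::as_tibble)),
       seed = cfg$seed)
}

#' Annotate aligned frames with kinematics, regions and phases
#'
#' Convenience pipeline used both by the trace-planting forward model and
#' by real-session analysis: computes speed/acceleration, assigns maze
#' regions and zones, extracts navigation trials from the aligned events,
#' and labels trial phases.
#'
#' @param session an `aligned_session`.
#' @param geom a [ymaze_geometry()].
#' @param smooth_window moving-average window in seconds (0 to skip).
#' @return the session with `frames` augmented and a `trials` element.
#' @export
annotate_session <- function(session, geom = ymaze_geometry(), smooth_window = 0) {
  fr <- session$frames
  attr(fr, "frame_rate") <- session$traces$sample_rate
  if (smooth_window > 0) fr <- smooth_centroid(fr, smooth_window)
  fr <- compute_kinematics(fr)
  fr <- assign_regions(fr, geom)
  trials <- extract_navigation_trials(fr, session$events)
  fr <- label_trial_phases(fr, trials)
  session$frames <- fr
  session$trials <- trials
  session$geometry <- geom
  session
}

#' Simulate a complete aligned synthetic session
#'
#' Behavior, events, alignment onto the neural clock, frame annotation and
#' planted traces in one call.
#'
#' @param cfg a [sim_config()].
#' @param geom a [ymaze_geometry()].
#' @return an `aligned_session` with `trials` and `ground_truth`.
#' @export
simulate_session <- function(cfg = sim_config(), geom = ymaze_geometry()) {
  beh <- simulate_ymaze_session(cfg, geom)
  dur <- max(beh$traj$time)
  n_frames <- floor(dur * cfg$neural_rate) + 1
  shell <- neural_traces(matrix(0, 1, n_frames), sample_rate = cfg$neural_rate)
  ses <- align_behavior_to_neural(beh$traj, shell, beh$events)
  ses <- annotate_session(ses, geom)
  bins <- table(bin_acceleration(ses$frames)$accel_bin)
  for (b in c("low", "high")) {
    if (is.na(bins[b]) || bins[b] < 100) {
      rlang::warn(sprintf(
        "only %d frames in the %s-acceleration bin (< 100); consider a longer session.",
        if (is.na(bins[b])) 0L else as.integer(bins[b]), b))
    }
  }
  planted <- plant_traces(ses$frames, cfg)
  ses$traces <- planted$traces
  ses$ground_truth <- planted$ground_truth
  ses$itinerary <- beh$itinerary
  ses$config <- cfg
  ses
}

#' Simulate data under the trajectory encoding model
#'
#' Generates frames exactly under the linear encoding model
#' `x(t) = beta0 + beta1 * Position(t) + beta2 * Acceleration(t) + eps`,
#' with AR(1)-smoothed standard-normal regressor series and Gaussian noise,
#' for ordinary-least-squares recovery checks.
#'
#' @param beta0,beta1,beta2 true coefficients.
#' @param noise_sd SD of eps.
#' @param n_frames series length (>= 10).
#' @param seed RNG seed.
#' @param ar AR(1) coefficient of the regressor series.
#' @return tibble with `t`, `x`, `position`, `acceleration`.
#' @export
simulate_glm_session <- function(beta0, beta1, beta2, noise_sd, n_frames,
                                 seed = 1, ar = 0.9) {
  if (n_frames < 10) rlang::abort("n_frames must be at least 10.")
  set.seed(seed)
  mk <- function() {
    z <- as.numeric(stats::filter(rnorm(n_frames), ar, method = "recursive"))
    as.numeric(scale(z))
  }
  pos <- mk()
  acc <- mk()
  eps <- if (noise_sd > 0) rnorm(n_frames, 0, noise_sd) else 0
  tibble::tibble(
    t = seq_len(n_frames) - 1,
    x = beta0 + beta1 * pos + beta2 * acc + eps,
    position = pos, acceleration = acc
  )
}
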