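#' @importFrom stats quantile median
NULL

.infer_rate <- function(df) {
  fr <- attr(df, "frame_rate")
  if (is.null(fr)) fr <- 1 / median(diff(df$time))
  fr
}

#' Smooth centroid coordinates with a centred moving average
#'
#' Applies a centred moving average of `window` seconds (default 0.5 s) to
#' the x and y columns. Edges use truncated windows; invalid frames are
#' left untouched and do not contribute to their neighbours' averages.
#'
#' @param df trajectory or aligned-frame tibble with `time`, `x`, `y`
#'   (and optionally `valid`).
#' @param window window length in seconds; must span at least 2 frames and
#'   no more than the trajectory.
#' @return the input tibble with smoothed `x`, `y`.
#' @export
smooth_centroid <- function(df, window = 0.5) {
  fr <- .infer_rate(df)
  nw <- window * fr
  if (nw < 2) rlang::abort("smoothing window must span at least 2 frames.")
  if (nw > nrow(df)) rlang::abort("smoothing window longer than the trajectory.")
  k <- floor(nw / 2)
  valid <- if ("valid" %in% names(df)) df$valid else rep(TRUE, nrow(df))
  run <- function(v) {
    v0 <- ifelse(valid, v, 0)
    w0 <- as.numeric(valid)
    cs <- c(0, cumsum(v0))
    cw <- c(0, cumsum(w0))
    n <- length(v)
    i <- seq_len(n)
    lo <- pmax(i - k, 1L)
    hi <- pmin(i + k, n)
    s <- cs[hi + 1] - cs[lo]
    m <- cw[hi + 1] - cw[lo]
    out <- ifelse(m > 0, s / m, NA_real_)
    ifelse(valid, out, v)
  }
  df$x <- run(df$x)
  df$y <- run(df$y)
  df
}

#' Frame-wise speed and signed linear acceleration
#'
#' Speed is the frame-to-frame centroid displacement divided by the frame
#' interval (cm/s). Acceleration is the signed first difference of speed
#' divided by the frame interval (cm/s^2) -- the time derivative of speed,
#' not the magnitude of the 2-D acceleration vector, so decelerations are
#' negative and can be excluded from the acceleration-tuning bins.
#' The first frame has no speed and the first two no acceleration.
#'
#' @param df trajectory tibble (typically after [smooth_centroid()]).
#' @return the tibble with `speed` and `accel` columns added.
#' @export
compute_kinematics <- function(df) {
  n <- nrow(df)
  dt <- diff(df$time)
  step <- sqrt(diff(df$x)^2 + diff(df$y)^2)
  speed <- c(NA_real_, step / dt)
  accel <- c(NA_real_, diff(speed) / dt)
  if ("valid" %in% names(df)) {
    okpair <- c(FALSE, df$valid[-n] & df$valid[-1])
    speed[!okpair] <- NA_real_
    accel <- c(NA_real_, diff(speed) / dt)
  }
  df$speed <- speed
  df$accel <- accel
  df
}

#' Sliding-window tortuosity
#'
#' Momentary tortuosity at frame t is the cumulative path length L(t) over
#' a symmetric window of +/- `half_window` seconds divided by the
#' straight-line (Euclidean) distance D(t) between the window endpoints:
#' T(t) = L(t)/D(t). T is 1 on straight segments and grows with meandering.
#' Frames whose window extends past the recording, contains invalid
#' coordinates, or whose D(t) falls below `d_floor` (out-and-back paths)
#' are undefined (NA) rather than capped.
#'
#' The running summary is the 75th percentile of T over frames whose speed
#' exceeds `speed_threshold`; see [running_speed_threshold()] for deriving
#' that threshold from a set of reference sessions.
#'
#' @param df tibble with `time`, `x`, `y` and (for the summary) `speed`.
#' @param half_window seconds, default 1.25.
#' @param speed_threshold cm/s; `NULL` skips the summary.
#' @param d_floor degeneracy floor for D(t) in cm.
#' @return the tibble with a `tortuosity` column; the summary (or NA, with
#'   attribute `defined = FALSE` when no frame passes the threshold) is in
#'   attribute `tortuosity_summary`.
#' @export
compute_tortuosity <- function(df, half_window = 1.25, speed_threshold = NULL,
                               d_floor = 0.1) {
  fr <- .infer_rate(df)
  w <- round(half_window * fr)
  if (w < 2) rlang::abort("half_window must span at least 2 frames.")
  n <- nrow(df)
  tor <- rep(NA_real_, n)
  if (n >= 2 * w + 1) {
    valid <- if ("valid" %in% names(df)) df$valid else rep(TRUE, n)
    step <- sqrt(diff(df$x)^2 + diff(df$y)^2)
    step_ok <- valid[-n] & valid[-1]
    cumd <- c(0, cumsum(ifelse(step_ok, step, 0)))
    cumbad <- c(0, cumsum(!step_ok))
    idx <- (w + 1):(n - w)
    L <- cumd[idx + w] - cumd[idx - w]              # steps t-w .. t+w-1
    nbad <- cumbad[idx + w] - cumbad[idx - w]
    D <- sqrt((df$x[idx + w] - df$x[idx - w])^2 + (df$y[idx + w] - df$y[idx - w])^2)
    val <- L / D
    val[nbad > 0] <- NA_real_
    val[D < d_floor] <- NA_real_
    tor[idx] <- val
  }
  df$tortuosity <- tor
  summ <- NA_real_
  defined <- FALSE
  if (!is.null(speed_threshold) && "speed" %in% names(df)) {
    run <- !is.na(df$speed) & df$speed > speed_threshold & !is.na(tor)
    if (any(run)) {
      summ <- as.numeric(quantile(tor[run], 0.75))
      defined <- TRUE
    }
  }
  attr(summ, "defined") <- defined
  attr(df, "tortuosity_summary") <- summ
  df
}

#' Running-speed threshold from reference sessions
#'
#' The threshold that defines "running" epochs for the tortuosity summary:
#' the mean of the per-session 75th-percentile speeds across a set of
#' reference recordings.
#'
#' @param kins list of tibbles with a `speed` column.
#' @export
running_speed_threshold <- function(kins) {
  mean(vapply(kins, function(k) as.numeric(quantile(k$speed, 0.75, na.rm = TRUE)),
              numeric(1)))
}

#' Turn angles from three consecutive frames
#'
#' The turn angle at frame t is the unsigned angle in the horizontal plane
#' between the displacement vectors (t-1 -> t) and (t -> t+1), in degrees
#' in [0, 180]: 0 for straight motion, 180 for a full reversal. Steps
#' shorter than `min_step` cm are excluded (NA) so centroid jitter does not
#' dominate the distribution.
#'
#' @param df trajectory tibble.
#' @param min_step minimum displacement per step, cm.
#' @return the tibble with a `turn_angle` column.
#' @export
compute_turn_angles <- function(df, min_step = 0.05) {
  n <- nrow(df)
  dx <- diff(df$x)
  dy <- diff(df$y)
  len <- sqrt(dx^2 + dy^2)
  a <- rep(NA_real_, n)
  if (n >= 3) {
    i <- seq_len(n - 2)               # angle at frame i+1
    dot <- dx[i] * dx[i + 1] + dy[i] * dy[i + 1]
    ok <- len[i] >= min_step & len[i + 1] >= min_step
    costh <- pmin(1, pmax(-1, dot / (len[i] * len[i + 1])))
    ang <- acos(costh) * 180 / pi
    ang[!ok | !is.finite(ang)] <- NA_real_
    a[i + 1] <- ang
  }
  df$turn_angle <- a
  df
}

#' Histogram of turn angles
#'
#' @param df tibble with a `turn_angle` column.
#' @param breaks angular bin edges in degrees.
#' @return tibble with `bin`, `lower`, `upper`, `count`.
#' @export
turn_angle_histogram <- function(df, breaks = seq(0, 180, by = 30)) {
  a <- df$turn_angle[!is.na(df$turn_angle)]
  h <- hist(a, breaks = breaks, plot = FALSE, include.lowest = TRUE, right = FALSE)
  tibble::tibble(
    bin = paste0("[", head(breaks, -1), ",", breaks[-1], ")"),
    lower = head(breaks, -1), upper = breaks[-1], count = h$counts
  )
}

#' Immobility bouts
#'
#' Maximal runs of frames with speed below `threshold` (2 cm/s) lasting at
#' least `min_duration` (1 s), returned as half-open 0-based frame
#' intervals. Frames with undefined speed break runs.
#'
#' @param df tibble with `speed`.
#' @param threshold cm/s.
#' @param min_duration seconds.
#' @return tibble with `start_frame`, `end_frame`, `duration_s`.
#' @export
label_immobility <- function(df, threshold = 2, min_duration = 1) {
  fr <- .infer_rate(df)
  below <- !is.na(df$speed) & df$speed < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / fr >= min_duration - 1e-9)
  tibble::tibble(
    start_frame = starts[keep] - 1L,
    end_frame = ends[keep],            # half-open
    duration_s = r$lengths[keep] / fr
  )
}

#' Assign maze regions and zones per frame
#'
#' Point-in-polygon assignment of every valid frame to a coarse region
#' (arm1/arm2/arm3/center) and, when the geometry defines them, to the
#' five-zone variant and the reward zones. Points on a shared boundary go
#' to the first-listed region; points outside every polygon get region
#' `"none"` and are invalid for region-based statistics.
#'
#' @param df frame tibble with `x`, `y`.
#' @param geom a [maze_geometry()].
#' @return the tibble with `region`, and for Y-maze geometry `zone5`,
#'   `in_reward1`, `in_reward2` columns.
#' @export
assign_regions <- function(df, geom) {
  n <- nrow(df)
  region <- rep("none", n)
  for (nm in names(geom$regions)) {
    hit <- region == "none" & .pip(df$x, df$y, geom$regions[[nm]])
    region[hit] <- nm
  }
  region[!is.finite(df$x)] <- "none"
  df$region <- region
  if (!is.null(geom$zones5)) {
    zone <- rep("none", n)
    for (z in geom$zones5) {
      hit <- zone == "none" & .pip(df$x, df$y, z$poly)
      zone[hit] <- z$zone
    }
    zone[!is.finite(df$x)] <- "none"
    df$zone5 <- zone
  }
  if (!is.null(geom$reward_zones)) {
    df$in_reward1 <- .pip(df$x, df$y, geom$reward_zones$arm1)
    df$in_reward2 <- .pip(df$x, df$y, geom$reward_zones$arm2)
  }
  df
}

#' Extract qualified navigation trials
#'
#' A navigation trial is one traversal between the two reward arms: it
#' starts at the first sustained movement (speed >= `speed_threshold` for
#' `move_sustain` seconds while still in the origin arm) after the previous
#' water delivery, and ends at arrival in the destination reward zone,
#' strictly before that traversal's water delivery. Intervals are 0-based
#' half-open `[start_frame, end_frame)`. A trial is disqualified (but kept,
#' flagged) when more than `arm3_frac` of its frames are in arm 3 or it
#' exceeds `max_duration` seconds.
#'
#' @param df aligned frame tibble with `region`, `speed`, `in_reward1`,
#'   `in_reward2`.
#' @param events event tibble with a `frame` column (from
#'   [align_behavior_to_neural()]).
#' @param speed_threshold movement-initiation speed, cm/s.
#' @param move_sustain seconds of sustained movement defining initiation.
#' @param arm3_frac maximum tolerated fraction of frames in arm 3.
#' @param max_duration maximum trial duration, seconds.
#' @return tibble of trials: `trial_id`, `start_frame`, `end_frame`,
#'   `direction`, `qualified`, `n_frames`, `arm3_fraction`, `duration_s`.
#' @export
extract_navigation_trials <- function(df, events, speed_threshold = 2,
                                      move_sustain = 0.5, arm3_frac = 0.2,
                                      max_duration = 60) {
  fr <- .infer_rate(df)
  k <- max(1L, round(move_sustain * fr))
  wd <- events[events$kind == "water_delivery", , drop = FALSE]
  wd <- wd[order(wd$frame), , drop = FALSE]
  out <- list()
  if (nrow(wd) >= 2) {
    moving <- !is.na(df$speed) & df$speed >= speed_threshold
    for (i in seq_len(nrow(wd) - 1)) {
      s_from <- wd$spout[i]
      s_to <- wd$spout[i + 1]
      if (s_from == s_to) next
      origin <- paste0("arm", s_from)
      dest_rw <- if (s_to == 1) df$in_reward1 else df$in_reward2
      f0 <- wd$frame[i] + 1L          # 0-based; candidate window (f0, f1)
      f1 <- wd$frame[i + 1]
      rows <- (f0 + 1L):(f1 + 1L)     # 1-based rows covering frames f0..f1
      rows <- rows[rows <= nrow(df)]
      start <- NA_integer_
      for (r in rows) {
        hi <- min(r + k - 1L, nrow(df))
        if (hi - r + 1L < k) break
        if (all(moving[r:hi]) && all(df$region[r:hi] == origin)) {
          start <- r - 1L
          break
        }
      }
      if (is.na(start)) next
      arr <- which(dest_rw[(start + 1L):(f1 + 1L)])
      if (length(arr) == 0) next
      end <- start + arr[1] - 1L      # first frame inside dest reward zone
      end <- min(end, f1)             # strictly before the delivery frame
      if (end <= start) next
      seg <- df$region[(start + 1L):end]
      a3 <- mean(seg == "arm3")
      dur <- (end - start) / fr
      out[[length(out) + 1]] <- tibble::tibble(
        start_frame = start, end_frame = end,
        direction = sprintf("arm%d→arm%d", s_from, s_to),
        qualified = a3 <= arm3_frac && dur <= max_duration,
        n_frames = end - start, arm3_fraction = a3, duration_s = dur
      )
    }
  }
  trials <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    start_frame = integer(), end_frame = integer(), direction = character(),
    qualified = logical(), n_frames = integer(), arm3_fraction = numeric(),
    duration_s = numeric()
  )
  trials$trial_id <- seq_len(nrow(trials))
  dplyr::relocate(trials, "trial_id")
}

#' Label trial membership and path phase per frame
#'
#' Path phases are defined relative to the journey, not to absolute space:
#' frames in the origin arm are `starting`, in the center `central`, in the
#' destination arm `terminal`, regardless of which arm the trial departs
#' from. Frames outside any trial (or in arm 3) have phase `none`.
#'
#' @param df aligned frame tibble with `region`.
#' @param trials output of [extract_navigation_trials()].
#' @param qualified_only restrict phase labels to qualified trials.
#' @return the tibble with `trial_id` (NA outside trials) and `phase`.
#' @export
label_trial_phases <- function(df, trials, qualified_only = TRUE) {
  df$trial_id <- NA_integer_
  df$phase <- "none"
  for (i in seq_len(nrow(trials))) {
    if (qualified_only && !trials$qualified[i]) next
    rows <- (trials$start_frame[i] + 1L):trials$end_frame[i]
    df$trial_id[rows] <- trials$trial_id[i]
    origin <- sub("→.*", "", trials$direction[i])
    dest <- sub(".*→", "", trials$direction[i])
    ph <- rep("none", length(rows))
    ph[df$region[rows] == origin] <- "starting"
    ph[df$region[rows] == "center"] <- "central"
    ph[df$region[rows] == dest] <- "terminal"
    df$phase[rows] <- ph
  }
  df
}

#' Learning-curve metrics from the alternating-reward task
#'
#' Computes the session-level spatial-learning metrics: time to complete
#' the first 30 valid licks (licks accompanied by water delivery), the
#' ratio of entries into the reward arms (1 and 2) versus the empty arm
#' (3), and the error-lick rate (dry licks / all licks) within the 30-lick
#' task period. Arm entries are counted on region transitions from the
#' center into an arm.
#'
#' @param events event tibble (aligned, with `frame`, or raw with `time`).
#' @param df aligned frame tibble with `region` (for entry counts).
#' @param n_licks task criterion, default 30.
#' @param tol lick/delivery co-occurrence tolerance, seconds.
#' @return one-row tibble: `time_to_valid_licks`, `reward_arm_entry_ratio`,
#'   `error_lick_rate`, `n_valid_licks`, plus a `defined` flag.
#' @export
learning_metrics <- function(events, df, n_licks = 30, tol = 0.1) {
  licks <- events$time[events$kind == "lick"]
  wd <- events$time[events$kind == "water_delivery"]
  if (length(licks) == 0) rlang::abort("no lick events in the session.")
  valid <- vapply(licks, function(t) any(abs(wd - t) <= tol + 1e-9), logical(1))
  t0 <- df$time[1]
  vt <- licks[valid]
  defined <- length(vt) >= n_licks
  t_end <- if (defined) vt[n_licks] else max(df$time)
  ttl <- if (defined) vt[n_licks] - t0 else NA_real_
  inwin <- licks <= t_end + 1e-9
  err <- if (any(inwin)) mean(!valid[inwin]) else NA_real_
  rows <- df$time <= t_end + 1e-9
  reg <- df$region[rows]
  prev <- c("none", reg[-length(reg)])
  entry <- prev == "center" & reg %in% c("arm1", "arm2", "arm3")
  n_rw <- sum(entry & reg %in% c("arm1", "arm2"))
  n_empty <- sum(entry & reg == "arm3")
  tibble::tibble(
    time_to_valid_licks = ttl,
    reward_arm_entry_ratio = if (n_empty > 0) n_rw / n_empty else Inf,
    error_lick_rate = err,
    n_valid_licks = sum(valid),
    defined = defined
  )
}

#' Open-field session metrics
#'
#' Computes the standard open-field battery over the analysis window
#' (everything after the initial `adaption` seconds, default 30 s):
#' accumulated distance, mean speed, mean signed acceleration, the
#' tortuosity running summary, center entries, the turn-angle histogram
#' and immobility bouts.
#'
#' @param df frame tibble (raw trajectory is smoothed internally).
#' @param geom an [openfield_geometry()].
#' @param adaption seconds discarded at the start.
#' @param speed_threshold running threshold for the tortuosity summary;
#'   defaults to this session's 75th-percentile speed.
#' @param smooth_window moving-average window, seconds.
#' @return one-row tibble of metrics; the turn-angle histogram and
#'   immobility bouts are attached as attributes `turn_histogram` and
#'   `immobility`.
#' @export
openfield_metrics <- function(df, geom = openfield_geometry(), adaption = 30,
                              speed_threshold = NULL, smooth_window = 0.5) {
  if (max(df$time) - df$time[1] <= adaption) {
    rlang::abort("session shorter than the adaption window.")
  }
  fr <- .infer_rate(df)
  win <- df[df$time >= df$time[1] + adaption, , drop = FALSE]
  attr(win, "frame_rate") <- fr
  if (smooth_window > 0) win <- smooth_centroid(win, smooth_window)
  win <- compute_kinematics(win)
  if (is.null(speed_threshold)) {
    speed_threshold <- as.numeric(quantile(win$speed, 0.75, na.rm = TRUE))
  }
  win <- compute_tortuosity(win, speed_threshold = speed_threshold)
  win <- compute_turn_angles(win)
  win <- assign_regions(win, geom)
  step <- sqrt(diff(win$x)^2 + diff(win$y)^2)
  prev <- c("none", win$region[-nrow(win)])
  entries <- sum(prev != "center" & win$region == "center")
  tibble::tibble(
    accumulated_distance = sum(step, na.rm = TRUE),
    mean_speed = mean(win$speed, na.rm = TRUE),
    mean_accel = mean(win$accel, na.rm = TRUE),
    tortuosity_p75 = as.numeric(attr(win, "tortuosity_summary")),
    center_entries = entries,
    n_immobility_bouts = nrow(label_immobility(win))
  ) -> out
  attr(out, "turn_histogram") <- turn_angle_histogram(win)
  attr(out, "immobility") <- label_immobility(win)
  out
}
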