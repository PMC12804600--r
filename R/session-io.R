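#' @import tibble
#' @importFrom rlang abort warn .data
#' @importFrom stats approx
NULL

FORMAT_VERSION <- "1"

#' Construct a trajectory table
#'
#' A trajectory is a tibble with one row per video frame, columns `time`
#' (seconds, strictly increasing), `x`, `y` (cm) and a logical `valid`
#' column marking frames whose coordinates are usable. The camera frame
#' rate and arena identity travel along as attributes.
#'
#' Coordinates are expressed in cm with the origin at the maze/arena
#' centroid and y pointing up. Frames are 0-based; all frame intervals in
#' this package are half-open `[start, end)`.
#'
#' @param df data frame with columns `time`, `x`, `y` (and optionally
#'   `valid`).
#' @param frame_rate frames per second (> 0).
#' @param arena `"ymaze"` or `"open_field"`.
#' @return a `nav_trajectory` tibble.
#' @export
trajectory <- function(df, frame_rate, arena = c("ymaze", "open_field")) {
  arena <- match.arg(arena)
  stopifnot(is.data.frame(df), all(c("time", "x", "y") %in% names(df)))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number.")
  }
  out <- tibble::as_tibble(df[, intersect(c("time", "x", "y", "valid"), names(df))])
  if (!"valid" %in% names(out)) out$valid <- TRUE
  bad <- which(diff(out$time) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("`time` must be strictly increasing; first violation at row %d.", bad[1] + 1))
  }
  if (any(!is.finite(out$time))) abort("non-finite timestamps.")
  if (any(!is.finite(out$x[out$valid])) || any(!is.finite(out$y[out$valid]))) {
    abort("non-finite coordinates on frames marked valid.")
  }
  structure(out,
    class = c("nav_trajectory", class(tibble::tibble())),
    frame_rate = frame_rate, arena = arena
  )
}

#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' Load a trajectory from CSV
#'
#' The file must have columns `time,x,y` (time in seconds) or `frame,x,y`
#' (in which case `frame_rate` is required to reconstruct timestamps).
#' Gaps of up to `max_gap` consecutive missing-coordinate frames are
#' linearly interpolated; longer gaps are kept as invalid frames and
#' recorded in the `gaps` attribute.
#'
#' @param path CSV file path.
#' @param frame_rate frames/s; required when the file has a `frame` column,
#'   otherwise inferred from the median time step if omitted.
#' @param arena arena identity, `"ymaze"` or `"open_field"`.
#' @param max_gap longest run of missing frames that is interpolated.
#' @return a [trajectory()] tibble.
#' @export
load_trajectory <- function(path, frame_rate = NULL, arena = "ymaze", max_gap = 3L) {
  df <- utils::read.csv(path)
  if (!"time" %in% names(df)) {
    if (!"frame" %in% names(df)) abort("file must have a `time` or `frame` column.")
    if (is.null(frame_rate)) abort("`frame_rate` is required for frame-indexed files.")
    df$time <- df$frame / frame_rate
  }
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(df$time))
  miss <- !is.finite(df$x) | !is.finite(df$y)
  if (mean(miss) > 0.2) {
    abort(sprintf("%.0f%% of frames have missing coordinates (limit 20%%).", 100 * mean(miss)))
  }
  df$valid <- !miss
  gaps <- list()
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      if (r$lengths[i] <= max_gap && starts[i] > 1 && ends[i] < nrow(df)) {
        idx <- starts[i]:ends[i]
        ok <- which(df$valid)
        df$x[idx] <- approx(df$time[ok], df$x[ok], xout = df$time[idx])$y
        df$y[idx] <- approx(df$time[ok], df$y[ok], xout = df$time[idx])$y
        df$valid[idx] <- TRUE
      } else {
        gaps[[length(gaps) + 1]] <- c(start = starts[i] - 1L, end = ends[i]) # 0-based half-open
      }
    }
  }
  out <- trajectory(df, frame_rate = frame_rate, arena = arena)
  attr(out, "gaps") <- gaps
  out
}

#' Construct an event log
#'
#' Events are licks, water deliveries and infrared-sensor triggers at the
#' two reward spouts. A water delivery must co-occur with a lick within
#' `tol` seconds (one neural frame by default): under the alternating
#' schedule a "valid lick" is a lick with water delivery and a dry lick is
#' one without.
#'
#' @param df data frame with columns `time`, `kind`
#'   (`lick`/`water_delivery`/`ir_trigger`) and `spout` (1 or 2).
#' @param tol co-occurrence tolerance in seconds.
#' @return a `nav_events` tibble.
#' @export
event_log <- function(df, tol = 0.1) {
  stopifnot(is.data.frame(df), all(c("time", "kind", "spout") %in% names(df)))
  kinds <- c("lick", "water_delivery", "ir_trigger")
  if (!all(df$kind %in% kinds)) abort("unknown event kind.")
  if (!all(df$spout %in% c(1L, 2L))) abort("`spout` must be 1 or 2.")
  out <- tibble::as_tibble(df[order(df$time), c("time", "kind", "spout")])
  wd <- out$time[out$kind == "water_delivery"]
  lk <- out$time[out$kind == "lick"]
  if (length(wd) > 0) {
    orphan <- vapply(wd, function(t) all(abs(lk - t) > tol + 1e-9), logical(1))
    if (any(orphan)) abort("water_delivery without a co-occurring lick.")
  }
  structure(out, class = c("nav_events", class(tibble::tibble())))
}

#' @rdname event_log
#' @param path CSV with columns `time,kind,spout`.
#' @export
load_events <- function(path, tol = 0.1) {
  event_log(utils::read.csv(path), tol = tol)
}

#' Construct a neural trace container
#'
#' Holds the extracted dF/F matrix (neurons x frames) sampled at
#' `sample_rate` Hz, neuron identifiers, and optional per-neuron
#' image-plane centroids (micrometres).
#'
#' @param mat numeric matrix, neurons x frames, all finite.
#' @param sample_rate Hz (nominally 10).
#' @param time optional frame timestamps; defaults to a 0-based regular
#'   clock at `sample_rate`.
#' @param neuron_ids character/integer ids, one per row.
#' @param centroids optional data frame with columns `neuron_id`, `cx`, `cy`.
#' @return a `neural_traces` object.
#' @export
neural_traces <- function(mat, sample_rate = 10, time = NULL, neuron_ids = NULL,
                          centroids = NULL) {
  stopifnot(is.matrix(mat))
  if (any(!is.finite(mat))) abort("trace matrix contains non-finite values.")
  if (is.null(time)) time <- seq(0, by = 1 / sample_rate, length.out = ncol(mat))
  if (length(time) != ncol(mat)) abort("`time` length must match frame count.")
  dur <- diff(range(time)) + 1 / sample_rate
  if (abs(ncol(mat) - sample_rate * dur) > 1 + 1e-6) {
    abort("frame count inconsistent with sample_rate and duration.")
  }
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(mat)))
  if (length(neuron_ids) != nrow(mat)) abort("one id per neuron required.")
  if (!is.null(centroids)) {
    centroids <- tibble::as_tibble(centroids)
    stopifnot(all(c("neuron_id", "cx", "cy") %in% names(centroids)))
  }
  structure(
    list(
      mat = mat, sample_rate = sample_rate, time = as.numeric(time),
      neuron_ids = as.character(neuron_ids), centroids = centroids
    ),
    class = "neural_traces"
  )
}

#' @export
print.neural_traces <- function(x, ...) {
  cat(sprintf(
    "<neural_traces> %d neurons x %d frames @ %g Hz (%.1f s)%s\n",
    nrow(x$mat), ncol(x$mat), x$sample_rate, diff(range(x$time)),
    if (is.null(x$centroids)) "" else ", with centroids"
  ))
  invisible(x)
}

#' @export
dim.neural_traces <- function(x) dim(x$mat)

# nearest neural frame (0-based); ties go to the earlier frame
.nearest_frame <- function(t, clock) {
  vapply(t, function(ti) which.min(abs(clock - ti)) - 1L, integer(1))
}

#' Align behavior onto the neural clock
#'
#' Resamples the behavioral trajectory by linear interpolation onto the
#' neural frame timestamps, snaps events to the nearest neural frame (ties
#' toward the earlier frame), and flags neural frames outside behavioral
#' support as invalid. The result carries one behavioral sample per neural
#' frame, so all downstream statistics live on a single clock.
#'
#' Aligning an already aligned session is the identity.
#'
#' @param traj a [trajectory()].
#' @param traces a [neural_traces()].
#' @param events a [event_log()] (optional).
#' @param min_overlap minimum fraction of the neural duration covered by
#'   behavior (default 0.95).
#' @return an `aligned_session` list with elements `frames` (tibble:
#'   `frame`, `time`, `x`, `y`, `valid`), `traces`, and `events` (with a
#'   0-based `frame` column).
#' @export
align_behavior_to_neural <- function(traj, traces, events = NULL, min_overlap = 0.95) {
  stopifnot(inherits(traj, "nav_trajectory"), inherits(traces, "neural_traces"))
  tn <- traces$time
  lo <- min(traj$time)
  hi <- max(traj$time)
  ov <- sum(tn >= lo - 1e-9 & tn <= hi + 1e-9) / length(tn)
  if (ov < min_overlap) {
    abort(sprintf("behavior covers only %.1f%% of the neural clock (need %.0f%%).",
                  100 * ov, 100 * min_overlap))
  }
  ok <- which(traj$valid)
  x <- approx(traj$time[ok], traj$x[ok], xout = tn, rule = 1)$y
  y <- approx(traj$time[ok], traj$y[ok], xout = tn, rule = 1)$y
  valid <- is.finite(x) & is.finite(y)
  frames <- tibble::tibble(
    frame = seq_along(tn) - 1L, time = tn,
    x = ifelse(valid, x, NA_real_), y = ifelse(valid, y, NA_real_),
    valid = valid
  )
  ev <- NULL
  if (!is.null(events)) {
    stopifnot(inherits(events, "nav_events"))
    ev <- tibble::as_tibble(events)
    ev$frame <- .nearest_frame(ev$time, tn)
  }
  structure(
    list(frames = frames, traces = traces, events = ev,
         behavior_rate = frame_rate(traj), arena = attr(traj, "arena")),
    class = "aligned_session"
  )
}

#' @export
print.aligned_session <- function(x, ...) {
  cat(sprintf(
    "<aligned_session> %s: %d neural frames @ %g Hz, %d neurons, %d events\n",
    x$arena, nrow(x$frames), x$traces$sample_rate, nrow(x$traces$mat),
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  invisible(x)
}

## ---- result persistence -----------------------------------------------

# Serialisable payloads: numbers go through jsonlite with 17 significant
# digits so the decimal representation round-trips IEEE doubles exactly;
# matrices as row lists.

.strip <- function(x) {
  if (is.matrix(x)) {
    list(.matrix = TRUE, nrow = nrow(x), data = as.numeric(t(x)),
         rownames = rownames(x), colnames = colnames(x),
         dimnames_names = names(dimnames(x)))
  } else if (is.data.frame(x)) {
    list(.df = TRUE, data = lapply(as.list(x), .strip))
  } else if (is.list(x)) {
    lapply(x, .strip)
  } else if (is.factor(x)) {
    list(.factor = TRUE, levels = levels(x), codes = as.integer(x))
  } else {
    x
  }
}

.unstrip <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- matrix(as.numeric(x$data), nrow = x$nrow, byrow = TRUE)
    rownames(m) <- unlist(x$rownames)
    colnames(m) <- unlist(x$colnames)
    if (!is.null(x$dimnames_names) && !is.null(dimnames(m))) {
      names(dimnames(m)) <- unlist(x$dimnames_names)
    }
    m
  } else if (is.list(x) && isTRUE(x$.df)) {
    tibble::as_tibble(lapply(x$data, .unstrip))
  } else if (is.list(x) && isTRUE(x$.factor)) {
    factor(unlist(x$levels)[x$codes], levels = unlist(x$levels))
  } else if (is.list(x)) {
    lapply(x, .unstrip)
  } else {
    x
  }
}

#' Save and reload analysis results
#'
#' Any result object in this package (tuning tables, d-prime tables, GLM
#' fits, decoding reports, ...) round-trips losslessly through a versioned
#' JSON envelope. Loading a file written by an incompatible format version,
#' or a corrupt file, raises an error rather than returning a partial
#' object.
#'
#' @param x result object.
#' @param path destination file (conventionally `.json`).
#' @export
save_results <- function(x, path) {
  env <- list(
    format_version = FORMAT_VERSION,
    class = class(x),
    attributes = .strip(attributes(x)[setdiff(names(attributes(x)),
                                              c("names", "row.names", "class"))]),
    payload = .strip(unclass(x))
  )
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  env <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort(sprintf("corrupt results file: %s", conditionMessage(e))))
  if (!identical(env$format_version, FORMAT_VERSION)) {
    abort(sprintf("results format version %s; this build reads version %s.",
                  env$format_version %||% "<missing>", FORMAT_VERSION))
  }
  obj <- .unstrip(.simplify_payload(env$payload))
  cls <- unlist(env$class)
  if (any(cls == "data.frame") || any(cls == "tbl_df")) obj <- tibble::as_tibble(obj)
  for (nm in names(env$attributes)) {
    attr(obj, nm) <- .unstrip(.simplify_payload(env$attributes[[nm]]))
  }
  class(obj) <- cls
  obj
}

# collapse length-1-scalar lists back to atomic vectors where homogeneous
.simplify_payload <- function(x) {
  if (!is.list(x)) return(x)
  if (any(names(x) %in% c(".matrix", ".df", ".factor"))) {
    return(lapply(x, .simplify_payload))
  }
  x <- lapply(x, .simplify_payload)
  atom <- all(vapply(x, function(e) is.atomic(e) && length(e) == 1 || is.null(e), logical(1)))
  if (atom && length(x) > 0 && is.null(names(x))) {
    x <- unlist(lapply(x, function(e) if (is.null(e)) NA else e))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- session directories ----------------------------------------------

#' Write / read a complete session directory
#'
#' A session directory holds `trajectory.csv`, `events.csv`, `traces.csv`
#' (frames x neurons with a leading `time` column), optional
#' `centroids.csv`, `geometry.json`, and for synthetic sessions
#' `ground_truth.csv`.
#'
#' @param traj,events,traces,geometry session components; any may be NULL.
#' @param ground_truth optional planted-tuning table.
#' @param dir directory (created if missing).
#' @export
write_session <- function(dir, traj = NULL, events = NULL, traces = NULL,
                          geometry = NULL, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) if (is.numeric(col)) sprintf("%.17g", col) else col)
    df
  }
  if (!is.null(traj)) {
    utils::write.csv(fmt(as.data.frame(traj)), file.path(dir, "trajectory.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(frame_rate = frame_rate(traj), arena = attr(traj, "arena")),
      file.path(dir, "trajectory_meta.json"), auto_unbox = TRUE, digits = I(17)
    )
  }
  if (!is.null(events)) {
    utils::write.csv(fmt(as.data.frame(events)), file.path(dir, "events.csv"), row.names = FALSE)
  }
  if (!is.null(traces)) {
    df <- as.data.frame(t(traces$mat))
    names(df) <- traces$neuron_ids
    df <- cbind(time = traces$time, df)
    utils::write.csv(fmt(df), file.path(dir, "traces.csv"), row.names = FALSE)
    jsonlite::write_json(list(sample_rate = traces$sample_rate),
                         file.path(dir, "traces_meta.json"), auto_unbox = TRUE, digits = I(17))
    if (!is.null(traces$centroids)) {
      utils::write.csv(fmt(as.data.frame(traces$centroids)),
                       file.path(dir, "centroids.csv"), row.names = FALSE)
    }
  }
  if (!is.null(geometry)) write_geometry(geometry, file.path(dir, "geometry.json"))
  if (!is.null(ground_truth)) {
    utils::write.csv(as.data.frame(ground_truth), file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
load_session <- function(dir) {
  out <- list()
  tp <- file.path(dir, "trajectory.csv")
  if (file.exists(tp)) {
    meta <- jsonlite::read_json(file.path(dir, "trajectory_meta.json"))
    out$traj <- load_trajectory(tp, frame_rate = meta$frame_rate, arena = meta$arena)
  }
  ep <- file.path(dir, "events.csv")
  if (file.exists(ep)) out$events <- load_events(ep)
  xp <- file.path(dir, "traces.csv")
  if (file.exists(xp)) {
    df <- utils::read.csv(xp, check.names = FALSE)
    meta <- jsonlite::read_json(file.path(dir, "traces_meta.json"))
    cen <- NULL
    cp <- file.path(dir, "centroids.csv")
    if (file.exists(cp)) cen <- utils::read.csv(cp)
    out$traces <- neural_traces(
      t(as.matrix(df[, -1, drop = FALSE])),
      sample_rate = meta$sample_rate, time = df$time,
      neuron_ids = names(df)[-1], centroids = cen
    )
  }
  gp <- file.path(dir, "geometry.json")
  if (file.exists(gp)) out$geometry <- load_geometry(gp)
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$ground_truth <- tibble::as_tibble(utils::read.csv(gt))
  out
}
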