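#' @importFrom stats lm coef var
NULL

#' Location-matched d-prime between acceleration states
#'
#' For every neuron and every matched spatial region, frames within the
#' region are split by the acceleration bins into a high group
#' ([25, 50] cm/s^2) and a low group ([5, 25)), and the discriminability
#' is `d' = (mu_high - mu_low) / sqrt(0.5 * (var_high + var_low))` with
#' unbiased (n-1) variances. Because both groups come from the same
#' region, a nonzero d' cannot be explained by position coding.
#'
#' Regions with fewer than `min_frames` frames in either group are skipped
#' with a warning. When both variances are zero: d' is 0 if the means are
#' equal, and a signed infinite-separation sentinel (`Inf`/`-Inf`, flagged
#' in `degenerate`) otherwise.
#'
#' @param traces a [neural_traces()].
#' @param frames annotated frame tibble (`region`, `accel`).
#' @param regions matched spatial regions (default arms 1 and 2).
#' @param min_frames minimum frames per group per region.
#' @param unit `"frame"` (default) treats each frame within the region as
#'   one response sample; `"trial"` averages within `trial_id` first.
#' @return a `dprime_result` tibble: one row per neuron x region with
#'   group moments, counts and `d_prime`.
#' @export
compute_dprime <- function(traces, frames, regions = c("arm1", "arm2"),
                           min_frames = 20, unit = c("frame", "trial")) {
  unit <- match.arg(unit)
  stopifnot(nrow(frames) == ncol(traces$mat))
  fr <- bin_acceleration(frames)
  rows <- list()
  for (rg in regions) {
    hi <- which(fr$region == rg & fr$accel_bin == "high")
    lo <- which(fr$region == rg & fr$accel_bin == "low")
    if (unit == "trial") {
      grp <- function(idx) {
        tid <- fr$trial_id[idx]
        keep <- !is.na(tid)
        split(idx[keep], tid[keep])
      }
      ghi <- grp(hi)
      glo <- grp(lo)
      if (length(ghi) < 2 || length(glo) < 2) {
        rlang::warn(sprintf("region %s: too few trials for trial-unit d'; skipped.", rg))
        next
      }
      resp <- function(groups, tr) vapply(groups, function(ix) mean(tr[ix]), numeric(1))
      for (i in seq_len(nrow(traces$mat))) {
        tr <- traces$mat[i, ]
        rows[[length(rows) + 1]] <- .dprime_row(traces$neuron_ids[i], rg,
                                                resp(ghi, tr), resp(glo, tr))
      }
    } else {
      if (length(hi) < min_frames || length(lo) < min_frames) {
        rlang::warn(sprintf(
          "region %s: %d high / %d low frames (< %d); skipped.",
          rg, length(hi), length(lo), min_frames))
        next
      }
      for (i in seq_len(nrow(traces$mat))) {
        tr <- traces$mat[i, ]
        rows[[length(rows) + 1]] <- .dprime_row(traces$neuron_ids[i], rg,
                                                tr[hi], tr[lo])
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  structure(out, class = c("dprime_result", class(tibble::tibble())),
            metadata = list(regions = regions, min_frames = min_frames, unit = unit))
}

.dprime_row <- function(id, region, x_high, x_low) {
  mu_h <- mean(x_high); mu_l <- mean(x_low)
  v_h <- var(x_high); v_l <- var(x_low)
  pooled <- 0.5 * (v_h + v_l)
  degenerate <- FALSE
  if (pooled == 0) {
    d <- if (mu_h == mu_l) 0 else sign(mu_h - mu_l) * Inf
    degenerate <- !is.finite(d)
  } else {
    d <- (mu_h - mu_l) / sqrt(pooled)
  }
  tibble::tibble(
    neuron_id = id, region = region,
    mu_high = mu_h, mu_low = mu_l, var_high = v_h, var_low = v_l,
    n_high = length(x_high), n_low = length(x_low),
    d_prime = d, degenerate = degenerate
  )
}

#' d-prime from precomputed group moments
#'
#' Direct evaluation of the discriminability formula from group means and
#' variances -- handy for closed-form checks and for summarising published
#' moments.
#'
#' @param mu_high,mu_low group means.
#' @param var_high,var_low group variances.
#' @export
dprime_value <- function(mu_high, mu_low, var_high, var_low) {
  pooled <- 0.5 * (var_high + var_low)
  ifelse(pooled == 0,
         ifelse(mu_high == mu_low, 0, sign(mu_high - mu_low) * Inf),
         (mu_high - mu_low) / sqrt(pooled))
}

#' Population regressors from tuned neuron classes
#'
#' Collapses each flagged neuron class into one scalar time series: the
#' z-scored mean dF/F across the class's neurons per frame (recorded in
#' the output metadata, since the mapping from neuron sets to regressors
#' is a modelling choice).
#'
#' @param traces a [neural_traces()].
#' @param tuning a `tuning_result` with flag columns.
#' @return tibble with `position` and `acceleration` regressor columns.
#' @export
build_population_regressors <- function(traces, tuning) {
  reg <- function(flag_col) {
    ids <- tuning$neuron_id[!is.na(tuning[[flag_col]]) & tuning[[flag_col]]]
    if (length(ids) == 0) {
      rlang::abort(sprintf(
        "no neurons flagged in %s; for synthetic sessions increase the planted gain.",
        flag_col))
    }
    m <- traces$mat[traces$neuron_ids %in% ids, , drop = FALSE]
    as.numeric(scale(colMeans(m)))
  }
  out <- tibble::tibble(
    position = reg("is_position_tuned"),
    acceleration = reg("is_acceleration_tuned")
  )
  attr(out, "metadata") <- list(mapping = "z-scored class-mean trace")
  out
}

#' Fit the trajectory encoding model
#'
#' Ordinary least squares for
#' `x(t) = beta0 + beta1 * Position(t) + beta2 * Acceleration(t) + eps`,
#' where the regressors are the population series from
#' [build_population_regressors()] (or any pair of frame series). Refuses
#' collinear designs (condition number above `max_kappa`).
#'
#' @param x trajectory x-coordinate series (cm).
#' @param position,acceleration regressor series.
#' @param max_kappa condition-number threshold for the design matrix.
#' @return a `glm_fit` object (see [tidy()] / [glance()] methods).
#' @export
fit_trajectory_glm <- function(x, position, acceleration, max_kappa = 1e6) {
  ok <- is.finite(x) & is.finite(position) & is.finite(acceleration)
  if (sum(ok) < 10) rlang::abort("need at least 10 valid frames.")
  X <- cbind(1, position[ok], acceleration[ok])
  kp <- kappa(X, exact = TRUE)
  if (kp > max_kappa) {
    rlang::abort(sprintf("collinear regressors (condition number %.3g).", kp))
  }
  df <- data.frame(x = x[ok], position = position[ok], acceleration = acceleration[ok])
  fit <- lm(x ~ position + acceleration, data = df)
  sm <- summary(fit)
  structure(
    list(
      beta = stats::setNames(as.numeric(coef(fit)), c("beta0", "beta1", "beta2")),
      se = stats::setNames(as.numeric(sm$coefficients[, 2]), c("beta0", "beta1", "beta2")),
      sigma2 = sm$sigma^2, r_squared = sm$r.squared, n = sum(ok),
      kappa = kp, lm = fit
    ),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf(
    "<glm_fit> n=%d  beta0=%.4g  beta1=%.4g  beta2=%.4g  R^2=%.3f\n",
    x$n, x$beta[1], x$beta[2], x$beta[3], x$r_squared
  ))
  invisible(x)
}

#' Decoding contribution of tuned subsets by remove-and-retrain ablation
#'
#' Retrains the specified decoder from scratch with each tuned-neuron
#' class removed before dimensionality reduction (removal + retrain, not
#' input zeroing, because PCA mixing makes zeroing ill-defined), together
#' with a size-matched random-removal control per class, and reports the
#' metric change versus the full model averaged over seeds.
#'
#' @param session annotated `aligned_session`.
#' @param tuning a `tuning_result` (statistical or
#'   [tuning_from_ground_truth()]).
#' @param decoder decoder kind (default `"position_lstm"`).
#' @param cfg optional [decoder_config()] override.
#' @param seeds integer vector; each seed retrains every condition.
#' @param classes tuned classes to ablate.
#' @return an `ablation_report` tibble: condition x seed metrics with
#'   `delta_accuracy` relative to the same-seed full model.
#' @export
ablation_contribution <- function(session, tuning, decoder = "position_lstm",
                                  cfg = NULL, seeds = 1:5,
                                  classes = c("acceleration", "position", "path")) {
  all_ids <- session$traces$neuron_ids
  rows <- list()
  for (seed in seeds) {
    full <- .train_decoder(session, decoder, cfg, neurons = NULL, seed = seed)
    rows[[length(rows) + 1]] <- .ablation_row("full", seed, 0L, full$report)
    set.seed(seed + 90001L)
    for (cl in classes) {
      flag <- tuning[[paste0("is_", cl, "_tuned")]]
      drop_ids <- tuning$neuron_id[!is.na(flag) & flag]
      if (length(drop_ids) == 0) next
      if (length(drop_ids) >= length(all_ids)) {
        rlang::abort("ablation would remove the entire population.")
      }
      keep <- setdiff(all_ids, drop_ids)
      rep_t <- .train_decoder(session, decoder, cfg, neurons = keep, seed = seed)
      rows[[length(rows) + 1]] <- .ablation_row(paste0("drop_", cl, "_tuned"),
                                                seed, length(drop_ids), rep_t$report,
                                                full$report)
      rnd <- sample(all_ids, length(drop_ids))
      rep_r <- .train_decoder(session, decoder, cfg,
                              neurons = setdiff(all_ids, rnd), seed = seed)
      rows[[length(rows) + 1]] <- .ablation_row(paste0("drop_random_matched_", cl),
                                                seed, length(rnd), rep_r$report,
                                                full$report)
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ablation_report", class(tibble::tibble())),
            metadata = list(decoder = decoder, seeds = seeds))
}

.ablation_row <- function(condition, seed, n_dropped, report, full = NULL) {
  tibble::tibble(
    condition = condition, seed = seed, n_dropped = n_dropped,
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, f1 = report$f1,
    delta_accuracy = if (is.null(full)) 0 else report$accuracy - full$accuracy
  )
}

#' Lick-period removal control
#'
#' Tests whether decoding rests on reward-consumption behavior rather than
#' position coding: all neural frames within `pad` seconds of any lick are
#' removed from training and evaluation windows, the decoder is retrained
#' with the identical seed, and the paired accuracy change is reported per
#' seed.
#'
#' @param session annotated `aligned_session` with lick events.
#' @param decoder decoder kind.
#' @param cfg optional [decoder_config()].
#' @param seeds paired seeds.
#' @param pad removal pad around each lick, seconds.
#' @return tibble: seed, accuracy with/without lick frames,
#'   `delta_accuracy`, `n_frames_removed`.
#' @export
lick_removal_control <- function(session, decoder = "position_lstm", cfg = NULL,
                                 seeds = 1:5, pad = 0.5) {
  excl <- lick_frames(session, pad)
  rows <- lapply(seeds, function(seed) {
    with_l <- .train_decoder(session, decoder, cfg, seed = seed)
    without <- .train_decoder(session, decoder, cfg, seed = seed,
                              exclude_frames = excl)
    tibble::tibble(
      seed = seed,
      accuracy_with = with_l$report$accuracy,
      accuracy_without = without$report$accuracy,
      delta_accuracy = without$report$accuracy - with_l$report$accuracy,
      n_frames_removed = length(excl)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pad") <- pad
  out
}

#' Frames removed by a lick pad
#'
#' @param session aligned session.
#' @param pad seconds around each lick (0 removes exactly the lick frames).
#' @return 0-based frame indices.
#' @export
lick_frames <- function(session, pad = 0.5) {
  ev <- session$events
  licks <- ev[ev$kind == "lick", , drop = FALSE]
  if (nrow(licks) == 0) rlang::abort("session has no lick events.")
  tn <- session$frames$time
  near <- rep(FALSE, length(tn))
  for (t in licks$time) near <- near | (tn >= t - pad - 1e-9 & tn <= t + pad + 1e-9)
  sort(unique(c(session$frames$frame[near], licks$frame)))
}
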