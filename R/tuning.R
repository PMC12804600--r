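#' @importFrom stats fft wilcox.test
NULL

#' Bin signed acceleration into the two analysis categories
#'
#' Frames are categorised as `low` ([5, 25) cm/s^2) or `high`
#' ([25, 50] cm/s^2); all other frames -- decelerations (negative), very
#' low accelerations below 5 cm/s^2, values above 50, and frames with
#' undefined acceleration -- are `excluded`. The bin boundary at 25 belongs
#' to `high` (half-open convention: the printed integer bins would
#' otherwise leave (24, 25) unassigned for continuous accelerations).
#'
#' @param df frame tibble with an `accel` column (cm/s^2).
#' @param low,high bin edges.
#' @return the tibble with an `accel_bin` column
#'   (`low`/`high`/`excluded`).
#' @export
bin_acceleration <- function(df, low = c(5, 25), high = c(25, 50)) {
  a <- df$accel
  bin <- rep("excluded", nrow(df))
  bin[!is.na(a) & a >= low[1] & a < low[2]] <- "low"
  bin[!is.na(a) & a >= high[1] & a <= high[2]] <- "high"
  df$accel_bin <- bin
  df
}

# circular cross-correlation: for each shift s, sum_t I[t] * z[t+s mod T]
.circ_xcorr <- function(fz, fI, T) {
  Re(fft(fz * Conj(fI), inverse = TRUE)) / T
}

# per-indicator windowed sums of the trace for every circular shift
.shift_sums <- function(trace, label_ffts) {
  T <- length(trace)
  fz <- fft(trace)
  lapply(label_ffts$conds, function(cc) .circ_xcorr(fz, cc$f, T))
}

# FFTs of indicator vectors; `inds` is a named list of logical vectors
.ind_ffts <- function(inds) {
  list(conds = lapply(inds, function(I) {
    I <- as.numeric(I %in% TRUE)
    list(f = fft(I), n = sum(I))
  }), T = length(inds[[1]]))
}

.label_ffts <- function(labels, conditions) {
  .ind_ffts(stats::setNames(
    lapply(conditions, function(k) !is.na(labels) & labels == k), conditions))
}

# default reference set: every other condition ("one vs rest")
.default_refs <- function(conds) {
  stats::setNames(lapply(conds, function(k) setdiff(conds, k)), conds)
}

# turn (condition, reference-set) pairs into mean-contrast weight vectors:
# +1 on the condition mean, pooled-mean weights on the references
.refs_to_contrasts <- function(references, ns) {
  out <- list()
  for (k in names(references)) {
    refs <- references[[k]]
    ntot <- sum(ns[refs])
    if (ntot == 0) next
    w <- c(1, -ns[refs] / ntot)
    names(w) <- c(k, refs)
    out[[k]] <- w
  }
  out
}

#' Permutation test of condition tuning for one trace
#'
#' The tuning statistic for condition k is the mean dF/F over frames in k
#' minus the mean over its reference frames (by default all other labeled
#' frames; pass `references` for contrast-controlled comparisons, e.g.
#' arm 1 against arm 2 only). The null is built by
#' circularly shifting the trace relative to the labels by a uniform
#' random offset of at least `min_shift` seconds (which preserves the
#' calcium autocorrelation while destroying the behavioral alignment); the
#' one-sided p for each condition is `(1 + #{null >= observed}) /
#' (1 + n_permutations)`. A neuron is flagged when its combined p -- the
#' minimum over conditions, Sidak-adjusted for the number of conditions
#' tested so the neuron-level false-positive rate stays at `alpha` -- falls
#' below `alpha` ("responds to one or more conditions"). The preferred
#' condition is the largest statistic among individually significant
#' conditions.
#'
#' @param trace numeric dF/F vector.
#' @param labels character vector, NA = unlabeled frame.
#' @param n_permutations null draws (default 1000).
#' @param seed RNG seed.
#' @param min_shift minimum circular shift, seconds.
#' @param sample_rate Hz.
#' @param alpha significance level.
#' @param min_frames conditions with fewer labeled frames are skipped.
#' @param references named list mapping each condition to the conditions
#'   whose pooled frames form its comparison group; default one-vs-rest.
#' @param correction `"sidak"` (default) or `"none"` for the combined p.
#' @param backend `"circshift"` (default) or `"ranksum"` (frame-wise
#'   Wilcoxon rank-sum, ignores autocorrelation; comparison backend).
#' @return list: `p` (named per-condition), `statistic`, `p_combined`,
#'   `significant`, `preferred`, `tested`.
#' @export
test_condition_tuning <- function(trace, labels, n_permutations = 1000, seed = 1,
                                  min_shift = 5, sample_rate = 10, alpha = 0.05,
                                  min_frames = 20, references = NULL,
                                  correction = c("sidak", "none"),
                                  backend = c("circshift", "ranksum")) {
  correction <- match.arg(correction)
  backend <- match.arg(backend)
  conds <- sort(unique(labels[!is.na(labels)]))
  if (is.null(references)) references <- .default_refs(conds)
  lf <- .label_ffts(labels, conds)
  ns <- vapply(lf$conds, `[[`, numeric(1), "n")
  contrasts <- .refs_to_contrasts(references, ns)
  inds <- stats::setNames(
    lapply(conds, function(k) !is.na(labels) & labels == k), conds)
  res <- .test_tuning_core(trace, lf, contrasts, n_permutations, seed, min_shift,
                           sample_rate, min_frames, correction, backend, inds)
  res$significant <- !is.na(res$p_combined) && res$p_combined < alpha
  res$preferred <- .preferred_condition(res, alpha)
  res
}

.preferred_condition <- function(res, alpha) {
  sig <- names(res$p)[!is.na(res$p) & res$p < alpha]
  if (length(sig) == 0) return(NA_character_)
  sig[which.max(res$statistic[sig])]
}

# core shared with classify_neurons (indicator FFTs precomputed once).
# contrasts: named list of weight vectors over indicator means; the
# statistic for contrast k is sum_j w_j * mean_j (positive weights are the
# condition side, negative the comparison side). `inds` (named list of
# logical vectors) is only needed by the rank-sum backend.
.test_tuning_core <- function(trace, lf, contrasts, n_permutations, seed,
                              min_shift, sample_rate, min_frames, correction,
                              backend, inds = NULL) {
  ns <- vapply(lf$conds, `[[`, numeric(1), "n")
  ck <- names(contrasts)
  nplus <- vapply(contrasts, function(w) sum(ns[names(w)[w > 0]]), numeric(1))
  nminus <- vapply(contrasts, function(w) sum(ns[names(w)[w < 0]]), numeric(1))
  tested <- ck[nplus >= min_frames & nminus >= min_frames]
  p <- stats::setNames(rep(NA_real_, length(ck)), ck)
  stat <- stats::setNames(rep(NA_real_, length(ck)), ck)
  if (length(tested) == 0) {
    return(list(p = p, statistic = stat, p_combined = NA_real_, tested = tested))
  }
  if (backend == "ranksum") {
    for (k in tested) {
      w <- contrasts[[k]]
      ink <- Reduce(`|`, inds[names(w)[w > 0]])
      oth <- Reduce(`|`, inds[names(w)[w < 0]])
      stat[k] <- mean(trace[ink]) - mean(trace[oth])
      p[k] <- wilcox.test(trace[ink], trace[oth], alternative = "greater",
                          exact = FALSE)$p.value
    }
  } else {
    T <- lf$T
    smin <- ceiling(min_shift * sample_rate)
    if (T - 2 * smin < n_permutations / 10) {
      rlang::abort("session too short for the requested minimum shift.")
    }
    sums <- .shift_sums(trace, lf)
    set.seed(seed)
    shifts <- sample.int(T - 2 * smin, n_permutations, replace = TRUE) + smin
    for (k in tested) {
      w <- contrasts[[k]]
      s <- 0
      for (j in names(w)) s <- s + w[[j]] * sums[[j]] / ns[[j]]
      stat[k] <- s[1]                       # shift 0
      null <- s[shifts + 1]
      p[k] <- (1 + sum(null >= s[1] - 1e-12)) / (1 + n_permutations)
    }
  }
  pmin_ <- min(p[tested])
  p_comb <- if (correction == "sidak") 1 - (1 - pmin_)^length(tested) else pmin_
  list(p = p, statistic = stat, p_combined = p_comb, tested = tested)
}

#' Classify neurons as position-, path- and acceleration-tuned
#'
#' Runs the three tuning tests on every neuron: the acceleration test over
#' all frames in the low/high bins, the position test over frames in
#' arm1/center/arm2, and the path test over phase-labeled frames inside
#' qualified navigation trials only. Conjunctive flags mark neurons
#' significant for acceleration together with position or path.
#'
#' Each condition is contrasted against frames matched on the other
#' factor: arm 1 against arm 2 (and vice versa), center against both arms,
#' and the path phases starting against terminal. This keeps the tests
#' dissociable -- with a plain one-vs-rest contrast every arm neuron would
#' be "path-tuned" simply because phases are defined by regions. The
#' central phase is not a separate path condition: it labels (nearly) the
#' same frames as center position tuning and is reported there.
#'
#' @param traces a [neural_traces()].
#' @param frames annotated frame tibble (`accel`, `region`, `phase`; see
#'   [annotate_session()]).
#' @param alpha significance level (raw, per the one-or-more-conditions
#'   rule).
#' @param n_permutations,seed,min_shift,min_frames,correction,backend as in
#'   [test_condition_tuning()].
#' @param phase_guard seconds dropped from the start of every path-phase
#'   segment before testing, so calcium decay from the previous region
#'   cannot masquerade as phase tuning (default 0.8 s, about twice the
#'   GCaMP6f decay constant).
#' @return a `tuning_result` tibble with one row per neuron: per-condition
#'   p-values, per-test combined p-values and statistics, flags, preferred
#'   conditions, and test metadata in attributes.
#' @export
classify_neurons <- function(traces, frames, alpha = 0.05, n_permutations = 1000,
                             seed = 7, min_shift = 5, min_frames = 20,
                             phase_guard = 0.8,
                             correction = c("sidak", "none"),
                             backend = c("circshift", "ranksum")) {
  correction <- match.arg(correction)
  backend <- match.arg(backend)
  stopifnot(nrow(frames) == ncol(traces$mat))
  specs <- .tuning_testspecs(frames, phase_guard = phase_guard)
  lfs <- lapply(specs, function(sp) if (!is.null(sp)) .ind_ffts(sp$inds))
  n <- nrow(traces$mat)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    out <- list(neuron_id = traces$neuron_ids[i])
    for (test in names(specs)) {
      if (is.null(specs[[test]])) {
        out[[paste0("p_", test)]] <- NA_real_
        out[[paste0("is_", test, "_tuned")]] <- NA
        out[[paste0("pref_", test)]] <- NA_character_
        next
      }
      r <- .test_tuning_core(traces$mat[i, ], lfs[[test]],
                             specs[[test]]$contrasts,
                             n_permutations, seed + i, min_shift,
                             traces$sample_rate, min_frames, correction,
                             backend, specs[[test]]$inds)
      for (k in names(r$p)) out[[paste0("p_", test, "_", k)]] <- r$p[[k]]
      out[[paste0("p_", test)]] <- r$p_combined
      out[[paste0("is_", test, "_tuned")]] <-
        if (is.na(r$p_combined)) NA else r$p_combined < alpha
      out[[paste0("pref_", test)]] <- .preferred_condition(r, alpha)
    }
    rows[[i]] <- tibble::as_tibble(out)
  }
  res <- dplyr::bind_rows(rows)
  res$conj_accel_position <- res$is_acceleration_tuned & res$is_position_tuned
  res$conj_accel_path <- res$is_acceleration_tuned & res$is_path_tuned
  structure(res,
    class = c("tuning_result", class(res)),
    metadata = list(
      method = backend, correction = correction, n_permutations = n_permutations,
      seed = seed, alpha = alpha, min_shift = min_shift, min_frames = min_frames
    )
  )
}

# drop the first `guard` seconds of every TRUE run of an indicator
.guard_runs <- function(ind, time, guard) {
  if (guard <= 0 || !any(ind)) return(ind)
  g <- round(guard / stats::median(diff(time)))
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  for (i in which(r$values)) {
    ind[begins[i]:min(begins[i] + g - 1, ends[i])] <- FALSE
  }
  ind
}

# indicator sets and contrast weights for the three tests.
#
# The arm-1/arm-2 position contrasts are stratified by path phase and the
# path contrasts by traversal direction, with equal weight on the two
# directions: this cancels the label-driven component of the *other*
# factor exactly (not just in expectation), which is what makes pure
# position and pure path tuning dissociable in finite sessions.
# `path` is NULL when no qualified trials exist.
.tuning_testspecs <- function(frames, min_stratum = 5, phase_guard = 0.8) {
  ab <- bin_acceleration(frames)$accel_bin
  acc_inds <- list(low = ab == "low", high = ab == "high")
  acc <- list(inds = acc_inds,
              contrasts = list(low = c(low = 1, high = -1),
                               high = c(high = 1, low = -1)))

  phase <- if ("phase" %in% names(frames)) frames$phase else rep("none", nrow(frames))
  # drop the first `phase_guard` seconds of every phase segment and every
  # center visit: calcium decay bleeds activity from the previous region
  # into a segment onset (most visibly center -> terminal and
  # origin arm -> center), which would masquerade as path or position
  # tuning of neurons coding the previous region
  if (phase_guard > 0 && any(phase %in% c("starting", "terminal"))) {
    for (ph in c("starting", "terminal")) {
      guarded <- .guard_runs(phase == ph, frames$time, phase_guard)
      phase[phase == ph & !guarded] <- "none"
    }
  }
  reg <- frames$region
  st <- ifelse(phase %in% c("starting", "terminal"), phase, "out")
  pos_inds <- list(
    a1_st = reg == "arm1" & st == "starting",
    a1_te = reg == "arm1" & st == "terminal",
    a1_out = reg == "arm1" & st == "out",
    a2_st = reg == "arm2" & st == "starting",
    a2_te = reg == "arm2" & st == "terminal",
    a2_out = reg == "arm2" & st == "out",
    center = .guard_runs(reg == "center", frames$time, phase_guard)
  )
  ns <- vapply(pos_inds, sum, numeric(1))
  strata <- c("st", "te", "out")
  ws <- pmin(ns[paste0("a1_", strata)], ns[paste0("a2_", strata)])
  names(ws) <- strata
  ws[ws < min_stratum] <- 0
  arm_contrast <- NULL
  if (sum(ws) > 0) {
    wn <- ws / sum(ws)
    arm_contrast <- c(stats::setNames(wn, paste0("a1_", strata)),
                      stats::setNames(-wn, paste0("a2_", strata)))
    arm_contrast <- arm_contrast[abs(arm_contrast) > 0]
  }
  narm <- ns[setdiff(names(ns), "center")]
  center_contrast <- c(center = 1, -narm[narm > 0] / sum(narm))
  names(center_contrast) <- c("center", names(narm[narm > 0]))
  pos_contrasts <- list()
  if (!is.null(arm_contrast)) {
    pos_contrasts$arm1 <- arm_contrast
    pos_contrasts$arm2 <- -arm_contrast
  }
  pos_contrasts$center <- center_contrast
  pos <- list(inds = pos_inds, contrasts = pos_contrasts)

  path <- NULL
  if (any(phase %in% c("starting", "terminal"))) {
    origin <- ifelse(st == "starting", reg,
                     ifelse(st == "terminal" & reg == "arm1", "arm2",
                            ifelse(st == "terminal" & reg == "arm2", "arm1", NA)))
    path_inds <- list(
      s12 = st == "starting" & origin == "arm1",
      s21 = st == "starting" & origin == "arm2",
      t12 = st == "terminal" & origin == "arm1",
      t21 = st == "terminal" & origin == "arm2"
    )
    path_inds <- lapply(path_inds, function(v) v %in% TRUE)
    np <- vapply(path_inds, sum, numeric(1))
    both_dirs <- all(np >= min_stratum)
    start_contrast <- if (both_dirs) {
      c(s12 = 0.5, s21 = 0.5, t12 = -0.5, t21 = -0.5)
    } else {
      ws_ <- np[c("s12", "s21")]; wt_ <- np[c("t12", "t21")]
      c(ws_ / sum(ws_), -wt_ / sum(wt_))
    }
    path <- list(inds = path_inds,
                 contrasts = list(starting = start_contrast,
                                  terminal = -start_contrast))
  }
  list(acceleration = acc, position = pos, path = path)
}

#' Tuning flags straight from planted ground truth
#'
#' Builds a `tuning_result`-shaped flag table from a synthetic session's
#' ground-truth table, bypassing the statistical tests. Used to study
#' downstream stages (ablation, regressor construction) with exactly known
#' neuron classes.
#'
#' @param ground_truth tibble from [plant_traces()].
#' @return tibble with `neuron_id` and the three flag columns.
#' @export
tuning_from_ground_truth <- function(ground_truth) {
  cls <- ground_truth$class
  res <- tibble::tibble(
    neuron_id = ground_truth$neuron_id,
    is_acceleration_tuned = cls %in% c("acceleration", "conjunctive_accel_position",
                                       "conjunctive_accel_path"),
    is_position_tuned = cls %in% c("position", "conjunctive_accel_position"),
    is_path_tuned = cls %in% c("path", "conjunctive_accel_path")
  )
  res$conj_accel_position <- res$is_acceleration_tuned & res$is_position_tuned
  res$conj_accel_path <- res$is_acceleration_tuned & res$is_path_tuned
  structure(res, class = c("tuning_result", class(res)),
            metadata = list(method = "ground_truth"))
}

#' Export the spatial map of tuned cells
#'
#' Flat table of neuron image-plane centroids with class flags, for
#' plotting the cross-cortical (salt-and-pepper) distribution of the three
#' tuned types. No spatial statistic is computed.
#'
#' @param result a `tuning_result`.
#' @param traces the [neural_traces()] carrying per-neuron centroids.
#' @return tibble: `neuron_id`, `cx`, `cy`, flags.
#' @export
export_spatial_map <- function(result, traces) {
  if (is.null(traces$centroids)) rlang::abort("traces carry no neuron centroids.")
  miss <- setdiff(result$neuron_id, traces$centroids$neuron_id)
  if (length(miss) > 0) {
    rlang::abort(sprintf("no centroid for neuron(s): %s", paste(miss, collapse = ", ")))
  }
  flags <- result[, c("neuron_id", "is_acceleration_tuned", "is_position_tuned",
                      "is_path_tuned", "conj_accel_position", "conj_accel_path")]
  dplyr::inner_join(traces$centroids, tibble::as_tibble(flags), by = "neuron_id")
}
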