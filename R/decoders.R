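#' @importFrom stats prcomp predict sd
NULL

#' Decoder configuration
#'
#' Hyperparameters for the four decoding models, with defaults matching
#' the published training recipes: the path transformer (PCA-256 inputs,
#' 196-token padding, 128-dim embedding with a class token, AdamW at
#' lr 1e-4 / weight decay 1e-4, cosine annealing, dropout 0.3, 30 epochs,
#' 8:2 split), the 2-s-window bidirectional-LSTM position classifier
#' (Adam lr 1e-3 / weight decay 1e-5, plateau halving, 50 epochs, batch
#' 16, 70/30 split), and the future-trajectory regressor and 5-zone
#' classifier (batch 64, lr 5e-4, 80 epochs, 80/20 split). Transformer
#' internals the recipe leaves open (encoder depth 2, 4 heads,
#' feed-forward width 256) are configurable; every field is serialized
#' with each report.
#'
#' @param kind one of `"path_transformer"`, `"position_lstm"`,
#'   `"traj_lstm"`, `"zone_lstm"`.
#' @param ... overrides of any default field.
#' @return a `decoder_config` list.
#' @export
decoder_config <- function(kind = c("path_transformer", "position_lstm",
                                    "traj_lstm", "zone_lstm"), ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    path_transformer = list(
      n_components = 256, max_len = 196, d_model = 128, n_heads = 4,
      n_layers = 2, d_ff = 256, d_head_mlp = 64, dropout = 0.3,
      optimizer = "adamw", lr = 1e-4, weight_decay = 1e-4,
      schedule = "cosine", epochs = 30, batch_size = 16, val_frac = 0.2
    ),
    position_lstm = list(
      window_s = 2, step_mult = 2, d_embed = 64, d_hidden = 64, conv_k = 3,
      dropout = 0.2, optimizer = "adam", lr = 1e-3, weight_decay = 1e-5,
      schedule = "plateau", plateau_factor = 0.5, plateau_patience = 5,
      epochs = 50, batch_size = 16, val_frac = 0.3
    ),
    traj_lstm = list(
      input_frames = 15, horizon_frames = 5, window_step = 5,
      d_embed = 64, d_hidden = 64, conv_k = 3, dropout = 0.1,
      optimizer = "adam", lr = 5e-4, weight_decay = 0,
      schedule = "none", epochs = 80, batch_size = 64, val_frac = 0.2
    ),
    zone_lstm = list(
      window_frames = 10, step_mult = 2, d_embed = 64, d_hidden = 64,
      conv_k = 3, dropout = 0.1, optimizer = "adam", lr = 5e-4,
      weight_decay = 0, schedule = "none", epochs = 80, batch_size = 64,
      val_frac = 0.2
    )
  )
  base$shuffle_labels <- FALSE   # permute labels before the split (null control)
  over <- list(...)
  base[names(over)] <- over
  base$kind <- kind
  if (is.null(base$split_seed)) base$split_seed <- 1L
  if (is.null(base$train_seed)) base$train_seed <- 1L
  structure(base, class = "decoder_config")
}

# stratified split: each class represented in both partitions
.stratified_split <- function(labels, val_frac, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2) {
      rlang::abort(sprintf("class '%s' has fewer than 2 samples; cannot split.", cl))
    }
    nv <- max(1, min(length(idx) - 1, round(val_frac * length(idx))))
    val <- c(val, sample(idx, nv))
  }
  list(train = setdiff(seq_along(labels), val), val = sort(val))
}

#' Classification report
#'
#' Accuracy, macro-averaged precision/recall/F1 and the confusion matrix
#' for a set of predictions. Per-class precision with no predicted
#' positives is 0 (and likewise recall with no true positives), the usual
#' convention for macro averaging.
#'
#' @param truth,pred class labels.
#' @param classes class universe (default: union observed).
#' @return a `decoding_report` list.
#' @export
decoding_report <- function(truth, pred, classes = NULL) {
  if (length(truth) == 0) rlang::abort("empty evaluation set.")
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(
    list(
      accuracy = sum(tp) / sum(cm),
      precision = mean(prec), recall = mean(rec), f1 = mean(f1),
      per_class = tibble::tibble(class = classes, precision = as.numeric(prec),
                                 recall = as.numeric(rec), f1 = as.numeric(f1),
                                 n = as.numeric(rowSums(cm))),
      confusion = unclass(cm), n = length(truth)
    ),
    class = "decoding_report"
  )
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> n=%d  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Reduce trials to PCA component sequences and pad
#'
#' Fits PCA over the neuron axis on the time-concatenated frames of the
#' *training* trials only (no leakage), projects every trial's frames into
#' component space, keeps the top `n_components` (zero-filling when fewer
#' neurons/components exist), and head-truncates or zero-pads each
#' sequence to exactly `max_len` tokens with an explicit length for the
#' attention mask.
#'
#' @param trial_mats list of neurons x frames matrices, one per trial.
#' @param train_idx indices of training trials used to fit the basis.
#' @param n_components components retained (default 256).
#' @param max_len padded sequence length (default 196).
#' @return list with `tensors` (per trial: `x` max_len x n_components,
#'   `len`), `basis` (`rotation`, `center`, `var_explained`),
#'   `n_truncated`.
#' @export
reduce_and_pad <- function(trial_mats, train_idx, n_components = 256, max_len = 196) {
  if (length(trial_mats) < 2) rlang::abort("need at least 2 trials.")
  tr_frames <- t(do.call(cbind, trial_mats[train_idx]))   # frames x neurons
  pc <- prcomp(tr_frames, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  ctr <- pc$center
  n_trunc <- 0L
  tensors <- lapply(trial_mats, function(m) {
    pr <- sweep(t(m), 2, ctr) %*% rot                      # frames x k
    if (k < n_components) {
      pr <- cbind(pr, matrix(0, nrow(pr), n_components - k))
    }
    len <- nrow(pr)
    if (len > max_len) {
      n_trunc <<- n_trunc + 1L
      pr <- pr[seq_len(max_len), , drop = FALSE]
      len <- max_len
    } else if (len < max_len) {
      pr <- rbind(pr, matrix(0, max_len - len, n_components))
    }
    list(x = pr, len = len)
  })
  if (n_trunc > 0) {
    rlang::warn(sprintf("%d trial(s) longer than %d frames were head-truncated.",
                        n_trunc, max_len))
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(tensors = tensors,
       basis = list(rotation = rot, center = ctr, var_explained = ve[seq_len(k)]),
       n_truncated = n_trunc)
}

# neuron-id selection helper: NULL keeps everything
.subset_neurons <- function(traces, neurons) {
  if (is.null(neurons)) return(traces$mat)
  keep <- traces$neuron_ids %in% neurons
  if (!any(keep)) rlang::abort("neuron subset is empty.")
  traces$mat[keep, , drop = FALSE]
}

# closed-form non-overlapping window start frames (0-based)
.window_starts <- function(n_frames, window, step) {
  if (n_frames < window) return(integer(0))
  seq(0L, n_frames - window, by = step)
}

## ---- shared LSTM-family training --------------------------------------

.lstm_train <- function(Xtr, ytr, Xval, yval, cfg) {
  set.seed(cfg$train_seed)
  params <- .lstm_init(cfg)
  state <- .opt_init(params)
  sched <- list(lr = cfg$lr, best = Inf, wait = 0)
  ntr <- dim(Xtr)[1]
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(ntr)
    for (b0 in seq(1, ntr, by = cfg$batch_size)) {
      take <- ord[b0:min(b0 + cfg$batch_size - 1, ntr)]
      Xb <- Xtr[take, , , drop = FALSE]
      yb <- if (cfg$loss == "ce") ytr[take] else ytr[take, , drop = FALSE]
      out <- .lstm_batch(params, Xb, yb, cfg, train = TRUE)
      st <- .opt_step(params, out$grads, state, lr = sched$lr,
                      weight_decay = cfg$weight_decay, decoupled = TRUE)
      params <- st$params
      state <- st$state
    }
    if (identical(cfg$schedule, "plateau")) {
      v <- .lstm_batch(params, Xval,
                       if (cfg$loss == "ce") yval else yval,
                       cfg, train = FALSE, grads_wanted = FALSE)
      sched <- .plateau_update(sched, v$loss, cfg$plateau_factor, cfg$plateau_patience)
    }
  }
  params
}

.lstm_predict <- function(params, X, cfg) {
  .lstm_batch(params, X,
              if (cfg$loss == "ce") rep(1L, dim(X)[1]) else
                matrix(0, dim(X)[1], cfg$n_out),
              cfg, train = FALSE, grads_wanted = FALSE)$out
}

# z-scoring statistics from training windows only
.norm_stats <- function(X) {
  flat <- matrix(X, prod(dim(X)[1:2]), dim(X)[3])
  mu <- colMeans(flat)
  s <- apply(flat, 2, sd)
  s[s < 1e-8] <- 1
  list(mu = mu, sd = s)
}

.apply_norm <- function(X, ns) {
  for (j in seq_len(dim(X)[3])) X[, , j] <- (X[, , j] - ns$mu[j]) / ns$sd[j]
  X
}

## ---- the four decoders -------------------------------------------------

#' Train the transformer path classifier
#'
#' Decodes the traversal direction (arm1 to arm2 vs arm2 to arm1) from
#' whole-trial population sequences: trials are PCA-reduced and padded
#' ([reduce_and_pad()]), each token linearly embedded, a learned class
#' token prepended, learned position embeddings added, and a transformer
#' encoder applied with padding masked from attention; the class-token
#' output feeds a small feed-forward classifier trained with cross-entropy.
#'
#' @param session annotated `aligned_session` (needs `trials`).
#' @param cfg a [decoder_config()] of kind `"path_transformer"`.
#' @param neurons optional neuron-id subset (ablations remove neurons
#'   before the PCA).
#' @param exclude_frames optional 0-based frames to drop from every trial
#'   sequence (lick-period controls).
#' @return list with `model` (a `nav_decoder`) and `report` (validation
#'   [decoding_report()]).
#' @export
train_path_transformer <- function(session, cfg = decoder_config("path_transformer"),
                                   neurons = NULL, exclude_frames = NULL) {
  trials <- session$trials[session$trials$qualified, , drop = FALSE]
  if (nrow(trials) < 4) rlang::abort("need at least 4 qualified trials.")
  labels <- trials$direction
  if (length(unique(labels)) < 2) rlang::abort("both path classes must be present.")
  mat <- .subset_neurons(session$traces, neurons)
  mats <- lapply(seq_len(nrow(trials)), function(i) {
    fr <- (trials$start_frame[i] + 1):trials$end_frame[i]
    if (!is.null(exclude_frames)) fr <- setdiff(fr, exclude_frames + 1L)
    mat[, fr, drop = FALSE]
  })
  keep <- vapply(mats, ncol, integer(1)) >= 2
  mats <- mats[keep]
  labels <- labels[keep]
  if (isTRUE(cfg$shuffle_labels)) {
    set.seed(cfg$train_seed + 7777L)
    labels <- sample(labels)
  }
  sp <- .stratified_split(labels, cfg$val_frac, cfg$split_seed)
  rp <- reduce_and_pad(mats, sp$train, cfg$n_components, cfg$max_len)
  classes <- sort(unique(labels))
  y <- match(labels, classes)
  batch_of <- function(idx) {
    lapply(idx, function(i) list(x = rp$tensors[[i]]$x, len = rp$tensors[[i]]$len,
                                 label = y[i]))
  }
  cfg$n_classes <- length(classes)
  set.seed(cfg$train_seed)
  params <- .tf_init(cfg)
  state <- .opt_init(params)
  ntr <- length(sp$train)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (identical(cfg$schedule, "cosine")) .cosine_lr(cfg$lr, epoch, cfg$epochs) else cfg$lr
    ord <- sample(sp$train)
    for (b0 in seq(1, ntr, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, ntr)]
      out <- .tf_batch(params, batch_of(idx), cfg, train = TRUE)
      st <- .opt_step(params, out$grads, state, lr = lr,
                      weight_decay = cfg$weight_decay, decoupled = TRUE)
      params <- st$params
      state <- st$state
    }
  }
  val_out <- .tf_batch(params, batch_of(sp$val), cfg, train = FALSE,
                       grads_wanted = FALSE)
  pred <- classes[max.col(val_out$logits)]
  report <- decoding_report(labels[sp$val], pred, classes)
  report$config <- cfg
  report$config_hash <- rlang::hash(cfg)
  model <- structure(list(kind = "path_transformer", params = params, cfg = cfg,
                          basis = rp$basis, classes = classes),
                     class = "nav_decoder")
  list(model = model, report = report, split = sp)
}

# assemble window array (B x T x C) from frame starts (0-based)
.window_array <- function(mat, starts, window) {
  B <- length(starts)
  X <- array(0, dim = c(B, window, nrow(mat)))
  for (i in seq_len(B)) {
    X[i, , ] <- t(mat[, (starts[i] + 1):(starts[i] + window), drop = FALSE])
  }
  X
}

.drop_excluded <- function(starts, window, exclude_frames) {
  if (is.null(exclude_frames) || length(starts) == 0) return(starts)
  bad <- vapply(starts, function(s) any(exclude_frames >= s & exclude_frames < s + window),
                logical(1))
  starts[!bad]
}

# shared LSTM classifier over labeled windows
.lstm_classifier <- function(mat, starts, labels, cfg, classes) {
  if (isTRUE(cfg$shuffle_labels)) {
    set.seed(cfg$train_seed + 7777L)
    labels <- sample(labels)
  }
  y <- match(labels, classes)
  sp <- .stratified_split(labels, cfg$val_frac, cfg$split_seed)
  window <- cfg$.window
  Xtr <- .window_array(mat, starts[sp$train], window)
  Xval <- .window_array(mat, starts[sp$val], window)
  ns <- .norm_stats(Xtr)
  Xtr <- .apply_norm(Xtr, ns)
  Xval <- .apply_norm(Xval, ns)
  cfg$n_components <- nrow(mat)
  cfg$n_out <- length(classes)
  cfg$loss <- "ce"
  params <- .lstm_train(Xtr, y[sp$train], Xval, y[sp$val], cfg)
  pred <- classes[max.col(.lstm_predict(params, Xval, cfg))]
  report <- decoding_report(labels[sp$val], pred, classes)
  report$config <- cfg
  report$config_hash <- rlang::hash(cfg)
  model <- structure(list(kind = cfg$kind, params = params, cfg = cfg,
                          norm = ns, classes = classes),
                     class = "nav_decoder")
  list(model = model, report = report, split = sp)
}

#' Train the bidirectional-LSTM position classifier
#'
#' Segments the session into non-overlapping 2-s windows with an
#' inter-window step of twice the window length (so adjacent samples never
#' overlap), labels each window with the maze region at its final frame
#' (arm1/arm2/arm3/center), and trains the linear-embedding + layer-norm +
#' 1-D convolution + bidirectional LSTM classifier on a stratified 70/30
#' split with Adam and plateau-halving.
#'
#' @inheritParams train_path_transformer
#' @param cfg a [decoder_config()] of kind `"position_lstm"`.
#' @export
train_position_classifier <- function(session, cfg = decoder_config("position_lstm"),
                                      neurons = NULL, exclude_frames = NULL) {
  rate <- session$traces$sample_rate
  window <- round(cfg$window_s * rate)
  step <- cfg$step_mult * window
  mat <- .subset_neurons(session$traces, neurons)
  starts <- .window_starts(ncol(mat), window, step)
  starts <- .drop_excluded(starts, window, exclude_frames)
  lab <- session$frames$region[starts + window]      # region at final frame
  ok <- lab %in% c("arm1", "arm2", "arm3", "center") &
    vapply(starts, function(s) all(session$frames$valid[(s + 1):(s + window)]), logical(1))
  starts <- starts[ok]
  lab <- lab[ok]
  classes <- c("arm1", "arm2", "arm3", "center")
  miss <- setdiff(classes, unique(lab))
  if (length(miss) > 0) {
    rlang::abort(sprintf("position class(es) absent from the data: %s",
                         paste(miss, collapse = ", ")))
  }
  cfg$.window <- window
  .lstm_classifier(mat, starts, lab, cfg, classes)
}

#' Train the 5-zone classifier
#'
#' 10-frame windows labeled with the modal zone within the window (ties
#' broken toward the zone listed first along the corridor); same recipe
#' as the trajectory regressor (80/20 split, batch 64, lr 5e-4, 80
#' epochs).
#'
#' @inheritParams train_path_transformer
#' @param cfg a [decoder_config()] of kind `"zone_lstm"`.
#' @export
train_zone_classifier <- function(session, cfg = decoder_config("zone_lstm"),
                                  neurons = NULL, exclude_frames = NULL) {
  window <- cfg$window_frames
  step <- cfg$step_mult * window
  mat <- .subset_neurons(session$traces, neurons)
  starts <- .window_starts(ncol(mat), window, step)
  starts <- .drop_excluded(starts, window, exclude_frames)
  classes <- c("arm1_distal", "arm1_proximal", "middle", "arm2_proximal", "arm2_distal")
  modal <- function(s) {
    z <- session$frames$zone5[(s + 1):(s + window)]
    z <- z[z %in% classes]
    if (length(z) == 0) return(NA_character_)
    counts <- table(factor(z, levels = classes))
    classes[which.max(counts)]
  }
  lab <- vapply(starts, modal, character(1))
  ok <- !is.na(lab)
  starts <- starts[ok]
  lab <- lab[ok]
  miss <- setdiff(classes, unique(lab))
  if (length(miss) > 0) {
    rlang::abort(sprintf("zone(s) absent from the data: %s", paste(miss, collapse = ", ")))
  }
  cfg$.window <- window
  .lstm_classifier(mat, starts, lab, cfg, classes)
}

#' Train the future-trajectory regressor
#'
#' Predicts the animal's continuous future path: input is the preceding
#' 1.5 s of population activity (15 frames), target the next 0.5 s of
#' x,y coordinates (5 frames), trained with mean-squared error on a
#' random 80/20 split. The report gives per-axis RMSE (cm) on the test
#' split plus the RMSE of predicting the training-mean trajectory as a
#' baseline.
#'
#' @inheritParams train_path_transformer
#' @param cfg a [decoder_config()] of kind `"traj_lstm"`.
#' @export
train_trajectory_regressor <- function(session, cfg = decoder_config("traj_lstm"),
                                       neurons = NULL, exclude_frames = NULL) {
  mat <- .subset_neurons(session$traces, neurons)
  win <- cfg$input_frames
  hor <- cfg$horizon_frames
  nfr <- ncol(mat)
  starts <- seq(0L, nfr - win - hor, by = cfg$window_step)
  starts <- .drop_excluded(starts, win + hor, exclude_frames)
  ok <- vapply(starts, function(s) all(session$frames$valid[(s + 1):(s + win + hor)]),
               logical(1))
  starts <- starts[ok]
  if (length(starts) < 10) rlang::abort("session too short for trajectory windows.")
  Y <- t(vapply(starts, function(s) {
    fut <- (s + win + 1):(s + win + hor)
    c(session$frames$x[fut], session$frames$y[fut])
  }, numeric(2 * hor)))
  set.seed(cfg$split_seed)
  val <- sample(length(starts), max(1, round(cfg$val_frac * length(starts))))
  tr <- setdiff(seq_along(starts), val)
  Xtr <- .window_array(mat, starts[tr], win)
  Xval <- .window_array(mat, starts[val], win)
  ns <- .norm_stats(Xtr)
  Xtr <- .apply_norm(Xtr, ns)
  Xval <- .apply_norm(Xval, ns)
  cfg$n_components <- nrow(mat)
  cfg$n_out <- 2 * hor
  cfg$loss <- "mse"
  # targets are z-scored with training statistics and un-scaled for
  # reporting, so the loss scale is independent of the arena coordinates
  y_mu <- colMeans(Y[tr, , drop = FALSE])
  y_sd <- apply(Y[tr, , drop = FALSE], 2, sd)
  y_sd[y_sd < 1e-8] <- 1
  zY <- function(m) sweep(sweep(m, 2, y_mu), 2, y_sd, `/`)
  params <- .lstm_train(Xtr, zY(Y[tr, , drop = FALSE]),
                        Xval, zY(Y[val, , drop = FALSE]), cfg)
  pred <- sweep(sweep(.lstm_predict(params, Xval, cfg), 2, y_sd, `*`), 2, y_mu, `+`)
  resid <- pred - Y[val, , drop = FALSE]
  base <- sweep(Y[val, , drop = FALSE], 2, colMeans(Y[tr, , drop = FALSE]))
  report <- tibble::tibble(
    rmse_x = sqrt(mean(resid[, 1:hor]^2)),
    rmse_y = sqrt(mean(resid[, (hor + 1):(2 * hor)]^2)),
    rmse = sqrt(mean(resid^2)),
    baseline_rmse = sqrt(mean(base^2)),
    n_test = length(val)
  )
  model <- structure(list(kind = "traj_lstm", params = params, cfg = cfg, norm = ns,
                          target_norm = list(mu = y_mu, sd = y_sd)),
                     class = "nav_decoder")
  list(model = model, report = report, split = list(train = tr, val = val))
}

#' Evaluate a trained decoder on a window/trial dataset
#'
#' @param model a `nav_decoder`.
#' @param data for LSTM models, a list with `X` (array B x T x C) and
#'   `truth`; for the transformer, a list of trial samples (`x`, `len`)
#'   plus `truth`.
#' @return a [decoding_report()].
#' @export
evaluate_decoder <- function(model, data) {
  if (length(data$truth) == 0) rlang::abort("empty evaluation set.")
  if (model$kind == "path_transformer") {
    out <- .tf_batch(model$params, lapply(seq_along(data$samples), function(i) {
      c(data$samples[[i]], list(label = 1L))
    }), model$cfg, train = FALSE, grads_wanted = FALSE)
    pred <- model$classes[max.col(out$logits)]
  } else {
    X <- .apply_norm(data$X, model$norm)
    pred <- model$classes[max.col(.lstm_predict(model$params, X, model$cfg))]
  }
  decoding_report(data$truth, pred, model$classes)
}

# internal dispatcher used by ablation / lick-removal analyses
.train_decoder <- function(session, kind, cfg = NULL, neurons = NULL,
                           exclude_frames = NULL, seed = 1L) {
  if (is.null(cfg)) cfg <- decoder_config(kind)
  cfg$split_seed <- seed
  cfg$train_seed <- seed
  fn <- switch(kind,
    path_transformer = train_path_transformer,
    position_lstm = train_position_classifier,
    zone_lstm = train_zone_classifier,
    traj_lstm = train_trajectory_regressor
  )
  fn(session, cfg, neurons = neurons, exclude_frames = exclude_frames)
}
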