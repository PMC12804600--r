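# The decoders run on a hand-written layer library; these tests pin its
# gradients to central finite differences on tiny models and check the
# optimizer/schedule machinery.

test_that("transformer gradients match finite differences", {
  set.seed(1)
  cfg <- list(n_components = 3, max_len = 5, d_model = 4, n_heads = 2,
              n_layers = 2, d_ff = 6, d_head_mlp = 4, n_classes = 2, dropout = 0)
  params <- cortexnav:::.tf_init(cfg)
  batch <- lapply(1:3, function(i) {
    list(x = matrix(rnorm(15), 5, 3), len = sample(3:5, 1), label = sample(1:2, 1))
  })
  out <- cortexnav:::.tf_batch(params, batch, cfg, train = FALSE, grads_wanted = TRUE)
  loss_fn <- function(p) cortexnav:::.tf_batch(p, batch, cfg, train = FALSE,
                                               grads_wanted = FALSE)$loss
  ng <- cortexnav:::.num_grad(loss_fn, params, names(params), max_entries = 3)
  for (nm in names(params)) {
    a <- out$grads[[nm]][seq_along(ng[[nm]])]
    expect_equal(a, ng[[nm]], tolerance = 1e-4, info = nm)
  }
})

test_that("bidirectional LSTM gradients match finite differences", {
  set.seed(2)
  X <- array(rnorm(2 * 6 * 3), c(2, 6, 3))

  cfg <- list(n_components = 3, d_embed = 4, d_hidden = 3, conv_k = 3,
              n_out = 2, loss = "ce", dropout = 0)
  p <- cortexnav:::.lstm_init(cfg)
  y <- c(1L, 2L)
  out <- cortexnav:::.lstm_batch(p, X, y, cfg, train = FALSE, grads_wanted = TRUE)
  lf <- function(pp) cortexnav:::.lstm_batch(pp, X, y, cfg, train = FALSE,
                                             grads_wanted = FALSE)$loss
  ng <- cortexnav:::.num_grad(lf, p, names(p), max_entries = 4)
  for (nm in names(p)) {
    expect_equal(out$grads[[nm]][seq_along(ng[[nm]])], ng[[nm]],
                 tolerance = 1e-4, info = nm)
  }

  cfg$loss <- "mse"; cfg$n_out <- 4
  p <- cortexnav:::.lstm_init(cfg)
  Y <- matrix(rnorm(8), 2, 4)
  out <- cortexnav:::.lstm_batch(p, X, Y, cfg, train = FALSE, grads_wanted = TRUE)
  lf <- function(pp) cortexnav:::.lstm_batch(pp, X, Y, cfg, train = FALSE,
                                             grads_wanted = FALSE)$loss
  ng <- cortexnav:::.num_grad(lf, p, names(p), max_entries = 4)
  for (nm in names(p)) {
    expect_equal(out$grads[[nm]][seq_along(ng[[nm]])], ng[[nm]],
                 tolerance = 1e-4, info = nm)
  }
})

test_that("the optimizer descends and the schedules behave", {
  # AdamW on a quadratic
  p <- list(w = matrix(c(5, -3), 1))
  st <- cortexnav:::.opt_init(p)
  for (i in 1:300) {
    g <- list(w = 2 * p$w)
    up <- cortexnav:::.opt_step(p, g, st, lr = 0.05)
    p <- up$params; st <- up$state
  }
  expect_lt(max(abs(p$w)), 1e-2)

  expect_equal(cortexnav:::.cosine_lr(1e-3, 1, 30), 1e-3)
  expect_lt(cortexnav:::.cosine_lr(1e-3, 30, 30), 1e-4)

  sched <- list(lr = 1, best = Inf, wait = 0)
  sched <- cortexnav:::.plateau_update(sched, 1.0)   # improvement
  for (i in 1:5) sched <- cortexnav:::.plateau_update(sched, 1.0)
  expect_equal(sched$lr, 0.5)
})

test_that("classification reports match hand computation", {
  r <- decoding_report(rep(c("a", "b"), each = 10),
                       rep(c("a", "b"), each = 10))
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)

  # confusion [[5,5],[5,5]]
  truth <- rep(c("a", "b"), each = 10)
  pred <- c(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  r <- decoding_report(truth, pred)
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$f1, 0.5)

  # all predictions one class on balanced data: accuracy 1/2, macro-F1 1/3
  r <- decoding_report(rep(c("a", "b"), each = 10), rep("a", 20))
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$f1, 1 / 3)
  expect_equal(r$precision, 0.25)
  expect_equal(r$recall, 0.5)

  expect_error(decoding_report(character(0), character(0)), "empty")
})

test_that("window bookkeeping matches the closed form", {
  # 100 s at 10 Hz, 2-s windows, step 4 s -> 25 windows
  starts <- cortexnav:::.window_starts(1000, 20, 40)
  expect_length(starts, floor((1000 - 20) / 40) + 1)
  expect_length(starts, 25)
  # generic closed form on random cases
  set.seed(3)
  for (i in 1:20) {
    n <- sample(50:2000, 1); w <- sample(5:30, 1); s <- sample(5:60, 1)
    expect_length(cortexnav:::.window_starts(n, w, s),
                  if (n < w) 0 else floor((n - w) / s) + 1)
  }
})

test_that("PCA reduction preserves variance and respects rank bounds", {
  set.seed(4)
  # 30 uncorrelated unit-variance neurons, 30 components: variance preserved
  mats <- lapply(1:6, function(i) matrix(rnorm(30 * 50), 30, 50))
  rp <- reduce_and_pad(mats, train_idx = 1:4, n_components = 30, max_len = 60)
  tot_in <- sum(apply(t(do.call(cbind, mats[1:4])), 2, var))
  tot_out <- sum(apply(do.call(rbind, lapply(rp$tensors[1:4], function(t) t$x[seq_len(t$len), ])), 2, var))
  expect_equal(tot_out, tot_in, tolerance = 1e-6)

  # 10-neuron session: components beyond the rank are identically zero
  mats <- lapply(1:4, function(i) matrix(rnorm(10 * 40), 10, 40))
  rp <- reduce_and_pad(mats, 1:3, n_components = 16, max_len = 50)
  expect_true(all(abs(rp$tensors[[1]]$x[, 11:16]) == 0))

  # rank-1 population: first component explains (almost) everything
  base <- sin(seq(0, 6, length.out = 80))
  g <- runif(12, 0.5, 2)
  mats <- lapply(1:4, function(i) outer(g, base * runif(1, 0.8, 1.2)) + rnorm(12 * 80, 0, 1e-3))
  rp <- reduce_and_pad(mats, 1:3, n_components = 5, max_len = 80)
  expect_gt(rp$basis$var_explained[1], 0.99)

  # over-long trials are head-truncated with a warning
  mats <- lapply(1:3, function(i) matrix(rnorm(5 * 30), 5, 30))
  expect_warning(rp <- reduce_and_pad(mats, 1:2, n_components = 4, max_len = 20),
                 "truncated")
  expect_equal(rp$n_truncated, 3L)
  expect_equal(rp$tensors[[1]]$len, 20)
})

test_that("stratified splits keep every class on both sides", {
  set.seed(5)
  labels <- sample(c("a", "b", "c"), 60, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  sp <- cortexnav:::.stratified_split(labels, 0.3, seed = 2)
  expect_setequal(c(sp$train, sp$val), seq_along(labels))
  expect_length(intersect(sp$train, sp$val), 0)
  for (cl in c("a", "b", "c")) {
    expect_true(cl %in% labels[sp$train])
    expect_true(cl %in% labels[sp$val])
  }
  expect_error(cortexnav:::.stratified_split(c("a", "a", "b"), 0.3, 1), "fewer than 2")
})
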