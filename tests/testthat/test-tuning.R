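test_that("acceleration binning follows the half-open convention", {
  df <- tibble::tibble(accel = c(30, -3, 25, 5, 24.9, 4.9, 50, 50.1, NA),
                       time = seq_len(9) / 10)
  b <- bin_acceleration(df)$accel_bin
  expect_equal(b, c("high", "excluded", "high", "low", "low", "excluded",
                    "high", "excluded", "excluded"))
})

test_that("the circular-shift statistic matches a direct computation", {
  set.seed(42)
  T <- 300
  z <- rnorm(T)
  lab <- sample(c("a", "b", NA), T, replace = TRUE)
  lf <- cortexnav:::.label_ffts(lab, c("a", "b"))
  sums <- cortexnav:::.shift_sums(z, lf)
  ns <- vapply(lf$conds, `[[`, numeric(1), "n")
  stat_fft <- sums[["a"]] / ns[["a"]] - sums[["b"]] / ns[["b"]]
  naive <- function(shift) {
    zz <- z[((seq_len(T) - 1 + shift) %% T) + 1]
    mean(zz[!is.na(lab) & lab == "a"]) - mean(zz[!is.na(lab) & lab == "b"])
  }
  for (s in c(0, 1, 7, 150, 299)) {
    expect_equal(stat_fft[s + 1], naive(s), tolerance = 1e-10)
  }
})

test_that("degenerate and null traces are never flagged", {
  lab <- rep(c("a", "b"), each = 300)
  r <- test_condition_tuning(rep(2, 600), lab, n_permutations = 200, seed = 1)
  expect_equal(unname(r$statistic["a"]), 0)
  expect_equal(unname(r$p[["a"]]), 1)
  expect_false(r$significant)
  expect_true(is.na(r$preferred))

  # all-zero trace matrix yields zero tuned neurons of any type
  ses <- small_session()
  zero <- neural_traces(matrix(0, 5, nrow(ses$frames)),
                        sample_rate = ses$traces$sample_rate,
                        time = ses$frames$time)
  res <- classify_neurons(zero, ses$frames, n_permutations = 200, seed = 3)
  expect_equal(sum(res$is_acceleration_tuned, na.rm = TRUE), 0)
  expect_equal(sum(res$is_position_tuned, na.rm = TRUE), 0)
  expect_equal(sum(res$is_path_tuned, na.rm = TRUE), 0)
})

test_that("classification is deterministic and recovers planted tuning", {
  ses <- small_session()
  r1 <- classify_neurons(ses$traces, ses$frames, n_permutations = 300, seed = 5)
  r2 <- classify_neurons(ses$traces, ses$frames, n_permutations = 300, seed = 5)
  expect_identical(r1$p_acceleration, r2$p_acceleration)
  expect_identical(r1$is_position_tuned, r2$is_position_tuned)

  gt <- ses$ground_truth
  expect_gte(mean(r1$is_position_tuned[gt$class == "position"]), 0.5)
  expect_gte(mean(r1$is_path_tuned[gt$class == "path"]), 0.5)
  # the short smoke session has few high-acceleration frames; full-power
  # acceleration recovery is exercised on default-length sessions elsewhere
  expect_gte(mean(r1$is_acceleration_tuned[gt$class == "acceleration"]), 0.25)
  # flags respect the combined-p rule
  alpha <- attr(r1, "metadata")$alpha
  expect_identical(r1$is_position_tuned, r1$p_position < alpha)
})

test_that("circularly shifting all labels destroys planted detection", {
  ses <- small_session()
  frames <- ses$frames
  n <- nrow(frames)
  shift <- 1500
  rot <- function(v) v[((seq_len(n) - 1 + shift) %% n) + 1]
  sh <- frames
  sh$region <- rot(frames$region)
  sh$phase <- rot(frames$phase)
  sh$trial_id <- rot(frames$trial_id)
  sh$accel <- rot(frames$accel)
  res <- classify_neurons(ses$traces, sh, n_permutations = 300, seed = 5)
  gt <- ses$ground_truth
  planted <- gt$class != "untuned"
  hit <- rowSums(cbind(res$is_acceleration_tuned[planted],
                       res$is_position_tuned[planted],
                       res$is_path_tuned[planted]), na.rm = TRUE) > 0
  # three tests at alpha 0.05 each: chance-level family rate ~ 0.14
  expect_lte(mean(hit), 0.35)
})

test_that("the rank-sum backend agrees with the permutation backend on strong tuning", {
  ses <- small_session()
  gt <- ses$ground_truth
  i <- which(gt$class == "position")[1]
  lab <- ifelse(ses$frames$region %in% c("arm1", "center", "arm2"),
                ses$frames$region, NA)
  r_perm <- test_condition_tuning(ses$traces$mat[i, ], lab, n_permutations = 300,
                                  seed = 2, sample_rate = 10)
  r_rank <- test_condition_tuning(ses$traces$mat[i, ], lab, backend = "ranksum")
  expect_true(r_perm$significant)
  expect_true(r_rank$significant)
  expect_identical(r_perm$preferred, r_rank$preferred)
})

test_that("spatial maps carry centroids and faithful flags", {
  ses <- small_session()
  res <- classify_neurons(ses$traces, ses$frames, n_permutations = 100, seed = 4)
  map <- export_spatial_map(res, ses$traces)
  expect_equal(nrow(map), nrow(res))
  expect_identical(map$is_position_tuned[match(res$neuron_id, map$neuron_id)],
                   res$is_position_tuned)

  # missing centroid errors with the neuron named
  tr2 <- ses$traces
  tr2$centroids <- tr2$centroids[-1, ]
  expect_error(export_spatial_map(res, tr2), res$neuron_id[1])
  tr3 <- ses$traces
  tr3$centroids <- NULL
  expect_error(export_spatial_map(res, tr3), "no neuron centroids")

  # round trip through the results store
  f <- tempfile(fileext = ".json")
  save_results(map, f)
  expect_equal(as.data.frame(load_results(f)), as.data.frame(map))
})

test_that("ground-truth flag tables mirror planted classes", {
  ses <- small_session()
  tun <- tuning_from_ground_truth(ses$ground_truth)
  gt <- ses$ground_truth
  expect_identical(tun$is_acceleration_tuned,
                   gt$class %in% c("acceleration", "conjunctive_accel_position",
                                   "conjunctive_accel_path"))
  expect_identical(tun$conj_accel_position, gt$class == "conjunctive_accel_position")
})
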