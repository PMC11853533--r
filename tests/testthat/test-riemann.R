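test_that("eigenvalue entropy matches closed forms", {
  expect_equal(eigen_entropy(diag(2)), log(2), tolerance = 1e-12)
  expect_equal(eigen_entropy(diag(8)), log(8), tolerance = 1e-12)
  # concentration: one dominant eigenvalue drives entropy toward 0
  expect_lt(eigen_entropy(diag(c(1, 1e-9))), 1e-6)
  expect_error(eigen_entropy(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("reference selection averages the five lowest-entropy candidates", {
  same <- replicate(5, diag(3), simplify = FALSE)
  expect_equal(unclass(reference_matrix(same)), diag(3))
  # candidates with a known entropy ordering, checked against a sort oracle
  cands <- lapply(1:9, function(i) {
    assert_spd(diag(c(1, exp(-i / 2), exp(-i / 2))))
  })
  ent <- vapply(cands, eigen_entropy, 0)
  pick <- order(ent)[1:5]
  expected <- Reduce(`+`, lapply(cands[pick], unclass)) / 5
  expect_equal(unclass(reference_matrix(cands)), expected)
  expect_silent(assert_spd(reference_matrix(cands)))
  expect_error(reference_matrix(cands[1:4]), "at least 5")
})

test_that("AIR distance matches hand computations", {
  expect_equal(air_distance(diag(2), diag(2)), 0, tolerance = 1e-10)
  expect_equal(air_distance(diag(2), 4 * diag(2)), sqrt(2 * log(4)^2),
               tolerance = 1e-10)
  expect_equal(air_distance(diag(c(1, 2)), diag(c(2, 1))), sqrt(2) * log(2),
               tolerance = 1e-10)
  expect_error(air_distance(diag(2), diag(3)), "dimension")
})

test_that("AIR distance is a metric with affine invariance, matching an oracle", {
  set.seed(81)
  for (i in 1:20) {
    a <- random_spd(5, 100 + i)
    b <- random_spd(5, 200 + i)
    cc <- random_spd(5, 300 + i)
    dab <- air_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, air_distance(b, a), tolerance = 1e-8)
    expect_lte(dab, air_distance(a, cc) + air_distance(cc, b) + 1e-8)
    # congruence invariance under a random invertible transform
    w <- matrix(rnorm(25), 5) + diag(5)
    expect_equal(air_distance(assert_spd(t(w) %*% unclass(a) %*% w),
                              assert_spd(t(w) %*% unclass(b) %*% w)),
                 dab, tolerance = 1e-8)
    # generalized-eigenvalue oracle
    expect_equal(dab, air_oracle(a, b), tolerance = 1e-6)
  }
  expect_equal(air_distance(random_spd(4, 7), random_spd(4, 7)), 0,
               tolerance = 1e-10)
})

test_that("sliding covariance windows advance one trough at a time", {
  set.seed(82)
  seg <- mc_segment(matrix(rnorm(4 * 3000), 4, 3000), 500)
  g <- gfp(seg)
  n_tr <- length(g$trough_indices)
  sc <- sliding_covariances(seg, g, window_troughs = n_tr)
  expect_length(sc$matrices, 1)
  sc5 <- sliding_covariances(seg, g$trough_indices[1:40], window_troughs = 35)
  expect_length(sc5$matrices, 6)   # 40 - 35 + 1
  expect_true(all(diff(sc5$times) > 0))
  expect_true(all(sc5$times_end > sc5$times))
  expect_error(sliding_covariances(seg, g$trough_indices[1:10], 35), "troughs")
  # stationarity: successive windows stay closer than a x4-rescaled matrix
  d_succ <- mean(vapply(1:5, function(i) {
    air_distance(sc5$matrices[[i]], sc5$matrices[[i + 1]])
  }, 0))
  d_scaled <- air_distance(sc5$matrices[[1]],
                           assert_spd(4 * unclass(sc5$matrices[[1]])))
  expect_lt(d_succ, d_scaled)
})

test_that("distance series is zero against itself and flags level shifts", {
  set.seed(83)
  seg <- mc_segment(matrix(rnorm(4 * 3000), 4, 3000), 500)
  g <- gfp(seg)
  sc <- sliding_covariances(seg, g, 35)
  ds <- distance_series(seg, sc$matrices[[1]], g, 35)
  expect_equal(ds$values[1], 0, tolerance = 1e-10)
  expect_true(all(ds$values >= 0))
  # doubled channel variances sit farther from the reference than the
  # matched-statistics segment does
  ref <- reference_matrix(sc$matrices)
  seg2 <- mc_segment(seg$samples * 2, 500)
  ds2 <- distance_series(seg2, ref, gfp(seg2), 35)
  expect_gt(mean(ds2$values), mean(distance_series(seg, ref, g, 35)$values))
})

test_that("derivative thresholds detect constructed steps with the 0.1 rule", {
  mk <- function(values) structure(list(values = values,
                                        times = seq_along(values) * 0.02,
                                        times_end = seq_along(values) * 0.02),
                                   class = "distance_series")
  # constant series: no candidate, trial excluded
  od <- detect_onset(mk(rep(2, 40)))
  expect_true(od$excluded)
  expect_false(od$adjusted_by_plr)
  # small step (0.05 < 0.1 across flanking troughs): detected, not adjusted
  small <- c(rep(1, 20), rep(1.05, 20))
  od1 <- detect_onset(mk(small))
  expect_false(od1$excluded)
  expect_equal(od1$detected_index, 21L)
  expect_false(od1$adjusted_by_plr)
  # large step (0.15 >= 0.1): flagged for pupil adjustment
  od2 <- detect_onset(mk(c(rep(1, 20), rep(1.15, 20))))
  expect_false(od2$excluded)
  expect_true(od2$adjusted_by_plr)
  expect_error(detect_onset(mk(rep(1, 5))), "short")
})

test_that("pupil fallback finds constrictions and ignores flat traces", {
  s <- pattern_schedule()
  flat <- normalize_pupil(pupil_trial(rep(4, 200), rep(4, 200), rate = 30,
                                      t0 = -1))
  expect_true(is.na(plr_fallback_onset(flat)))
  zero_gain <- synth_pupil_trial(synth_config(seed = 84,
                                              plr_constriction_gain = 0,
                                              blink_rate = 0), s, 1, seed = 2)
  expect_true(is.na(plr_fallback_onset(normalize_pupil(zero_gain))))
  gazed <- synth_pupil_trial(synth_config(seed = 84, blink_rate = 0), s, 1,
                             window = c(-1, 6.5), seed = 3)
  est <- plr_fallback_onset(normalize_pupil(gazed), expected_start = -0.5)
  expect_false(is.na(est))
  expect_gte(est, -0.1)
  expect_lte(est, 0.5)
})

test_that("epoch pair defaults cover rest, task and post-task ranges", {
  p <- default_epoch_pairs()
  expect_length(p, 3)
  expect_equal(p[[2]]$ref_range, c(-3, 0))
  expect_equal(p[[2]]$target_range, c(0, 5))
  expect_equal(p[[3]]$target_range, c(5, 8))
})
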