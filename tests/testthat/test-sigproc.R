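test_that("rereferencing subtracts the reference row and drops it", {
  set.seed(1)
  x <- matrix(rnorm(3 * 50), 3, 50, dimnames = list(c("O1", "O2", "Cz"), NULL))
  seg <- mc_segment(x, 500)
  out <- rereference(seg, "Cz")
  expect_equal(out$channel_labels, c("O1", "O2"))
  expect_equal(out$samples, sweep(x[1:2, ], 2, x[3, ], "-"))
  # constant case: O1 = 2, Cz = 0.5 -> 1.5
  cseg <- mc_segment(rbind(O1 = rep(2, 10), Cz = rep(0.5, 10)), 500)
  expect_equal(unname(rereference(cseg, "Cz")$samples[1, ]), rep(1.5, 10))
  expect_error(rereference(seg, "Pz"), "O1")
})

test_that("band-pass attenuates out-of-band tones and passes in-band ones", {
  t <- (0:4999) / 500
  tone <- function(f) mc_segment(rbind(a = sin(2 * pi * f * t)), 500)
  rms <- function(seg) sqrt(mean(seg$samples^2))
  for (family in c("butterworth", "elliptic")) {
    hi <- bandpass(tone(100), 2, 30, family, 3)
    expect_lt(rms(hi) / rms(tone(100)), 0.05)
    mid <- bandpass(tone(10), 2, 30, family, 3)
    expect_gt(rms(mid) / rms(tone(10)), 0.9)
  }
  z <- bandpass(mc_segment(rbind(a = rep(0, 100)), 500), 2, 30)
  expect_equal(max(abs(z$samples)), 0)
  expect_error(bandpass(tone(10), 2, 300), "Nyquist")
})

test_that("band-pass filtering is linear", {
  set.seed(7)
  x <- rnorm(1000); y <- rnorm(1000)
  f <- function(v) bandpass(mc_segment(rbind(a = v), 500), 2, 30)$samples[1, ]
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-8)
})

test_that("GFP matches hand computation and is offset-invariant", {
  # all channels equal -> zero field
  eq <- mc_segment(matrix(1, 4, 20), 500)
  expect_equal(max(gfp(eq)$values), 0)
  # channels (1, -1): sqrt(((1-0)^2 + (-1-0)^2)/2) = 1
  pm <- mc_segment(matrix(c(1, -1), 2, 20), 500)
  expect_equal(gfp(pm)$values, rep(1, 20))
  pm8 <- mc_segment(matrix(rep(c(1, -1), 4), 8, 20), 500)
  expect_equal(gfp(pm8)$values, rep(1, 20))
  set.seed(2)
  x <- matrix(rnorm(8 * 100), 8, 100)
  g1 <- gfp(mc_segment(x, 500))
  g2 <- gfp(mc_segment(x + 5, 500))  # common offset to every channel
  expect_equal(g1$values, g2$values, tolerance = 1e-12)
  expect_identical(g1$trough_indices, g2$trough_indices)
})

test_that("GFP troughs are strict local minima with deterministic plateaus", {
  v <- c(3, 1, 2, 2, 1, 1, 2, 3)
  # build a 2-channel segment whose GFP equals v
  seg <- mc_segment(rbind(v, -v), 500)
  g <- gfp(seg)
  expect_equal(g$values, v)
  expect_true(all(g$values[g$trough_indices] <=
                    g$values[g$trough_indices - 1]))
  expect_true(2 %in% g$trough_indices)   # strict minimum
  expect_true(5 %in% g$trough_indices)   # plateau resolved to first sample
  expect_false(6 %in% g$trough_indices)
})

test_that("covariance matches the uncentered product and the SPD contract", {
  # zero matrix with ridge
  z <- mc_segment(matrix(0, 2, 10), 500)
  expect_equal(unname(unclass(covariance(z, 1e-6))), diag(1e-6, 2))
  # hand product, N - 1 = 1
  h <- mc_segment(matrix(c(1, -1, 1, -1), 2, 2, byrow = TRUE), 500)
  expect_equal(unname(unclass(covariance(h))), matrix(2, 2, 2))
  # brute-force product on a random segment
  set.seed(3)
  x <- matrix(rnorm(8 * 500), 8, 500)
  seg <- mc_segment(x, 500)
  expect_equal(unname(unclass(covariance(seg))), x %*% t(x) / 499,
               tolerance = 1e-12)
  # PSD always; strictly PD with ridge
  for (i in 1:5) {
    set.seed(i)
    s <- covariance(mc_segment(matrix(rnorm(4 * 30), 4, 30), 500),
                    regularization = 1e-8, relative = TRUE)
    expect_silent(assert_spd(s))
  }
})

test_that("epoching uses a half-open window on the sample grid", {
  set.seed(4)
  seg <- mc_segment(matrix(rnorm(2 * 2500), 2, 2500), 500, t0 = 0)
  ep <- epoch(seg, c(0.5, 2.0, 4.0), window_ms = c(-100, 350))
  expect_length(ep$epochs, 3)
  expect_true(all(vapply(ep$epochs, function(e) ncol(e$samples), 0) == 225))
  expect_equal(ep$epochs[[1]]$t0, 0.4)
  # an event too close to the segment start is dropped and counted
  ep2 <- epoch(seg, c(0.05, 2.0), window_ms = c(-100, 350))
  expect_length(ep2$epochs, 1)
  expect_equal(ep2$n_dropped, 1L)
  expect_warning(epoch(seg, c(-3, 10), window_ms = c(-100, 350)), "outside")
})
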