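test_that("threshold walk matches the hand-traced example", {
  rv <- c(0, 0, 10, 100, 10, 0, 0)
  expect_equal(find_onset(rv, peak = 4), 3L)
  expect_equal(find_end(rv, peak = 4), 5L)
})

test_that("boundary rules apply when speed never crosses the threshold", {
  rv <- c(6, 7, 8, 9, 100)
  expect_equal(find_onset(rv, peak = 5), 1L) # always supra-threshold
  expect_equal(find_end(rv, peak = 5), 5L) # monotone rising
  expect_error(find_onset(numeric(0)), "empty")
  expect_error(find_end(numeric(0)), "empty")
})

test_that("segmentation is invariant to uniform speed scaling", {
  set.seed(31)
  for (i in 1:20) {
    rv <- reach_speed(render_reach(A = runif(1, 4, 12), dur = runif(1, 0.5, 1.2),
                                   t0 = runif(1, 0.5, 1.2),
                                   noise_sd = 0.02))
    c1 <- runif(1, 0.01, 100)
    expect_identical(find_onset(rv), find_onset(c1 * rv))
    expect_identical(find_end(rv), find_end(c1 * rv))
  }
})

test_that("detected crossings match the analytic 5% crossing of a minimum-jerk bell", {
  # closed-form speed v(tau) ~ 30 tau^2 (1-tau)^2; find the continuous 5%
  # crossings by dense root bracketing, independently of the detector
  fs <- 100
  vshape <- function(tau) 30 * tau^2 * (1 - tau)^2
  vmax <- vshape(0.5)
  lo <- uniroot(function(u) vshape(u) - 0.05 * vmax, c(1e-6, 0.5))$root
  hi <- 1 - lo
  for (dur in c(0.7, 1.0, 1.3)) {
    t0 <- 0.8
    rv <- reach_speed(render_reach(A = 9, dur = dur, t0 = t0))
    onset_true <- (t0 + lo * dur) * fs + 1
    end_true <- (t0 + hi * dur) * fs + 1
    expect_lt(abs(find_onset(rv) - onset_true), 2.0)
    expect_lt(abs(find_end(rv) - end_true), 2.0)
  }
})

test_that("onward segmentation covers the main movement, not a tiny early twitch", {
  fs <- 100
  n <- 300
  # main reach plus an early twitch of 3% of the main amplitude
  main <- minimum_jerk(0, 8, 1.2, 1.0, fs, n)
  twitch <- minimum_jerk(0, 0.24, 0.3, 0.2, fs, n)
  xyz <- matrix(c(2, 3, 1), n, 3, byrow = TRUE) +
    outer(main + twitch, c(1, 0, 0))
  Pf <- cbind(lowpass(xyz[, 1], fs), lowpass(xyz[, 2], fs), lowpass(xyz[, 3], fs))
  ks <- list(rd = resultant_displacement(Pf, Pf[1, ]),
             rv = resultant_velocity(Pf, fs = fs), fs = fs)
  seg <- segment_onward(ks)
  expect_false(seg$fallback)
  expect_gt(seg$onset, 0.9 * fs) # after the twitch
  expect_gt(ks$rd[seg$end] - ks$rd[seg$onset], 0.95 * 8)
})

test_that("implausible primary segments trigger the flagged fallback", {
  fs <- 100
  n <- 300
  # genuine movement, plus a one-sample spike that becomes the global peak
  path <- minimum_jerk(0, 6, 1.0, 1.0, fs, n)
  rv <- abs(stencil_derivative(path, fs))
  rd <- path
  rv[20] <- max(rv) * 10
  seg <- segment_onward(list(rd = rd, rv = rv, fs = fs))
  expect_true(seg$fallback)
  # fallback lands on the genuine movement, not the spike: the recovered
  # segment sits inside the movement window and carries most of the path
  expect_gt(seg$onset, 100)
  expect_lt(seg$end, 201)
  expect_gt(rd[seg$end] - rd[seg$onset], 0.8 * 6)
})

test_that("zero speed profiles raise the no-movement error", {
  ks <- list(rd = rep(1, 50), rv = rep(0, 50), fs = 100)
  expect_error(segment_onward(ks), "no movement detected")
})

test_that("resampling to 100 points preserves linearity, identity and endpoints", {
  # linear ramp stays a ramp with exact endpoints
  prof <- seq(0, 1, length.out = 151)
  out <- resample_100(prof, 26, 125)
  expect_equal(out, seq(prof[26], prof[125], length.out = 100))

  # a segment of exactly 100 samples is returned unchanged
  prof <- rnorm(300)
  expect_equal(resample_100(prof, 51, 150), prof[51:150])

  # endpoints exact for arbitrary profiles
  out <- resample_100(prof, 10, 250)
  expect_identical(out[1], prof[10])
  expect_identical(out[100], prof[250])

  expect_error(resample_100(prof, 10, 11), "degenerate")
})

test_that("resampled minimum-jerk displacement tracks the closed form", {
  fs <- 100
  n <- 300
  A <- 7
  t0 <- 0.8
  dur <- 1.2
  rd <- minimum_jerk(0, A, t0, dur, fs, n)
  onset <- round(t0 * fs) + 1L
  end <- round((t0 + dur) * fs) + 1L
  out <- resample_100(rd, onset, end)
  tau <- seq(onset - 1, end - 1, length.out = 100) / fs
  tau <- pmin(pmax((tau - t0) / dur, 0), 1)
  truth <- A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  expect_lt(max(abs(out - truth)), 1e-3 * A)
})
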