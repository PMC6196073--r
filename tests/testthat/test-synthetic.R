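test_that("minimum-jerk trajectories satisfy the closed-form landmarks", {
  fs <- 100
  n <- 300
  expect_equal(minimum_jerk(2, 2, 0.5, 1, fs, n), rep(2, n))

  # midpoint symmetry of the quintic
  x <- minimum_jerk(1, 7, 0.5, 1, fs, n)
  expect_equal(x[0.5 * fs + 1 + 50], 1 + 0.5 * (7 - 1))

  # peak speed 1.875 * amplitude / duration at the midpoint
  dur <- 0.8
  x <- minimum_jerk(0, 6, 1, dur, fs, n)
  v <- stencil_derivative(x, fs)
  expect_equal(max(v), 1.875 * 6 / dur, tolerance = 1e-4)
  expect_equal(which.max(v), round((1 + dur / 2) * fs) + 1L, tolerance = 1)

  expect_error(minimum_jerk(0, 1, -0.1, 1, fs, n), "invalid window")
  expect_error(minimum_jerk(0, 1, 2.5, 1, fs, n), "invalid window")
})

test_that("submovement superposition reduces to and extends minimum jerk", {
  fs <- 100
  n <- 300
  one <- compose_submovements(list(list(x0 = 1, xf = 5, t0 = 0.5, dur = 1)),
                              fs, n)
  expect_equal(one, minimum_jerk(1, 5, 0.5, 1, fs, n))

  # two non-overlapping equal submovements: total displacement adds
  two <- compose_submovements(list(
    list(x0 = 0, xf = 3, t0 = 0.3, dur = 0.8),
    list(x0 = 0, xf = 3, t0 = 1.6, dur = 0.8)
  ), fs, n)
  expect_equal(two[n] - two[1], 6)

  # well-separated submovements give a two-peaked speed profile
  v <- stencil_derivative(two, fs)
  localmax <- which(diff(sign(diff(v))) == -2) + 1
  big <- localmax[v[localmax] > 0.5 * max(v)]
  expect_length(big, 2L)

  expect_error(compose_submovements(list(), fs, n), "non-empty")
})

test_that("default maps encode the reported effect directions", {
  rm <- default_ratio_map()
  expect_equal(nrow(rm), 12L)
  expect_true(all(rm$r > 0 & rm$r < 1))
  # r increases distal -> proximal within each finger
  for (f in unique(rm$finger)) {
    rr <- rm$r[rm$finger == f][match(c("distal", "middle", "proximal"),
                                     rm$phalanx[rm$finger == f])]
    expect_true(all(diff(rr) > 0))
  }
  # r increases index -> little within each phalanx
  for (p in unique(rm$phalanx)) {
    rr <- rm$r[rm$phalanx == p][match(c("index", "middle", "ring", "little"),
                                      rm$finger[rm$phalanx == p])]
    expect_true(all(diff(rr) > 0))
  }

  sm <- default_submovement_map()
  expect_true(all(sm$thumb_submovements == 1L))
  expect_true(all(sm$finger_submovements > sm$thumb_submovements))
  expect_true(all(sm$finger_submovements <= 4L))
})

test_that("simulation configuration rejects inconsistent settings", {
  expect_error(sim_config(amplitude_total = 50), "hand-scale")
  expect_error(sim_config(duration = 1), "does not fit")
  expect_error(sim_config(ratio_map = data.frame(code = "ID", r = 0.5)),
               "ratio_map")
  expect_error(sim_config(submovement_map = submovement_map_constant(5),
                          submovement_gap = 0.25),
               "too dense|overlap")
  expect_error(pipeline_config(bogus_key = 1), "unknown config key")
})

test_that("sessions are deterministic under a seed and block randomized", {
  cfg <- tiny_cfg(seed = 61L)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$recordings[[7]]$positions, s2$recordings[[7]]$positions)

  s3 <- simulate_session(tiny_cfg(seed = 62L))
  expect_false(identical(s1$recordings[[1]]$positions,
                         s3$recordings[[1]]$positions))

  # 2 participants x 12 tasks x 2 trials
  expect_length(s1$recordings, 48L)
  expect_equal(nrow(s1$truth), 48L)
  expect_equal(nrow(s1$manifest), 48L)
  # every participant performs every task exactly trials_per_task times,
  # and each block of 12 is a permutation of the task set
  for (p in unique(s1$manifest$participant)) {
    tasks <- s1$manifest$task[s1$manifest$participant == p]
    expect_equal(unname(table(tasks)), rep(2L, 12L), ignore_attr = TRUE)
    expect_setequal(tasks[1:12], task_grid()$code)
  }
  # ground truth is internally consistent
  expect_true(all(s1$truth$onset_s < s1$truth$end_s))
  expect_true(all(s1$truth$end_s < cfg$duration))
  expect_equal(s1$truth$thumb_displacement /
                 (s1$truth$thumb_displacement + s1$truth$finger_displacement),
               s1$truth$r)
})

test_that("single trials expose recorded ground truth and full sensor sets", {
  cfg <- sim_config(seed = 63L)
  set.seed(63)
  tr <- simulate_trial("ring", "proximal", cfg)
  expect_s3_class(tr$recording, "trial_recording")
  expect_setequal(names(tr$recording$positions), sensor_ids())
  expect_equal(tr$recording$n_samples, 300L)
  expect_equal(tr$truth$task, "RP")
  expect_gt(tr$truth$r, 0.5) # proximal targets are thumb dominated
  expect_equal(tr$truth$finger_submovements, 4L)
})
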