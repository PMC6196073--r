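test_that("participant means match an independent groupby oracle", {
  cfg <- tiny_cfg(seed = 51L)
  res <- simulate_and_analyze(cfg)$results
  pm <- participant_means(res)

  # single trial per cell: means equal the trials
  key <- unique(as.data.frame(res)[, c("participant", "task", "trial")])
  sel <- key$trial[!duplicated(key[, c("participant", "task")])]
  one <- res[res$trial %in% sel, ]
  pm1 <- participant_means(one)
  expect_equal(nrow(pm1), nrow(one))
  expect_equal(sort(pm1$value), sort(one$value))

  # independent oracle via aggregate on the full table
  agg <- stats::aggregate(value ~ participant + task + effector + measure,
                          data = as.data.frame(res), FUN = mean)
  m <- merge(as.data.frame(pm), agg,
             by = c("participant", "task", "effector", "measure"))
  expect_equal(m$value.x, m$value.y)

  # identical trials give the common value
  rep15 <- data.frame(
    participant = "P01", task = "ID", trial = 1:15,
    effector = "thumb", measure = "D", value = 0.7
  )
  expect_equal(participant_means(rep15)$value, 0.7)
})

test_that("two-level effector ANOVA equals the squared paired t-test", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    d <- data.frame(
      participant = rep(sprintf("P%02d", 1:n), 2),
      effector = rep(c("thumb", "finger"), each = n),
      value = rnorm(2 * n)
    )
    a <- rm_anova_effector(d)
    tt <- t.test(d$value[d$effector == "thumb"],
                 d$value[d$effector == "finger"], paired = TRUE)
    expect_equal(a$f_value, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(a$epsilon_hf, 1)
  }
  # identical thumb and finger values: F = 0, p = 1
  d <- data.frame(participant = rep(sprintf("P%d", 1:6), 2),
                  effector = rep(c("thumb", "finger"), each = 6),
                  value = rep(rnorm(6), 2))
  a <- rm_anova_effector(d)
  expect_equal(a$f_value, 0)
  expect_equal(a$p_value, 1)
})

test_that("two-way RM-ANOVA matches aov and car on random data", {
  set.seed(53)
  n <- 8
  Y <- matrix(rnorm(n * 12), n)
  cells <- .mk_cells(Y)
  res <- rm_anova_2way(cells)

  df <- cells
  df$participant <- factor(df$participant)
  df$finger <- factor(df$finger, FINGERS_T)
  df$phalanx <- factor(df$phalanx, PHAL_T)
  a <- summary(aov(value ~ finger * phalanx + Error(participant / (finger * phalanx)),
                   data = df))
  f_aov <- c(
    a[["Error: participant:finger"]][[1]]$`F value`[1],
    a[["Error: participant:phalanx"]][[1]]$`F value`[1],
    a[["Error: participant:finger:phalanx"]][[1]]$`F value`[1]
  )
  expect_equal(res$f_value, f_aov, tolerance = 1e-10)

  idata <- data.frame(finger = factor(rep(FINGERS_T, each = 3), FINGERS_T),
                      phalanx = factor(rep(PHAL_T, 4), PHAL_T))
  # car warns when its raw HF estimate exceeds 1 before clipping
  s <- suppressWarnings(
    summary(car::Anova(lm(Y ~ 1), idata = idata,
                       idesign = ~ finger * phalanx, type = 3),
            multivariate = FALSE)
  )
  adj <- s$pval.adjustments
  expect_equal(res$epsilon_gg, unname(adj[, "GG eps"]), tolerance = 1e-10)
  expect_equal(res$epsilon_hf, pmin(1, unname(adj[, "HF eps"])), tolerance = 1e-10)
  expect_equal(res$p_value, unname(adj[, "Pr(>F[HF])"]), tolerance = 1e-10)
})

test_that("sums of squares are conserved and F is shift/scale invariant", {
  set.seed(54)
  Y <- matrix(rnorm(6 * 12), 6)
  res <- rm_anova_2way(.mk_cells(Y))
  parts <- sum(res$ss_effect) + sum(res$ss_error) + attr(res, "ss_participant")
  expect_equal(parts, attr(res, "ss_total"), tolerance = 1e-12)

  res2 <- rm_anova_2way(.mk_cells(3.7 * Y + 11))
  expect_equal(res2$f_value, res$f_value, tolerance = 1e-10)
  expect_equal(res2$epsilon_hf, res$epsilon_hf, tolerance = 1e-10)
})

test_that("zero-variance data yield F = 0 for every effect", {
  Y <- matrix(2.5, 5, 12)
  res <- rm_anova_2way(.mk_cells(Y))
  expect_equal(res$f_value, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
})

test_that("Huynh-Feldt epsilon behaves across sphericity regimes", {
  # two levels: epsilon is exactly 1
  set.seed(55)
  expect_equal(huynh_feldt_epsilon(matrix(rnorm(20), 10, 2)), 1)

  # compound symmetry at large n: epsilon near 1
  n <- 200
  k <- 4
  subj <- rnorm(n, 0, 2)
  Y <- matrix(rnorm(n * k), n) + subj
  expect_gt(huynh_feldt_epsilon(Y), 0.95)

  # strongly non-spherical: epsilon stays above the 1/(k-1) floor
  Y <- cbind(rnorm(12, 0, 10), matrix(rnorm(12 * 3, 0, 0.01), 12))
  eps <- huynh_feldt_epsilon(Y)
  expect_gte(eps, 1 / (k - 1) - 1e-9)
  expect_lt(eps, 1)

  # adjusted p is never smaller than the unadjusted p when epsilon < 1
  set.seed(56)
  Y <- matrix(rnorm(8 * 12), 8) %*% diag(c(rep(3, 4), rep(1, 8)))
  res <- rm_anova_2way(.mk_cells(Y))
  p_un <- with(res, pf(f_value, df_effect, df_error, lower.tail = FALSE))
  expect_true(all(res$p_value >= p_un - 1e-12))

  expect_warning(huynh_feldt_epsilon(matrix(rnorm(3 * 5), 3, 5)), "singular")
})

test_that("post-hoc pairwise comparisons honor the correction contract", {
  set.seed(57)
  n <- 8
  # identical levels: all adjusted p = 1
  d0 <- data.frame(participant = rep(sprintf("P%d", 1:n), 3),
                   phalanx = rep(PHAL_T, each = n),
                   value = rep(rnorm(n), 3))
  ph0 <- posthoc_pairwise(d0, "phalanx")
  expect_equal(ph0$p_adjusted, rep(1, 3))

  # adjusted >= raw, always
  d1 <- data.frame(participant = rep(sprintf("P%d", 1:n), 3),
                   phalanx = rep(PHAL_T, each = n),
                   value = rnorm(3 * n))
  ph1 <- posthoc_pairwise(d1, "phalanx")
  expect_true(all(ph1$p_adjusted >= ph1$p_raw))

  # a strong monotone distal > middle > proximal effect: all three pairs
  # significant at 0.001 (effect 1.0 per step, noise sd 0.05, n = 8)
  eff <- c(distal = 2, middle = 1, proximal = 0)
  d2 <- data.frame(participant = rep(sprintf("P%d", 1:n), 3),
                   phalanx = rep(PHAL_T, each = n),
                   value = eff[rep(PHAL_T, each = n)] + rnorm(3 * n, 0, 0.05))
  ph2 <- posthoc_pairwise(d2, "phalanx")
  expect_true(all(ph2$p_adjusted < 0.001))
  # ordering information: distal minus middle and middle minus proximal positive
  expect_true(all(ph2$mean_diff > 0))

  # Holm is available and never exceeds Bonferroni
  ph3 <- posthoc_pairwise(d1, "phalanx", method = "holm")
  expect_true(all(ph3$p_adjusted <= ph1$p_adjusted + 1e-12))
})
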