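test_that("phase extrema of simple signals", {
  tt <- seq(0, 10, by = 0.01)
  s <- sin(2 * pi * tt / 10)
  ex <- phase_extrema(tt, 3 * s, c(0, 10))
  expect_equal(ex$min, -3, tolerance = 1e-4)
  expect_equal(ex$max, 3, tolerance = 1e-4)
  z <- phase_extrema(tt, rep(0, length(tt)), c(0, 10))
  expect_equal(c(z$min, z$max), c(0, 0))
  expect_error(phase_extrema(tt, s, c(20, 30)), "empty")
})

test_that("occlusion AUC is a signed trapezoidal integral", {
  tt <- seq(0, 100, by = 0.1)
  y <- rep(-10, length(tt))
  expect_equal(occlusion_auc(tt, y, c(0, 100)), -1000)
  # linearity
  set.seed(2)
  r <- cumsum(rnorm(length(tt)))
  expect_equal(occlusion_auc(tt, 2 * r, c(10, 90)),
               2 * occlusion_auc(tt, r, c(10, 90)))
  expect_error(occlusion_auc(tt, y, c(50, 50.05)), "2 samples")
})

test_that("AUC is additive over a split at any interior point", {
  set.seed(3)
  tt <- seq(0, 60, by = 0.1)
  y <- cumsum(rnorm(length(tt)))
  for (cut in c(7.3, 20, 41.14)) {
    expect_equal(auc_between(tt, y, 0, cut) + auc_between(tt, y, cut, 60),
                 auc_between(tt, y, 0, 60), tolerance = 1e-9)
  }
})

test_that("PORH AUC integrates between interpolated bounds", {
  tt <- seq(0, 20, by = 0.1)
  tri <- 10 - abs(tt - 10)  # triangle 0 -> 10 -> 0 over 20 s
  expect_equal(porh_auc(tt, tri, 0, 20), 100)
  expect_equal(porh_auc(tt, tri, 5, 5), 0)
  expect_error(porh_auc(tt, tri, 10, 5), "inverted")

  # exponential spike: integral from onset to the 63% decay point is
  # A * tau * 0.63 (analytic)
  t2 <- seq(0, 300, by = 0.1)
  y <- 10 * exp(-t2 / 20)
  t63 <- 20 * log(1 / 0.37)
  expect_equal(porh_auc(t2, y, 0, t63), 10 * 20 * 0.63, tolerance = 0.05)
})

test_that("63% time constants match proportionality and root-finding oracles", {
  tt <- seq(0, 420, by = 0.1)
  ramp <- tt / 420 * 30
  expect_equal(time_constant_63(tt, ramp, c(0, 420), "rise")$tau,
               0.63 * 420, tolerance = 0.1)

  # independent oracle: solve 1 - exp(-t/60) = 0.63 * (1 - exp(-420/60))
  y <- 25 * (1 - exp(-tt / 60))
  oracle <- uniroot(function(t) (1 - exp(-t / 60)) -
                      0.63 * (1 - exp(-420 / 60)), c(1, 419))$root
  expect_equal(time_constant_63(tt, y, c(0, 420), "rise")$tau, oracle,
               tolerance = 0.1)

  step <- ifelse(tt >= 100, 12, 0)
  expect_equal(time_constant_63(tt, step, c(0, 420), "rise")$tau, 100,
               tolerance = 0.1)
  # falling direction mirrors the rising one
  expect_equal(time_constant_63(tt, -y, c(0, 420), "fall")$tau,
               time_constant_63(tt, y, c(0, 420), "rise")$tau)
  expect_true(time_constant_63(tt, rep(0, length(tt)),
                               c(0, 420), "rise")$flagged)
})

test_that("30-s slopes agree with OLS theory", {
  tt <- seq(0, 100, by = 0.1)
  expect_equal(slope_30s(tt, 0.1 * tt, 10)$slope, 0.1, tolerance = 1e-12)
  expect_equal(slope_30s(tt, rep(4, length(tt)), 10)$slope, 0)
  expect_true(slope_30s(tt, tt, 90)$flagged)    # < 30 s of data remain
  expect_true(slope_30s(tt, tt, NA)$flagged)

  # noisy ramp: estimate within 3 SE of the truth (OLS sampling theory)
  set.seed(4)
  idx <- tt >= 10 & tt <= 40
  sigma <- 0.5
  y <- 0.2 * tt + rnorm(length(tt), 0, sigma)
  se <- sigma / sqrt(sum((tt[idx] - mean(tt[idx]))^2))
  expect_lt(abs(slope_30s(tt, y, 10)$slope - 0.2), 3 * se)
})

test_that("cycle averaging uses only non-flagged cycles", {
  cyc <- data.frame(cycle = 1:3, tsi_min = c(1, 2, 3),
                    tsi_auc_porh = c(10, NA, 30))
  avg <- average_cycles(cyc)
  expect_equal(avg$tsi_min, 2)
  expect_equal(avg$tsi_auc_porh, 20)
  expect_equal(attr(avg, "counts")[["tsi_auc_porh"]], 2L)

  same <- data.frame(cycle = 1:3, x = c(5, 5, 5))
  expect_equal(average_cycles(same)$x, 5)

  allna <- data.frame(cycle = 1:3, x = c(NA_real_, NA, NA))
  expect_message(out <- average_cycles(allna), "missing in all cycles")
  expect_true(is.na(out$x))
})

test_that("ankle-brachial index is the ratio of highest pressures", {
  expect_equal(compute_abi(c(120, 118), c(116, 114)), 120 / 116)
  expect_equal(compute_abi(120, 120), 1)
  expect_error(compute_abi(numeric(), 120), "non-empty")
  expect_error(compute_abi(c(120, -3), 120), "positive")
})

test_that("offsets removed by normalization do not affect tau or slopes", {
  sch <- mini_schedule()
  p <- mini_params(cuff_pressure = 250, sbp = 118)
  sim <- simulate_session(p, sch)
  shifted <- sim
  shifted$recording$data$tsi <- shifted$recording$data$tsi + 0  # no-op
  shifted$recording$data$o2hb <- shifted$recording$data$o2hb + 12.5
  shifted$recording$data$hhb <- shifted$recording$data$hhb - 3.1
  a <- extract_noiseless(sim, sch)$features
  b <- extract_noiseless(shifted, sch)$features
  for (col in c("o2hb_tau", "hhb_tau", "o2hb_slope_deoxy",
                "hhb_slope_reoxy")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-9)
  }
})
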