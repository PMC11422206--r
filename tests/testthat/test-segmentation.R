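triangle <- function() {
  tt <- seq(0, 100, by = 0.1)
  list(t = tt, y = 10 - abs(tt - 50) / 5)  # 0 -> 10 at 50 s -> 0
}

test_that("curve bounds sit at the 10% crossings of a triangle", {
  tr <- triangle()
  # independent oracle: y = t/5 crosses 0.1 * 10 = 1 at t = 5; symmetric at 95
  b <- detect_curve_bounds(tr$t, tr$y, c(0, 100))
  expect_equal(b$peak, 50)
  expect_equal(b$start, 5, tolerance = 1e-9)
  expect_equal(b$end, 95, tolerance = 1e-9)
  expect_false(b$no_event || b$end_fallback)
})

test_that("flat windows yield no event and plateaus end at the window end", {
  tt <- seq(0, 100, by = 0.1)
  z <- detect_curve_bounds(tt, rep(0, length(tt)), c(0, 100))
  expect_true(z$no_event)

  step <- ifelse(tt >= 30, 8, 0)  # rises, never returns
  s <- detect_curve_bounds(tt, step, c(0, 100))
  expect_equal(s$end, 100)
  expect_true(s$end_fallback)
})

test_that("curve bounds are invariant to positive rescaling", {
  set.seed(11)
  tt <- seq(0, 60, by = 0.1)
  y <- splinefun(seq(0, 60, by = 10), c(0, 1, 6, 9, 4, 1, 0))(tt)
  ref <- detect_curve_bounds(tt, y, c(0, 60))
  for (k in c(0.01, 3, 250)) {
    b <- detect_curve_bounds(tt, k * y, c(0, 60))
    expect_equal(c(b$start, b$peak, b$end), c(ref$start, ref$peak, ref$end))
  }
})

test_that("spike detection takes the earliest global maximum", {
  tt <- seq(0, 200, by = 0.1)
  y <- exp(-(tt - 30)^2 / 50) + exp(-(tt - 90)^2 / 50)  # two equal peaks
  sp <- find_spike(tt, y, c(0, 200), horizon_s = 200)
  expect_equal(sp$spike_time, 30, tolerance = 0.1)

  neg <- find_spike(tt, -1 - 0 * tt, c(0, 200))
  expect_true(neg$no_hyperemia)

  # the search horizon truncates the window
  late <- ifelse(tt > 150, 5, 0)
  sp2 <- find_spike(tt, late, c(0, 200), horizon_s = 120)
  expect_true(sp2$no_hyperemia)  # the late rise is outside the horizon
})

test_that("zero crossing is interpolated left of the spike", {
  tt <- seq(0, 100, by = 0.1)
  zc <- zero_crossing_before(tt, tt - 50, spike_time = 100, window_start = 0)
  expect_equal(zc$time, 50, tolerance = 1e-9)
  expect_false(zc$fallback)

  expect_warning(
    alw <- zero_crossing_before(tt, tt + 1, spike_time = 100,
                                window_start = 0),
    "window start")
  expect_equal(alw$time, 0)
  expect_true(alw$fallback)
})

test_that("63% spike decay matches analytic solutions", {
  tt <- seq(0, 300, by = 0.1)
  # exponential decay tau = 20: crossing at t = 20 * log(1/0.37)
  y <- 10 * exp(-tt / 20)
  d <- decay63_after(tt, y, spike_time = 0, spike_value = 10,
                     phase_end = 300)
  expect_equal(d$time, 20 * log(1 / 0.37), tolerance = 0.05)

  lin <- pmax(10 * (1 - tt / 100), 0)  # linear decay over 100 s
  dl <- decay63_after(tt, lin, 0, 10, 300)
  expect_equal(dl$time, 63, tolerance = 1e-6)

  const <- rep(10, length(tt))
  dc <- decay63_after(tt, const, 0, 10, 300)
  expect_true(dc$fallback)
  expect_equal(dc$time, 300)
  expect_error(decay63_after(tt, y, 0, -1, 300), "positive spike")
})

test_that("marks on a noiseless simulated cycle match the model oracle", {
  sch <- mini_schedule()
  p <- mini_params(cuff_pressure = 250, sbp = 118)
  sim <- simulate_session(p, sch)
  ext <- extract_noiseless(sim, sch)
  tr <- true_cycle_features(p, sch)
  mk <- ext$marks[ext$marks$channel == "tsi", ]
  expect_lt(abs(mk$spike_time - tr$tsi_spike_time), 0.1)
  expect_lt(abs(mk$zero_cross - tr$tsi_zero_cross), 0.1)
  expect_lt(abs(mk$decay63 - tr$tsi_decay63), 0.1)
  expect_lt(abs(mk$deoxy_start - tr$tsi_deoxy_start), 0.1)
  expect_lt(abs(mk$reoxy_start - tr$tsi_reoxy_start), 0.1)
  # the crossing sits shortly after deflation for a complete occlusion
  cyc <- schedule_cycles(sch)
  expect_lt(mk$zero_cross - cyc$occl_end[1], 6 + 30)
})
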