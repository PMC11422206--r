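test_that("occlusion completeness follows the logistic convention", {
  expect_equal(occlusion_completeness(116, 116, 10), 0.5)
  expect_equal(occlusion_completeness(166, 116, 10), 1 / (1 + exp(-5)))
  expect_lt(occlusion_completeness(0, 116, 10), 1e-4)
  # smooth, monotone non-decreasing in cuff pressure
  p <- seq(0, 300, by = 5)
  cc <- occlusion_completeness(p, 118, 10)
  expect_true(all(diff(cc) >= 0))
  expect_true(all(cc >= 0 & cc <= 1))
  expect_error(occlusion_completeness(100, 118, 0), "positive")
})

test_that("pressure rules resolve to cuff pressures", {
  expect_equal(resolve_cuff_pressure("SBP+50", 116), 166)
  expect_equal(resolve_cuff_pressure(250, 116), 250)
  expect_error(resolve_cuff_pressure("half of AOP", 116), "unrecognized")
})

test_that("null response gives flat channels and no hyperemia", {
  p <- mini_params(cuff_pressure = 0, sbp = 500, a_ven = 0, h_amp = 0)
  sim <- simulate_session(p, mini_schedule())
  d <- sim$recording$data
  expect_lt(diff(range(d$hhb)), 1e-9)
  expect_lt(diff(range(d$o2hb)), 1e-9)
  expect_lt(diff(range(d$tsi)), 1e-9)
})

test_that("occlusion kinetics follow the stated exponential", {
  # completeness is 1 to machine precision at overwhelming pressure
  p <- mini_params(cuff_pressure = 10000, sbp = 118, a_ven = 0, a_art = 20,
                   tau_deoxy = 60)
  sch <- build_schedule(baseline_s = 120, occlusion_s = 180,
                        reperfusion_s = 240, cuff_ramp_s = 6)
  sim <- simulate_session(p, sch)
  d <- sim$recording$data
  t0 <- 120
  at <- function(t) d$hhb[which.min(abs(d$time - t))]
  expect_equal(at(t0 + 60), 20 * (1 - exp(-1)), tolerance = 1e-6)
  expect_equal(at(t0 + 120), 20 * (1 - exp(-2)), tolerance = 1e-6)
  # O2Hb mirrors with negative amplitude during occlusion
  expect_equal(at(t0 + 60), -d$o2hb[which.min(abs(d$time - (t0 + 60)))],
               tolerance = 1e-6)
})

test_that("identical seeds yield identical sessions and cohorts", {
  p <- sim_params(cuff_pressure = 168, seed = 42)
  sch <- mini_schedule()
  a <- simulate_session(p, sch)
  b <- simulate_session(p, sch)
  expect_identical(a$recording$data, b$recording$data)
  gs <- list(G2 = list(rule = "SBP+50", n = 2))
  c1 <- simulate_cohort(gs, seed = 7, schedule = sch)
  c2 <- simulate_cohort(gs, seed = 7, schedule = sch)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$recordings[[1]]$data, c2$recordings[[1]]$data)
})

test_that("simulated TSI stays within [0, 100] under default noise", {
  for (cuff in c(50, 168, 250)) {
    p <- sim_params(cuff_pressure = cuff, seed = cuff)
    sim <- simulate_session(p, build_schedule())
    expect_true(all(sim$recording$data$tsi > 0 &
                      sim$recording$data$tsi < 100))
  }
})

test_that("cohort pressure resolution and grouping are correct", {
  sch <- mini_schedule()
  co <- simulate_cohort(list(G2 = list(rule = "SBP+50", n = 3)),
                        seed = 1, schedule = sch,
                        sbp_mean = 116, sbp_sd = 0)
  expect_true(all(co$manifest$cuff_pressure == 166))
  expect_equal(nrow(co$manifest), 6L)  # 3 subjects x 2 sessions
  expect_error(simulate_cohort(list(), seed = 1), "at least one group")
  expect_error(simulate_cohort(list(G1 = list(rule = 50, n = 0)), seed = 1),
               "n >= 1")
})

test_that("venous-only pressures give near-zero occlusion completeness", {
  co <- simulate_cohort(list(G1 = list(rule = 50, n = 8)), seed = 3,
                        schedule = mini_schedule(), params = mini_params())
  expect_true(all(co$truth$completeness < 0.01))
})

test_that("extracted |TSI AUC| is non-decreasing in cuff pressure", {
  sch <- mini_schedule()
  aucs <- vapply(c(50, 110, 170, 250), function(cuff) {
    p <- mini_params(cuff_pressure = cuff, sbp = 118)
    ext <- extract_noiseless(simulate_session(p, sch), sch)
    abs(ext$features$tsi_auc[1])
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(tau_deoxy = 0), "positive")
  expect_error(sim_params(noise_sd = -1), "non-negative")
  expect_error(sim_params(cuff_pressure = -5), "non-negative")
  expect_error(simulate_session(sim_params()), "cuff_pressure")
})
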