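test_that("default protocol has 7 phases totalling 4560 s", {
  sch <- build_schedule()
  expect_equal(nrow(sch), 7L)
  expect_equal(attr(sch, "total_s"), 900 + 3 * 420 + 600 + 600 + 1200)
  expect_equal(sch$label,
               c("baseline", "O1", "R1", "O2", "R2", "O3", "R3"))
  expect_equal(sch$t_end - sch$t_start,
               c(900, 420, 600, 420, 600, 420, 1200))
})

test_that("phases partition [0, total) exactly", {
  for (sch in list(build_schedule(), mini_schedule(),
                   build_schedule(baseline_s = 30, occlusion_s = 10,
                                  reperfusion_s = c(5, 7)))) {
    expect_equal(sch$t_start[1], 0)
    expect_equal(sch$t_start[-1], sch$t_end[-nrow(sch)])
    expect_equal(sch$t_end[nrow(sch)], attr(sch, "total_s"))
  }
})

test_that("baseline-only and custom schedules are accepted", {
  solo <- build_schedule(baseline_s = 600, reperfusion_s = numeric())
  expect_equal(nrow(solo), 1L)
  expect_equal(solo$label, "baseline")
  custom <- as_schedule(data.frame(label = c("baseline", "O1", "R1"),
                                   t_start = c(0, 100, 200),
                                   t_end = c(100, 200, 400)))
  expect_equal(nrow(schedule_cycles(custom)), 1L)
})

test_that("ill-formed schedules are rejected", {
  expect_error(build_schedule(occlusion_s = -10), "positive")
  expect_error(as_schedule(data.frame(label = c("baseline", "O1"),
                                      t_start = c(0, 50),
                                      t_end = c(100, 200))),
               "contiguous|overlap")
  expect_error(as_schedule(data.frame(label = "baseline",
                                      t_start = 10, t_end = 100)),
               "start at t = 0")
})

test_that("cycle windows pair each occlusion with its reperfusion", {
  cyc <- schedule_cycles(build_schedule())
  expect_equal(nrow(cyc), 3L)
  expect_equal(cyc$occl_end, cyc$reperf_start)
  expect_equal(cyc$occl_start, c(900, 1920, 2940))
})
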