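test_that("needle-EMG grading follows the insertion-count bands", {
  expect_equal(grade_myotonic_discharges(c(2, 4, 7, 10)),
               c("0", "1+", "2+", "3+"))
  expect_equal(grade_myotonic_discharges(0), "0")
  expect_equal(grade_myotonic_discharges(3), "1+")
  expect_equal(grade_myotonic_discharges(5), "1+")
  expect_equal(grade_myotonic_discharges(6), "2+")
  expect_equal(grade_myotonic_discharges(9), "2+")
  expect_error(grade_myotonic_discharges(11), "\\[0, 10\\]")
  expect_error(grade_myotonic_discharges(-1), "\\[0, 10\\]")
  expect_error(grade_myotonic_discharges(2.5), "integer")
  # total monotone step function on 0..10
  grades <- grade_myotonic_discharges(0:10)
  ranks <- match(grades, c("0", "1+", "2+", "3+"))
  expect_true(all(diff(ranks) >= 0))
  expect_length(grades, 11)
})

test_that("relaxation time matches the line-crossing closed form", {
  # linear decay from peak 100 at t=0 to 0 at t=1: the 90% -> 5% span
  # covers 85% of the ramp
  tr <- force_trace(force = 100 * (1 - seq(0, 1, by = 0.001)), rate = 1000)
  expect_equal(relaxation_time(tr), 0.85, tolerance = 1e-9)
  # invariance to force-unit rescaling
  tr2 <- force_trace(force = 0.037 * 100 * (1 - seq(0, 1, by = 0.001)),
                     rate = 1000)
  expect_equal(relaxation_time(tr2), relaxation_time(tr), tolerance = 1e-12)
  # coarse sampling still interpolates to the same answer on a line
  tr3 <- force_trace(force = 100 * (1 - seq(0, 1, by = 0.25)), rate = 4)
  expect_equal(relaxation_time(tr3), 0.85, tolerance = 1e-9)
})

test_that("relaxation time handles instantaneous drops and failures", {
  # instantaneous drop between two samples: both crossings interpolate
  # inside one sample interval
  tr <- force_trace(force = c(100, 100, 0, 0), rate = 10)
  expect_lte(relaxation_time(tr), 0.1)
  expect_gte(relaxation_time(tr), 0)
  # plateau at 10% of peak never relaxes
  plateau <- force_trace(force = c(100, 60, 30, 10, 10, 10), rate = 10)
  expect_error(relaxation_time(plateau), "not relaxed")
  flat <- force_trace(force = rep(50, 10), rate = 10)
  expect_error(relaxation_time(flat), "flat")
})

test_that("non-monotone decay uses the last 90% down-crossing", {
  # force rebounds above 90% after the peak before finally relaxing
  f <- c(100, 85, 95, 50, 20, 4, 1)
  tr <- force_trace(force = f, time = 0:6)
  # last down-crossing of 90 is between t=2 (95) and t=3 (50);
  # 5-crossing between t=4 (20) and t=5 (4)
  t90 <- 2 + (90 - 95) / (50 - 95)
  t05 <- 4 + (5 - 20) / (4 - 20)
  expect_equal(relaxation_time(tr), t05 - t90, tolerance = 1e-9)
})

test_that("transient-paresis decline is the percent drop from peak", {
  expect_equal(transient_paresis_decline(
    force_trace(force = rep(80, 40), rate = 10)), 0)
  # linear 100 -> 80 within the window
  tr <- force_trace(force = seq(100, 80, length.out = 31), rate = 10)
  expect_equal(transient_paresis_decline(tr), 20, tolerance = 1e-9)
  # peak at the end of the trace: nothing after it
  end_peak <- force_trace(force = c(10, 50, 100), rate = 1)
  expect_warning(res <- transient_paresis_decline(end_peak), "window end")
  expect_equal(res, 0)
  # decline measured only within the window
  f <- c(100, 95, 90, 85, 40)           # at 1 Hz: last sample outside 3 s
  expect_equal(transient_paresis_decline(force_trace(force = f, rate = 1),
                                         window = 3), 15)
})

test_that("force traces round-trip through both CSV layouts", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(time = seq(0, 1, by = 0.1),
                   force = 100 * (1 - seq(0, 1, by = 0.1)))
  write.csv(df, f, row.names = FALSE)
  tr <- read_force_trace(f)
  expect_equal(tr$force, df$force)
  expect_equal(relaxation_time(tr), 0.85, tolerance = 1e-9)

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("# rate: 10", format(df$force, trim = TRUE)), f2)
  tr2 <- read_force_trace(f2)
  expect_equal(tr2$force, df$force, tolerance = 1e-6)
  expect_equal(diff(tr2$time[1:2]), 0.1)
})
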