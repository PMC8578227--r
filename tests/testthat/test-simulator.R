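# The dynamical PQRST cohort simulator.

test_that("R peaks land where the beat parameters place them", {
  e <- synthesize_beat_train(beat_train(12, rr_interval = 1000))
  pk <- detect_r_peaks(e)
  expect_true(all(abs(diff(pk) - 500) <= 1))
  # analytic peak times attached by the simulator agree with detection
  r_ms <- attr(e, "r_peak_ms")
  inner <- pk[pk > 130 & pk < 4760]
  expect_true(all(abs(inner - (r_ms[seq_along(inner)] / 2 + 1)) <= 1))
})

test_that("zero amplitudes give the zero record and scaling is linear", {
  z <- synthesize_beat_train(beat_train(12, p_amplitude = 0, r_amplitude = 0,
                                        t_amplitude = 0, stj_offset = 0))
  expect_true(all(z$samples == 0))

  e1 <- synthesize_beat_train(beat_train(12))
  e2 <- synthesize_beat_train(beat_train(12, r_amplitude = 2 * 1287))
  pk <- detect_r_peaks(e1)
  for (lead in c("II", "V5")) {
    expect_equal(e2$samples[lead, pk], 2 * e1$samples[lead, pk],
                 tolerance = 1e-9)
  }

  # signal energy scales quadratically with a global amplitude multiplier
  e4 <- synthesize_beat_train(beat_train(12, p_amplitude = 300,
                                         r_amplitude = 3 * 1287,
                                         t_amplitude = 3 * 343,
                                         stj_offset = 6))
  expect_equal(sum(e4$samples^2), 9 * sum(e1$samples^2), tolerance = 1e-9)
})

test_that("invalid beat parameters are rejected", {
  expect_error(synthesize_beat_train(beat_train(12, pr_interval = 100,
                                                p_duration = 120)),
               "pr_interval < p_duration")
  expect_error(synthesize_beat_train(beat_train(2, rr_interval = 1000)),
               "span")
  expect_error(synthesize_beat_train(beat_train(12, qt_interval = 80)),
               "qt_interval")
})

test_that("cohort draws honour their truncation bounds and degenerate sds", {
  set.seed(30)
  spec <- population_spec()
  co <- sample_cohort(spec, 1000, signals = FALSE)
  p <- co$params
  for (nm in c("heart_rate", "p_duration", "qrs_duration", "pr_interval",
               "stj_offset", "r_amplitude", "t_amplitude", "p_amplitude")) {
    l <- spec[[nm]]
    col <- if (nm == "stj_offset") "stj_offset" else nm
    expect_true(all(p[[col]] >= l[3] - 1e-9 & p[[col]] <= l[4] + 1e-9),
                label = paste(nm, "within truncation"))
  }
  expect_true(all(p$qt_interval >= spec$qt_interval[3] - 1e-9))
  expect_true(all(p$qt_interval <= spec$qt_interval[4] + 1e-9))

  dg <- population_spec(heart_rate = c(70, 0, 60, 90),
                        p_duration = c(105, 0, 82, 130),
                        qt_interval = c(395, 0, 352, 436),
                        qrs_duration = c(90, 0, 74, 110),
                        pr_interval = c(156, 0, 120, 198),
                        stj_offset = c(2, 0, -44, 58),
                        r_amplitude = c(1287, 0, 600, 2163),
                        t_amplitude = c(343, 0, 126, 664),
                        p_amplitude = c(100, 0, 50, 150),
                        qt_noise_sd = 0)
  cd <- sample_cohort(dg, 5)
  for (i in 2:5) {
    expect_identical(cd$ecgs[[i]]$samples, cd$ecgs[[1]]$samples)
  }
  expect_error(population_spec(heart_rate = c(70, 8, 90, 60)), "infeasible")
})

test_that("cohort statistics match the population targets", {
  set.seed(31)
  co <- sample_cohort(population_spec(), 1000, signals = FALSE)
  p <- co$params
  # mean heart rate reproduces the cohort target of 70 bpm
  expect_lt(abs(mean(p$heart_rate) - 70), 1)
  # QT/RR coupling induces the positive association seen in normal cohorts
  expect_gt(cor(p$qt_interval, p$rr_interval), 0)
})

test_that("empirical percentiles bracket the calibrated truncated-normal quantiles", {
  set.seed(32)
  spec <- population_spec()
  co <- sample_cohort(spec, 10000, signals = FALSE)
  for (nm in c("p_duration", "pr_interval", "qrs_duration", "r_amplitude")) {
    l <- spec[[nm]]
    cal <- ecggan:::calibrate_truncnorm(l[1], l[2], l[3], l[4])
    q_lo <- ecggan:::qtrunc_norm(0.025, cal[1], cal[2], l[3], l[4])
    q_hi <- ecggan:::qtrunc_norm(0.975, cal[1], cal[2], l[3], l[4])
    emp <- stats::quantile(co$params[[nm]], c(0.025, 0.975), names = FALSE)
    span <- l[4] - l[3]
    expect_lt(abs(emp[1] - q_lo), 0.05 * span)
    expect_lt(abs(emp[2] - q_hi), 0.05 * span)
  }
})

test_that("cohorts round trip through the text interchange format", {
  set.seed(33)
  co <- sample_cohort(population_spec(), 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  files <- list.files(dir, pattern = "^ecg_")
  expect_length(files, 2)
  back <- read_ecg8(file.path(dir, files[1]))
  expect_equal(back$samples, co$ecgs[[1]]$samples, tolerance = 1e-9,
               ignore_attr = TRUE)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 2)
})
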