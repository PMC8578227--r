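# Interval/amplitude extraction and the rule-based normality screen.

test_that("heart rate follows HR = 60 / RR", {
  f <- extract_features(synthesize_beat_train(beat_train(12,
                                                         rr_interval = 1000)))
  expect_equal(f$heart_rate, 60, tolerance = 0.01)
  expect_equal(f$rr_mean, 1000, tolerance = 0.5)
  expect_equal(f$heart_rate, 60000 / f$rr_mean, tolerance = 1e-12)
})

test_that("extraction recovers the simulator's ground truth (200-record cohort)", {
  set.seed(42)
  co <- sample_cohort(population_spec(), 200)
  f <- extract_features(co)
  gt <- co$params
  rate_within <- function(est, tru, tol) mean(!is.na(est) & abs(est - tru) <= tol)
  expect_gte(rate_within(f$heart_rate, gt$heart_rate, 0.5), 0.9)
  expect_gte(rate_within(f$qt_interval, gt$qt_interval, 15), 0.9)
  expect_gte(rate_within(f$pr_interval, gt$pr_interval, 15), 0.9)
  expect_gte(rate_within(f$qrs_duration, gt$qrs_duration, 10), 0.9)
  # amplitudes read from V5 agree with the generating parameters
  expect_lt(median(abs(f$r_amplitude_v5 - gt$r_amplitude), na.rm = TRUE), 20)
  expect_lt(median(abs(f$t_amplitude_v5 - gt$t_amplitude), na.rm = TRUE), 20)
  expect_lt(median(abs(f$stj_amplitude_v5 - gt$stj_offset), na.rm = TRUE), 20)
})

test_that("per-record medians ignore partial edge beats", {
  base <- extract_features(synthesize_beat_train(beat_train(14),
                                                 first_r = 400))
  shifted <- extract_features(synthesize_beat_train(beat_train(14),
                                                    first_r = 150))
  for (nm in c("p_duration", "pr_interval", "qrs_duration", "qt_interval")) {
    expect_equal(base[[nm]], shifted[[nm]], tolerance = 4,
                 label = nm)
  }
})

test_that("polarity inversion leaves the detected peaks unchanged", {
  e <- synthesize_beat_train(beat_train(12))
  inv <- ecg8(-e$samples)
  expect_equal(detect_r_peaks(inv), detect_r_peaks(e))
})

test_that("a flat record raises an undetectable-rhythm error", {
  expect_error(detect_r_peaks(ecg8(matrix(0, 8, 5000))),
               "undetectable rhythm")
  # but a flat record inside a multi-record extraction yields an NA row
  e <- synthesize_beat_train(beat_train(12))
  f <- extract_features(list(e, ecg8(matrix(0, 8, 5000))))
  expect_false(is.na(f$heart_rate[1]))
  expect_true(is.na(f$heart_rate[2]))
})

test_that("screening labels flip exactly at the 60 and 100 bpm boundaries", {
  mid <- tibble::tibble(pr_interval = 156, qrs_duration = 90,
                        qt_interval = 395)
  hr <- c(59, 59.999, 60, 70, 99.999, 100, 100.5)
  v <- screen_normality(dplyr::mutate(mid[rep(1, 7), ], heart_rate = hr))
  expect_equal(as.character(v$label),
               c("bradycardia", "bradycardia", "normal", "normal", "normal",
                 "tachycardia", "tachycardia"))
  # monotone in HR: label changes only at the two boundaries
  expect_equal(length(rle(as.character(v$label))$values), 3)
})

test_that("the population mean profile screens normal", {
  f <- tibble::tibble(heart_rate = 70, pr_interval = 156, qrs_duration = 90,
                      qt_interval = 395)
  v <- screen_normality(f)
  expect_equal(as.character(v$label), "normal")
  expect_length(v$failed_rules[[1]], 0)
})

test_that("interval rules and missing features fail explicitly", {
  f <- tibble::tibble(
    heart_rate = c(70, 70, 70, NA),
    pr_interval = c(230, 156, 156, 156),
    qrs_duration = c(90, 130, 90, 90),
    qt_interval = c(395, 395, 300, 395))
  v <- screen_normality(f)
  expect_equal(as.character(v$label), rep("other_abnormal", 4))
  expect_equal(v$failed_rules[[1]], "pr_range")
  expect_equal(v$failed_rules[[2]], "qrs_wide")
  expect_equal(v$failed_rules[[3]], "qt_range")
  expect_equal(v$failed_rules[[4]], "heart_rate_missing")
  # label is normal exactly when no rule fails
  expect_true(all((as.character(v$label) == "normal") ==
                    (lengths(v$failed_rules) == 0)))
})

test_that("rules round trip through YAML", {
  r <- normality_rules(qt_low = 340)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_normality_rules(r, path)
  expect_equal(read_normality_rules(path), r)
})
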