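# Cohort-level evaluation surfaces.

test_that("fraction_normal is a brute-force count and permutation invariant", {
  expect_equal(fraction_normal(rep("normal", 10)), 1)
  labs <- c("normal", "bradycardia", "normal", "tachycardia")
  expect_equal(fraction_normal(labs), 0.5)
  set.seed(40)
  labs2 <- sample(c("normal", "other_abnormal"), 101, replace = TRUE)
  expect_equal(fraction_normal(labs2), sum(labs2 == "normal") / 101)
  expect_equal(fraction_normal(sample(labs2)), fraction_normal(labs2))
  expect_error(fraction_normal(character(0)), "empty")
})

test_that("summary percentiles agree with a sort-based oracle", {
  set.seed(41)
  x <- rnorm(501)
  f <- tibble::tibble(heart_rate = x)
  s <- summarize_cohort(f)
  # oracle: linear interpolation between order statistics
  lin_q <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  expect_equal(s$stats$pct_2_5, lin_q(x, 0.025), tolerance = 1e-9)
  expect_equal(s$stats$pct_97_5, lin_q(x, 0.975), tolerance = 1e-9)
  expect_equal(s$stats$mean, mean(x), tolerance = 1e-12)
  expect_equal(s$stats$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-12)
})

test_that("degenerate and flagged features are handled", {
  f <- tibble::tibble(heart_rate = rep(70, 5), qt_interval = NA_real_,
                      rr_mean = rep(800, 5))
  s <- summarize_cohort(f)
  hr <- s$stats[s$stats$feature == "heart_rate", ]
  expect_equal(hr$sd, 0)
  expect_equal(hr$pct_2_5, hr$mean)
  expect_equal(hr$pct_97_5, hr$mean)
  qt <- s$stats[s$stats$feature == "qt_interval", ]
  expect_true(qt$flagged)
  expect_true(is.na(qt$mean))
})

test_that("QT exactly linear in RR gives r^2 = 1", {
  f <- tibble::tibble(rr_mean = seq(600, 1200, length.out = 20))
  f$qt_interval <- 200 + 0.2 * f$rr_mean
  f$heart_rate <- 60000 / f$rr_mean
  s <- summarize_cohort(f)
  expect_equal(s$qt_rr_r2, 1, tolerance = 1e-12)
})

test_that("a simulated population cohort reports the target heart-rate mean", {
  set.seed(43)
  co <- sample_cohort(population_spec(), 1000, signals = FALSE)
  s <- summarize_cohort(co$params)
  hr <- s$stats[s$stats$feature == "heart_rate", ]
  expect_lt(abs(hr$mean - 70), 1)
})

test_that("checkpoint_compare ranks, tolerates failures, and is order invariant", {
  set.seed(44)
  co <- sample_cohort(population_spec(), 60)
  replay <- function(n) co$ecgs[seq_len(n)]
  noise <- function(n) lapply(seq_len(n), function(i)
    ecg8(matrix(rnorm(8 * 5000, sd = 300), 8, 5000)))

  single <- checkpoint_compare(list(only = replay), eval_batch_size = 20)
  expect_true(single$best[1])
  expect_equal(single$rank[1], 1L)

  cmp <- checkpoint_compare(list(replay = replay, noise = noise,
                                 broken = "/nonexistent/ckpt"),
                            eval_batch_size = 20)
  expect_equal(nrow(cmp), 3)
  expect_match(cmp$status[3], "failed")
  expect_true(cmp$best[cmp$checkpoint == "replay"])
  expect_gt(cmp$fraction_normal[1], cmp$fraction_normal[2])

  cmp_rev <- checkpoint_compare(list(noise = noise, replay = replay),
                                eval_batch_size = 20)
  expect_equal(
    cmp_rev$rank[match(c("replay", "noise"), cmp_rev$checkpoint)],
    cmp$rank[match(c("replay", "noise"), cmp$checkpoint)])
})

test_that("tidiers and report writers expose the summary", {
  set.seed(45)
  co <- sample_cohort(population_spec(), 100, signals = FALSE)
  feats <- co$params
  feats$label <- factor(rep(c("normal", "other_abnormal"), 50))
  s <- summarize_cohort(feats)
  expect_equal(s$fraction_normal, 0.5)
  td <- tidy(s)
  expect_true(all(c("feature", "mean", "sd", "pct_2_5", "pct_97_5") %in%
                    names(td)))
  gl <- glance(s)
  expect_equal(gl$n, 100)
  csv <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".md")
  write_cohort_report(s, csv, md)
  expect_equal(nrow(utils::read.csv(csv)), nrow(td))
  expect_true(any(grepl("Fraction classified normal", readLines(md))))
})

test_that("plots build without evaluation errors", {
  set.seed(46)
  co <- sample_cohort(population_spec(), 50, signals = FALSE)
  f <- co$params
  f$rr_mean <- f$rr_interval
  expect_s3_class(plot_hr_distribution(f), "ggplot")
  expect_s3_class(plot_qt_rr(f), "ggplot")
  e <- synthesize_beat_train(beat_train(12))
  p <- autoplot(e)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
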