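# Per-record interval/amplitude extraction and rule-based normality
# screening.
#
# The screener is a transparent stand-in for a commercial ECG interpreter:
# a small set of hard-boundary rules with the conventional clinical
# boundaries as defaults, extensible through a YAML rule file. It is a
# functional replacement, not a replication, of any proprietary system.

# moving average with edge fill, used to suppress the broad T/P waves
# before R-peak picking
detrend_ma <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  bad <- is.na(sm)
  sm[bad] <- x[bad]   # zero the (unusable) half-window edges
  as.numeric(x - sm)
}

#' Detect R peaks
#'
#' Peak picking on a designated rhythm lead: the signal is detrended with a
#' short moving average (which attenuates the broad P/T waves much more
#' than the narrow QRS), polarity is auto-detected, local maxima above 60%
#' of the global maximum are kept, and a refractory window suppresses
#' double detections.
#'
#' @param ecg an [ecg8()] record.
#' @param lead rhythm lead (default `"II"`).
#' @param min_rr_ms refractory window in ms.
#' @return ascending integer vector of R-peak sample indices (1-based).
#'   Errors with "undetectable rhythm" when fewer than 2 peaks are found.
#' @export
detect_r_peaks <- function(ecg, lead = "II", min_rr_ms = 200) {
  stopifnot(inherits(ecg, "ecg8"))
  x <- ecg$samples[lead, ]
  rate <- ecg$sampling_rate
  k <- max(3L, round(0.062 * rate))
  y <- detrend_ma(x, k)
  if (max(abs(y)) == 0) {
    stop("undetectable rhythm: flat signal on lead ", lead, call. = FALSE)
  }
  if (max(y) < -min(y)) y <- -y  # polarity auto-detect
  thr <- 0.6 * max(y)
  n <- length(y)
  cand <- which(y >= thr &
                  y >= c(-Inf, y[-n]) &
                  y >= c(y[-1], -Inf))
  if (length(cand) == 0) {
    stop("undetectable rhythm: no peaks above threshold", call. = FALSE)
  }
  refr <- round(min_rr_ms / 1000 * rate)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (y[i] > y[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  # refine to the local extremum of the raw (polarity-corrected) signal
  pol <- if (stats::median(sign(x[keep])) < 0) -1 else 1
  w <- pol * x
  keep <- vapply(keep, function(i) {
    lo <- max(1L, i - 6L); hi <- min(n, i + 6L)
    lo + which.max(w[lo:hi]) - 1L
  }, integer(1))
  keep <- unique(keep)
  if (length(keep) < 2) {
    stop("undetectable rhythm: fewer than 2 R peaks", call. = FALSE)
  }
  sort(keep)
}

# first sample index (moving outward from `start` along `dir`) opening a
# sustained sub-threshold run; NA when no such run exists in the window
scan_crossing <- function(w, start, dir, thr, run, max_steps) {
  n <- length(w)
  steps <- seq_len(max_steps)
  idx <- start + dir * steps
  idx <- idx[idx >= 1 & idx <= n]
  if (length(idx) < run) return(NA_integer_)
  below <- abs(w[idx]) < thr
  cs <- cumsum(below)
  runsum <- cs - c(rep(0, run), cs[seq_len(length(cs) - run)])
  hit <- which(runsum == run)
  if (!length(hit)) return(NA_integer_)
  idx[hit[1] - run + 1L]
}

# delineate one beat; returns a list of fiducials (sample indices) or NULL
delineate_beat <- function(w, r, rate, thr_rel = WAVE_THRESH) {
  n <- length(w)
  spms <- rate / 1000  # samples per ms
  r_amp <- w[r]
  if (r_amp <= 0) return(NULL)
  thr_q <- thr_rel * r_amp

  on <- scan_crossing(w, r, -1L, thr_q, run = 5L,
                      max_steps = round(130 * spms))
  if (is.na(on)) return(NULL)
  # provisional J from QRS symmetry, then ST level, then the true offset
  j0 <- r + (r - on)
  st_win <- (j0 + round(24 * spms)):(j0 + round(54 * spms))
  st_win <- st_win[st_win >= 1 & st_win <= n]
  if (length(st_win) < 3) return(NULL)
  st_level <- stats::median(w[st_win])
  # the QRS offset opens a long sub-threshold stretch (the ST segment).
  # A 24 ms run with a lowered threshold keeps the brief dip between the S
  # wave and J (whose recovery peak sits just under the onset threshold)
  # from merging with the ST segment.
  off <- scan_crossing(w - st_level, r, 1L, 0.6 * thr_q, run = 12L,
                       max_steps = round(160 * spms))
  if (is.na(off)) return(NULL)

  # P wave in the 220 ms window before QRS onset
  p_lo <- max(1L, on - round(220 * spms))
  p_hi <- on - round(10 * spms)
  p_on <- p_off <- p_pk <- NA_integer_
  if (p_hi - p_lo > 10) {
    seg <- p_lo:p_hi
    p_pk <- seg[which.max(w[seg])]
    p_amp <- w[p_pk]
    if (p_amp > max(10, 0.02 * r_amp)) {
      thr_p <- thr_rel * p_amp
      p_on <- scan_crossing(w, p_pk, -1L, thr_p, run = 3L,
                            max_steps = round(120 * spms))
      p_off <- scan_crossing(w, p_pk, 1L, thr_p, run = 3L,
                             max_steps = round(120 * spms))
    } else {
      p_pk <- NA_integer_
    }
  }

  # T wave after the ST segment
  t_lo <- off + round(60 * spms)
  t_hi <- min(n, off + round(420 * spms))
  t_pk <- t_end <- NA_integer_
  if (t_hi - t_lo > 10) {
    seg <- t_lo:t_hi
    t_pk <- seg[which.max(abs(w[seg]))]
    t_amp <- abs(w[t_pk])
    if (t_amp > max(10, 0.02 * r_amp)) {
      t_end <- scan_crossing(w, t_pk, 1L, thr_rel * t_amp, run = 5L,
                             max_steps = round(200 * spms))
    } else {
      t_pk <- NA_integer_
    }
  }

  list(r = r, qrs_on = on, qrs_off = off, p_on = p_on, p_off = p_off,
       p_pk = p_pk, t_pk = t_pk, t_end = t_end, st_level = st_level)
}

#' Extract interval and amplitude features from an ECG
#'
#' R peaks are detected on the rhythm lead; per-beat fiducials (P onset and
#' offset, QRS onset and offset, T offset) come from threshold delineation
#' of the wave envelopes (crossings at 4.39% of the local wave peak, i.e.
#' the +/- 2.5 sd points of a Gaussian wave), with the ST level estimated
#' from the post-QRS plateau so an STJ offset does not bias the QRS offset.
#' Per-record features are medians across beats; heart rate is
#' `60000 / mean(RR in ms)`. Amplitudes (R, T, STJ) are read from lead V5.
#'
#' @param ecg an [ecg8()] record, a list of records, or an `ecg_cohort`.
#' @param rhythm_lead lead used for rhythm and intervals.
#' @param amplitude_lead lead used for amplitudes.
#' @return a tibble with one row per record: `heart_rate` (bpm), `rr_mean`
#'   (ms), `p_duration`, `pr_interval`, `qrs_duration`, `qt_interval` (ms),
#'   `r_amplitude_v5`, `t_amplitude_v5`, `stj_amplitude_v5` (uV), and
#'   `n_beats`. Undetectable waves yield `NA` markers; for multi-record
#'   input a record whose rhythm is undetectable yields an all-`NA` row
#'   rather than an error.
#' @examples
#' p <- data.frame(rr_interval = 1000, p_duration = 105, pr_interval = 156,
#'                 qrs_duration = 90, qt_interval = 395, p_amplitude = 100,
#'                 r_amplitude = 1287, t_amplitude = 343, stj_offset = 2)
#' extract_features(synthesize_beat_train(p[rep(1, 11), ]))$heart_rate
#' @export
extract_features <- function(ecg, rhythm_lead = "II", amplitude_lead = "V5") {
  if (inherits(ecg, "ecg_cohort")) ecg <- ecg$ecgs
  if (is.list(ecg) && !inherits(ecg, "ecg8")) {
    rows <- lapply(seq_along(ecg), function(i) {
      out <- tryCatch(
        extract_features(ecg[[i]], rhythm_lead, amplitude_lead),
        error = function(e) na_feature_row())
      out$record <- i
      out
    })
    return(dplyr::relocate(dplyr::bind_rows(rows), "record"))
  }
  stopifnot(inherits(ecg, "ecg8"))
  rate <- ecg$sampling_rate
  dt <- 1000 / rate
  peaks <- detect_r_peaks(ecg, lead = rhythm_lead)
  rr <- diff(peaks) * dt
  x <- ecg$samples[rhythm_lead, ]
  pol <- if (stats::median(sign(x[peaks])) < 0) -1 else 1
  w <- pol * x
  v5 <- ecg$samples[amplitude_lead, ]
  spms <- rate / 1000

  margin_l <- round(260 * spms)
  margin_r <- round(480 * spms)
  full <- peaks[peaks > margin_l & peaks <= length(w) - margin_r]
  beats <- lapply(full, function(r) delineate_beat(w, r, rate))
  beats <- beats[!vapply(beats, is.null, logical(1))]

  med <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals)) stats::median(vals) else NA_real_
  }
  g <- function(field) {
    vapply(beats, function(b) {
      v <- b[[field]]
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  if (length(beats)) {
    qrs_ms <- med((g("qrs_off") - g("qrs_on")) * dt)
    pr_ms <- med((g("qrs_on") - g("p_on")) * dt)
    p_ms <- med((g("p_off") - g("p_on")) * dt)
    qt_ms <- med((g("t_end") - g("qrs_on")) * dt)
    r_v5 <- med(v5[stats::na.omit(as.integer(g("r")))])
    t_idx <- g("t_pk")
    t_v5 <- med(v5[as.integer(t_idx[!is.na(t_idx)])])
    stj_v5 <- med(vapply(beats, function(b) {
      win <- (b$qrs_off + round(24 * spms)):(b$qrs_off + round(54 * spms))
      win <- win[win >= 1 & win <= length(v5)]
      if (length(win) < 3) NA_real_ else stats::median(v5[win])
    }, numeric(1)))
  } else {
    qrs_ms <- pr_ms <- p_ms <- qt_ms <- r_v5 <- t_v5 <- stj_v5 <- NA_real_
  }
  tibble::tibble(
    heart_rate = 60000 / mean(rr), rr_mean = mean(rr),
    p_duration = p_ms, pr_interval = pr_ms, qrs_duration = qrs_ms,
    qt_interval = qt_ms, r_amplitude_v5 = r_v5, t_amplitude_v5 = t_v5,
    stj_amplitude_v5 = stj_v5, n_beats = length(beats))
}

na_feature_row <- function() {
  tibble::tibble(
    heart_rate = NA_real_, rr_mean = NA_real_, p_duration = NA_real_,
    pr_interval = NA_real_, qrs_duration = NA_real_, qt_interval = NA_real_,
    r_amplitude_v5 = NA_real_, t_amplitude_v5 = NA_real_,
    stj_amplitude_v5 = NA_real_, n_beats = 0L)
}

#' Normality screening rules
#'
#' Hard-boundary rules with the conventional clinical defaults: heart rate
#' normal on `[60, 100)` bpm (below 60 is sinus bradycardia, 100 or above
#' sinus tachycardia), PR interval in `[120, 220]` ms, QRS duration below
#' 120 ms, QT interval in `[350, 460]` ms (the QT band is a configurable
#' package default, not a population-derived value). Rules can be stored
#' and shared as YAML.
#'
#' @param hr_low,hr_high bradycardia / tachycardia boundaries (bpm); normal
#'   is `hr_low <= HR < hr_high`.
#' @param pr_low,pr_high PR interval bounds (ms, inclusive).
#' @param qrs_max QRS duration must be strictly below this (ms).
#' @param qt_low,qt_high QT interval bounds (ms, inclusive).
#' @return a `normality_rules` list.
#' @export
normality_rules <- function(hr_low = 60, hr_high = 100, pr_low = 120,
                            pr_high = 220, qrs_max = 120, qt_low = 350,
                            qt_high = 460) {
  structure(list(hr_low = hr_low, hr_high = hr_high, pr_low = pr_low,
                 pr_high = pr_high, qrs_max = qrs_max, qt_low = qt_low,
                 qt_high = qt_high),
            class = "normality_rules")
}

#' @param path YAML file with any subset of the rule fields.
#' @rdname normality_rules
#' @export
read_normality_rules <- function(path) {
  do.call(normality_rules, yaml::read_yaml(path))
}

#' @param rules a `normality_rules` object.
#' @rdname normality_rules
#' @export
write_normality_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(rules)
}

#' Screen extracted features for normality
#'
#' Applies the hard-boundary rules to each record. A heart rate outside the
#' normal band labels the record `bradycardia` (below the lower boundary)
#' or `tachycardia` (at or above the upper boundary); any other rule
#' failure labels it `other_abnormal`; a record is `normal` exactly when no
#' rule fails. Missing features fail their rules explicitly (rule id
#' `<feature>_missing`).
#'
#' @param features a tibble from [extract_features()] (any extra columns
#'   are carried through).
#' @param rules a [normality_rules()] object.
#' @return the input tibble plus `label` (factor: normal, bradycardia,
#'   tachycardia, other_abnormal) and `failed_rules` (list column of
#'   character rule ids, empty for normal records).
#' @examples
#' f <- tibble::tibble(heart_rate = c(59, 100, 70),
#'                     pr_interval = 156, qrs_duration = 90,
#'                     qt_interval = 395)
#' screen_normality(f)$label
#' @export
screen_normality <- function(features, rules = normality_rules()) {
  stopifnot(is.data.frame(features))
  lab <- character(nrow(features))
  fails <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    failed <- character(0)
    hr_label <- NULL
    chk <- function(v) !is.null(v) && length(v) == 1 && !is.na(v)
    hr <- f$heart_rate
    if (!chk(hr)) {
      failed <- c(failed, "heart_rate_missing")
    } else if (hr < rules$hr_low) {
      failed <- c(failed, "hr_low")
      hr_label <- "bradycardia"
    } else if (hr >= rules$hr_high) {
      failed <- c(failed, "hr_high")
      hr_label <- "tachycardia"
    }
    pr <- f$pr_interval
    if (!chk(pr)) {
      failed <- c(failed, "pr_missing")
    } else if (pr < rules$pr_low || pr > rules$pr_high) {
      failed <- c(failed, "pr_range")
    }
    qrs <- f$qrs_duration
    if (!chk(qrs)) {
      failed <- c(failed, "qrs_missing")
    } else if (qrs >= rules$qrs_max) {
      failed <- c(failed, "qrs_wide")
    }
    qt <- f$qt_interval
    if (!chk(qt)) {
      failed <- c(failed, "qt_missing")
    } else if (qt < rules$qt_low || qt > rules$qt_high) {
      failed <- c(failed, "qt_range")
    }
    lab[i] <- if (length(failed) == 0) {
      "normal"
    } else if (!is.null(hr_label)) {
      hr_label
    } else {
      "other_abnormal"
    }
    fails[[i]] <- failed
  }
  out <- tibble::as_tibble(features)
  out$label <- factor(lab, levels = c("normal", "bradycardia",
                                      "tachycardia", "other_abnormal"))
  out$failed_rules <- fails
  out
}
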