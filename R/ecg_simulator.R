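# Synthetic "normal population" ECG cohort generator.
#
# Each beat is a sum of Gaussian bumps (P, Q, R, S, T) on the time axis plus
# a tapered ST plateau carrying the STJ offset, in the spirit of the
# dynamical PQRST models used for single-lead ECG synthesis, extended to 8
# leads by a fixed per-lead projection. Population-level parameters are
# drawn from truncated normals with a QT-RR coupling, so the cohort mimics
# the interval/amplitude statistics of a screened normal population.
#
# Geometry conventions (all relative to the R peak at t = 0, in ms):
#   QRS onset = -qrs/2, offset (J point) = +qrs/2
#   R: N(0, (qrs/5)^2) * r_amplitude
#   Q: centre -0.35 qrs, sd qrs/18, amplitude -0.10 r
#   S: centre +0.35 qrs, sd qrs/18, amplitude -0.20 r
#   P: sd p_duration/5, centre = QRS onset - pr + p_duration/2
#   T: sd 32 ms, offset (2.5 sd past centre) at QRS onset + qt
#   ST: stj_offset times a plateau = 1 on [J, J+60], half-cosine tapers of
#       20 ms on both sides
# A Gaussian wave's nominal duration is the +/- 2.5 sd span, so a
# noise-free delineator thresholding at exp(-2.5^2/2) ~ 4.39% of the wave's
# peak recovers onsets/offsets exactly (up to sampling quantisation).

WAVE_THRESH <- exp(-2.5^2 / 2)  # relative amplitude at +/- 2.5 sd
T_SIGMA_MS <- 32

#' Default per-lead projection
#'
#' Scale factors mapping the beat template to the 8 stored leads. V5 carries
#' the largest R wave (the reporting lead for amplitudes); V1 is inverted,
#' as in typical adult ECGs.
#'
#' @return named numeric vector of length 8.
#' @export
default_lead_projection <- function() {
  c(I = 0.55, II = 0.9, V1 = -0.35, V2 = 0.5, V3 = 0.7, V4 = 0.9,
    V5 = 1, V6 = 0.85)
}

#' Population specification for cohort sampling
#'
#' Per-parameter `(mean, sd, low, high)` truncated-normal laws. The defaults
#' are the summary statistics of a screened normal adult population --
#' means/sds with truncation at the population 2.5% / 97.5% percentiles:
#' heart rate 70 +/- 8 bpm in `[60, 90]`, P duration 105 +/- 12 ms in
#' `[82, 130]`, QT 395 +/- 21 ms in `[352, 436]`, QRS 90 +/- 9 ms in
#' `[74, 110]`, PR 156 +/- 19 ms in `[120, 198]`, STJ 2 +/- 27 uV in
#' `[-44, 58]`, R amplitude (V5) 1287 +/- 402 uV in `[600, 2163]`, T
#' amplitude (V5) 343 +/- 137 uV in `[126, 664]`. P amplitude (not tabulated
#' for the reference population) defaults to 100 +/- 25 uV in `[50, 150]`.
#'
#' QT is not drawn independently: it follows the coupling
#' `QT = a * (RR / 1000)^b + noise`, with `b = 0.5` (a Bazett-like
#' exponent), Gaussian noise of sd `qt_noise_sd` (10 ms), and `a` fixed so
#' the mean-RR record has the target mean QT; draws are rejected into the QT
#' truncation bounds. This reproduces the positive QT/RR association of
#' normal cohorts.
#'
#' @param heart_rate,p_duration,qt_interval,qrs_duration,pr_interval
#'   numeric `(mean, sd, low, high)` for the interval parameters (bpm / ms).
#' @param stj_offset,r_amplitude,t_amplitude,p_amplitude the same for the
#'   amplitude parameters (microvolts, as seen in lead V5).
#' @param qt_rr_exponent exponent `b` of the QT-RR coupling.
#' @param qt_noise_sd sd (ms) of the QT noise around the coupling curve.
#' @param lead_projection per-lead scale factors
#'   ([default_lead_projection()]).
#' @param noise_uv sd of additive white measurement noise (uV; 0 = clean).
#' @return a `population_spec` object.
#' @export
population_spec <- function(heart_rate = c(70, 8, 60, 90),
                            p_duration = c(105, 12, 82, 130),
                            qt_interval = c(395, 21, 352, 436),
                            qrs_duration = c(90, 9, 74, 110),
                            pr_interval = c(156, 19, 120, 198),
                            stj_offset = c(2, 27, -44, 58),
                            r_amplitude = c(1287, 402, 600, 2163),
                            t_amplitude = c(343, 137, 126, 664),
                            p_amplitude = c(100, 25, 50, 150),
                            qt_rr_exponent = 0.5,
                            qt_noise_sd = 10,
                            lead_projection = default_lead_projection(),
                            noise_uv = 0) {
  laws <- list(heart_rate = heart_rate, p_duration = p_duration,
               qt_interval = qt_interval, qrs_duration = qrs_duration,
               pr_interval = pr_interval, stj_offset = stj_offset,
               r_amplitude = r_amplitude, t_amplitude = t_amplitude,
               p_amplitude = p_amplitude)
  for (nm in names(laws)) {
    l <- laws[[nm]]
    if (length(l) != 4) stop(nm, " must be (mean, sd, low, high)",
                             call. = FALSE)
    if (l[2] < 0) stop(nm, ": sd must be >= 0", call. = FALSE)
    if (l[3] >= l[4]) stop(nm, ": infeasible truncation (low >= high)",
                           call. = FALSE)
  }
  stopifnot(length(lead_projection) == 8, all(is.finite(lead_projection)))
  structure(c(laws, list(qt_rr_exponent = qt_rr_exponent,
                         qt_noise_sd = qt_noise_sd,
                         lead_projection = lead_projection,
                         noise_uv = noise_uv)),
            class = "population_spec")
}

# truncated-normal draws via inverse-CDF; exact for sd = 0
rtrunc_norm <- function(n, mean, sd, low, high) {
  if (sd == 0) return(rep(min(max(mean, low), high), n))
  lo <- stats::pnorm(low, mean, sd)
  hi <- stats::pnorm(high, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# mean / sd of a normal truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (al * da - be * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# quantile of the truncated normal (closed form)
qtrunc_norm <- function(p, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  stats::qnorm(pa + p * (pb - pa), mu, sigma)
}

# The population table reports *cohort* statistics: the printed mean/sd are
# moments of the screened (truncated) distribution, not of the underlying
# normal. Solve for the underlying (mu, sigma) whose truncation to [a, b]
# has the target mean and sd.
calibrate_truncnorm <- function(target_mean, target_sd, a, b) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), a, b)
    (mo[1] - target_mean)^2 / target_sd^2 + (mo[2] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# draw so that the truncated draws reproduce the target cohort moments
rtrunc_calibrated <- function(n, target_mean, target_sd, low, high) {
  cal <- calibrate_truncnorm(target_mean, target_sd, low, high)
  rtrunc_norm(n, cal[1], cal[2], low, high)
}

validate_beat_params <- function(p) {
  need <- c("rr_interval", "p_duration", "pr_interval", "qrs_duration",
            "qt_interval", "p_amplitude", "r_amplitude", "t_amplitude",
            "stj_offset")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("beat parameters missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dur <- c("rr_interval", "p_duration", "pr_interval", "qrs_duration",
           "qt_interval")
  for (nm in dur) {
    if (any(p[[nm]] <= 0)) stop(nm, " must be positive", call. = FALSE)
  }
  if (any(p$pr_interval < p$p_duration)) {
    stop("invalid beat: pr_interval < p_duration (the P wave would overlap ",
         "the QRS complex)", call. = FALSE)
  }
  if (any(p$qt_interval <= p$qrs_duration)) {
    stop("invalid beat: qt_interval must exceed qrs_duration", call. = FALSE)
  }
  invisible(p)
}

# add a * exp(-(t - c)^2 / (2 s^2)) to `sig` over a +/- 4 sd support window
add_bump <- function(sig, t_ms, centre, sd, amp) {
  if (amp == 0 || sd <= 0) return(sig)
  i <- which(t_ms >= centre - 4 * sd & t_ms <= centre + 4 * sd)
  if (length(i)) {
    sig[i] <- sig[i] + amp * exp(-((t_ms[i] - centre)^2) / (2 * sd^2))
  }
  sig
}

# tapered ST plateau: 1 on [j, j + hold], half-cosine ramps of `taper` ms
add_st_plateau <- function(sig, t_ms, j, amp, hold = 60, taper = 20) {
  if (amp == 0) return(sig)
  i <- which(t_ms >= j - taper & t_ms <= j + hold + taper)
  if (!length(i)) return(sig)
  tt <- t_ms[i]
  w <- numeric(length(tt))
  ramp_in <- tt < j
  w[ramp_in] <- (1 - cos(pi * (tt[ramp_in] - (j - taper)) / taper)) / 2
  w[tt >= j & tt <= j + hold] <- 1
  ramp_out <- tt > j + hold
  w[ramp_out] <- (1 + cos(pi * (tt[ramp_out] - (j + hold)) / taper)) / 2
  sig[i] <- sig[i] + amp * w
  sig
}

#' Synthesise an 8-lead ECG from beat parameters
#'
#' Places one PQRST complex per row of `params` (beats spaced by their
#' `rr_interval`), sums the Gaussian waves analytically on the sample grid,
#' and projects the single-channel template onto the 8 stored leads.
#' Deterministic given the parameters.
#'
#' @param params data frame with one row per beat: columns `rr_interval`,
#'   `p_duration`, `pr_interval`, `qrs_duration`, `qt_interval` (ms) and
#'   `p_amplitude`, `r_amplitude`, `t_amplitude`, `stj_offset` (uV, as seen
#'   in lead V5). The cumulated `rr_interval` must span the record.
#' @param rate sampling rate in Hz.
#' @param n_samples samples per channel (5000 for the canonical record).
#' @param lead_projection per-lead scale factors.
#' @param first_r time of the first R peak, ms.
#' @param noise_uv sd of additive white noise, uV.
#' @return an [ecg8()] record. The analytic R-peak times are attached as
#'   attribute `r_peak_ms`.
#' @examples
#' p <- data.frame(rr_interval = 1000, p_duration = 105, pr_interval = 156,
#'                 qrs_duration = 90, qt_interval = 395, p_amplitude = 100,
#'                 r_amplitude = 1287, t_amplitude = 343, stj_offset = 2)
#' e <- synthesize_beat_train(p[rep(1, 11), ])
#' @export
synthesize_beat_train <- function(params, rate = 500, n_samples = 5000,
                                  lead_projection = default_lead_projection(),
                                  first_r = 400, noise_uv = 0) {
  params <- as.data.frame(params)
  validate_beat_params(params)
  duration_ms <- n_samples / rate * 1000
  r_times <- first_r + c(0, cumsum(params$rr_interval))[seq_len(nrow(params))]
  if (max(r_times) + params$rr_interval[nrow(params)] < duration_ms) {
    stop("beat train too short: cumulative RR intervals must span the ",
         duration_ms / 1000, " s record", call. = FALSE)
  }
  t_ms <- (seq_len(n_samples) - 1) * 1000 / rate
  sig <- numeric(n_samples)
  for (k in seq_len(nrow(params))) {
    p <- params[k, ]
    r0 <- r_times[k]
    if (r0 - p$pr_interval > duration_ms + 200) next
    qrs_on <- r0 - p$qrs_duration / 2
    j <- r0 + p$qrs_duration / 2
    sig <- add_bump(sig, t_ms, r0, p$qrs_duration / 5, p$r_amplitude)
    sig <- add_bump(sig, t_ms, r0 - 0.35 * p$qrs_duration,
                    p$qrs_duration / 18, -0.10 * p$r_amplitude)
    sig <- add_bump(sig, t_ms, r0 + 0.35 * p$qrs_duration,
                    p$qrs_duration / 18, -0.20 * p$r_amplitude)
    sig <- add_bump(sig, t_ms, qrs_on - p$pr_interval + p$p_duration / 2,
                    p$p_duration / 5, p$p_amplitude)
    sig <- add_bump(sig, t_ms, qrs_on + p$qt_interval - 2.5 * T_SIGMA_MS,
                    T_SIGMA_MS, p$t_amplitude)
    sig <- add_st_plateau(sig, t_ms, j, p$stj_offset)
  }
  samples <- outer(unname(lead_projection), sig)
  if (noise_uv > 0) {
    samples <- samples + matrix(stats::rnorm(length(samples), sd = noise_uv),
                                nrow = 8)
  }
  out <- ecg8(samples, sampling_rate = rate,
              strict = n_samples == 5000 && rate == 500)
  attr(out, "r_peak_ms") <- r_times[r_times >= 0 & r_times < duration_ms]
  out
}

#' Sample a synthetic normal cohort
#'
#' Draws per-record beat parameters from the population law (each parameter
#' a truncated normal; QT tied to RR through the coupling described in
#' [population_spec()]), synthesises each record, and returns the signals
#' together with their ground-truth parameters. Because the population
#' table's mean/sd describe the *screened cohort*, the underlying normal of
#' each parameter is moment-matched so that the truncated draws reproduce
#' the target mean and sd (a left-heavier underlying law for heart rate,
#' for instance, whose truncation to `[60, 90]` still has mean 70). Within
#' a record all beats are identical (no beat-to-beat variability). Seed the
#' RNG for reproducible cohorts.
#'
#' @param spec a [population_spec()].
#' @param n number of records (>= 1).
#' @param rate,n_samples passed to [synthesize_beat_train()].
#' @param signals synthesise the signals? With `FALSE` only the ground-truth
#'   parameter table is drawn (fast, for population-level statistics).
#' @return an `ecg_cohort`: list with `ecgs` (list of [ecg8()]) and
#'   `params` (tibble of ground truth, one row per record: `record`,
#'   `rr_interval`, `heart_rate`, the intervals and the amplitudes).
#' @examples
#' set.seed(7)
#' co <- sample_cohort(population_spec(), 3)
#' co$params$heart_rate
#' @export
sample_cohort <- function(spec, n, rate = 500, n_samples = 5000,
                          signals = TRUE) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  n <- as.integer(n)
  draw <- function(nm) {
    l <- spec[[nm]]
    rtrunc_calibrated(n, l[1], l[2], l[3], l[4])
  }
  hr <- draw("heart_rate")
  rr <- 60000 / hr
  p_dur <- draw("p_duration")
  qrs <- draw("qrs_duration")
  pr <- draw("pr_interval")
  stj <- draw("stj_offset")
  r_amp <- draw("r_amplitude")
  t_amp <- draw("t_amplitude")
  p_amp <- draw("p_amplitude")

  # keep the P wave inside the PR interval (10 ms margin), re-drawing the
  # few joint draws that violate it
  pl <- spec$p_duration
  for (i in which(p_dur > pr - 10)) {
    hi <- min(pl[4], pr[i] - 10)
    p_dur[i] <- if (hi <= pl[3]) pr[i] - 10 else
      rtrunc_norm(1, pl[1], pl[2], pl[3], hi)
  }

  # QT-RR coupling: a * (RR/1000)^b + noise, rejected into the QT bounds
  ql <- spec$qt_interval
  rr_ref <- 60000 / spec$heart_rate[1] / 1000
  a <- ql[1] / rr_ref^spec$qt_rr_exponent
  qt_det <- a * (rr / 1000)^spec$qt_rr_exponent
  qt <- qt_det + stats::rnorm(n, sd = spec$qt_noise_sd)
  for (it in 1:100) {
    bad <- which(qt < ql[3] | qt > ql[4])
    if (!length(bad)) break
    qt[bad] <- qt_det[bad] + stats::rnorm(length(bad), sd = spec$qt_noise_sd)
  }
  qt <- pmin(pmax(qt, ql[3]), ql[4])
  qt <- pmax(qt, qrs + 240)  # keep the T wave clear of the ST segment

  params <- tibble::tibble(
    record = seq_len(n), rr_interval = rr, heart_rate = hr,
    p_duration = p_dur, pr_interval = pr, qrs_duration = qrs,
    qt_interval = qt, p_amplitude = p_amp, r_amplitude = r_amp,
    t_amplitude = t_amp, stj_offset = stj)

  if (!signals) {
    return(structure(list(ecgs = list(), params = params),
                     class = "ecg_cohort"))
  }
  duration_ms <- n_samples / rate * 1000
  ecgs <- lapply(seq_len(n), function(i) {
    nb <- ceiling(duration_ms / rr[i]) + 1L
    beats <- params[rep(i, nb), c("rr_interval", "p_duration", "pr_interval",
                                  "qrs_duration", "qt_interval",
                                  "p_amplitude", "r_amplitude",
                                  "t_amplitude", "stj_offset")]
    synthesize_beat_train(beats, rate = rate, n_samples = n_samples,
                          lead_projection = spec$lead_projection,
                          noise_uv = spec$noise_uv)
  })
  structure(list(ecgs = ecgs, params = params), class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  d <- dim(x$ecgs[[1]]$samples)
  cat("<ecg_cohort> ", length(x$ecgs), " records, ", d[1], " leads x ",
      d[2], " samples\n", sep = "")
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One delimited-text ECG file per record (`ecg_00001.txt`, ...) plus
#' `ground_truth.csv` with the per-record beat parameters.
#'
#' @param cohort an `ecg_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$ecgs)) {
    write_ecg8(cohort$ecgs[[i]], file.path(dir, sprintf("ecg_%05d.txt", i)))
  }
  utils::write.csv(cohort$params, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# stack a cohort (or list of records) into a (8, length, n) training array,
# optionally windowed to a reduced signal length
#' Convert a cohort to a training array
#'
#' @param cohort an `ecg_cohort` or list of [ecg8()] records.
#' @param length optional window length in samples; a window starting at
#'   `offset` is cut from each record (for reduced-scale training).
#' @param offset 1-based start sample of the window.
#' @return numeric array `(8, length, n)` in microvolts.
#' @export
cohort_to_array <- function(cohort, length = NULL, offset = 1L) {
  ecgs <- if (inherits(cohort, "ecg_cohort")) cohort$ecgs else cohort
  x <- as_batch(ecgs)
  if (!is.null(length)) {
    stopifnot(offset >= 1L, offset + length - 1L <= dim(x)[2])
    x <- x[, offset:(offset + length - 1L), , drop = FALSE]
  }
  x
}
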