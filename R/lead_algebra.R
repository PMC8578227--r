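# Conversion between the 8-independent-channel storage representation and
# the clinical 12-lead ECG.
#
# A 12-lead ECG carries only 8 independent channels: the limb leads III,
# aVR, aVL and aVF are fixed linear combinations (Einthoven / Goldberger) of
# leads I and II. We store (I, II, V1..V6) and derive the rest:
#   III = II - I,  aVR = -(I + II)/2,  aVL = I - II/2,  aVF = II - I/2.

ECG8_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
ECG12_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct an 8-channel ECG record
#'
#' The storage unit for generation, training and evaluation: 8 independent
#' channels (leads I, II, V1-V6) by `n` time points, amplitudes in
#' microvolts. The canonical record is 10 s at 500 Hz (5000 samples); other
#' lengths are allowed for reduced-scale work when `strict = FALSE`.
#'
#' @param samples numeric matrix, channels x time (8 x 5000 canonically).
#'   A 5000 x 8 matrix is transposed with a message-free heuristic only when
#'   unambiguous.
#' @param sampling_rate sampling frequency in Hz (default 500).
#' @param lead_order character vector naming the 8 rows.
#' @param strict require exactly 8 x 5000 at 500 Hz?
#' @return an object of class `ecg8`.
#' @examples
#' e <- ecg8(matrix(0, 8, 5000))
#' dim(e$samples)
#' @export
ecg8 <- function(samples, sampling_rate = 500, lead_order = ECG8_LEADS,
                 strict = TRUE) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) != 8 && ncol(samples) == 8) samples <- t(samples)
  if (nrow(samples) != 8) {
    stop("an ecg8 record needs exactly 8 channels, got ", nrow(samples),
         call. = FALSE)
  }
  if (length(lead_order) != 8) {
    stop("`lead_order` must name the 8 stored channels", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("ecg8 amplitudes must all be finite", call. = FALSE)
  }
  if (strict && ncol(samples) != 5000) {
    stop("a canonical ecg8 record has 5000 samples (10 s at 500 Hz); got ",
         ncol(samples), ". Use strict = FALSE for reduced-scale records.",
         call. = FALSE)
  }
  rownames(samples) <- lead_order
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 lead_order = lead_order),
            class = "ecg8")
}

#' @export
print.ecg8 <- function(x, ...) {
  cat("<ecg8> ", nrow(x$samples), " leads x ", ncol(x$samples),
      " samples @ ", x$sampling_rate, " Hz (",
      ncol(x$samples) / x$sampling_rate, " s)\n", sep = "")
  cat("  leads:", paste(x$lead_order, collapse = ", "), "\n")
  invisible(x)
}

#' The 12 x 8 lead-derivation matrix
#'
#' Linear map taking the stored channels (I, II, V1-V6) to the 12 clinical
#' leads. Its rank is 8: the four derived limb leads add no information.
#'
#' @return a 12 x 8 numeric matrix with lead names on rows and columns.
#' @examples
#' qr(lead_derivation_matrix())$rank
#' @export
lead_derivation_matrix <- function() {
  d <- matrix(0, 12, 8, dimnames = list(ECG12_LEADS, ECG8_LEADS))
  d["I", "I"] <- 1
  d["II", "II"] <- 1
  d["III", c("I", "II")] <- c(-1, 1)
  d["aVR", c("I", "II")] <- c(-0.5, -0.5)
  d["aVL", c("I", "II")] <- c(1, -0.5)
  d["aVF", c("I", "II")] <- c(-0.5, 1)
  for (v in paste0("V", 1:6)) d[v, v] <- 1
  d
}

#' Derive the 12-lead view from an 8-channel record
#'
#' Applies the Einthoven/Goldberger identities sample-wise:
#' III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2.
#' The 8 stored channels are copied unchanged, so the round trip through
#' [reduce_8_from_12()] is exact (bitwise on integer microvolt inputs).
#'
#' @param ecg an [ecg8()] record.
#' @return an object of class `ecg12` (fields `samples` 12 x n,
#'   `sampling_rate`, `lead_order`).
#' @examples
#' e <- ecg8(matrix(rnorm(8 * 5000), 8, 5000))
#' e12 <- derive_12_from_8(e)
#' max(abs(e12$samples["I", ] + e12$samples["III", ] - e12$samples["II", ]))
#' @export
derive_12_from_8 <- function(ecg) {
  if (!inherits(ecg, "ecg8")) {
    stop("`ecg` must be an ecg8 record; see ecg8()", call. = FALSE)
  }
  if (!identical(ecg$lead_order, ECG8_LEADS)) {
    stop("unrecognized lead order: expected ",
         paste(ECG8_LEADS, collapse = ", "), call. = FALSE)
  }
  s <- ecg$samples
  out <- rbind(
    I   = s["I", ],
    II  = s["II", ],
    III = s["II", ] - s["I", ],
    aVR = -(s["I", ] + s["II", ]) / 2,
    aVL = s["I", ] - s["II", ] / 2,
    aVF = s["II", ] - s["I", ] / 2,
    s[paste0("V", 1:6), , drop = FALSE]
  )
  rownames(out) <- ECG12_LEADS
  structure(list(samples = out, sampling_rate = ecg$sampling_rate,
                 lead_order = ECG12_LEADS),
            class = "ecg12")
}

#' @export
print.ecg12 <- function(x, ...) {
  cat("<ecg12> 12 leads x ", ncol(x$samples), " samples @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Reduce a 12-lead ECG to its 8 independent channels
#'
#' Returns the stored channels (I, II, V1-V6). The four derived leads are
#' checked against their defining identities; a violation beyond `tol`
#' raises a warning naming the worst lead and the maximum residual (in the
#' amplitude unit of the input).
#'
#' @param ecg an `ecg12` object (or a 12 x n matrix with the standard lead
#'   order).
#' @param tol residual tolerance in amplitude units (default 1e-6).
#' @return an [ecg8()] record.
#' @export
reduce_8_from_12 <- function(ecg, tol = 1e-6) {
  if (inherits(ecg, "ecg12")) {
    s <- ecg$samples
    rate <- ecg$sampling_rate
  } else {
    s <- as.matrix(ecg)
    if (nrow(s) != 12 && ncol(s) == 12) s <- t(s)
    if (nrow(s) != 12) stop("expected 12 channels", call. = FALSE)
    rownames(s) <- ECG12_LEADS
    rate <- 500
  }
  resid <- rbind(
    III = s["III", ] - (s["II", ] - s["I", ]),
    aVR = s["aVR", ] + (s["I", ] + s["II", ]) / 2,
    aVL = s["aVL", ] - (s["I", ] - s["II", ] / 2),
    aVF = s["aVF", ] - (s["II", ] - s["I", ] / 2)
  )
  worst <- apply(abs(resid), 1, max)
  if (any(worst > tol)) {
    bad <- names(worst)[worst > tol]
    warning("derived-lead identities violated for ",
            paste(bad, collapse = ", "),
            " (max residual ", format(max(worst), digits = 6), ")",
            call. = FALSE)
  }
  ecg8(s[ECG8_LEADS, , drop = FALSE], sampling_rate = rate,
       strict = ncol(s) == 5000)
}

#' Read / write delimited-text ECG records
#'
#' The text interchange format is one record per file: 5000 rows of 8
#' whitespace- or comma-separated amplitude values (microvolts), columns in
#' the order I, II, V1-V6, no header. `write_ecg8()`/`read_ecg8()` round
#' trip exactly on integer amplitudes. `write_ecg12()` exports the 12-lead
#' view with a header row of lead labels.
#'
#' @param path file path.
#' @param sampling_rate sampling rate recorded on the returned object.
#' @param strict passed to [ecg8()].
#' @return `read_ecg8()` returns an [ecg8()] record; the writers return
#'   their input invisibly.
#' @export
read_ecg8 <- function(path, sampling_rate = 500, strict = TRUE) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric",
                                   sep = "", comment.char = ""))
  if (ncol(m) == 1) {  # comma-separated fallback
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = ","))
  }
  if (ncol(m) != 8) stop("expected 8 columns, got ", ncol(m), call. = FALSE)
  ecg8(t(m), sampling_rate = sampling_rate, strict = strict)
}

#' @param ecg the record to write (rows = time, columns = leads on disk).
#' @rdname read_ecg8
#' @export
write_ecg8 <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg8"))
  utils::write.table(t(ecg$samples), path, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(ecg)
}

#' @param header write the lead labels as a header row?
#' @rdname read_ecg8
#' @export
write_ecg12 <- function(ecg, path, header = TRUE) {
  stopifnot(inherits(ecg, "ecg12"))
  utils::write.table(t(ecg$samples), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(ecg)
}
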