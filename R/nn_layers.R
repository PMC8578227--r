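# Network building blocks on (channels, time, batch) arrays.

# 1D convolution via im2col + BLAS matmul. Weight is (C_out, C_in * K),
# bias (C_out, 1). Zero ("constant") padding; `pad` is the total amount,
# split left/right (extra sample goes right).
nn_conv1d <- function(x, w, b, kernel, stride = 1L, pad = 0L) {
  d <- dim(ad_value(x))
  pl <- pad %/% 2L
  pr <- pad - pl
  xp <- ad_pad_time(x, pl, pr)
  lp <- d[2] + pad
  lout <- (lp - kernel) %/% stride + 1L
  stopifnot((lp - kernel) %% stride == 0L)
  m <- ad_im2col(xp, kernel, stride, lout)
  y <- ad_add_bias(ad_matmul(w, m), b)
  ad_reshape(y, c(nrow(ad_value(w)), lout, d[3]))
}

# fully-connected layer on (n_in, B) matrices
nn_linear <- function(x, w, b) {
  ad_add_bias(ad_matmul(w, x), b)
}

# fan-in-scaled Gaussian initialisation (uses the current RNG stream)
init_conv <- function(c_out, c_in, kernel, gain = 2) {
  fan_in <- c_in * kernel
  w <- matrix(stats::rnorm(c_out * fan_in, sd = sqrt(gain / fan_in)),
              c_out, fan_in)
  list(w = w, b = matrix(0, c_out, 1))
}

init_linear <- function(n_out, n_in, gain = 2) {
  w <- matrix(stats::rnorm(n_out * n_in, sd = sqrt(gain / n_in)), n_out, n_in)
  list(w = w, b = matrix(0, n_out, 1))
}

#' Phase shuffle a feature map
#'
#' Shifts every channel of every record in time by an integer drawn uniformly
#' from `[-n, n]`, filling the vacated edge samples by reflection. The output
#' has the same shape as the input. Used after the critic's convolution
#' layers to stop it keying on the absolute phase of periodic features.
#'
#' @param x numeric array `(channels, time, batch)` (a plain array or an
#'   internal tape node). A matrix is treated as `(channels, time)` with
#'   batch 1.
#' @param n maximum absolute shift (non-negative integer). `n = 0` is the
#'   identity.
#' @param shifts optional integer matrix `(channels, batch)` of forced
#'   shifts, mainly for testing; when `NULL` shifts are drawn from the
#'   current RNG stream.
#' @return the shuffled array, same shape and type as the input.
#' @examples
#' x <- array(rnorm(2 * 8 * 1), c(2, 8, 1))
#' identical(phase_shuffle(x, 0), x)
#' phase_shuffle(x, 2, shifts = matrix(1L, 2, 1))[, , 1]
#' @export
phase_shuffle <- function(x, n, shifts = NULL) {
  if (n < 0) stop("phase shuffle width `n` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  was_matrix <- FALSE
  if (!is_node(x) && is.matrix(x)) {
    was_matrix <- TRUE
    dim(x) <- c(dim(x), 1L)
  }
  d <- dim(ad_value(x))
  if (n == 0L) {
    return(if (was_matrix) {
      y <- x
      dim(y) <- d[1:2]
      y
    } else x)
  }
  C <- d[1]; L <- d[2]; B <- d[3]
  if (is.null(shifts)) {
    shifts <- matrix(sample.int(2L * n + 1L, C * B, replace = TRUE) - n - 1L,
                     C, B)
  }
  stopifnot(all(abs(shifts) <= n), nrow(shifts) == C, ncol(shifts) == B)
  # reflected source index per (channel, time, batch)
  t_idx <- rep(rep(seq_len(L), each = C), times = B)
  s_vec <- as.vector(shifts[cbind(rep.int(seq_len(C), L * B),
                                  rep(seq_len(B), each = C * L))])
  # positive shift advances the signal: out[t] = x[t + s], edges reflected
  # (repeatedly, so maps stay valid even when the shift exceeds the length)
  src <- t_idx + s_vec
  if (L == 1L) {
    src[] <- 1L
  } else {
    repeat {
      lo <- src < 1L
      hi <- src > L
      if (!any(lo) && !any(hi)) break
      src[lo] <- 2L - src[lo]
      src[hi] <- 2L * L - src[hi]
    }
  }
  c_part <- rep.int(seq_len(C), L * B)
  b_part <- rep(seq_len(B), each = C * L)
  idx <- c_part + C * (src - 1L) + C * L * (b_part - 1L)
  dim(idx) <- d
  y <- ad_gather(x, idx)
  if (was_matrix) dim(y) <- d[1:2]
  y
}
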