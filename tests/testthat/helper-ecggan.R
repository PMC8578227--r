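# Shared fixtures, all generated in code.

# canonical single-beat parameter row (the population mean profile)
mean_beat <- function(...) {
  out <- data.frame(rr_interval = 60000 / 70, p_duration = 105,
                    pr_interval = 156, qrs_duration = 90, qt_interval = 395,
                    p_amplitude = 100, r_amplitude = 1287,
                    t_amplitude = 343, stj_offset = 2)
  args <- list(...)
  out[names(args)] <- args
  out
}

beat_train <- function(n_beats = 12, ...) {
  mean_beat(...)[rep(1, n_beats), ]
}

# reduced architectures for fast structural tests
tiny_gen_spec <- function() {
  wavegan_spec(length = 200L, base_width = 16L,
               up_factors = c(5L, 2L, 2L, 2L, 1L, 1L), kernel = 9L)
}

tiny_p2p_spec <- function() {
  pulse2pulse_spec(length = 64L, base_width = 4L,
                   down_strides = c(2L, 2L, 2L, 2L, 2L, 2L), kernel = 9L)
}

tiny_critic_spec <- function() {
  critic_spec(length = 64L, base_width = 4L,
              strides = c(2L, 2L, 2L, 2L, 2L, 1L, 1L), kernel = 9L)
}

tiny_config <- function(...) {
  args <- list(batch_size = 4L, max_epochs = 1L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(training_config, args)
}

# an analytic critic: w . vec(x), as a function usable wherever an
# ecg_critic is accepted by gradient_penalty()
linear_critic_fun <- function(w_vec, c_chan, l_len) {
  force(w_vec)
  function(x) {
    b <- dim(ecggan:::ad_value(x))[3]
    ecggan:::ad_matmul(matrix(w_vec, 1),
                       ecggan:::ad_reshape(x, c(c_chan * l_len, b)))
  }
}
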