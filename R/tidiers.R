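# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary
#'
#' One row per tabulated feature with mean, sd and the 2.5% / 97.5%
#' percentiles.
#'
#' @param x a `cohort_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cohort_summary <- function(x, ...) {
  x$stats
}

#' Glance at a cohort summary
#'
#' @inheritParams tidy.cohort_summary
#' @return a one-row tibble with `n`, `fraction_normal` and `qt_rr_r2`.
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n = x$n, fraction_normal = x$fraction_normal,
                 qt_rr_r2 = x$qt_rr_r2)
}

#' Tidy a training run
#'
#' The per-update loss history: one row per critic or generator update.
#'
#' @param x a `gan_train_state` from [train_gan()].
#' @param ... unused.
#' @return a tibble with `step`, `epoch`, `kind`, `wasserstein`, `penalty`
#'   and `loss`.
#' @export
tidy.gan_train_state <- function(x, ...) {
  x$history
}

#' Glance at a training run
#'
#' @inheritParams tidy.gan_train_state
#' @return a one-row tibble with the counters and the final loss values.
#' @export
glance.gan_train_state <- function(x, ...) {
  h <- x$history
  hc <- h[h$kind == "critic", ]
  hg <- h[h$kind == "generator", ]
  tibble::tibble(
    epochs = x$epoch,
    critic_updates = x$critic_updates,
    generator_updates = x$generator_updates,
    final_wasserstein = if (nrow(hc)) hc$wasserstein[nrow(hc)] else NA_real_,
    final_penalty = if (nrow(hc)) hc$penalty[nrow(hc)] else NA_real_,
    final_generator_loss = if (nrow(hg)) hg$loss[nrow(hg)] else NA_real_)
}
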