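# Adversarial training: Wasserstein objective with gradient penalty, Adam,
# a 5:1 critic:generator update schedule, checkpointing and bitwise-exact
# resumption.

#' Training configuration
#'
#' Defaults are the adversarial-training hyperparameters used throughout:
#' Adam with learning rate 1e-4, beta1 = 0.5, beta2 = 0.9; batch size 32;
#' five critic updates per generator update; gradient-penalty weight 10.
#'
#' @param learning_rate Adam step size (shared by generator and critic).
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size records per batch; the last incomplete batch of an
#'   epoch is dropped so the 5:1 cycle arithmetic stays exact.
#' @param critic_updates_per_generator_update critic:generator update ratio.
#' @param gp_weight gradient-penalty coefficient (lambda).
#' @param max_epochs training epochs (one epoch = one pass over the data).
#' @param checkpoint_every write a checkpoint every this many epochs (when a
#'   checkpoint directory is given to [train_gan()]).
#' @param seed integer seed for all training randomness (shuffling, latents,
#'   interpolation draws, phase shuffle).
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, beta1 = 0.5, beta2 = 0.9,
                            batch_size = 32L,
                            critic_updates_per_generator_update = 5L,
                            gp_weight = 10, max_epochs = 1L,
                            checkpoint_every = 1L, seed = NULL) {
  stopifnot(learning_rate >= 0, beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            batch_size >= 1, critic_updates_per_generator_update >= 1,
            gp_weight >= 0, max_epochs >= 1)
  structure(list(
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    batch_size = as.integer(batch_size),
    critic_updates_per_generator_update =
      as.integer(critic_updates_per_generator_update),
    gp_weight = gp_weight, max_epochs = as.integer(max_epochs),
    checkpoint_every = as.integer(checkpoint_every),
    seed = if (!is.null(seed)) as.integer(seed)), class = "training_config")
}

#' Read / write a training configuration as YAML
#' @param path YAML file path.
#' @return `read_training_config()` returns a `training_config`.
#' @export
read_training_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(training_config, vals)
}

#' @param config a `training_config`.
#' @rdname read_training_config
#' @export
write_training_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- gradient penalty ------------------------------------------------------

# build the penalty node; critic_fun maps an input node to a (1, B) score
# node. eps is drawn per record.
gp_node <- function(critic_fun, real, fake, lambda, higher = FALSE) {
  d <- dim(real)
  b <- d[3]
  eps <- stats::runif(b)
  epsa <- array(rep(eps, each = d[1] * d[2]), d)
  xh <- ad_node(epsa * real + (1 - epsa) * fake)
  scores <- critic_fun(xh)
  gx <- ad_grad(ad_sum(scores), xh, higher = higher)
  sq <- ad_reshape(ad_mul(gx, gx), c(d[1] * d[2], b))
  ssq <- ad_matmul(matrix(1, 1, d[1] * d[2]), sq)      # (1, B)
  norm <- ad_pow(ad_add(ssq, 1e-12), 0.5)
  dev <- ad_sub(norm, array(1, c(1, b)))
  ad_mul(ad_mean(ad_mul(dev, dev)), lambda)
}

#' Wasserstein gradient penalty
#'
#' `lambda` times the mean over interpolates `x = e * real + (1 - e) * fake`
#' (`e ~ U(0, 1)`, drawn per record) of the squared excursion of the
#' critic-gradient norm from 1: `(||d critic(x) / d x||_2 - 1)^2`. Always
#' non-negative; zero exactly when every interpolate sees a unit-norm
#' gradient.
#'
#' @param critic an `ecg_critic`, or any function mapping an input node to a
#'   score node (one score per record) -- the latter admits closed-form
#'   critics in tests.
#' @param real_batch,fake_batch arrays `(channels, time, batch)` of equal
#'   shape, in the units the critic consumes.
#' @param lambda penalty weight (default 10).
#' @return the scalar penalty.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch, lambda = 10) {
  real_batch <- as_batch(real_batch)
  fake_batch <- as_batch(fake_batch)
  if (!identical(dim(real_batch), dim(fake_batch))) {
    stop("real and fake batches must have identical shapes", call. = FALSE)
  }
  cf <- if (inherits(critic, "ecg_critic")) {
    function(x) critic_forward(critic$spec, critic$params, x)
  } else {
    critic
  }
  ad_value(gp_node(cf, real_batch, fake_batch, lambda, higher = FALSE))
}

# ---- single optimisation steps ---------------------------------------------

#' One critic update
#'
#' Freezes the generator, draws fresh latents, and applies one Adam update
#' to the critic under the loss
#' `mean(critic(fake)) - mean(critic(real)) + gradient penalty`.
#'
#' @param critic an `ecg_critic`.
#' @param generator an `ecg_generator` (left untouched).
#' @param real_batch array `(8, length, batch)` of real records in
#'   normalised units (i.e. already divided by the amplitude scale).
#' @param config a [training_config()].
#' @param opt Adam state from a previous call, or `NULL` to initialise.
#' @param z optional pre-drawn latents.
#' @return list with the updated `critic`, `opt`, and the loss components
#'   `wasserstein` (mean real score minus mean fake score), `penalty`, and
#'   `loss` (the minimised total).
#' @export
critic_step <- function(critic, generator, real_batch, config, opt = NULL,
                        z = NULL) {
  real_batch <- as_batch(real_batch)
  b <- dim(real_batch)[3]
  if (is.null(opt)) opt <- adam_init(critic$params)
  if (is.null(z)) z <- sample_latent(generator, b)
  fake <- if (generator$spec$kind == "wavegan_star") {
    wavegan_generate(generator, z, rescale = FALSE)
  } else {
    pulse2pulse_generate(generator, z, rescale = FALSE)
  }
  pnodes <- lapply(critic$params, ad_node)
  # joint forward over [real | fake] for the Wasserstein part (first-order
  # only), plus a separate interpolate pass carrying the differentiable
  # gradient graph for the penalty
  s <- critic_forward(critic$spec, pnodes,
                      ad_concat_b(real_batch, fake))    # (1, 2B)
  s_real <- ad_gather(s, matrix(seq_len(b), 1))
  s_fake <- ad_gather(s, matrix(b + seq_len(b), 1))
  core <- ad_sub(ad_mean(s_fake), ad_mean(s_real))
  cf <- function(x) critic_forward(critic$spec, pnodes, x)
  pen <- gp_node(cf, real_batch, fake, config$gp_weight, higher = TRUE)
  total <- ad_add(core, pen)
  if (!is.finite(ad_value(total))) {
    stop("non-finite critic loss (wasserstein part ",
         format(ad_value(core)), ", penalty ", format(ad_value(pen)),
         "); aborting", call. = FALSE)
  }
  grads <- ad_grad(total, pnodes)
  names(grads) <- names(critic$params)
  upd <- adam_step(opt, critic$params, grads, config$learning_rate,
                   config$beta1, config$beta2)
  critic$params <- upd$params
  list(critic = critic, opt = upd$opt,
       wasserstein = -ad_value(core),  # mean(real score) - mean(fake score)
       penalty = ad_value(pen), loss = ad_value(total))
}

#' One generator update
#'
#' Freezes the critic, draws fresh latents, and applies one Adam update to
#' the generator under the loss `-mean(critic(generator(z)))`.
#'
#' @inheritParams critic_step
#' @param batch_size latents to draw when `z` is `NULL`.
#' @return list with the updated `generator`, `opt`, and `loss`.
#' @export
generator_step <- function(critic, generator, config, opt = NULL, z = NULL,
                           batch_size = config$batch_size) {
  if (is.null(opt)) opt <- adam_init(generator$params)
  if (is.null(z)) z <- sample_latent(generator, batch_size)
  gnodes <- lapply(generator$params, ad_node)
  fake <- if (generator$spec$kind == "wavegan_star") {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
    wavegan_forward(generator$spec, gnodes, z)
  } else {
    pulse2pulse_forward(generator$spec, gnodes, as_batch(z))
  }
  scores <- critic_forward(critic$spec, critic$params, fake)
  loss <- ad_neg(ad_mean(scores))
  if (!is.finite(ad_value(loss))) {
    stop("non-finite generator loss; aborting", call. = FALSE)
  }
  grads <- ad_grad(loss, gnodes)
  names(grads) <- names(generator$params)
  upd <- adam_step(opt, generator$params, grads, config$learning_rate,
                   config$beta1, config$beta2)
  generator$params <- upd$params
  list(generator = generator, opt = upd$opt, loss = ad_value(loss))
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a training checkpoint
#'
#' A checkpoint is a directory `ckpt_epoch{N}/` holding the generator and
#' critic parameter archives, both optimizer states, the RNG state and the
#' loop counters, so training resumed from it reproduces the uninterrupted
#' run bitwise.
#'
#' @param state a `gan_train_state` (as returned by [train_gan()]).
#' @param dir checkpoint root directory.
#' @return `save_checkpoint()` returns the checkpoint path;
#'   `load_checkpoint()` the restored state list.
#' @export
save_checkpoint <- function(state, dir) {
  path <- file.path(dir, sprintf("ckpt_epoch%d", state$epoch))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(spec = state$generator$spec, params = state$generator$params),
          file.path(path, "generator.rds"))
  saveRDS(list(spec = state$critic$spec, params = state$critic$params),
          file.path(path, "critic.rds"))
  saveRDS(list(opt_g = state$opt_g, opt_c = state$opt_c),
          file.path(path, "optimizer.rds"))
  saveRDS(state$rng_state, file.path(path, "rng.rds"))
  saveRDS(state[c("epoch", "generator_updates", "critic_updates",
                  "history", "config")],
          file.path(path, "state.rds"))
  path
}

#' @param path a checkpoint directory written by `save_checkpoint()`.
#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  gen <- readRDS(file.path(path, "generator.rds"))
  cri <- readRDS(file.path(path, "critic.rds"))
  opt <- readRDS(file.path(path, "optimizer.rds"))
  st <- readRDS(file.path(path, "state.rds"))
  cls <- if (gen$spec$kind == "wavegan_star") "wavegan_generator" else
    "pulse2pulse_generator"
  list(
    generator = structure(gen, class = c(cls, "ecg_generator")),
    critic = structure(cri, class = "ecg_critic"),
    opt_g = opt$opt_g, opt_c = opt$opt_c,
    rng_state = readRDS(file.path(path, "rng.rds")),
    epoch = st$epoch, generator_updates = st$generator_updates,
    critic_updates = st$critic_updates, history = st$history,
    config = st$config)
}

# ---- the training loop -----------------------------------------------------

#' Train a generator/critic pair
#'
#' Runs the adversarial loop: per cycle, `critic_updates_per_generator_update`
#' critic updates on fresh real batches, then one generator update. One
#' epoch is one pass over the dataset; the trailing batches that cannot fill
#' a complete cycle are dropped. Fully reproducible given `config$seed`, and
#' resumable bitwise from a checkpoint.
#'
#' @param generator an `ecg_generator` (ignored when resuming).
#' @param critic an `ecg_critic` (ignored when resuming).
#' @param dataset real records: an array `(8, length, n)`, or a list of
#'   [ecg8()] records / matrices, in microvolts (normalised internally by
#'   the generator spec's amplitude scale).
#' @param config a [training_config()].
#' @param checkpoint_dir directory for checkpoints (`NULL` to disable).
#' @param resume_from a checkpoint directory to continue from; training runs
#'   on to `config$max_epochs`.
#' @param log_file optional CSV path receiving the per-step loss log.
#' @param verbose print a line per epoch?
#' @return a `gan_train_state`: the trained `generator` and `critic`, both
#'   optimizer states, the counters `epoch`, `generator_updates`,
#'   `critic_updates`, and `history`, a tibble with one row per update
#'   (columns `step`, `epoch`, `kind`, `wasserstein`, `penalty`, `loss`).
#' @export
train_gan <- function(generator, critic, dataset, config,
                      checkpoint_dir = NULL, resume_from = NULL,
                      log_file = NULL, verbose = FALSE) {
  ratio <- config$critic_updates_per_generator_update

  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    generator <- ck$generator
    critic <- ck$critic
    opt_g <- ck$opt_g
    opt_c <- ck$opt_c
    history <- list(ck$history)
    n_steps <- nrow(ck$history)
    gen_updates <- ck$generator_updates
    critic_updates <- ck$critic_updates
    start_epoch <- ck$epoch + 1L
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    opt_g <- adam_init(generator$params)
    opt_c <- adam_init(critic$params)
    history <- list()
    n_steps <- 0L
    gen_updates <- 0L
    critic_updates <- 0L
    start_epoch <- 1L
  }

  data <- as_batch(dataset) / generator$spec$scale
  n <- dim(data)[3]
  if (n < config$batch_size) {
    stop("dataset has ", n, " records but the batch size is ",
         config$batch_size, call. = FALSE)
  }

  rec <- function(kind, epoch, w, p, l) {
    n_steps <<- n_steps + 1L
    history[[length(history) + 1L]] <<- tibble::tibble(
      step = n_steps, epoch = epoch, kind = kind,
      wasserstein = w, penalty = p, loss = l)
  }

  if (start_epoch <= config$max_epochs) {
    for (epoch in start_epoch:config$max_epochs) {
      idx <- sample.int(n)
      n_batches <- n %/% config$batch_size
      n_cycles <- n_batches %/% ratio
      used <- 0L
      for (cy in seq_len(n_cycles)) {
        for (r in seq_len(ratio)) {
          take <- idx[used + seq_len(config$batch_size)]
          used <- used + config$batch_size
          cs <- critic_step(critic, generator,
                            data[, , take, drop = FALSE], config, opt_c)
          critic <- cs$critic
          opt_c <- cs$opt
          critic_updates <- critic_updates + 1L
          rec("critic", epoch, cs$wasserstein, cs$penalty, cs$loss)
        }
        gs <- generator_step(critic, generator, config, opt_g)
        generator <- gs$generator
        opt_g <- gs$opt
        gen_updates <- gen_updates + 1L
        rec("generator", epoch, NA_real_, NA_real_, gs$loss)
      }
      if (verbose) {
        message(sprintf("epoch %d | critic updates %d | generator updates %d",
                        epoch, critic_updates, gen_updates))
      }
      state <- structure(list(
        generator = generator, critic = critic, opt_g = opt_g, opt_c = opt_c,
        epoch = epoch, generator_updates = gen_updates,
        critic_updates = critic_updates,
        history = dplyr::bind_rows(history), config = config,
        rng_state = get(".Random.seed", envir = globalenv())),
        class = "gan_train_state")
      if (!is.null(checkpoint_dir) && epoch %% config$checkpoint_every == 0L) {
        save_checkpoint(state, checkpoint_dir)
      }
    }
  } else {
    state <- structure(list(
      generator = generator, critic = critic, opt_g = opt_g, opt_c = opt_c,
      epoch = start_epoch - 1L, generator_updates = gen_updates,
      critic_updates = critic_updates,
      history = dplyr::bind_rows(history), config = config,
      rng_state = get(".Random.seed", envir = globalenv())),
      class = "gan_train_state")
  }
  if (!is.null(log_file)) {
    utils::write.csv(state$history, log_file, row.names = FALSE)
  }
  state
}

#' @export
print.gan_train_state <- function(x, ...) {
  cat("<gan_train_state> ", x$epoch, " epochs | ",
      x$critic_updates, " critic updates | ",
      x$generator_updates, " generator updates\n", sep = "")
  invisible(x)
}

#' The reduced-scale training profile
#'
#' A self-contained configuration for CPU-scale end-to-end runs: 512-sample
#' signals, channel widths one eighth of the full architecture, batch size
#' 8. All optimisation hyperparameters (Adam settings, 5:1 update ratio,
#' penalty weight) are the full-scale ones.
#'
#' @param max_epochs,checkpoint_every,seed forwarded to [training_config()].
#' @return list with elements `generator_spec`, `critic_spec` and `config`.
#' @export
smoke_profile <- function(max_epochs = 100L, checkpoint_every = 50L,
                          seed = 1L) {
  list(
    generator_spec = pulse2pulse_spec(length = 512L, base_width = 8L,
                                      down_strides = rep(2L, 6)),
    critic_spec = critic_spec(length = 512L, base_width = 8L,
                              strides = c(2L, 2L, 2L, 2L, 2L, 2L, 1L)),
    config = training_config(batch_size = 8L, max_epochs = max_epochs,
                             checkpoint_every = checkpoint_every,
                             seed = seed))
}
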