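# WGAN-GP training loop: penalty oracles, Adam, isolation contracts,
# schedule bookkeeping, determinism, checkpoint resumption.

test_that("gradient penalty matches its closed forms", {
  set.seed(20)
  C <- 8L; L <- 16L; B <- 4L
  real <- array(rnorm(C * L * B), c(C, L, B))
  fake <- array(rnorm(C * L * B), c(C, L, B))

  # unit-gradient linear critic: penalty 0 for any batches
  w <- rnorm(C * L); w <- w / sqrt(sum(w^2))
  expect_equal(gradient_penalty(linear_critic_fun(w, C, L), real, fake),
               0, tolerance = 1e-10)

  # zero critic: gradient norm 0 everywhere, penalty = lambda
  expect_equal(gradient_penalty(linear_critic_fun(rep(0, C * L), C, L),
                                real, fake, lambda = 10),
               10, tolerance = 1e-4)
  expect_error(gradient_penalty(linear_critic_fun(w, C, L), real,
                                fake[, , 1:2]), "identical shapes")
})

test_that("gradient penalty on a quadratic critic matches a finite-difference oracle", {
  set.seed(21)
  C <- 1L; L <- 4L; B <- 3L
  a <- rnorm(L); q <- rnorm(L, sd = 0.5)
  # critic(x) = a.x + 0.5 * sum(q * x^2) per record
  quad <- function(x) {
    xb <- ecggan:::ad_reshape(x, c(L, dim(ecggan:::ad_value(x))[3]))
    lin <- ecggan:::ad_matmul(matrix(a, 1), xb)
    sq <- ecggan:::ad_matmul(matrix(q / 2, 1), ecggan:::ad_mul(xb, xb))
    ecggan:::ad_add(lin, sq)
  }
  real <- array(rnorm(L * B), c(C, L, B))
  fake <- array(rnorm(L * B), c(C, L, B))
  lambda <- 10

  # independent oracle: draw the same interpolates, evaluate the critic
  # gradient by central finite differences, average the squared norm
  # excursions directly
  seed <- 2024
  set.seed(seed)
  pen <- gradient_penalty(quad, real, fake, lambda = lambda)
  set.seed(seed)
  eps <- runif(B)
  oracle <- 0
  for (i in seq_len(B)) {
    xh <- eps[i] * real[1, , i] + (1 - eps[i]) * fake[1, , i]
    g <- numeric(L)
    h <- 1e-5
    for (j in seq_len(L)) {
      x1 <- xh; x1[j] <- x1[j] + h
      x2 <- xh; x2[j] <- x2[j] - h
      f1 <- sum(a * x1) + sum(q * x1^2) / 2
      f2 <- sum(a * x2) + sum(q * x2^2) / 2
      g[j] <- (f1 - f2) / (2 * h)
    }
    oracle <- oracle + (sqrt(sum(g^2)) - 1)^2
  }
  oracle <- lambda * oracle / B
  expect_equal(pen, oracle, tolerance = 1e-4)
  expect_gte(pen, 0)
})

test_that("gradient penalty is non-negative across random critics", {
  set.seed(22)
  cri <- build_model(tiny_critic_spec())
  for (i in 1:5) {
    real <- array(rnorm(8 * 64 * 4, sd = 2), c(8, 64, 4))
    fake <- array(rnorm(8 * 64 * 4, sd = 2), c(8, 64, 4))
    expect_gte(gradient_penalty(cri, real, fake), 0)
  }
})

test_that("one Adam step matches the closed-form update", {
  # single parameter, one step: m = (1-b1) g, v = (1-b2) g^2,
  # theta' = theta - lr * (m / (1-b1)) / (sqrt(v / (1-b2)) + eps)
  params <- list(w = matrix(2))
  grads <- list(w = matrix(0.3))
  opt <- ecggan:::adam_init(params)
  lr <- 1e-4; b1 <- 0.5; b2 <- 0.9
  upd <- ecggan:::adam_step(opt, params, grads, lr, b1, b2)
  expected <- 2 - lr * 0.3 / (sqrt(0.3^2) + 1e-8)
  expect_equal(upd$params$w[1, 1], expected, tolerance = 1e-10)
  # second step with the same gradient
  upd2 <- ecggan:::adam_step(upd$opt, upd$params, grads, lr, b1, b2)
  m2 <- (b1 * (1 - b1) * 0.3 + (1 - b1) * 0.3) / (1 - b1^2)
  v2 <- (b2 * (1 - b2) * 0.09 + (1 - b2) * 0.09) / (1 - b2^2)
  expect_equal(upd2$params$w[1, 1],
               upd$params$w[1, 1] - lr * m2 / (sqrt(v2) + 1e-8),
               tolerance = 1e-10)
})

test_that("steps update only their own network and lr 0 freezes it", {
  set.seed(23)
  gen <- build_model(tiny_p2p_spec())
  cri <- build_model(tiny_critic_spec())
  real <- array(rnorm(8 * 64 * 4), c(8, 64, 4))

  cfg0 <- tiny_config(learning_rate = 0)
  cs <- critic_step(cri, gen, real, cfg0)
  expect_identical(cs$critic$params, cri$params)       # lr 0: unchanged
  gs <- generator_step(cri, gen, cfg0)
  expect_identical(gs$generator$params, gen$params)

  cfg <- tiny_config()
  gen_before <- unlist(gen$params)
  cs <- critic_step(cri, gen, real, cfg)
  expect_identical(unlist(gen$params), gen_before)     # generator untouched
  expect_false(identical(cs$critic$params, cri$params))
  cri_before <- unlist(cri$params)
  gs <- generator_step(cri, gen, cfg)
  expect_identical(unlist(cri$params), cri_before)     # critic untouched
  expect_false(identical(gs$generator$params, gen$params))
})

test_that("the loop performs exactly 5 critic updates per generator update", {
  set.seed(24)
  gen <- build_model(tiny_p2p_spec())
  cri <- build_model(tiny_critic_spec())
  data <- array(rnorm(8 * 64 * 60), c(8, 64, 60))
  cfg <- tiny_config(max_epochs = 1L, seed = 5L)
  st <- train_gan(gen, cri, data, cfg)   # 15 batches -> 3 cycles
  expect_equal(st$generator_updates, 3L)
  expect_equal(st$critic_updates, 15L)
  expect_equal(st$critic_updates,
               cfg$critic_updates_per_generator_update * st$generator_updates)
  h <- st$history
  expect_equal(sum(h$kind == "critic"), 15L)
  expect_equal(sum(h$kind == "generator"), 3L)
  # within each cycle the 5 critic rows precede the generator row
  expect_equal(h$kind, rep(c(rep("critic", 5), "generator"), 3))
})

test_that("training is deterministic given the seed", {
  set.seed(25)
  gen <- build_model(tiny_p2p_spec())
  cri <- build_model(tiny_critic_spec())
  data <- array(rnorm(8 * 64 * 40), c(8, 64, 40))
  cfg <- tiny_config(max_epochs = 2L, seed = 7L)
  s1 <- train_gan(gen, cri, data, cfg)
  s2 <- train_gan(gen, cri, data, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$generator$params, s2$generator$params)
})

test_that("checkpoint -> reload -> continue reproduces the straight run bitwise", {
  set.seed(26)
  gen <- build_model(tiny_p2p_spec())
  cri <- build_model(tiny_critic_spec())
  data <- array(rnorm(8 * 64 * 40), c(8, 64, 40))
  dir <- withr::local_tempdir()

  cfg4 <- tiny_config(max_epochs = 4L, checkpoint_every = 2L, seed = 11L)
  straight <- train_gan(gen, cri, data, cfg4, checkpoint_dir = dir)

  resumed <- train_gan(dataset = data, config = cfg4,
                       resume_from = file.path(dir, "ckpt_epoch2"))
  expect_identical(resumed$generator$params, straight$generator$params)
  expect_identical(resumed$critic$params, straight$critic$params)
  expect_identical(resumed$history, straight$history)
  expect_identical(resumed$opt_c, straight$opt_c)
})

test_that("a convex toy objective decreases under the optimiser", {
  # generator = affine map fitted against a frozen linear critic score:
  # loss(theta) = -w . (theta * z) is improved monotonically in trend
  set.seed(27)
  nz <- 6L
  w <- rnorm(nz)
  theta <- list(a = matrix(rnorm(nz), nz, 1))
  opt <- ecggan:::adam_init(theta)
  losses <- numeric(50)
  for (i in 1:50) {
    z <- matrix(runif(nz, 0.5, 1.5), nz, 1)
    an <- ecggan:::ad_node(theta$a)
    out <- ecggan:::ad_mul(an, z)
    loss <- ecggan:::ad_neg(ecggan:::ad_sum(ecggan:::ad_mul(out, w)))
    # evaluate on a fixed probe latent for a noise-free trend statistic
    losses[i] <- -sum(theta$a * 1 * w)
    g <- ecggan:::ad_grad(loss, list(an))
    names(g) <- "a"
    upd <- ecggan:::adam_step(opt, theta, g, 0.05, 0.5, 0.9)
    theta <- upd$params; opt <- upd$opt
  }
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))
})

test_that("training configs round trip through YAML and validate", {
  cfg <- training_config(seed = 3L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$beta1, 0.5)
  expect_equal(cfg$beta2, 0.9)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$critic_updates_per_generator_update, 5L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_training_config(cfg, path)
  expect_equal(read_training_config(path), cfg)
  expect_error(training_config(beta1 = 1.2))
  expect_error(training_config(critic_updates_per_generator_update = 0))
})
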