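# Architecture contracts of the two generators and the critic.

test_that("generator and critic shape contracts hold across batch sizes", {
  set.seed(10)
  gen <- build_model(tiny_gen_spec())
  p2p <- build_model(tiny_p2p_spec())
  cri <- build_model(tiny_critic_spec())
  for (b in c(1L, 2L, 32L)) {
    z <- sample_latent(gen, b)
    out <- wavegan_generate(gen, z)
    expect_equal(dim(out), c(8L, 200L, b))
    z2 <- sample_latent(p2p, b)
    out2 <- pulse2pulse_generate(p2p, z2)
    expect_equal(dim(out2), c(8L, 64L, b))
    expect_length(criticize(cri, out2), b)
  }
})

test_that("latent mis-shapes raise shape errors", {
  set.seed(11)
  gen <- build_model(tiny_gen_spec())
  p2p <- build_model(tiny_p2p_spec())
  expect_error(wavegan_generate(gen, matrix(0, 7, 1)), "length 100")
  expect_error(pulse2pulse_generate(p2p, array(0, c(8, 32, 1))), "8 x 64")
  expect_error(phase_shuffle(array(0, c(2, 8, 1)), -1), ">= 0")
})

test_that("forward passes are deterministic and finite over many latents", {
  set.seed(12)
  gen <- build_model(tiny_gen_spec())
  p2p <- build_model(tiny_p2p_spec())
  z <- sample_latent(gen, 2)
  expect_identical(wavegan_generate(gen, z), wavegan_generate(gen, z))
  z2 <- sample_latent(p2p, 1)
  expect_identical(pulse2pulse_generate(p2p, z2),
                   pulse2pulse_generate(p2p, z2))
  for (s in 1:100) {
    set.seed(s)
    expect_true(all(is.finite(wavegan_generate(gen, sample_latent(gen, 1)))))
  }
})

test_that("introspection reports the contracted layer counts", {
  sw <- model_summary(wavegan_spec())
  expect_equal(attr(sw, "n_blocks"), 6L)
  expect_equal(sum(sw$kind == "deconv_block"), 6L)
  expect_equal(sw$out_length[nrow(sw)], 5000L)
  expect_equal(sw$out_channels[nrow(sw)], 8L)

  sp <- model_summary(pulse2pulse_spec())
  expect_equal(attr(sp, "n_down"), 6L)
  expect_equal(attr(sp, "n_up"), 6L)
  expect_equal(attr(sp, "n_skips"), 6L)
  # skip concatenation doubles every up block's input width
  up <- sp[sp$kind == "up_block", ]
  down <- sp[sp$kind == "down_block", ]
  skip_w <- c(rev(down$out_channels)[-1], 8L)
  prev_w <- c(down$out_channels[6], up$out_channels[-6])
  expect_equal(up$in_channels, prev_w + skip_w)

  sc <- model_summary(critic_spec())
  expect_equal(attr(sc, "n_conv_layers"), 7L)
  expect_equal(sum(sc$kind == "conv1d"), 7L)
  expect_true(all(sc$phase_shuffle[1:6]))
  expect_false(sc$phase_shuffle[7])

  path <- withr::local_tempfile(fileext = ".json")
  write_model_summary(critic_spec(), path)
  j <- jsonlite::read_json(path)
  expect_length(j, 8L)  # 7 conv layers + linear head
})

test_that("the U-net output depends on its skip connections", {
  set.seed(13)
  p2p <- build_model(tiny_p2p_spec())
  z <- sample_latent(p2p, 1)
  with_skips <- pulse2pulse_generate(p2p, z)
  without <- pulse2pulse_generate(p2p, z, use_skips = FALSE)
  expect_equal(dim(without), dim(with_skips))
  expect_gt(max(abs(with_skips - without)), 0)
})

test_that("phase shuffle obeys its contract", {
  x <- array(0, c(1, 4, 1))
  x[1, , 1] <- c(1, 2, 3, 4)
  # n = 0 is the identity
  expect_identical(phase_shuffle(x, 0), x)
  # forced shift +1 with reflection fill
  expect_equal(as.vector(phase_shuffle(x, 1, shifts = matrix(1L, 1, 1))),
               c(2, 3, 4, 3))
  expect_equal(as.vector(phase_shuffle(x, 1, shifts = matrix(-1L, 1, 1))),
               c(2, 1, 2, 3))
  # any draw preserves length and is one of the 2n+1 shift-and-reflects
  set.seed(14)
  n <- 2L
  xr <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  for (rep in 1:20) {
    y <- phase_shuffle(xr, n)
    expect_equal(dim(y), dim(xr))
    for (ch in 1:3) for (b in 1:2) {
      variants <- vapply(-n:n, function(s)
        isTRUE(all.equal(y[ch, , b],
                         as.vector(phase_shuffle(xr[ch, , b, drop = FALSE],
                                                 n, matrix(s, 1, 1))))),
        logical(1))
      expect_true(any(variants))
    }
  }
})

test_that("a zero-weight critic scores every record zero", {
  set.seed(15)
  cri <- build_model(tiny_critic_spec())
  cri$params <- lapply(cri$params, function(p) { p[] <- 0; p })
  x <- array(rnorm(8 * 64 * 3), c(8, 64, 3))
  expect_equal(criticize(cri, x), c(0, 0, 0))
})

test_that("the uniform latent law has mean 0, sd 1, bounded support", {
  set.seed(16)
  z <- sample_latent(wavegan_spec(), 2000)
  expect_lt(max(abs(z)), sqrt(3) + 1e-9)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(sd(z), 1, tolerance = 0.01)
})
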