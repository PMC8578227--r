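# The three network architectures: an up-sampling deconvolution generator
# mapping a 100-point latent vector to an 8 x 5000 ECG, a 1D U-net generator
# mapping an 8 x 5000 noise field to an ECG of the same shape through six
# down- and six up-sampling blocks with skip concatenation, and the critic
# they share: seven 1D convolution layers with Leaky ReLU and phase shuffle,
# ending in a single unbounded realness score per record.
#
# Networks operate in normalised amplitude units; training data are divided
# by a fixed `scale` (default 6000 uV, bringing normal ECGs to roughly
# [-1, 1]) and generated signals are multiplied back.

#' Architecture specification: deconvolution generator
#'
#' A latent vector is projected linearly to `base_width` channels of length
#' `length / prod(up_factors)`, then passes through six deconvolution
#' blocks, each an up-sampling layer, a constant (zero) padding layer, a 1D
#' convolution and a ReLU (the last block is linear). Channel widths halve
#' toward the 8-channel output.
#'
#' @param length output samples per channel (5000 = 10 s at 500 Hz).
#' @param latent_dim latent vector length (100).
#' @param base_width channel width after the initial projection.
#' @param up_factors per-block integer up-sampling factors; their product
#'   times the initial length must equal `length`.
#' @param kernel convolution kernel size.
#' @param latent_dist `"uniform"` for U(-sqrt(3), sqrt(3)) (zero mean, unit
#'   sd) or `"normal"` for N(0, 1).
#' @param scale amplitude normalisation constant in microvolts.
#' @return a `generator_spec` object.
#' @examples
#' s <- wavegan_spec()
#' s$block_count
#' @export
wavegan_spec <- function(length = 5000L, latent_dim = 100L,
                         base_width = 512L,
                         up_factors = c(5L, 5L, 5L, 2L, 2L, 2L),
                         kernel = 25L,
                         latent_dist = c("uniform", "normal"),
                         scale = 6000) {
  latent_dist <- match.arg(latent_dist)
  length <- as.integer(length)
  up_factors <- as.integer(up_factors)
  if (length %% prod(up_factors) != 0L) {
    stop("prod(up_factors) must divide `length`", call. = FALSE)
  }
  init_length <- length %/% prod(up_factors)
  nb <- length(up_factors)
  widths <- pmax(8L, as.integer(base_width %/% 2^seq_len(nb)))
  widths[nb] <- 8L
  structure(list(kind = "wavegan_star", length = length,
                 latent_dim = as.integer(latent_dim),
                 base_width = as.integer(base_width),
                 init_length = init_length,
                 up_factors = up_factors, channel_widths = widths,
                 kernel = as.integer(kernel), block_count = nb,
                 skip_connections = FALSE,
                 latent_dist = latent_dist, scale = scale),
            class = "generator_spec")
}

#' Architecture specification: 1D U-net generator
#'
#' The noise field (8 channels, same length as the output ECG) passes
#' through six down-sampling blocks (strided 1D convolution + Leaky ReLU)
#' and six up-sampling blocks mirroring them (up-sample, zero pad, convolve,
#' ReLU; last block linear). Each up block consumes the concatenation of its
#' upstream features with the mirror-level down-block features -- the sixth
#' skip is the noise input itself -- so every up block's input width is
#' doubled relative to the skip-free design.
#'
#' @inheritParams wavegan_spec
#' @param down_strides per-block integer strides; up-sampling factors are
#'   these reversed.
#' @param leaky_slope negative slope of the down-path Leaky ReLU.
#' @export
pulse2pulse_spec <- function(length = 5000L, base_width = 64L,
                             down_strides = c(2L, 2L, 2L, 5L, 5L, 5L),
                             kernel = 25L, leaky_slope = 0.2,
                             latent_dist = c("uniform", "normal"),
                             scale = 6000) {
  latent_dist <- match.arg(latent_dist)
  length <- as.integer(length)
  down_strides <- as.integer(down_strides)
  if (length %% prod(down_strides) != 0L) {
    stop("prod(down_strides) must divide `length`", call. = FALSE)
  }
  nb <- length(down_strides)
  down_widths <- pmin(as.integer(base_width) * 2L^(seq_len(nb) - 1L),
                      8L * as.integer(base_width))
  up_widths <- c(rev(down_widths)[-1], 8L)
  structure(list(kind = "pulse2pulse", length = length,
                 base_width = as.integer(base_width),
                 down_strides = down_strides,
                 up_factors = rev(down_strides),
                 down_widths = down_widths, up_widths = up_widths,
                 kernel = as.integer(kernel), block_count = nb,
                 skip_connections = TRUE, leaky_slope = leaky_slope,
                 latent_dist = latent_dist, scale = scale),
            class = "generator_spec")
}

#' Architecture specification: the shared critic
#'
#' Seven 1D convolution layers, each followed by a Leaky ReLU and (after
#' layers 1-6) a phase-shuffle layer; the final feature map is flattened
#' into a single linear realness score per record.
#'
#' @inheritParams wavegan_spec
#' @param strides per-layer convolution strides (7 of them; their product
#'   must divide `length`).
#' @param phase_shuffle_n maximum phase-shuffle shift.
#' @param leaky_slope Leaky ReLU negative slope.
#' @export
critic_spec <- function(length = 5000L, base_width = 64L,
                        strides = c(5L, 5L, 5L, 2L, 2L, 2L, 1L),
                        kernel = 25L, phase_shuffle_n = 2L,
                        leaky_slope = 0.2, scale = 6000) {
  length <- as.integer(length)
  strides <- as.integer(strides)
  if (length(strides) != 7L) stop("the critic has 7 layers", call. = FALSE)
  if (length %% prod(strides) != 0L) {
    stop("prod(strides) must divide `length`", call. = FALSE)
  }
  widths <- pmin(as.integer(base_width) * 2L^(0:6), 8L * as.integer(base_width))
  structure(list(layer_count = 7L, length = length, strides = strides,
                 channel_widths = widths, kernel = as.integer(kernel),
                 phase_shuffle_n = as.integer(phase_shuffle_n),
                 leaky_slope = leaky_slope,
                 final_length = length %/% prod(strides), scale = scale),
            class = "critic_spec")
}

# ---- parameter initialisation ----------------------------------------------

#' Instantiate a generator or critic with freshly initialised weights
#'
#' Weights are drawn with fan-in-scaled Gaussian initialisation from the
#' current RNG stream; call `set.seed()` first for reproducible models.
#'
#' @param spec a `generator_spec` or `critic_spec`.
#' @return an `ecg_generator` or `ecg_critic` object: a list with `spec` and
#'   a flat named list `params` of weight matrices.
#' @examples
#' set.seed(1)
#' g <- build_model(wavegan_spec(length = 500, base_width = 32))
#' length(g$params)
#' @export
build_model <- function(spec) {
  if (inherits(spec, "critic_spec")) return(build_critic_(spec))
  stopifnot(inherits(spec, "generator_spec"))
  k <- spec$kernel
  params <- list()
  if (spec$kind == "wavegan_star") {
    pr <- init_linear(spec$base_width * spec$init_length, spec$latent_dim)
    params$proj.w <- pr$w
    params$proj.b <- pr$b
    c_in <- spec$base_width
    for (i in seq_len(spec$block_count)) {
      c_out <- spec$channel_widths[i]
      l <- init_conv(c_out, c_in, k)
      params[[paste0("up", i, ".w")]] <- l$w
      params[[paste0("up", i, ".b")]] <- l$b
      c_in <- c_out
    }
    cls <- c("wavegan_generator", "ecg_generator")
  } else {
    c_in <- 8L
    for (i in seq_len(spec$block_count)) {
      c_out <- spec$down_widths[i]
      l <- init_conv(c_out, c_in, k)
      params[[paste0("down", i, ".w")]] <- l$w
      params[[paste0("down", i, ".b")]] <- l$b
      c_in <- c_out
    }
    nb <- spec$block_count
    skip_widths <- c(rev(spec$down_widths)[-1], 8L)  # d5..d1, then the input
    h_in <- spec$down_widths[nb]
    for (i in seq_len(nb)) {
      c_out <- spec$up_widths[i]
      l <- init_conv(c_out, h_in + skip_widths[i], k)
      params[[paste0("up", i, ".w")]] <- l$w
      params[[paste0("up", i, ".b")]] <- l$b
      h_in <- c_out
    }
    cls <- c("pulse2pulse_generator", "ecg_generator")
  }
  structure(list(spec = spec, params = params), class = cls)
}

build_critic_ <- function(spec) {
  k <- spec$kernel
  params <- list()
  c_in <- 8L
  for (i in 1:7) {
    c_out <- spec$channel_widths[i]
    l <- init_conv(c_out, c_in, k)
    params[[paste0("conv", i, ".w")]] <- l$w
    params[[paste0("conv", i, ".b")]] <- l$b
    c_in <- c_out
  }
  hd <- init_linear(1L, c_in * spec$final_length, gain = 1)
  params$head.w <- hd$w
  params$head.b <- hd$b
  structure(list(spec = spec, params = params), class = "ecg_critic")
}

# ---- latent sampling -------------------------------------------------------

#' Sample latent noise for a generator
#'
#' For the deconvolution generator: a `latent_dim x n` matrix. For the U-net
#' generator: an `8 x length x n` array. The default law is the uniform
#' distribution with mean 0 and sd 1, i.e. U(-sqrt(3), sqrt(3));
#' `latent_dist = "normal"` in the spec switches to N(0, 1).
#'
#' @param spec a `generator_spec` (or an `ecg_generator`, whose spec is
#'   used).
#' @param n number of latent draws.
#' @return matrix or 3D array of latent values.
#' @export
sample_latent <- function(spec, n = 1L) {
  if (inherits(spec, "ecg_generator")) spec <- spec$spec
  stopifnot(inherits(spec, "generator_spec"))
  sampler <- if (spec$latent_dist == "uniform") {
    function(m) stats::runif(m, -sqrt(3), sqrt(3))
  } else {
    function(m) stats::rnorm(m)
  }
  if (spec$kind == "wavegan_star") {
    matrix(sampler(spec$latent_dim * n), spec$latent_dim, n)
  } else {
    array(sampler(8L * spec$length * n), c(8L, spec$length, n))
  }
}

# ---- forward passes --------------------------------------------------------

# internal forwards take (spec, params, input) where params entries may be
# tape nodes; outputs are in normalised units
wavegan_forward <- function(spec, params, z) {
  b <- ncol(z)
  h <- nn_linear(z, params$proj.w, params$proj.b)
  h <- ad_relu(ad_reshape(h, c(spec$base_width, spec$init_length, b)))
  for (i in seq_len(spec$block_count)) {
    h <- ad_upsample(h, spec$up_factors[i])
    h <- nn_conv1d(h, params[[paste0("up", i, ".w")]],
                   params[[paste0("up", i, ".b")]],
                   kernel = spec$kernel, stride = 1L, pad = spec$kernel - 1L)
    if (i < spec$block_count) h <- ad_relu(h)
  }
  h
}

pulse2pulse_forward <- function(spec, params, z, use_skips = TRUE) {
  nb <- spec$block_count
  k <- spec$kernel
  feats <- vector("list", nb)
  h <- z
  for (i in seq_len(nb)) {
    s <- spec$down_strides[i]
    h <- nn_conv1d(h, params[[paste0("down", i, ".w")]],
                   params[[paste0("down", i, ".b")]],
                   kernel = k, stride = s, pad = k - s)
    h <- ad_leaky_relu(h, spec$leaky_slope)
    feats[[i]] <- h
  }
  for (i in seq_len(nb)) {
    h <- ad_upsample(h, spec$up_factors[i])
    skip <- if (i < nb) feats[[nb - i]] else z
    if (use_skips) {
      h <- ad_concat_c(h, skip)
    } else {
      # ablation: keep layer shapes by zero-filling the skip channels
      zero <- ad_value(skip)
      zero[] <- 0
      h <- ad_concat_c(h, zero)
    }
    h <- nn_conv1d(h, params[[paste0("up", i, ".w")]],
                   params[[paste0("up", i, ".b")]],
                   kernel = k, stride = 1L, pad = k - 1L)
    if (i < nb) h <- ad_relu(h)
  }
  h
}

critic_forward <- function(spec, params, x, shuffle = TRUE) {
  h <- x
  for (i in 1:7) {
    s <- spec$strides[i]
    h <- nn_conv1d(h, params[[paste0("conv", i, ".w")]],
                   params[[paste0("conv", i, ".b")]],
                   kernel = spec$kernel, stride = s, pad = spec$kernel - s)
    h <- ad_leaky_relu(h, spec$leaky_slope)
    if (shuffle && i < 7 && spec$phase_shuffle_n > 0) {
      h <- phase_shuffle(h, spec$phase_shuffle_n)
    }
  }
  d <- dim(ad_value(h))
  flat <- ad_reshape(h, c(d[1] * d[2], d[3]))
  nn_linear(flat, params$head.w, params$head.b)  # (1, B)
}

as_batch <- function(x, length = NULL) {
  if (inherits(x, "ecg8")) x <- x$samples
  if (is.list(x)) {
    mats <- lapply(x, function(e) if (inherits(e, "ecg8")) e$samples else e)
    x <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  }
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(is.array(x), base::length(dim(x)) == 3L)
  if (!is.null(length) && dim(x)[2] != length) {
    stop("expected signals of length ", length, ", got ", dim(x)[2],
         call. = FALSE)
  }
  x
}

#' Generate ECGs with the deconvolution generator
#'
#' Deterministic given the latent input and the weights.
#'
#' @param generator an `ecg_generator` built from [wavegan_spec()].
#' @param z latent matrix `latent_dim x n` (a vector is treated as one
#'   record).
#' @param rescale multiply by the spec's amplitude scale to get microvolts?
#' @return numeric array `8 x length x n`.
#' @export
wavegan_generate <- function(generator, z, rescale = TRUE) {
  spec <- generator$spec
  stopifnot(spec$kind == "wavegan_star")
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (nrow(z) != spec$latent_dim) {
    stop("latent vector must have length ", spec$latent_dim, ", got ",
         nrow(z), call. = FALSE)
  }
  out <- wavegan_forward(spec, generator$params, z)
  if (rescale) out <- out * spec$scale
  out
}

#' Generate ECGs with the U-net generator
#'
#' @param generator an `ecg_generator` built from [pulse2pulse_spec()].
#' @param z noise array `8 x length x n` (an `8 x length` matrix is one
#'   record).
#' @param rescale multiply by the amplitude scale to get microvolts?
#' @param use_skips forward with the skip concatenations (`TRUE`, the
#'   architecture) or with the skip channels zeroed (ablation; weights are
#'   shared so the comparison isolates the skips' contribution).
#' @return numeric array `8 x length x n`.
#' @export
pulse2pulse_generate <- function(generator, z, rescale = TRUE,
                                 use_skips = TRUE) {
  spec <- generator$spec
  stopifnot(spec$kind == "pulse2pulse")
  z <- as_batch(z)
  if (dim(z)[1] != 8L || dim(z)[2] != spec$length) {
    stop("latent field must be 8 x ", spec$length, ", got ",
         dim(z)[1], " x ", dim(z)[2], call. = FALSE)
  }
  out <- pulse2pulse_forward(spec, generator$params, z, use_skips = use_skips)
  if (rescale) out <- out * spec$scale
  out
}

#' Score ECGs with the critic
#'
#' One unbounded real score per record: large for records the critic deems
#' real. Deterministic given the weights when the phase-shuffle draws are
#' seeded (or disabled).
#'
#' @param critic an `ecg_critic`.
#' @param x an [ecg8()] record, a list of them, an `8 x length` matrix or an
#'   `8 x length x n` array, in microvolts when `normalise = TRUE`.
#' @param shuffle apply the phase-shuffle layers? (Drawn from the current
#'   RNG stream.)
#' @param normalise divide by the spec's amplitude scale first?
#' @return numeric vector of `n` scores.
#' @export
criticize <- function(critic, x, shuffle = TRUE, normalise = TRUE) {
  stopifnot(inherits(critic, "ecg_critic"))
  x <- as_batch(x, length = critic$spec$length)
  if (normalise) x <- x / critic$spec$scale
  as.vector(critic_forward(critic$spec, critic$params, x, shuffle = shuffle))
}

#' Convenience generation of ECG records
#'
#' Samples latents from the generator's latent law and returns finished
#' records in microvolts.
#'
#' @param generator an `ecg_generator`.
#' @param n number of records.
#' @param z optional pre-drawn latents (see [sample_latent()]).
#' @return a list of [ecg8()] records (`strict` only when the generator
#'   emits 5000-sample signals).
#' @export
generate_ecg <- function(generator, n = 1L, z = NULL) {
  if (is.null(z)) z <- sample_latent(generator, n)
  wav <- generator$spec$kind == "wavegan_star"
  if (wav && is.null(dim(z))) z <- matrix(z, ncol = 1)
  n <- if (wav) ncol(z) else dim(as_batch(z))[3]
  if (!wav) z <- as_batch(z)
  # forward in small chunks to bound the im2col working memory
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 8))
  out <- vector("list", n)
  for (ix in chunks) {
    o <- if (wav) {
      wavegan_generate(generator, z[, ix, drop = FALSE])
    } else {
      pulse2pulse_generate(generator, z[, , ix, drop = FALSE])
    }
    strict <- dim(o)[2] == 5000L
    for (j in seq_along(ix)) {
      out[[ix[j]]] <- ecg8(o[, , j], strict = strict)
    }
  }
  out
}

# ---- introspection ---------------------------------------------------------

#' Layer-by-layer architecture summary
#'
#' @param model an `ecg_generator`, `ecg_critic`, `generator_spec` or
#'   `critic_spec`.
#' @return a tibble with one row per layer: kind, channels in/out, kernel,
#'   resampling factor or stride, activation, output length and parameter
#'   count. Attributes `n_blocks`, `n_down`, `n_up`, `n_skips` and
#'   `n_conv_layers` summarise the counts the architecture contracts fix.
#' @examples
#' model_summary(critic_spec(length = 500, base_width = 8,
#'                           strides = c(2, 2, 5, 5, 1, 1, 1)))
#' @export
model_summary <- function(model) {
  spec <- if (inherits(model, c("ecg_generator", "ecg_critic"))) {
    model$spec
  } else {
    model
  }
  k <- spec$kernel
  rows <- list()
  if (inherits(spec, "critic_spec")) {
    c_in <- 8L
    len <- spec$length
    for (i in 1:7) {
      len <- len %/% spec$strides[i]
      c_out <- spec$channel_widths[i]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = paste0("conv", i), kind = "conv1d",
        in_channels = c_in, out_channels = c_out, kernel = k,
        factor = spec$strides[i], activation = "leaky_relu",
        phase_shuffle = i < 7 && spec$phase_shuffle_n > 0,
        out_length = len, params = c_out * (c_in * k + 1))
      c_in <- c_out
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = "head", kind = "linear", in_channels = c_in,
      out_channels = 1L, kernel = NA_integer_, factor = 1L,
      activation = "linear", phase_shuffle = FALSE, out_length = 1L,
      params = c_in * spec$final_length + 1)
    out <- dplyr::bind_rows(rows)
    attr(out, "n_conv_layers") <- 7L
    return(out)
  }
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$kind == "wavegan_star") {
    rows[[1]] <- tibble::tibble(
      layer = "proj", kind = "linear", in_channels = spec$latent_dim,
      out_channels = spec$base_width, kernel = NA_integer_, factor = 1L,
      activation = "relu", phase_shuffle = FALSE,
      out_length = spec$init_length,
      params = spec$base_width * spec$init_length * (spec$latent_dim + 1))
    c_in <- spec$base_width
    len <- spec$init_length
    for (i in seq_len(spec$block_count)) {
      len <- len * spec$up_factors[i]
      c_out <- spec$channel_widths[i]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = paste0("deconv", i), kind = "deconv_block",
        in_channels = c_in, out_channels = c_out, kernel = k,
        factor = spec$up_factors[i],
        activation = if (i < spec$block_count) "relu" else "linear",
        phase_shuffle = FALSE, out_length = len,
        params = c_out * (c_in * k + 1))
      c_in <- c_out
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "n_blocks") <- spec$block_count
    return(out)
  }
  # pulse2pulse
  c_in <- 8L
  len <- spec$length
  for (i in seq_len(spec$block_count)) {
    len <- len %/% spec$down_strides[i]
    c_out <- spec$down_widths[i]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = paste0("down", i), kind = "down_block", in_channels = c_in,
      out_channels = c_out, kernel = k, factor = spec$down_strides[i],
      activation = "leaky_relu", phase_shuffle = FALSE, out_length = len,
      params = c_out * (c_in * k + 1))
    c_in <- c_out
  }
  skip_widths <- c(rev(spec$down_widths)[-1], 8L)
  for (i in seq_len(spec$block_count)) {
    len <- len * spec$up_factors[i]
    c_out <- spec$up_widths[i]
    cin_eff <- c_in + skip_widths[i]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = paste0("up", i), kind = "up_block", in_channels = cin_eff,
      out_channels = c_out, kernel = k, factor = spec$up_factors[i],
      activation = if (i < spec$block_count) "relu" else "linear",
      phase_shuffle = FALSE, out_length = len,
      params = c_out * (cin_eff * k + 1))
    c_in <- c_out
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_down") <- spec$block_count
  attr(out, "n_up") <- spec$block_count
  attr(out, "n_skips") <- spec$block_count
  out
}

#' Write an architecture summary as JSON
#'
#' @param model see [model_summary()].
#' @param path output path.
#' @return the summary tibble, invisibly.
#' @export
write_model_summary <- function(model, path) {
  s <- model_summary(model)
  jsonlite::write_json(s, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(s)
}
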