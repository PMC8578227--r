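# Reverse-mode automatic differentiation on dense arrays.
#
# Design: a define-by-run tape. Every primitive accepts plain arrays or tape
# nodes; with only plain inputs it computes eagerly and returns a plain array
# (zero overhead), with at least one node input it records a node carrying a
# pullback. Pullbacks are written in terms of the primitives themselves, so
# calling ad_grad() with higher = TRUE yields gradient *nodes* that can be
# differentiated again -- this is what lets the Wasserstein gradient penalty
# be backpropagated through to the critic weights.

.ad <- new.env(parent = emptyenv())
.ad$count <- 0L
.ad$higher <- FALSE
.ad$cache <- new.env(parent = emptyenv())   # index caches for structured ops

ad_node <- function(value, parents = list(), pullback = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$parents <- parents
  e$pb <- pullback
  .ad$count <- .ad$count + 1L
  e$id <- .ad$count
  class(e) <- "ad_node"
  e
}

is_node <- function(x) inherits(x, "ad_node")

#' @keywords internal
ad_value <- function(x) if (is_node(x)) x$v else x

# Inside pullbacks: captured operands stay on the tape only when a
# differentiable gradient graph was requested.
capv <- function(x) if (.ad$higher) x else ad_value(x)

any_node <- function(...) {
  for (a in list(...)) if (is_node(a)) return(TRUE)
  FALSE
}

# ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(a, b) {
  if (!any_node(a, b)) return(a + b)
  av <- ad_value(a); bv <- ad_value(b)
  la <- length(av); lb <- length(bv)
  ad_node(av + bv, list(a, b), function(g) list(
    if (is_node(a)) (if (la == 1L && lb > 1L) ad_sum(g) else g) else NULL,
    if (is_node(b)) (if (lb == 1L && la > 1L) ad_sum(g) else g) else NULL))
}

ad_sub <- function(a, b) ad_add(a, ad_neg(b))

ad_neg <- function(a) {
  if (!is_node(a)) return(-a)
  ad_node(-a$v, list(a), function(g) list(ad_neg(g)))
}

ad_mul <- function(a, b) {
  if (!any_node(a, b)) return(a * b)
  av <- ad_value(a); bv <- ad_value(b)
  la <- length(av); lb <- length(bv)
  ad_node(av * bv, list(a, b), function(g) list(
    if (is_node(a)) {
      ga <- ad_mul(g, capv(b))
      if (la == 1L && lb > 1L) ad_sum(ga) else ga
    } else NULL,
    if (is_node(b)) {
      gb <- ad_mul(g, capv(a))
      if (lb == 1L && la > 1L) ad_sum(gb) else gb
    } else NULL))
}

ad_pow <- function(a, p) {
  if (!is_node(a)) return(a^p)
  ad_node(a$v^p, list(a), function(g)
    list(ad_mul(g, ad_mul(ad_pow(capv(a), p - 1), p))))
}

ad_sum <- function(a) {
  if (!is_node(a)) return(sum(a))
  dims <- dim(a$v)
  n <- length(a$v)
  ad_node(sum(a$v), list(a), function(g)
    list(ad_bcast(g, dims, n)))
}

# broadcast a scalar to a full array; adjoint pair of ad_sum
ad_bcast <- function(a, dims, n) {
  if (!is_node(a)) {
    out <- rep.int(as.vector(a), n)
    if (!is.null(dims)) dim(out) <- dims
    return(out)
  }
  out <- rep.int(as.vector(a$v), n)
  if (!is.null(dims)) dim(out) <- dims
  ad_node(out, list(a), function(g) list(ad_sum(g)))
}

ad_mean <- function(a) ad_mul(ad_sum(a), 1 / length(ad_value(a)))

ad_leaky_relu <- function(a, slope = 0.2) {
  v <- ad_value(a)
  mask <- (v >= 0) + slope * (v < 0)   # piecewise-constant derivative
  if (!is_node(a)) return(v * mask)
  ad_node(v * mask, list(a), function(g) list(ad_mul(g, mask)))
}

ad_relu <- function(a) ad_leaky_relu(a, slope = 0)

# ---- linear algebra --------------------------------------------------------

ad_t <- function(a) {
  if (!is_node(a)) return(t(a))
  ad_node(t(a$v), list(a), function(g) list(ad_t(g)))
}

ad_matmul <- function(a, b) {
  if (!any_node(a, b)) return(a %*% b)
  ad_node(ad_value(a) %*% ad_value(b), list(a, b), function(g) list(
    if (is_node(a)) ad_matmul_nt(g, capv(b)) else NULL,
    if (is_node(b)) ad_matmul_tn(capv(a), g) else NULL))
}

# a %*% t(b) and t(a) %*% b without forming the transpose; together with
# ad_matmul these three close under differentiation
ad_matmul_nt <- function(a, b) {
  if (!any_node(a, b)) return(tcrossprod(a, b))
  ad_node(tcrossprod(ad_value(a), ad_value(b)), list(a, b), function(g) list(
    if (is_node(a)) ad_matmul(g, capv(b)) else NULL,
    if (is_node(b)) ad_matmul_tn(g, capv(a)) else NULL))
}

ad_matmul_tn <- function(a, b) {
  if (!any_node(a, b)) return(crossprod(a, b))
  ad_node(crossprod(ad_value(a), ad_value(b)), list(a, b), function(g) list(
    if (is_node(a)) ad_matmul_nt(capv(b), g) else NULL,
    if (is_node(b)) ad_matmul(capv(a), g) else NULL))
}

ad_reshape <- function(a, dims) {
  if (!is_node(a)) { dim(a) <- dims; return(a) }
  old <- dim(a$v)
  v <- a$v
  dim(v) <- dims
  ad_node(v, list(a), function(g) list(ad_reshape(g, old)))
}

# bias add: X is (m, n), b is a length-m vector (stored as m x 1 matrix)
ad_add_bias <- function(x, b) {
  if (!any_node(x, b)) return(x + as.vector(b))
  xv <- ad_value(x)
  n <- ncol(xv)
  ad_node(xv + as.vector(ad_value(b)), list(x, b), function(g) list(
    if (is_node(x)) g else NULL,
    if (is_node(b)) ad_matmul(g, matrix(1, n, 1)) else NULL))
}

# ---- gather / scatter (mutually adjoint) -----------------------------------

scatter_plain <- function(v, idx, n, out_dim = NULL) {
  out <- numeric(n)
  idx <- as.vector(idx)
  v <- as.vector(v)
  dup <- duplicated(idx)
  if (!any(dup)) {
    out[idx] <- v
  } else if (mean(dup) < 0.2) {
    # near-injective map (e.g. phase-shuffle edges): assign, then add the
    # few colliding entries
    out[idx[!dup]] <- v[!dup]
    for (i in which(dup)) out[idx[i]] <- out[idx[i]] + v[i]
  } else {
    s <- rowsum(v, idx)
    out[as.integer(rownames(s))] <- s
  }
  if (!is.null(out_dim)) dim(out) <- out_dim
  out
}

ad_gather <- function(x, idx) {
  xv <- ad_value(x)
  out <- xv[as.vector(idx)]
  dim(out) <- dim(idx)
  if (!is_node(x)) return(out)
  n <- length(xv)
  out_dim <- dim(xv)
  ad_node(out, list(x), function(g) list(ad_scatter(g, idx, n, out_dim)))
}

ad_scatter <- function(x, idx, n, out_dim = NULL) {
  if (!is_node(x)) return(scatter_plain(x, idx, n, out_dim))
  ad_node(scatter_plain(x$v, idx, n, out_dim), list(x),
          function(g) list(ad_gather(g, idx)))
}

# ---- structured linear ops on (C, L, B) feature arrays ---------------------

# zero padding / cropping along the time axis (possibly asymmetric)
ad_pad_time <- function(x, pl, pr = pl) {
  if (pl == 0L && pr == 0L) return(x)
  xv <- ad_value(x)
  d <- dim(xv)
  out <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  out[, (pl + 1L):(pl + d[2]), ] <- xv
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_crop_time(g, pl, pr)))
}

ad_crop_time <- function(x, pl, pr = pl) {
  if (pl == 0L && pr == 0L) return(x)
  xv <- ad_value(x)
  d <- dim(xv)
  out <- xv[, (pl + 1L):(d[2] - pr), , drop = FALSE]
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_pad_time(g, pl, pr)))
}

# nearest-neighbour up-sampling by integer factor f; adjoint is sum-pooling
ad_upsample <- function(x, f) {
  if (f == 1L) return(x)
  xv <- ad_value(x)
  d <- dim(xv)
  out <- xv[, rep(seq_len(d[2]), each = f), , drop = FALSE]
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_sumpool(g, f)))
}

ad_sumpool <- function(x, f) {
  if (f == 1L) return(x)
  xv <- ad_value(x)
  d <- dim(xv)           # (C, f * L, B)
  L <- d[2] %/% f
  a4 <- xv
  dim(a4) <- c(d[1], f, L, d[3])
  out <- a4[, 1, , , drop = FALSE]
  if (f > 1L) for (j in 2:f) out <- out + a4[, j, , , drop = FALSE]
  dim(out) <- c(d[1], L, d[3])
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_upsample(g, f)))
}

# channel concatenation / cropping / zero-embedding
ad_concat_c <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- dim(av); db <- dim(bv)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- av
  out[da[1] + seq_len(db[1]), , ] <- bv
  if (!any_node(a, b)) return(out)
  ad_node(out, list(a, b), function(g) list(
    if (is_node(a)) ad_crop_c(g, 1L, da[1]) else NULL,
    if (is_node(b)) ad_crop_c(g, da[1] + 1L, da[1] + db[1]) else NULL))
}

ad_crop_c <- function(x, from, to) {
  xv <- ad_value(x)
  ctot <- dim(xv)[1]
  out <- xv[from:to, , , drop = FALSE]
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_embed_c(g, from, ctot)))
}

ad_embed_c <- function(x, from, ctot) {
  xv <- ad_value(x)
  d <- dim(xv)
  out <- array(0, c(ctot, d[2], d[3]))
  out[from:(from + d[1] - 1L), , ] <- xv
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_crop_c(g, from, from + d[1] - 1L)))
}

# batch-axis concatenation / cropping (lets one forward pass score several
# sub-batches jointly)
ad_concat_b <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- dim(av); db <- dim(bv)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- av
  out[, , da[3] + seq_len(db[3])] <- bv
  if (!any_node(a, b)) return(out)
  ad_node(out, list(a, b), function(g) list(
    if (is_node(a)) ad_crop_b(g, 1L, da[3]) else NULL,
    if (is_node(b)) ad_crop_b(g, da[3] + 1L, da[3] + db[3]) else NULL))
}

ad_crop_b <- function(x, from, to) {
  xv <- ad_value(x)
  btot <- dim(xv)[3]
  out <- xv[, , from:to, drop = FALSE]
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_embed_b(g, from, btot)))
}

ad_embed_b <- function(x, from, btot) {
  xv <- ad_value(x)
  d <- dim(xv)
  out <- array(0, c(d[1], d[2], btot))
  out[, , from:(from + d[3] - 1L)] <- xv
  if (!is_node(x)) return(out)
  ad_node(out, list(x), function(g) list(ad_crop_b(g, from, from + d[3] - 1L)))
}

# ---- im2col / col2im (the conv workhorses; mutually adjoint) ---------------

im2col_index <- function(C, Lp, B, K, stride, Lout) {
  key <- paste(C, Lp, B, K, stride, Lout, sep = "_")
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  c_idx <- rep.int(seq_len(C), K * Lout * B)
  k_idx <- rep.int(rep(seq_len(K), each = C), Lout * B)
  l_idx <- rep.int(rep(seq_len(Lout), each = C * K), B)
  b_idx <- rep(seq_len(B), each = C * K * Lout)
  idx <- c_idx + C * ((l_idx - 1L) * stride + k_idx - 1L) + C * Lp * (b_idx - 1L)
  if (length(idx) <= 4e6) {
    .ad$cache[[key]] <- idx   # plain vector; callers set dims on the result
  }
  idx
}

im2col_plain <- function(xp, K, stride, Lout) {
  d <- dim(xp)
  out <- xp[im2col_index(d[1], d[2], d[3], K, stride, Lout)]
  dim(out) <- c(d[1] * K, Lout * d[3])
  out
}

# adjoint of im2col: accumulate the (C, K, Lout, B) patch gradients back
# onto the padded signal; 2D column arithmetic keeps the K-loop cheap
col2im_plain <- function(m, C, Lp, B, K, stride, Lout) {
  a <- m
  dim(a) <- c(C, K * Lout * B)
  out <- matrix(0, C, Lp * B)
  base <- rep.int((seq_len(Lout) - 1L) * stride, B) +
    rep(Lp * (seq_len(B) - 1L), each = Lout)            # k = 1 target cols
  sel0 <- rep.int(K * (seq_len(Lout) - 1L), B) +
    rep(K * Lout * (seq_len(B) - 1L), each = Lout)       # k = 1 source cols
  for (k in seq_len(K)) {
    cols <- base + k
    out[, cols] <- out[, cols] + a[, sel0 + k]
  }
  dim(out) <- c(C, Lp, B)
  out
}

ad_im2col <- function(x, K, stride, Lout) {
  if (!is_node(x)) return(im2col_plain(x, K, stride, Lout))
  d <- dim(x$v)
  ad_node(im2col_plain(x$v, K, stride, Lout), list(x), function(g)
    list(ad_col2im(g, d[1], d[2], d[3], K, stride, Lout)))
}

ad_col2im <- function(m, C, Lp, B, K, stride, Lout) {
  if (!is_node(m)) return(col2im_plain(m, C, Lp, B, K, stride, Lout))
  ad_node(col2im_plain(m$v, C, Lp, B, K, stride, Lout), list(m), function(g)
    list(ad_im2col(g, K, stride, Lout)))
}

# ---- gradient --------------------------------------------------------------

#' Reverse-mode gradient of a scalar tape node
#'
#' Differentiates `y` (a scalar produced by the `ad_*` primitives) with
#' respect to one node or a list of nodes. With `higher = TRUE` the returned
#' gradients are themselves tape nodes, so they can be differentiated again
#' (needed for gradient-penalty terms).
#'
#' @param y scalar output node.
#' @param wrt a single `ad_node` or a list of them.
#' @param higher build a differentiable gradient graph?
#' @return gradient array(s) (or node(s) when `higher = TRUE`), in the same
#'   structure as `wrt`; zero arrays for nodes `y` does not depend on.
#' @keywords internal
ad_grad <- function(y, wrt, higher = FALSE) {
  stopifnot(is_node(y))
  single <- is_node(wrt)
  wrt_list <- if (single) list(wrt) else wrt

  # reachable subgraph (iterative DFS)
  nodes <- new.env(parent = emptyenv())
  stack <- list(y)
  ids <- integer(0)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- n
    ids <- c(ids, n$id)
    for (p in n$parents) if (is_node(p)) stack[[length(stack) + 1L]] <- p
  }

  old <- .ad$higher
  .ad$higher <- higher
  on.exit(.ad$higher <- old, add = TRUE)

  adj <- new.env(parent = emptyenv())
  seed <- ad_value(y)
  seed[] <- 1
  adj[[as.character(y$id)]] <- if (higher) ad_node(seed) else seed

  for (id in sort(ids, decreasing = TRUE)) {
    n <- nodes[[as.character(id)]]
    g <- adj[[as.character(id)]]
    if (is.null(g) || is.null(n$pb)) next
    pgrads <- n$pb(g)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!is_node(p)) next
      pg <- pgrads[[i]]
      if (is.null(pg)) next
      key <- as.character(p$id)
      cur <- adj[[key]]
      adj[[key]] <- if (is.null(cur)) pg else ad_add(cur, pg)
    }
  }

  out <- lapply(wrt_list, function(w) {
    g <- adj[[as.character(w$id)]]
    if (is.null(g)) {
      z <- ad_value(w)
      z[] <- 0
      g <- if (higher) ad_node(z) else z
    }
    # shape guard: scalar adjoints may arrive as length-1 arrays
    g
  })
  if (single) out[[1]] else out
}
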