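## Minimal layer engine for the residual convolutional scorers.
##
## A network is an ordered list of ops acting on a channels-first tensor
## (matrix C x N for 1D, array C x N1 x N2 for 2D):
##   conv  : zero-padded ("same") convolution, W = (c_out, c_in, k) or
##           (c_out, c_in, k, k), bias b
##   inorm : instance normalization per channel over the spatial axes, with
##           affine gain/bias
##   relu  : rectifier
##   skip+ / skip- : push the current tensor / pop and add (residual block)
## Everything is plain R linear algebra; desk-scale configurations keep the
## tensors small.

.shift1 <- function(x, d) {
  # columns shifted by d with zero padding: out[, t] = x[, t + d]
  n <- ncol(x)
  out <- matrix(0, nrow(x), n)
  src <- seq_len(n) + d
  keep <- src >= 1L & src <= n
  out[, keep] <- x[, src[keep], drop = FALSE]
  out
}

.shift2 <- function(a, dx, dy) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[2]) + dx; kx <- sx >= 1L & sx <= d[2]
  sy <- seq_len(d[3]) + dy; ky <- sy >= 1L & sy <= d[3]
  out[, kx, ky] <- a[, sx[kx], sy[ky], drop = FALSE]
  out
}

.conv_fwd <- function(x, W, b) {
  if (length(dim(W)) == 3L) {
    k <- dim(W)[3]; half <- (k - 1L) %/% 2L
    out <- matrix(b, dim(W)[1], ncol(x))
    for (o in seq_len(k))
      out <- out + matrix(W[, , o], dim(W)[1], dim(W)[2]) %*%
        .shift1(x, o - 1L - half)
    out
  } else {
    k <- dim(W)[3]; half <- (k - 1L) %/% 2L
    d <- dim(x); nsp <- d[2] * d[3]
    out <- matrix(b, dim(W)[1], nsp)
    for (ox in seq_len(k)) for (oy in seq_len(k)) {
      Wk <- matrix(W[, , ox, oy], dim(W)[1], dim(W)[2])
      xs <- .shift2(x, ox - 1L - half, oy - 1L - half)
      out <- out + Wk %*% matrix(xs, d[1], nsp)
    }
    array(out, c(dim(W)[1], d[2], d[3]))
  }
}

.inorm_fwd <- function(x, g, be, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  mu <- rowMeans(xm)
  xc <- xm - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  y <- array(g * xhat + be, d)
  list(y = y, xhat = array(xhat, d), sd = sd_)
}

## Forward pass over an ops list; optionally retains per-op caches for
## backpropagation.
net_forward <- function(ops, x, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(ops)) else NULL
  stack <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    if (op$kind == "conv") {
      if (keep_cache) cache[[k]] <- x
      x <- .conv_fwd(x, op$W, op$b)
    } else if (op$kind == "inorm") {
      r <- .inorm_fwd(x, op$g, op$be)
      if (keep_cache) cache[[k]] <- r[c("xhat", "sd")]
      x <- r$y
    } else if (op$kind == "relu") {
      if (keep_cache) cache[[k]] <- (x > 0)
      x <- x * (x > 0)
    } else if (op$kind == "skip+") {
      stack[[length(stack) + 1L]] <- x
    } else if (op$kind == "skip-") {
      x <- x + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    } else stop("unknown op kind: ", op$kind)
    if (any(!is.finite(x))) stop("non-finite activation in layer ", k)
  }
  list(out = x, cache = cache)
}

## Reverse pass; returns the input gradient and one gradient list per op.
net_backward <- function(ops, cache, dout) {
  grads <- vector("list", length(ops))
  stack <- list()
  dx <- dout
  for (k in rev(seq_along(ops))) {
    op <- ops[[k]]
    if (op$kind == "conv") {
      x <- cache[[k]]
      oneD <- length(dim(op$W)) == 3L
      kk <- dim(op$W)[3]; half <- (kk - 1L) %/% 2L
      dW <- array(0, dim(op$W))
      if (oneD) {
        dxm <- matrix(0, nrow(x), ncol(x))
        for (o in seq_len(kk)) {
          Wk <- matrix(op$W[, , o], dim(op$W)[1], dim(op$W)[2])
          dW[, , o] <- dx %*% t(.shift1(x, o - 1L - half))
          dxm <- dxm + .shift1(t(Wk) %*% dx, -(o - 1L - half))
        }
        db <- rowSums(dx)
        grads[[k]] <- list(W = dW, b = db)
        dx <- dxm
      } else {
        d <- dim(x); nsp <- d[2] * d[3]
        dym <- matrix(dx, dim(op$W)[1], nsp)
        dxa <- array(0, d)
        for (ox in seq_len(kk)) for (oy in seq_len(kk)) {
          xs <- matrix(.shift2(x, ox - 1L - half, oy - 1L - half), d[1], nsp)
          dW[, , ox, oy] <- dym %*% t(xs)
          Wk <- matrix(op$W[, , ox, oy], dim(op$W)[1], dim(op$W)[2])
          dxa <- dxa + .shift2(array(t(Wk) %*% dym, c(d[1], d[2], d[3])),
                               -(ox - 1L - half), -(oy - 1L - half))
        }
        grads[[k]] <- list(W = dW, b = rowSums(dym))
        dx <- dxa
      }
    } else if (op$kind == "inorm") {
      xhat <- cache[[k]]$xhat; sd_ <- cache[[k]]$sd
      d <- dim(dx)
      dym <- matrix(dx, d[1])
      xh <- matrix(xhat, d[1])
      grads[[k]] <- list(g = rowSums(dym * xh), be = rowSums(dym))
      dxh <- dym * op$g
      dxm <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) / sd_
      dx <- array(dxm, d)
    } else if (op$kind == "relu") {
      dx <- dx * cache[[k]]
    } else if (op$kind == "skip+") {
      dx <- dx + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    } else if (op$kind == "skip-") {
      stack[[length(stack) + 1L]] <- dx
    }
  }
  list(dx = dx, grads = grads)
}

.conv_op <- function(c_out, c_in, k, ndim, init_sd) {
  W <- array(stats::rnorm(c_out * c_in * k^ndim, sd = init_sd),
             dim = c(c_out, c_in, rep(k, ndim)))
  list(kind = "conv", W = W, b = numeric(c_out))
}

.inorm_op <- function(c_out) list(kind = "inorm", g = rep(1, c_out),
                                  be = numeric(c_out))

## One (conv, inorm, relu) unit, with the normalization optionally disabled.
.unit <- function(c_out, c_in, k, ndim, norm, init_sd) {
  u <- list(.conv_op(c_out, c_in, k, ndim, init_sd))
  if (norm) u <- c(u, list(.inorm_op(c_out)))
  c(u, list(list(kind = "relu")))
}

#' Configuration of the residual alignment scorer
#'
#' Depths and kernels default to the reference architecture: two 1D residual
#' networks of 10 convolutional layers (kernel 3) with instance
#' normalization and ReLU after every convolution, outer concatenation of
#' the two sequence embeddings into a pairwise map joined with the
#' [pair_features()] channels, and a 2D residual network of 20 blocks of 3
#' convolutional layers (kernel 5).  Channel widths are configurable (the
#' architecture source leaves them open); desk-scale work uses small widths.
#'
#' @param conv1d_layers 1D convolution count (default 10).
#' @param kernel1d 1D kernel size (default 3).
#' @param res2d_blocks residual block count of the 2D network (default 20).
#' @param convs_per_block convolutions per 2D block (default 3).
#' @param kernel2d 2D kernel size (default 5).
#' @param width1d,width2d channel widths (defaults 32 and 64).
#' @param emit_gap_scores if `TRUE` the 2D head also emits `Ix`/`Iy` scores;
#'   otherwise those are learned scalar penalties.
#' @param use_instance_norm disable for exact small-scale oracle comparisons.
#' @param init_sd weight initialization scale.
#' @return List of class `drnf_config`.
#' @export
drnf_config <- function(conv1d_layers = 10L, kernel1d = 3L,
                        res2d_blocks = 20L, convs_per_block = 3L,
                        kernel2d = 5L, width1d = 32L, width2d = 64L,
                        emit_gap_scores = FALSE, use_instance_norm = TRUE,
                        init_sd = 0.1) {
  stopifnot(conv1d_layers >= 1, res2d_blocks >= 0, convs_per_block >= 1)
  structure(list(conv1d_layers = conv1d_layers, kernel1d = kernel1d,
                 res2d_blocks = res2d_blocks, convs_per_block = convs_per_block,
                 kernel2d = kernel2d, width1d = width1d, width2d = width2d,
                 emit_gap_scores = emit_gap_scores,
                 use_instance_norm = use_instance_norm, init_sd = init_sd),
            class = "drnf_config")
}

.build_net1d <- function(cfg, c_in) {
  H <- cfg$width1d; norm <- cfg$use_instance_norm
  ops <- .unit(H, c_in, cfg$kernel1d, 1L, norm, cfg$init_sd)
  remaining <- cfg$conv1d_layers - 1L
  while (remaining >= 2L) {
    ops <- c(ops, list(list(kind = "skip+")),
             .unit(H, H, cfg$kernel1d, 1L, norm, cfg$init_sd),
             .unit(H, H, cfg$kernel1d, 1L, norm, cfg$init_sd),
             list(list(kind = "skip-")))
    remaining <- remaining - 2L
  }
  if (remaining == 1L)
    ops <- c(ops, .unit(H, H, cfg$kernel1d, 1L, norm, cfg$init_sd))
  ops
}

.build_net2d <- function(cfg, c_in, n_out) {
  H <- cfg$width2d; norm <- cfg$use_instance_norm
  ops <- .unit(H, c_in, 1L, 2L, norm, cfg$init_sd)
  for (b in seq_len(cfg$res2d_blocks)) {
    ops <- c(ops, list(list(kind = "skip+")))
    for (l in seq_len(cfg$convs_per_block))
      ops <- c(ops, .unit(H, H, cfg$kernel2d, 2L, norm, cfg$init_sd))
    ops <- c(ops, list(list(kind = "skip-")))
  }
  c(ops, list(.conv_op(n_out, H, 1L, 2L, cfg$init_sd)))
}

#' Initialize parameters of the residual scorer
#'
#' @param config a [drnf_config()].
#' @param seed integer seed for the Gaussian weight initialization.
#' @param c_in_1d 1D input channels (54, see [seq_features()]).
#' @param pair_channels pairwise feature channels (9, see [pair_features()]).
#' @return List of class `drnf_params` with elements `net1d_t`, `net1d_q`,
#'   `net2d`, `gap` (Ix/Iy scalar penalties) and the config as attribute.
#' @export
drnf_init <- function(config = drnf_config(), seed = 1L, c_in_1d = 54L,
                      pair_channels = 9L) {
  with_seed(.mix_seed(seed, 31), {
    n_out <- if (config$emit_gap_scores) 3L else 1L
    p <- list(net1d_t = .build_net1d(config, c_in_1d),
              net1d_q = .build_net1d(config, c_in_1d),
              net2d = .build_net2d(config, 2L * config$width1d + pair_channels,
                                   n_out),
              gap = c(gap_ix = 0, gap_iy = 0))
    attr(p, "config") <- config
    class(p) <- "drnf_params"
    p
  })
}

## Outer concatenation: template embedding broadcast over query columns,
## query embedding over template rows, then the raw pairwise channels.
.outer_concat <- function(h_t, h_q, feats) {
  H <- nrow(h_t); n1 <- ncol(h_t); n2 <- ncol(h_q); nc <- dim(feats)[3]
  a <- array(0, c(2L * H + nc, n1, n2))
  a[seq_len(H), , ] <- array(rep(h_t, n2), c(H, n1, n2))
  a[H + seq_len(H), , ] <- aperm(array(rep(h_q, n1), c(H, n2, n1)), c(1, 3, 2))
  for (c in seq_len(nc)) a[2L * H + c, , ] <- feats[, , c]
  a
}

#' Residual-network emission scores
#'
#' Runs the full scorer: each protein's sequential features through its 1D
#' residual network, outer concatenation of the two embeddings into an
#' `n1 x n2` pairwise map joined with the pairwise feature channels, and the
#' 2D residual network, whose head emits the match score (and `Ix`/`Iy`
#' scores when configured; otherwise the learned scalar penalties fill those
#' slices).  Deterministic given parameters.
#'
#' @param q a [query_record()].
#' @param t a [template_record()].
#' @param params a [drnf_init()] parameter set.
#' @param feats optional precomputed [pair_features()].
#' @return A [score_table()].
#' @export
drnf_score <- function(q, t, params, feats = NULL) {
  stopifnot(inherits(params, "drnf_params"))
  if (is.null(feats)) feats <- pair_features(q, t)
  fw <- .drnf_forward(q, t, params, feats, keep_cache = FALSE)
  fw$theta
}

.drnf_forward <- function(q, t, params, feats, keep_cache = FALSE) {
  cfg <- attr(params, "config")
  f_t <- net_forward(params$net1d_t, seq_features(t), keep_cache)
  f_q <- net_forward(params$net1d_q, seq_features(q), keep_cache)
  a <- .outer_concat(f_t$out, f_q$out, feats)
  f2 <- net_forward(params$net2d, a, keep_cache)
  n1 <- t$length; n2 <- q$length
  z <- f2$out
  if (cfg$emit_gap_scores) {
    theta <- score_table(matrix(z[1, , ], n1, n2))
    theta$theta[, , 2] <- z[2, , ]
    theta$theta[, , 3] <- z[3, , ]
  } else {
    theta <- score_table(matrix(z[1, , ], n1, n2),
                         gap_ix = params$gap[1], gap_iy = params$gap[2])
  }
  list(theta = theta, f_t = f_t, f_q = f_q, f2 = f2,
       h_t = f_t$out, h_q = f_q$out)
}

## Backpropagate d(loss)/d(theta) to parameter gradients (same list shapes
## as the ops).  dtheta is an n1 x n2 x 5 array.
.drnf_backward <- function(params, fw, dtheta) {
  cfg <- attr(params, "config")
  n_out <- if (cfg$emit_gap_scores) 3L else 1L
  d <- dim(fw$f2$out)
  dz <- array(0, d)
  dz[1, , ] <- dtheta[, , 1]
  dgap <- c(0, 0)
  if (cfg$emit_gap_scores) {
    dz[2, , ] <- dtheta[, , 2]
    dz[3, , ] <- dtheta[, , 3]
  } else {
    dgap <- c(sum(dtheta[, , 2]), sum(dtheta[, , 3]))
  }
  b2 <- net_backward(params$net2d, fw$f2$cache, dz)
  H <- nrow(fw$h_t)
  da <- b2$dx
  dh_t <- apply(da[seq_len(H), , , drop = FALSE], c(1, 2), sum)
  dh_q <- apply(da[H + seq_len(H), , , drop = FALSE], c(1, 3), sum)
  b1t <- net_backward(params$net1d_t, fw$f_t$cache, dh_t)
  b1q <- net_backward(params$net1d_q, fw$f_q$cache, dh_q)
  list(net1d_t = b1t$grads, net1d_q = b1q$grads, net2d = b2$grads,
       gap = dgap)
}

## Flatten/unflatten all trainable arrays of a drnf_params object (used by
## the optimizer and by finite-difference checks).
drnf_flatten <- function(params) {
  v <- numeric(0)
  for (net in c("net1d_t", "net1d_q", "net2d"))
    for (op in params[[net]]) {
      if (op$kind == "conv") v <- c(v, as.numeric(op$W), op$b)
      if (op$kind == "inorm") v <- c(v, op$g, op$be)
    }
  c(v, unname(params$gap))
}

drnf_unflatten <- function(params, v) {
  pos <- 0L
  take <- function(n) { out <- v[pos + seq_len(n)]; pos <<- pos + n; out }
  for (net in c("net1d_t", "net1d_q", "net2d"))
    for (k in seq_along(params[[net]])) {
      op <- params[[net]][[k]]
      if (op$kind == "conv") {
        params[[net]][[k]]$W <- array(take(length(op$W)), dim(op$W))
        params[[net]][[k]]$b <- take(length(op$b))
      } else if (op$kind == "inorm") {
        params[[net]][[k]]$g <- take(length(op$g))
        params[[net]][[k]]$be <- take(length(op$be))
      }
    }
  params$gap <- stats::setNames(take(2L), c("gap_ix", "gap_iy"))
  stopifnot(pos == length(v))
  params
}

drnf_flatten_grads <- function(params, grads) {
  v <- numeric(0)
  for (net in c("net1d_t", "net1d_q", "net2d"))
    for (k in seq_along(params[[net]])) {
      op <- params[[net]][[k]]; g <- grads[[net]][[k]]
      if (op$kind == "conv") v <- c(v, as.numeric(g$W), g$b)
      if (op$kind == "inorm") v <- c(v, g$g, g$be)
    }
  c(v, grads$gap)
}
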