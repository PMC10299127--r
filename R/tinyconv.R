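# TinyConv: a small trainable convolutional backbone (three conv/ReLU/
# max-pool blocks, 3x3 'same' convolutions, 2x2 stride-2 pooling) used to
# exercise the full transfer-learning contract without pretrained weights.
# Forward and backward passes are implemented with im2col so that training
# (including end-to-end fine-tuning) runs in plain R at desk scale.

# Cached im2col linear-index matrices, keyed by (H, W, C): one row per
# output pixel, one column per patch element, ordered (dr, dc, channel)
# with dr fastest to match the column-major flattening of the kernels.
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C, k = 3L) {
  key <- paste(H, W, C, k, sep = "x")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  Hp <- H + k - 1L; Wp <- W + k - 1L
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  base <- (cc - 1L) * Hp + r
  t_ <- seq_len(k * k * C) - 1L
  dr <- t_ %% k
  dc <- (t_ %/% k) %% k
  ch <- t_ %/% (k * k)
  offset <- ch * (Hp * Wp) + dc * Hp + dr
  idx <- outer(base, offset, `+`)
  .im2col_cache[[key]] <- list(idx = idx, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]]
}

tc_pad <- function(x, pad = 1L) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

tc_conv_forward <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]; f <- dim(W)[4]
  ic <- im2col_idx(d[1], d[2], d[3], k)
  xp <- tc_pad(x, (k - 1L) %/% 2L)
  cols <- matrix(xp[ic$idx], nrow(ic$idx))
  out <- cols %*% matrix(W, k * k * d[3], f)
  out <- sweep(out, 2, b, `+`)
  list(out = array(out, c(d[1], d[2], f)), cols = cols, in_dim = d)
}

tc_conv_backward <- function(dout, cache, W) {
  d <- cache$in_dim; k <- dim(W)[1]; f <- dim(W)[4]
  ic <- im2col_idx(d[1], d[2], d[3], k)
  dmat <- matrix(dout, d[1] * d[2], f)
  dW <- array(crossprod(cache$cols, dmat), dim(W))
  db <- colSums(dmat)
  dcols <- dmat %*% t(matrix(W, k * k * d[3], f))
  dxp <- numeric(ic$Hp * ic$Wp * d[3])
  for (t_ in seq_len(ncol(dcols)))
    dxp[ic$idx[, t_]] <- dxp[ic$idx[, t_]] + dcols[, t_]
  pad <- (k - 1L) %/% 2L
  dx <- array(dxp, c(ic$Hp, ic$Wp, d[3]))[pad + seq_len(d[1]),
                                           pad + seq_len(d[2]), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

tc_pool_forward <- function(x) {
  d <- dim(x)
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  sub <- function(dr, dc) x[seq(dr, 2L * Ho, 2L), seq(dc, 2L * Wo, 2L), ,
                            drop = FALSE]
  cand <- list(sub(1, 1), sub(2, 1), sub(1, 2), sub(2, 2))
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  arg <- array(4L, dim(out))
  for (p in 3:1) arg[cand[[p]] == out] <- p   # first maximum wins
  list(out = out, arg = arg, in_dim = d, Ho = Ho, Wo = Wo)
}

tc_pool_backward <- function(dout, cache) {
  dx <- array(0, cache$in_dim)
  pos <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (p in 1:4) {
    sub <- array(0, dim(dout))
    sel <- cache$arg == p
    sub[sel] <- dout[sel]
    ri <- seq(pos[[p]][1], 2L * cache$Ho, 2L)
    ci <- seq(pos[[p]][2], 2L * cache$Wo, 2L)
    dx[ri, ci, ] <- dx[ri, ci, ] + sub
  }
  dx
}

#' Instantiate the TinyConv backbone
#'
#' Builds the small convolutional backbone with He-normal random weights
#' (deterministic given `seed`). Three blocks of 3x3 'same' convolution +
#' ReLU + 2x2 max-pooling with 8, 16 and 32 filters.
#'
#' @param input_side Spatial side of the (square) input.
#' @param n_channels Input channels (3 for connectivity stacks).
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `tinyconv_backbone` holding the weights and the
#'   derived feature shape.
#' @export
instantiate_tinyconv <- function(input_side, n_channels = 3L, seed = 0L) {
  spec <- backbone_spec("TinyConv")
  if (input_side < spec$min_input_side)
    stopf("TinyConv requires input side >= %d, got %d",
          spec$min_input_side, input_side)
  filters <- c(8L, 16L, 32L)
  with_seed(derive_seed(seed, 7L), {
    params <- list()
    cin <- n_channels
    for (b in 1:3) {
      fan_in <- 9L * cin
      params[[paste0("W", b)]] <- array(
        stats::rnorm(9L * cin * filters[b], sd = sqrt(2 / fan_in)),
        c(3L, 3L, cin, filters[b]))
      params[[paste0("b", b)]] <- numeric(filters[b])
      cin <- filters[b]
    }
    side <- input_side
    for (i in 1:3) side <- side %/% 2L
    structure(list(params = params, filters = filters,
                   input_side = as.integer(input_side),
                   n_channels = as.integer(n_channels),
                   feature_shape = c(side, side, filters[3]),
                   seed = as.integer(seed)),
              class = "tinyconv_backbone")
  })
}

#' @export
print.tinyconv_backbone <- function(x, ...) {
  cat(sprintf("<tinyconv_backbone> input %dx%dx%d -> features %s (seed %d)\n",
              x$input_side, x$input_side, x$n_channels,
              paste(x$feature_shape, collapse = "x"), x$seed))
  invisible(x)
}

# Forward pass; with_cache=TRUE keeps everything backprop needs.
tinyconv_forward <- function(bb, x, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", 3) else NULL
  h <- x
  for (b in 1:3) {
    cv <- tc_conv_forward(h, bb$params[[paste0("W", b)]],
                          bb$params[[paste0("b", b)]])
    act <- cv$out > 0
    relu <- cv$out * act
    pl <- tc_pool_forward(relu)
    if (with_cache) caches[[b]] <- list(conv = cv, act = act, pool = pl)
    h <- pl$out
  }
  list(features = h, caches = caches)
}

# Backprop a gradient w.r.t. the flattened features down to all conv
# parameters (and the input, discarded).
tinyconv_backward <- function(bb, caches, dfeat) {
  grads <- list()
  dh <- dfeat
  for (b in 3:1) {
    ca <- caches[[b]]
    dh <- tc_pool_backward(dh, ca$pool)
    dh <- dh * ca$act
    cb <- tc_conv_backward(dh, ca$conv, bb$params[[paste0("W", b)]])
    grads[[paste0("W", b)]] <- cb$dW
    grads[[paste0("b", b)]] <- cb$db
    dh <- cb$dx
  }
  grads
}
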