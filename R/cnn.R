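# Minimal native convolutional network ("tiny_cnn" backbone). Batches are
# numeric arrays dim c(H, W, C, N). Convolutions run as im2col + one BLAS
# matrix product; the stem is a fixed 4x4 average pooling so a 220 px tile
# enters the trainable stack as 55 x 55 x 3. Architecture:
#   avgpool4 -> conv3x3(8) relu maxpool2 -> conv3x3(16) relu maxpool2
#   -> conv3x3(32) relu -> global average pool -> dense(2) softmax
# Everything is deterministic given the R RNG state.

stem_downsample <- function(x) {
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("stem expects tile edges divisible by 4")
  oh <- d[1] %/% 4L; ow <- d[2] %/% 4L
  out <- array(0, dim = c(oh, ow, d[3], d[4]))
  ri <- seq(1L, d[1], by = 4L); ci <- seq(1L, d[2], by = 4L)
  for (dy in 0:3) for (dx in 0:3)
    out <- out + x[ri + dy, ci + dx, , , drop = FALSE]
  out / 16
}

im2col <- function(x, k) {
  d <- dim(x)                                  # H W C N
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  col <- matrix(0, nrow = oh * ow * d[4], ncol = k * k * d[3])
  idx <- 0L
  for (c in seq_len(d[3])) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    idx <- idx + 1L
    col[, idx] <- as.vector(x[dy:(dy + oh - 1L), dx:(dx + ow - 1L), c, ])
  }
  col
}

col2im <- function(dcol, d, k) {
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  dx_arr <- array(0, dim = d)
  idx <- 0L
  for (c in seq_len(d[3])) for (ddx in seq_len(k)) for (ddy in seq_len(k)) {
    idx <- idx + 1L
    dx_arr[ddy:(ddy + oh - 1L), ddx:(ddx + ow - 1L), c, ] <-
      dx_arr[ddy:(ddy + oh - 1L), ddx:(ddx + ow - 1L), c, , drop = FALSE] +
      array(dcol[, idx], dim = c(oh, ow, 1L, d[4]))
  }
  dx_arr
}

conv_forward <- function(x, W, b) {
  d <- dim(x); k <- sqrt(nrow(W) / d[3])
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  col <- im2col(x, k)
  out <- sweep(col %*% W, 2, b, "+")
  y <- aperm(array(out, dim = c(oh, ow, d[4], ncol(W))), c(1L, 2L, 4L, 3L))
  list(y = y, col = col, dims = d, k = k)
}

conv_backward <- function(cache, W, dy) {
  dd <- dim(dy)                                # OH OW F N
  dmat <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = dd[3])
  list(dW = crossprod(cache$col, dmat),
       db = colSums(dmat),
       dx = col2im(dmat %*% t(W), cache$dims, cache$k))
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  ri <- seq(1L, 2L * oh, by = 2L); ci <- seq(1L, 2L * ow, by = 2L)
  y <- pmax(x[ri, ci, , , drop = FALSE],      x[ri + 1L, ci, , , drop = FALSE],
            x[ri, ci + 1L, , , drop = FALSE], x[ri + 1L, ci + 1L, , , drop = FALSE])
  list(y = y, dims = d, oh = oh, ow = ow)
}

# x is the forward input (re-sliced here rather than cached, to bound memory)
maxpool2_backward <- function(cache, x, dy) {
  d <- cache$dims
  dx <- array(0, dim = d)
  ri <- seq(1L, 2L * cache$oh, by = 2L); ci <- seq(1L, 2L * cache$ow, by = 2L)
  remaining <- array(TRUE, dim = dim(dy))      # ties feed the first view only
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (i in 1:4) {
    v <- x[ri + offs[[i]][1], ci + offs[[i]][2], , , drop = FALSE]
    hit <- remaining & (v == cache$y)
    dx[ri + offs[[i]][1], ci + offs[[i]][2], , ] <-
      dx[ri + offs[[i]][1], ci + offs[[i]][2], , , drop = FALSE] + dy * hit
    remaining <- remaining & !hit
  }
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, nrow = d[1] * d[2]))  # over spatial, per (C, N)
  list(y = t(matrix(m, nrow = d[3])), dims = d) # N x C
}

gap_backward <- function(cache, dy) {           # dy: N x C
  d <- cache$dims
  per <- t(dy) / (d[1] * d[2])                  # C x N
  array(rep(as.vector(per), each = d[1] * d[2]), dim = d)
}

cnn_init <- function(channels = c(3L, 8L, 16L, 32L), n_classes = 2L, k = 3L) {
  he <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))
  params <- list()
  for (i in 1:3) {
    fan <- k * k * channels[i]
    params[[paste0("W", i)]] <- matrix(he(fan, fan * channels[i + 1L]),
                                       nrow = fan)
    params[[paste0("b", i)]] <- rep(0, channels[i + 1L])
  }
  params$Wfc <- matrix(he(channels[4L], channels[4L] * n_classes),
                       nrow = channels[4L])
  params$bfc <- rep(0, n_classes)
  params
}

cnn_forward <- function(params, x, keep_cache = TRUE) {
  c1 <- conv_forward(x, params$W1, params$b1)
  r1 <- pmax(c1$y, 0)
  p1 <- maxpool2_forward(r1)
  c2 <- conv_forward(p1$y, params$W2, params$b2)
  r2 <- pmax(c2$y, 0)
  p2 <- maxpool2_forward(r2)
  c3 <- conv_forward(p2$y, params$W3, params$b3)
  r3 <- pmax(c3$y, 0)
  g <- gap_forward(r3)
  logits <- sweep(g$y %*% params$Wfc, 2, params$bfc, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, logits = logits,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, g = g))
}

# y: integer class index 1..K; loss weighting per histotile::weighted_loss.
cnn_backward <- function(params, fwd, y, w_factor = 1.5) {
  n <- nrow(fwd$probs)
  onehot <- matrix(0, n, ncol(fwd$probs))
  onehot[cbind(seq_len(n), y)] <- 1
  pred <- max.col(fwd$probs, ties.method = "first")
  wts <- ifelse(pred != y, w_factor, 1)
  dlogits <- (fwd$probs - onehot) * wts / n
  ca <- fwd$cache
  grads <- list(dWfc = crossprod(ca$g$y, dlogits), dbfc = colSums(dlogits))
  dfeat <- dlogits %*% t(params$Wfc)
  dr3 <- gap_backward(ca$g, dfeat)
  dc3 <- dr3 * (ca$r3 > 0)
  b3 <- conv_backward(ca$c3, params$W3, dc3)
  grads$dW3 <- b3$dW; grads$db3 <- b3$db
  dp2 <- maxpool2_backward(ca$p2, ca$r2, b3$dx)
  dc2 <- dp2 * (ca$r2 > 0)
  b2 <- conv_backward(ca$c2, params$W2, dc2)
  grads$dW2 <- b2$dW; grads$db2 <- b2$db
  dp1 <- maxpool2_backward(ca$p1, ca$r1, b2$dx)
  dc1 <- dp1 * (ca$r1 > 0)
  b1 <- conv_backward(ca$c1, params$W1, dc1)
  grads$dW1 <- b1$dW; grads$db1 <- b1$db
  grads
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  map <- c(W1 = "dW1", b1 = "db1", W2 = "dW2", b2 = "db2",
           W3 = "dW3", b3 = "db3", Wfc = "dWfc", bfc = "dbfc")
  for (nm in names(map)) {
    g <- grads[[map[[nm]]]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
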