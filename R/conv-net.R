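# Internal convolutional-network machinery for the tiny CNN backend.
#
# Layers: [conv 3x3 (pad 1) -> ReLU -> 2x2 average pool] x (n_blocks - 1),
# then conv 3x3 -> ReLU (the designated feature layer), global average
# pooling and a linear two-class head. Convolutions run as im2col matrix
# products; the im2col index tables are precomputed per layer.

# Linear indices into the zero-padded (h+2) x (w+2) x cin array for every
# output pixel (rows) and every (offset, channel) patch entry (columns).
im2col_indices <- function(h, w, cin) {
  hp <- h + 2L; wp <- w + 2L
  r <- rep(seq_len(h), times = w)           # output pixel rows, col-major
  c <- rep(seq_len(w), each = h)
  cols <- vector("list", 9L * cin)
  j <- 0L
  for (ch in seq_len(cin)) {
    for (dc in 0:2) {
      for (dr in 0:2) {
        j <- j + 1L
        cols[[j]] <- (r + dr) + hp * (c + dc - 1L) + hp * wp * (ch - 1L)
      }
    }
  }
  matrix(unlist(cols), nrow = h * w)
}

conv_im2col <- function(x, idx) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  matrix(xp[idx], nrow = nrow(idx))
}

conv_forward <- function(x, layer, idx) {
  h <- dim(x)[1]; w <- dim(x)[2]
  P <- conv_im2col(x, idx)
  out <- P %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = array(out, c(h, w, ncol(layer$W))), P = P)
}

conv_backward <- function(dout, P, layer, h, w) {
  cin <- nrow(layer$W) / 9L
  dout_m <- matrix(dout, h * w)
  dW <- crossprod(P, dout_m)
  db <- colSums(dout_m)
  dP <- dout_m %*% t(layer$W)
  dxp <- numeric((h + 2L) * (w + 2L) * cin)
  idx <- attr(P, "idx")
  for (j in seq_len(ncol(idx))) {
    dxp[idx[, j]] <- dxp[idx[, j]] + dP[, j]
  }
  dxp <- array(dxp, c(h + 2L, w + 2L, cin))
  list(dW = dW, db = db, dx = dxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE])
}

pool_slices <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  list(x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE],
       x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE],
       x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE],
       x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE])
}

maxpool2 <- function(x) {
  s <- pool_slices(x)
  pmax(s[[1]], s[[2]], s[[3]], s[[4]])
}

# Gradient routed to the first (in slice order) element attaining the max,
# so ties break deterministically.
maxpool2_backward <- function(dp, x) {
  s <- pool_slices(x)
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  h <- dim(x)[1]; w <- dim(x)[2]; k <- dim(x)[3]
  dx <- array(0, c(h, w, k))
  taken <- array(FALSE, dim(out))
  rs <- list(seq(1, h, 2), seq(2, h, 2), seq(1, h, 2), seq(2, h, 2))
  cs <- list(seq(1, w, 2), seq(1, w, 2), seq(2, w, 2), seq(2, w, 2))
  for (i in 1:4) {
    m <- (s[[i]] == out) & !taken
    taken <- taken | m
    dx[rs[[i]], cs[[i]], ] <- dp * m
  }
  dx
}

# Full forward pass with caches for backprop. `px` is an intensity matrix on
# the [0, 255] scale; it is centered to [-0.5, 0.5] internally. Max pooling
# between blocks preserves the small bright structures (calcification
# flecks) that average pooling would wash out.
cnn_forward <- function(model, px, keep_cache = FALSE) {
  x <- array(px / 255 - 0.5, c(dim(px), 1L))
  nb <- model$n_blocks
  cache <- list(z = vector("list", nb), a = vector("list", nb),
                P = vector("list", nb))
  for (b in seq_len(nb)) {
    cf <- conv_forward(x, model$conv[[b]], model$idx[[b]])
    z <- cf$out
    a <- pmax(z, 0)
    if (keep_cache) {
      attr(cf$P, "idx") <- model$idx[[b]]
      cache$z[[b]] <- z; cache$a[[b]] <- a; cache$P[[b]] <- cf$P
    }
    x <- if (b < nb) maxpool2(a) else a
  }
  features <- x                                  # designated layer activation
  s <- apply(features, 3L, mean)                 # GAP
  scores <- drop(s %*% model$head$W) + model$head$b
  names(scores) <- model$classes
  out <- list(features = features, gap = s, scores = scores)
  if (keep_cache) out$cache <- cache
  out
}

# Gradients of the softmax cross-entropy loss for one sample.
cnn_backward <- function(model, fw, label_index) {
  p <- softmax(fw$scores)
  dscores <- p
  dscores[label_index] <- dscores[label_index] - 1
  grads <- list(head_W = outer(fw$gap, dscores), head_b = dscores,
                conv = vector("list", model$n_blocks))
  hf <- dim(fw$features)[1]; wf <- dim(fw$features)[2]
  ds <- drop(model$head$W %*% dscores)           # d loss / d GAP
  da <- array(rep(ds / (hf * wf), each = hf * wf), dim(fw$features))
  for (b in seq.int(model$n_blocks, 1L)) {
    z <- fw$cache$z[[b]]
    dz <- da * (z > 0)
    h <- dim(z)[1]; w <- dim(z)[2]
    cb <- conv_backward(dz, fw$cache$P[[b]], model$conv[[b]], h, w)
    grads$conv[[b]] <- list(dW = cb$dW, db = cb$db)
    if (b > 1L) da <- maxpool2_backward(cb$dx, fw$cache$a[[b - 1L]])
  }
  list(grads = grads, loss = -log(max(p[label_index], 1e-12)))
}

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# Adam optimizer over the model's parameter list.
adam_init <- function(model) {
  zero_like <- function(x) x * 0
  st <- list(t = 0L,
             m = list(head_W = zero_like(model$head$W),
                      head_b = zero_like(model$head$b),
                      conv = lapply(model$conv, function(l)
                        list(W = zero_like(l$W), b = zero_like(l$b)))))
  st$v <- st$m
  st
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(param, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(param = param - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  u <- upd(model$head$W, grads$head_W, state$m$head_W, state$v$head_W)
  model$head$W <- u$param; state$m$head_W <- u$m; state$v$head_W <- u$v
  u <- upd(model$head$b, grads$head_b, state$m$head_b, state$v$head_b)
  model$head$b <- u$param; state$m$head_b <- u$m; state$v$head_b <- u$v
  for (b in seq_along(model$conv)) {
    u <- upd(model$conv[[b]]$W, grads$conv[[b]]$dW,
             state$m$conv[[b]]$W, state$v$conv[[b]]$W)
    model$conv[[b]]$W <- u$param
    state$m$conv[[b]]$W <- u$m; state$v$conv[[b]]$W <- u$v
    u <- upd(model$conv[[b]]$b, grads$conv[[b]]$db,
             state$m$conv[[b]]$b, state$v$conv[[b]]$b)
    model$conv[[b]]$b <- u$param
    state$m$conv[[b]]$b <- u$m; state$v$conv[[b]]$b <- u$v
  }
  list(model = model, state = state)
}

sum_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  acc$head_W <- acc$head_W + g$head_W
  acc$head_b <- acc$head_b + g$head_b
  for (b in seq_along(acc$conv)) {
    acc$conv[[b]]$dW <- acc$conv[[b]]$dW + g$conv[[b]]$dW
    acc$conv[[b]]$db <- acc$conv[[b]]$db + g$conv[[b]]$db
  }
  acc
}

scale_grads <- function(g, f) {
  g$head_W <- g$head_W * f
  g$head_b <- g$head_b * f
  for (b in seq_along(g$conv)) {
    g$conv[[b]]$dW <- g$conv[[b]]$dW * f
    g$conv[[b]]$db <- g$conv[[b]]$db * f
  }
  g
}

# Evaluate an expression with a locally fixed RNG state.
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
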