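# Minimal vectorized neural-network engine: 3x3 same-padding convolutions
# (shift-and-multiply, so each conv is nine matrix products), ReLU, 2x2 max
# pooling, global average pooling, dense layers, dropout, softmax
# cross-entropy with per-class weights, and an RMSprop optimizer. Enough to
# train the compact slice classifier and the fully-connected texture
# detector on a CPU in minutes; all randomness is seed-controlled so
# training is bit-reproducible.
#
# Data layout: activations are arrays [batch, height, width, channels] or
# matrices [batch, features]; conv weights are arrays [3, 3, c_in, c_out].

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

nn_conv3 <- function(c_in, c_out) {
  list(type = "conv3",
       W = array(he_init(9 * c_in * c_out, 9 * c_in), c(3, 3, c_in, c_out)),
       b = numeric(c_out))
}
nn_relu <- function() list(type = "relu")
nn_maxpool2 <- function() list(type = "maxpool2")
nn_gap <- function() list(type = "gap")
nn_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(he_init(d_in * d_out, d_in), d_in, d_out),
       b = numeric(d_out))
}
nn_dropout <- function(rate) list(type = "dropout", rate = rate)

pad_hw <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  out[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  out
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv3 = {
      d <- dim(x)
      xp <- pad_hw(x)
      c_out <- dim(layer$W)[4]
      n <- d[1] * d[2] * d[3]
      y <- matrix(rep(layer$b, each = n), n, c_out)
      for (di in 0:2) for (dj in 0:2) {
        xs <- xp[, di + seq_len(d[2]), dj + seq_len(d[3]), , drop = FALSE]
        wk <- matrix(layer$W[di + 1, dj + 1, , ], d[4], c_out)
        y <- y + matrix(xs, n, d[4]) %*% wk
      }
      dim(y) <- c(d[1:3], c_out)
      list(y = y, cache = list(xp = xp, d = d))
    },
    relu = list(y = pmax(x, 0), cache = x > 0),
    maxpool2 = {
      d <- dim(x)
      h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
      i1 <- seq.int(1L, 2L * h2, 2L); j1 <- seq.int(1L, 2L * w2, 2L)
      s <- list(x[, i1, j1, , drop = FALSE], x[, i1 + 1L, j1, , drop = FALSE],
                x[, i1, j1 + 1L, , drop = FALSE],
                x[, i1 + 1L, j1 + 1L, , drop = FALSE])
      y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
      list(y = y, cache = list(s = s, y = y, d = d, h2 = h2, w2 = w2))
    },
    gap = {
      d <- dim(x)
      # mean over spatial dims per (batch, channel)
      m <- matrix(0, d[1], d[4])
      for (c in seq_len(d[4]))
        m[, c] <- rowMeans(matrix(x[, , , c], d[1], d[2] * d[3]))
      list(y = m, cache = d)
    },
    dense = list(y = sweep(x %*% layer$W, 2, layer$b, `+`),
                 cache = x),
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- matrix(runif(length(x)) < keep, nrow(x)) / keep
        list(y = x * mask, cache = mask)
      } else list(y = x, cache = NULL)
    }
  )
}

layer_backward <- function(layer, dy, cache) {
  switch(layer$type,
    conv3 = {
      d <- cache$d
      c_out <- dim(layer$W)[4]
      n <- d[1] * d[2] * d[3]
      dym <- matrix(dy, n, c_out)
      dW <- array(0, dim(layer$W))
      dxp <- array(0, dim(cache$xp))
      for (di in 0:2) for (dj in 0:2) {
        xs <- cache$xp[, di + seq_len(d[2]), dj + seq_len(d[3]), ,
                       drop = FALSE]
        wk <- matrix(layer$W[di + 1, dj + 1, , ], d[4], c_out)
        dW[di + 1, dj + 1, , ] <- crossprod(matrix(xs, n, d[4]), dym)
        dxs <- dym %*% t(wk)
        dim(dxs) <- c(d[1:3], d[4])
        dxp[, di + seq_len(d[2]), dj + seq_len(d[3]), ] <-
          dxp[, di + seq_len(d[2]), dj + seq_len(d[3]), , drop = FALSE] + dxs
      }
      dx <- dxp[, 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
      list(dx = dx, grads = list(W = dW, b = colSums(dym)))
    },
    relu = list(dx = dy * cache, grads = NULL),
    maxpool2 = {
      d <- cache$d
      dx <- array(0, d)
      i1 <- seq.int(1L, 2L * cache$h2, 2L)
      j1 <- seq.int(1L, 2L * cache$w2, 2L)
      off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
      taken <- array(FALSE, dim(cache$y))
      for (k in 1:4) {
        hit <- (cache$s[[k]] == cache$y) & !taken
        taken <- taken | hit
        dx[, i1 + off[[k]][1], j1 + off[[k]][2], ] <-
          dx[, i1 + off[[k]][1], j1 + off[[k]][2], , drop = FALSE] +
          dy * hit
      }
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache
      per <- 1 / (d[2] * d[3])
      dx <- array(0, d)
      for (c in seq_len(d[4]))
        dx[, , , c] <- array(rep(dy[, c] * per, d[2] * d[3]),
                             c(d[1], d[2], d[3]))
      list(dx = dx, grads = NULL)
    },
    dense = list(dx = dy %*% t(layer$W),
                 grads = list(W = crossprod(cache, dy), b = colSums(dy))),
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    }
  )
}

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, training)
    x <- step$y
    caches[[i]] <- step$cache
  }
  list(logits = x, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted softmax cross-entropy; y is an integer class vector (1-based)
ce_loss_grad <- function(logits, y, w_sample) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y)
  wsum <- sum(w_sample)
  loss <- -sum(w_sample * log(pmax(p[idx], 1e-12))) / wsum
  dz <- p
  dz[idx] <- dz[idx] - 1
  dz <- dz * (w_sample / wsum)
  list(loss = loss, dlogits = dz, probs = p)
}

net_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  dy <- dlogits
  for (i in rev(seq_along(layers))) {
    step <- layer_backward(layers[[i]], dy, caches[[i]])
    dy <- step$dx
    grads[i] <- list(step$grads)  # keep NULL slots (no-parameter layers)
  }
  grads
}

rmsprop_state <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) NULL
    else list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  })
}

rmsprop_update <- function(layers, grads, state, lr, rho = 0.9,
                           eps = 1e-7) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in c("W", "b")) {
      state[[i]][[p]] <- rho * state[[i]][[p]] + (1 - rho) * g[[p]]^2
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * g[[p]] / (sqrt(state[[i]][[p]]) + eps)
    }
  }
  list(layers = layers, state = state)
}

# One full training run over (x, y). x: [N,H,W,C] array or [N,d] matrix.
# Returns layers plus the per-epoch loss trace.
nn_train <- function(layers, x, y, epochs, lr, batch_size, class_weights,
                     seed, rho = 0.9, eps = 1e-7) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  state <- rmsprop_state(layers)
  trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq.int(1L, n, batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- if (is.matrix(x)) x[idx, , drop = FALSE]
              else x[idx, , , , drop = FALSE]
        yb <- y[idx]
        fw <- net_forward(layers, xb, training = TRUE)
        lg <- ce_loss_grad(fw$logits, yb, class_weights[yb])
        grads <- net_backward(layers, fw$caches, lg$dlogits)
        upd <- rmsprop_update(layers, grads, state, lr, rho, eps)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
      }
      trace[ep] <- ep_loss / n_batches
    }
  })
  list(layers = layers, loss_trace = trace)
}

nn_predict_probs <- function(layers, x) {
  softmax_rows(net_forward(layers, x, training = FALSE)$logits)
}

bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  ix <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  iy <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  ix <- pmin(pmax(ix, 1), h); iy <- pmin(pmax(iy, 1), w)
  x0 <- floor(ix); y0 <- floor(iy)
  x1 <- pmin(x0 + 1, h); y1 <- pmin(y0 + 1, w)
  fx <- ix - x0; fy <- iy - y0
  a <- img[x0, y0, drop = FALSE] * outer(1 - fx, 1 - fy)
  b <- img[x1, y0, drop = FALSE] * outer(fx, 1 - fy)
  cc <- img[x0, y1, drop = FALSE] * outer(1 - fx, fy)
  d <- img[x1, y1, drop = FALSE] * outer(fx, fy)
  a + b + cc + d
}
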