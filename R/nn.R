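# Minimal CNN engine.
#
# Feature maps are dense arrays laid out [H, W, N, C] (height, width,
# sample, channel): collapsing the first three dims column-major yields an
# (H*W*N) x C matrix, which makes convolution (im2col + BLAS matmul) and
# per-channel batch norm plain matrix algebra. Fully connected activations
# are N x D matrices. All randomness (init, shuffling, dropout) is drawn
# from the R RNG, so callers control determinism with a single seed.

nn_conv <- function(c_in, filters, k = 3L) {
  fan_in <- k * k * c_in
  list(type = "conv", k = k, c_in = c_in, f = filters,
       W = matrix(rnorm(fan_in * filters, 0, sqrt(2 / fan_in)),
                  fan_in, filters),
       b = numeric(filters), trainable = TRUE)
}

nn_bn <- function(channels) {
  list(type = "bn", c = channels, gamma = rep(1, channels),
       beta = numeric(channels), running_mean = numeric(channels),
       running_var = rep(1, channels), eps = 1e-5, momentum = 0.1,
       trainable = TRUE)
}

nn_relu <- function() list(type = "relu")

nn_pool <- function(s = 2L) list(type = "pool", s = as.integer(s))

nn_avgpool <- function() list(type = "avgpool")

nn_flatten <- function() list(type = "flatten")

nn_dense <- function(d_in, d_out, init_scale = NULL) {
  sdv <- init_scale %||% sqrt(2 / d_in)
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(rnorm(d_in * d_out, 0, sdv), d_in, d_out),
       b = numeric(d_out), trainable = TRUE)
}

nn_sigmoid <- function() list(type = "sigmoid")

nn_dropout <- function(p) list(type = "dropout", p = p)

nn_softmax <- function() list(type = "softmax")

# ---- forward ---------------------------------------------------------------

conv_index_cache <- new.env(parent = emptyenv())

# Linear gather indices mapping a padded [Hp, Wp, N, C] tensor to the
# (H*W*N) x (k*k*C) im2col matrix; memoised per shape.
conv_gather_index <- function(H, W, N, C, k) {
  key <- paste(H, W, N, C, k, sep = "x")
  hit <- conv_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  base <- rep(seq_len(H), times = W * N) +
    Hp * rep(rep(seq_len(W) - 1L, each = H), times = N) +
    (Hp * Wp) * rep(seq_len(N) - 1L, each = H * W)
  offs <- integer(0)
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    offs <- c(offs, di + Hp * dj + (Hp * Wp * N) * (seq_len(C) - 1L))
  }
  idx <- outer(base, offs, "+")
  conv_index_cache[[key]] <- idx
  idx
}

nn_forward_layer <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
      k <- layer$k; p <- (k - 1L) %/% 2L
      xp <- array(0, c(H + 2 * p, W + 2 * p, N, C))
      xp[p + seq_len(H), p + seq_len(W), , ] <- x
      idx <- conv_gather_index(H, W, N, C, k)
      cols <- matrix(xp[idx], nrow(idx), ncol(idx))
      out <- cols %*% layer$W
      out <- out + rep(layer$b, each = nrow(out))
      list(out = array(out, c(H, W, N, layer$f)),
           cache = list(cols = cols, dims = d))
    },
    bn = {
      d <- dim(x)
      m <- matrix(x, ncol = layer$c)
      rows <- nrow(m)
      if (training) {
        mu <- colMeans(m)
        centred <- m - rep(mu, each = rows)
        v <- colMeans(centred^2)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * v
      } else {
        mu <- layer$running_mean
        v <- layer$running_var
        centred <- m - rep(mu, each = rows)
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- centred * rep(invstd, each = rows)
      out <- xhat * rep(layer$gamma, each = rows) +
        rep(layer$beta, each = rows)
      list(out = array(out, d), layer = layer,
           cache = list(xhat = xhat, invstd = invstd, dims = d))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    pool = {
      # 2x2 max pooling in two 1-d stages (rows then columns), using
      # logical-recycling gathers; the per-stage argmax masks drive backprop
      d <- dim(x)
      if (layer$s != 2L) abort("only 2x2 max pooling is supported")
      H2 <- d[1] %/% 2L
      v <- as.vector(x)
      a1 <- v[c(TRUE, FALSE)]
      a2 <- v[c(FALSE, TRUE)]
      r2 <- a2 > a1
      m1 <- a1
      m1[r2] <- a2[r2]
      sel1 <- rep(c(TRUE, FALSE), each = H2)
      b1 <- m1[sel1]
      b2 <- m1[!sel1]
      c2 <- b2 > b1
      out <- b1
      out[c2] <- b2[c2]
      list(out = array(out, c(H2, d[2] %/% 2L, d[3], d[4])),
           cache = list(r2 = r2, c2 = c2, dims = d))
    },
    avgpool = {
      # parameter-free 2x2 average pooling (the tiny profile's stem)
      d <- dim(x)
      H2 <- d[1] %/% 2L
      v <- as.vector(x)
      m1 <- v[c(TRUE, FALSE)] + v[c(FALSE, TRUE)]
      sel1 <- rep(c(TRUE, FALSE), each = H2)
      out <- (m1[sel1] + m1[!sel1]) / 4
      list(out = array(out, c(H2, d[2] %/% 2L, d[3], d[4])),
           cache = list(dims = d))
    },
    flatten = {
      d <- dim(x)
      ap <- aperm(x, c(1, 2, 4, 3))
      list(out = t(matrix(ap, d[1] * d[2] * d[4], d[3])),
           cache = list(dims = d))
    },
    dense = {
      out <- x %*% layer$W
      out <- out + rep(layer$b, each = nrow(out))
      list(out = out, cache = list(x = x))
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = list(out = out))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        mask <- array(mask, dim(x) %||% length(x))
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    softmax = {
      z <- x - apply(x, 1, max)
      e <- exp(z)
      out <- e / rowSums(e)
      list(out = out, cache = list(out = out))
    },
    abort(paste0("unknown layer type ", layer$type))
  )
}

nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    res <- nn_forward_layer(model$layers[[i]], x, training)
    if (!is.null(res$layer)) model$layers[[i]] <- res$layer  # bn stats
    caches[[i]] <- res$cache
    x <- res$out
  }
  list(out = x, caches = caches, model = model)
}

# ---- backward --------------------------------------------------------------

nn_backward_layer <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      d <- cache$dims; H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
      k <- layer$k; p <- (k - 1L) %/% 2L
      dmat <- matrix(dout, H * W * N, layer$f)
      dW <- crossprod(cache$cols, dmat)
      db <- colSums(dmat)
      dcols <- tcrossprod(dmat, layer$W)
      dxp <- numeric((H + 2 * p) * (W + 2 * p) * N * C)
      idx <- conv_gather_index(H, W, N, C, k)
      for (col in seq_len(ncol(idx))) {   # scatter-add, one offset at a time
        j <- idx[, col]
        dxp[j] <- dxp[j] + dcols[, col]
      }
      dxp <- array(dxp, c(H + 2 * p, W + 2 * p, N, C))
      list(dx = dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE],
           grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$dims
      rows <- nrow(cache$xhat)
      dm <- matrix(dout, ncol = layer$c)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- dm * rep(layer$gamma, each = rows)
      sum_dxhat <- colSums(dxhat)
      sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
      dx <- (dxhat - rep(sum_dxhat / rows, each = rows) -
               cache$xhat * rep(sum_dxhat_xhat / rows, each = rows)) *
        rep(cache$invstd, each = rows)
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    pool = {
      d <- cache$dims
      H2 <- d[1] %/% 2L
      dv <- as.vector(dout)
      dm1 <- numeric(H2 * d[2] * d[3] * d[4])
      sel1 <- rep(c(TRUE, FALSE), each = H2)
      dm1[sel1] <- dv * !cache$c2
      dm1[!sel1] <- dv * cache$c2
      dx <- numeric(prod(d))
      dx[c(TRUE, FALSE)] <- dm1 * !cache$r2
      dx[c(FALSE, TRUE)] <- dm1 * cache$r2
      list(dx = array(dx, d), grads = NULL)
    },
    avgpool = {
      d <- cache$dims
      H2 <- d[1] %/% 2L
      dv <- as.vector(dout) / 4
      dm1 <- numeric(H2 * d[2] * d[3] * d[4])
      sel1 <- rep(c(TRUE, FALSE), each = H2)
      dm1[sel1] <- dv
      dm1[!sel1] <- dv
      dx <- numeric(prod(d))
      dx[c(TRUE, FALSE)] <- dm1
      dx[c(FALSE, TRUE)] <- dm1
      list(dx = array(dx, d), grads = NULL)
    },
    flatten = {
      d <- cache$dims
      ap <- array(t(dout), c(d[1], d[2], d[4], d[3]))
      list(dx = aperm(ap, c(1, 2, 4, 3)), grads = NULL)
    },
    dense = {
      list(dx = tcrossprod(dout, layer$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    sigmoid = list(dx = dout * cache$out * (1 - cache$out), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    softmax = {
      p <- cache$out
      list(dx = p * (dout - rowSums(dout * p)), grads = NULL)
    }
  )
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    res <- nn_backward_layer(model$layers[[i]], dout, caches[[i]])
    grads[i] <- list(res$grads)  # plain [[<- would drop NULL entries
    dout <- res$dx
  }
  grads
}

# ---- SGD with momentum -----------------------------------------------------

nn_init_velocity <- function(model) {
  lapply(model$layers, function(layer) {
    if (is.null(layer$W) && is.null(layer$gamma)) return(NULL)
    if (layer$type == "bn") {
      list(gamma = numeric(length(layer$gamma)),
           beta = numeric(length(layer$beta)))
    } else {
      list(W = layer$W * 0, b = numeric(length(layer$b)))
    }
  })
}

nn_sgd_step <- function(model, grads, velocity, lr, momentum) {
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    g <- grads[[i]]
    if (is.null(g) || !isTRUE(layer$trainable)) next
    for (nm in names(g)) {
      velocity[[i]][[nm]] <- momentum * velocity[[i]][[nm]] - lr * g[[nm]]
      layer[[nm]] <- layer[[nm]] + velocity[[i]][[nm]]
    }
    model$layers[[i]] <- layer
  }
  list(model = model, velocity = velocity)
}
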