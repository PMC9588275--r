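# Minimal CNN engine: single-image (batch size 1) forward/backward passes
# over a list of layers, with compiled conv kernels. Tensors are R arrays
# [H, W, C]; weights are [kh, kw, Cin, Cout]. Only what the cycle GAN
# needs: conv, instance norm, (leaky) ReLU, sigmoid, nearest-neighbour
# upsampling, average pooling, residual blocks.

init_conv_layer <- function(kh, kw, cin, cout, stride = 1L, pad = NULL,
                            gain = 2) {
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  w <- array(rnorm(kh * kw * cin * cout) * sqrt(gain / (kh * kw * cin)),
             dim = c(kh, kw, cin, cout))
  list(type = "conv", w = w, b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_inorm <- function(channels, eps = 1e-5) {
  list(type = "inorm", gamma = rep(1, channels), beta = numeric(channels),
       eps = eps)
}

layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
layer_relu <- function() layer_lrelu(alpha = 0)
layer_sigmoid <- function() list(type = "sigmoid")
layer_upsample <- function(factor = 2L) {
  list(type = "upsample", factor = as.integer(factor))
}
layer_avgpool <- function(factor = 2L) {
  list(type = "avgpool", factor = as.integer(factor))
}
layer_residual <- function(layers) list(type = "residual", layers = layers)

# pool the first two dims of [f, f, H, W, C] (helper for up/downsampling)
block_sum <- function(x, f, H, W, C) {
  dim(x) <- c(f, H, f, W, C)
  x <- aperm(x, c(1, 3, 2, 4, 5))
  colSums(x, dims = 2)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- nn_conv2d(x, dim(x), layer$w, dim(layer$w), layer$b,
                     layer$stride, layer$pad)
      list(out = y, cache = list(x = x))
    },
    inorm = {
      d <- dim(x)
      m <- d[1] * d[2]
      xm <- matrix(x, m, d[3])
      mu <- colMeans(xm)
      v <- colMeans(xm * xm) - mu^2
      inv_std <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - rep(mu, each = m)) * rep(inv_std, each = m)
      y <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
      dim(y) <- d
      list(out = y, cache = list(xhat = xhat, inv_std = inv_std, d = d))
    },
    lrelu = {
      neg <- x < 0
      y <- x
      y[neg] <- layer$alpha * x[neg]
      list(out = y, cache = list(neg = neg))
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = list(y = y))
    },
    upsample = {
      d <- dim(x)
      f <- layer$factor
      y <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
             drop = FALSE]
      list(out = y, cache = list(d = d))
    },
    avgpool = {
      d <- dim(x)
      f <- layer$factor
      if (d[1] %% f != 0 || d[2] %% f != 0) {
        stopf("avgpool: spatial dims (%d x %d) not divisible by %d", d[1], d[2], f)
      }
      y <- block_sum(x, f, d[1] %/% f, d[2] %/% f, d[3]) / f^2
      list(out = y, cache = list(d = d))
    },
    residual = {
      inner <- net_forward(layer$layers, x)
      if (!identical(dim(inner$out), dim(x))) {
        stopf("residual block must preserve tensor shape")
      }
      list(out = x + inner$out, cache = inner$cache)
    },
    stopf("unknown layer type '%s'", layer$type)
  )
}

layer_backward <- function(layer, cache, dy, want_grads = TRUE) {
  switch(layer$type,
    conv = {
      x <- cache$x
      d <- dim(x)
      dx <- nn_conv2d_grad_input(dy, dim(dy), layer$w, dim(layer$w),
                                 layer$stride, layer$pad, d[1], d[2])
      g <- NULL
      if (want_grads) {
        g <- nn_conv2d_grad_weights(x, d, dy, dim(dy), dim(layer$w)[1],
                                    dim(layer$w)[2], layer$stride, layer$pad)
      }
      list(dx = dx, grads = g)
    },
    inorm = {
      d <- cache$d
      m <- d[1] * d[2]
      dym <- matrix(dy, m, d[3])
      xhat <- cache$xhat
      dgamma <- colSums(dym * xhat)
      dbeta <- colSums(dym)
      dxhat <- dym * rep(layer$gamma, each = m)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- (dxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
        rep(cache$inv_std, each = m)
      dim(dx) <- d
      list(dx = dx,
           grads = if (want_grads) list(dgamma = dgamma, dbeta = dbeta) else NULL)
    },
    lrelu = {
      dx <- dy
      dx[cache$neg] <- layer$alpha * dy[cache$neg]
      list(dx = dx, grads = NULL)
    },
    sigmoid = {
      list(dx = dy * cache$y * (1 - cache$y), grads = NULL)
    },
    upsample = {
      d <- cache$d
      f <- layer$factor
      dx <- block_sum(dy, f, d[1], d[2], d[3])
      list(dx = dx, grads = NULL)
    },
    avgpool = {
      d <- cache$d
      f <- layer$factor
      dx <- dy[rep(seq_len(d[1] %/% f), each = f),
               rep(seq_len(d[2] %/% f), each = f), , drop = FALSE] / f^2
      list(dx = dx, grads = NULL)
    },
    residual = {
      inner <- net_backward(layer$layers, cache, dy, want_grads)
      list(dx = dy + inner$dx, grads = inner$grads)
    }
  )
}

net_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

net_backward <- function(layers, caches, dy, want_grads = TRUE) {
  grads <- if (want_grads) vector("list", length(layers)) else NULL
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy, want_grads)
    dy <- r$dx
    if (want_grads) grads[i] <- list(r$grads)  # keep NULL slots
  }
  list(dx = dy, grads = grads)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(grads_add(a[[i]], b[[i]]))
    return(a)
  }
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) {
    for (i in seq_along(g)) g[i] <- list(grads_scale(g[[i]], s))
    return(g)
  }
  g * s
}

# --- Adam -------------------------------------------------------------

adam_init <- function() list(t = 0L, m = NULL)

layer_param_names <- function(layer) {
  switch(layer$type,
    conv = c("w", "b"),
    inorm = c("gamma", "beta"),
    character(0))
}

grad_name_for <- function(layer, p) {
  switch(layer$type, conv = c(w = "dw", b = "db")[[p]],
         inorm = c(gamma = "dgamma", beta = "dbeta")[[p]])
}

# One Adam step over every parameter tensor of `layers` given matching
# `grads` (as produced by net_backward). `state` carries first/second
# moments and the step counter.
adam_step <- function(layers, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  if (is.null(state$m)) state$m <- vector("list", length(layers))
  walk <- function(layers, grads, mom) {
    if (is.null(mom)) mom <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      layer <- layers[[i]]
      g <- grads[[i]]
      if (is.null(g)) next
      if (layer$type == "residual") {
        r <- walk(layer$layers, g, mom[[i]])
        layer$layers <- r$layers
        mom[[i]] <- r$mom
        layers[[i]] <- layer
        next
      }
      if (is.null(mom[[i]])) mom[[i]] <- list()
      for (p in layer_param_names(layer)) {
        gp <- g[[grad_name_for(layer, p)]]
        if (is.null(gp)) next
        st <- mom[[i]][[p]]
        if (is.null(st)) st <- list(m = gp * 0, v = gp * 0)
        st$m <- beta1 * st$m + (1 - beta1) * gp
        st$v <- beta2 * st$v + (1 - beta2) * gp * gp
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
        mom[[i]][[p]] <- st
      }
      layers[[i]] <- layer
    }
    list(layers = layers, mom = mom)
  }
  r <- walk(layers, grads, state$m)
  state$m <- r$mom
  list(layers = r$layers, state = state)
}
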