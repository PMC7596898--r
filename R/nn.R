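# Minimal 1-D convolutional network engine (forward + reverse-mode
# gradients + Adam), written against base R matrix algebra. Data layout is
# [batch, length, channels] throughout. Only the layer types needed by the
# fast-compression residual architecture are implemented.

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))

layer_conv <- function(in_ch, out_ch, kernel, stride = 1L, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") he_init(kernel * in_ch * out_ch, kernel * in_ch)
       else numeric(kernel * in_ch * out_ch)
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = as.integer(stride),
       params = list(W = matrix(w, kernel * in_ch, out_ch),
                     b = numeric(out_ch)))
}

layer_bn <- function(ch) {
  list(type = "bn", ch = ch, eps = 1e-5, momentum = 0.9,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_relu <- function() list(type = "relu", params = list())
layer_dropout <- function(p) list(type = "dropout", p = p, params = list())
layer_maxpool <- function(size = 2L) list(type = "maxpool", size = as.integer(size),
                                          params = list())
layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(in_dim, out_dim, init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") he_init(in_dim * out_dim, in_dim) else numeric(in_dim * out_dim)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(w, in_dim, out_dim), b = numeric(out_dim)))
}

# residual node: out = branch(x) + shortcut(x); branch/shortcut are layer lists
layer_residual <- function(branch, shortcut) {
  list(type = "residual", branch = branch, shortcut = shortcut, params = list())
}

conv_out_len <- function(L, stride) as.integer(ceiling(L / stride))

conv_forward <- function(layer, x) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; C <- d[3L]
  k <- layer$kernel; s <- layer$stride
  oL <- conv_out_len(L, s)
  pad_total <- max((oL - 1L) * s + k - L, 0L)
  pl <- pad_total %/% 2L
  Lp <- L + pad_total
  xpad <- array(0, dim = c(B, Lp, C))
  xpad[, (pl + 1L):(pl + L), ] <- x
  col <- array(0, dim = c(B, oL, k, C))
  pos0 <- (seq_len(oL) - 1L) * s
  for (kk in seq_len(k)) col[, , kk, ] <- xpad[, pos0 + kk, , drop = FALSE]
  colmat <- col; dim(colmat) <- c(B * oL, k * C)
  y <- colmat %*% layer$params$W
  y <- sweep(y, 2L, layer$params$b, "+")
  dim(y) <- c(B, oL, layer$out_ch)
  list(out = y, cache = list(colmat = colmat, dims = c(B, L, C, oL, pl, Lp)))
}

conv_backward <- function(layer, cache, dy) {
  dm <- cache$dims; B <- dm[1L]; L <- dm[2L]; C <- dm[3L]
  oL <- dm[4L]; pl <- dm[5L]; Lp <- dm[6L]
  k <- layer$kernel; s <- layer$stride
  dymat <- dy; dim(dymat) <- c(B * oL, layer$out_ch)
  dW <- crossprod(cache$colmat, dymat)
  db <- colSums(dymat)
  dcol <- dymat %*% t(layer$params$W)
  dim(dcol) <- c(B, oL, k, C)
  dxpad <- array(0, dim = c(B, Lp, C))
  pos0 <- (seq_len(oL) - 1L) * s
  for (kk in seq_len(k)) {
    sl <- dcol[, , kk, , drop = FALSE]
    dim(sl) <- c(B, oL, C)
    dxpad[, pos0 + kk, ] <- dxpad[, pos0 + kk, , drop = FALSE] + sl
  }
  list(dx = dxpad[, (pl + 1L):(pl + L), , drop = FALSE],
       grads = list(W = dW, b = db))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x); M <- d[1L] * d[2L]
  xm <- x; dim(xm) <- c(M, d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  xhat <- sweep(sweep(xm, 2L, mu), 2L, sqrt(v + layer$eps), "/")
  y <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
  dim(y) <- d
  upd <- NULL
  if (training)
    upd <- list(running_mean = layer$momentum * layer$running_mean + (1 - layer$momentum) * mu,
                running_var = layer$momentum * layer$running_var + (1 - layer$momentum) * v)
  list(out = y, cache = list(xhat = xhat, sd = sqrt(v + layer$eps), dims = d),
       state = upd)
}

bn_backward <- function(layer, cache, dy) {
  d <- cache$dims; M <- d[1L] * d[2L]
  dym <- dy; dim(dym) <- c(M, d[3L])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, layer$params$gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dx <- sweep(t1 - t2, 2L, cache$sd, "/")
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pool_forward <- function(layer, x) {
  d <- dim(x); sz <- layer$size
  if (sz == 1L) return(list(out = x, cache = list(identity = TRUE, dims = d)))
  oL <- d[2L] %/% sz
  if (oL < 1L) stop_sparsebci("sequence too short for max-pooling",
                              class = "sparsebci_parameter_error")
  pos0 <- (seq_len(oL) - 1L) * sz
  out <- x[, pos0 + 1L, , drop = FALSE]
  arg <- array(1L, dim = dim(out))
  for (j in 2:sz) {
    cand <- x[, pos0 + j, , drop = FALSE]
    upd <- cand > out         # ties keep the earlier position
    out[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(out = out, cache = list(arg = arg, dims = d, oL = oL))
}

pool_backward <- function(layer, cache, dy) {
  if (isTRUE(cache$identity)) return(list(dx = dy, grads = list()))
  d <- cache$dims; sz <- layer$size; oL <- cache$oL
  dx <- array(0, dim = d)
  for (j in seq_len(sz)) {
    take <- cache$arg == j
    pos <- (seq_len(oL) - 1L) * sz + j
    dx[, pos, ] <- dy * take
  }
  list(dx = dx, grads = list())
}

seq_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  states <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, x),
      bn = bn_forward(l, x, training),
      relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
      dropout = {
        if (training && l$p > 0) {
          mask <- array(stats::runif(length(x)) >= l$p, dim = dim(x)) / (1 - l$p)
          list(out = x * mask, cache = list(mask = mask))
        } else list(out = x, cache = list(mask = NULL))
      },
      maxpool = pool_forward(l, x),
      flatten = {
        d <- dim(x)
        y <- x; dim(y) <- c(d[1L], d[2L] * d[3L])
        list(out = y, cache = list(dims = d))
      },
      dense = list(out = sweep(x %*% l$params$W, 2L, l$params$b, "+"),
                   cache = list(x = x)),
      residual = {
        rb <- seq_forward(l$branch, x, training)
        rs <- if (length(l$shortcut)) seq_forward(l$shortcut, x, training)
              else list(out = x, caches = NULL, states = NULL)
        list(out = rb$out + rs$out,
             cache = list(branch = rb$caches, shortcut = rs$caches),
             state = list(branch = rb$states, shortcut = rs$states))
      },
      stop("unknown layer type ", l$type))
    x <- r$out
    caches[i] <- list(r$cache)   # single-bracket: keep NULLs as elements
    states[i] <- list(r$state)
  }
  list(out = x, caches = caches, states = states)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cc <- caches[[i]]
    r <- switch(l$type,
      conv = conv_backward(l, cc, dy),
      bn = bn_backward(l, cc, dy),
      relu = list(dx = dy * cc$mask, grads = list()),
      dropout = list(dx = if (is.null(cc$mask)) dy else dy * cc$mask, grads = list()),
      maxpool = pool_backward(l, cc, dy),
      flatten = {
        dx <- dy; dim(dx) <- cc$dims
        list(dx = dx, grads = list())
      },
      dense = list(dx = dy %*% t(l$params$W),
                   grads = list(W = crossprod(cc$x, dy), b = colSums(dy))),
      residual = {
        gb <- seq_backward(l$branch, cc$branch, dy)
        if (length(l$shortcut)) {
          gs <- seq_backward(l$shortcut, cc$shortcut, dy)
          list(dx = gb$dx + gs$dx, grads = list(branch = gb$grads, shortcut = gs$grads))
        } else list(dx = gb$dx + dy, grads = list(branch = gb$grads, shortcut = list()))
      })
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(dx = dy, grads = grads)
}

# fold BN running-stat updates from `states` back into the layer list
seq_update_state <- function(layers, states) {
  for (i in seq_along(layers)) {
    st <- states[[i]]
    if (is.null(st)) next
    if (layers[[i]]$type == "bn") {
      layers[[i]]$running_mean <- st$running_mean
      layers[[i]]$running_var <- st$running_var
    } else if (layers[[i]]$type == "residual") {
      layers[[i]]$branch <- seq_update_state(layers[[i]]$branch, st$branch)
      if (length(layers[[i]]$shortcut))
        layers[[i]]$shortcut <- seq_update_state(layers[[i]]$shortcut, st$shortcut)
    }
  }
  layers
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Adam over the nested layer/params structure ---------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "residual")
      list(branch = adam_init(l$branch),
           shortcut = if (length(l$shortcut)) adam_init(l$shortcut) else list())
    else lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_apply <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "residual") {
      rb <- adam_apply(l$branch, grads[[i]]$branch, state[[i]]$branch, lr, t,
                       beta1, beta2, eps)
      layers[[i]]$branch <- rb$layers; state[[i]]$branch <- rb$state
      if (length(l$shortcut)) {
        rs <- adam_apply(l$shortcut, grads[[i]]$shortcut, state[[i]]$shortcut,
                         lr, t, beta1, beta2, eps)
        layers[[i]]$shortcut <- rs$layers; state[[i]]$shortcut <- rs$state
      }
    } else if (length(l$params)) {
      for (nm in names(l$params)) {
        g <- grads[[i]][[nm]]
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        layers[[i]]$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        state[[i]][[nm]] <- st
      }
    }
  }
  list(layers = layers, state = state)
}

count_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (l$type == "residual")
      count_params(l$branch) + if (length(l$shortcut)) count_params(l$shortcut) else 0L
    else sum(vapply(l$params, length, integer(1)), 0L)
  }, numeric(1)))
}

# zero the residual branch's convolution weights (testing hook: with the
# branch silenced the node must reduce to the identity/shortcut map)
zero_branch_params <- function(node) {
  node$branch <- lapply(node$branch, function(l) {
    if (l$type == "conv") {
      l$params$W[] <- 0
      l$params$b[] <- 0
    }
    l
  })
  node
}
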