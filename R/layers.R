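# Layer records: declarative descriptions (shapes + hyperparameters) that can
# be materialised into weight tensors and pushed through the engine. Budget
# accounting enumerates the declared shapes, so counting never requires the
# (potentially large) tensors themselves to be allocated.

new_layer <- function(type, name, ..., shapes = list(), buffers = list()) {
  structure(
    c(list(type = type, name = name, shapes = shapes, buffers = buffers,
           params = NULL), list(...)),
    class = "ppw_layer"
  )
}

ly_conv <- function(name, in_ch, out_ch, k = 3L, bias = TRUE) {
  shapes <- list(w = c(k, k, in_ch, out_ch))
  if (bias) shapes$b <- out_ch
  new_layer("conv", name, in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
            bias = bias, shapes = shapes)
}

ly_pconv <- function(name, in_ch, cp, k = 3L) {
  if (cp < 1) abort("partial convolution needs cp >= 1 after flooring")
  if (cp > in_ch) abort("cp cannot exceed the input channel count")
  if (k %% 2L == 0L) abort("partial convolution kernel must be odd")
  new_layer("pconv", name, in_ch = in_ch, out_ch = in_ch, cp = as.integer(cp),
            k = as.integer(k), shapes = list(w = c(k, k, cp, cp)))
}

ly_pmconv <- function(name, in_ch, cp, kernels = c(3L, 5L, 7L), groups = NULL) {
  if (any(kernels %% 2L == 0L)) abort("PMConv kernel sizes must all be odd")
  if (anyDuplicated(kernels)) abort("PMConv kernel sizes must be distinct")
  if (is.null(groups)) groups <- pm_group_plan(cp, length(kernels))
  if (sum(groups) != cp) abort("PMConv group sizes must sum to cp")
  if (any(groups < 1)) {
    abort("PMConv needs at least one channel per kernel group (cp too small)")
  }
  shapes <- lapply(seq_along(kernels), function(i) {
    c(kernels[i], kernels[i], groups[i], groups[i])
  })
  names(shapes) <- paste0("w", seq_along(kernels))
  new_layer("pmconv", name, in_ch = in_ch, out_ch = in_ch, cp = as.integer(cp),
            kernels = as.integer(kernels), groups = as.integer(groups),
            shapes = shapes)
}

# contiguous near-equal split: floor(cp/g) per group, remainder on the last
# (largest-kernel) group; kernels are assigned in ascending order
pm_group_plan <- function(cp, g) {
  sizes <- rep(cp %/% g, g)
  sizes[g] <- sizes[g] + cp %% g
  as.integer(sizes)
}

ly_pw <- function(name, in_ch, out_ch, bias = FALSE) {
  shapes <- list(w = c(in_ch, out_ch))
  if (bias) shapes$b <- out_ch
  new_layer("pw", name, in_ch = in_ch, out_ch = out_ch, bias = bias,
            shapes = shapes)
}

ly_bn <- function(name, ch) {
  new_layer("bn", name, in_ch = ch, out_ch = ch,
            shapes = list(gamma = ch, beta = ch),
            buffers = list(rm = numeric(ch), rv = rep(1, ch)))
}

ly_relu <- function(name, ch) new_layer("relu", name, in_ch = ch, out_ch = ch)

ly_eca <- function(name, ch, k) {
  new_layer("eca", name, in_ch = ch, out_ch = ch, k = as.integer(k),
            shapes = list(w = k))
}

ly_pool <- function(name, ch) new_layer("pool", name, in_ch = ch, out_ch = ch)

ly_gap <- function(name, ch) new_layer("gap", name, in_ch = ch, out_ch = ch)

ly_flatten <- function(name, ch) new_layer("flatten", name, in_ch = ch, out_ch = ch)

ly_fc <- function(name, in_n, out_n, bias = TRUE) {
  shapes <- list(w = c(in_n, out_n))
  if (bias) shapes$b <- out_n
  new_layer("fc", name, in_ch = in_n, out_ch = out_n, bias = bias,
            shapes = shapes)
}

ly_dropout <- function(name, ch, p = 0.5) {
  new_layer("dropout", name, in_ch = ch, out_ch = ch, p = p)
}

n_params_layer <- function(layer) sum(vapply(layer$shapes, prod, numeric(1)))
n_stored_layer <- function(layer) {
  n_params_layer(layer) + sum(vapply(layer$buffers, length, numeric(1)))
}

# fill the declared shapes with seeded He-normal weights (BLAS-independent
# of batch contents; uses the current RNG stream)
materialize_layer <- function(layer) {
  if (length(layer$shapes) == 0) return(layer)
  params <- list()
  for (nm in names(layer$shapes)) {
    sh <- layer$shapes[[nm]]
    params[[nm]] <- switch(layer$type,
      conv = if (nm == "w") he_init(sh, sh[1] * sh[2] * sh[3]) else numeric(sh),
      pconv = he_init(sh, sh[1] * sh[2] * sh[3]),
      pmconv = he_init(sh, sh[1] * sh[2] * sh[3]),
      pw = if (nm == "w") he_init(sh, sh[1]) else numeric(sh),
      fc = if (nm == "w") he_init(sh, sh[1]) else numeric(sh),
      bn = if (nm == "gamma") rep(1, sh) else numeric(sh),
      eca = runif(sh, -1, 1) / sqrt(sh),
      abort(sprintf("unknown layer type %s", layer$type))
    )
    if (nm %in% c("b", "beta")) params[[nm]] <- numeric(layer$shapes[[nm]])
  }
  layer$params <- params
  layer
}

# ---- forward / backward dispatch -------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  p <- layer$params
  switch(layer$type,
    conv = {
      r <- conv2d_fwd(x, p$w, p$b)
      list(y = r$y, cache = list(Xm = r$Xm, xdim = dim(x)), layer = layer)
    },
    pconv = {
      cp <- layer$cp
      xa <- x[, seq_len(cp), , , drop = FALSE]
      r <- conv2d_fwd(xa, p$w, NULL)
      y <- x
      y[, seq_len(cp), , ] <- r$y
      list(y = y, cache = list(Xm = r$Xm, xadim = dim(xa)), layer = layer)
    },
    pmconv = {
      y <- x
      caches <- vector("list", length(layer$kernels))
      off <- 0L
      for (g in seq_along(layer$kernels)) {
        idx <- off + seq_len(layer$groups[g])
        xg <- x[, idx, , , drop = FALSE]
        r <- conv2d_fwd(xg, p[[paste0("w", g)]], NULL)
        y[, idx, , ] <- r$y
        caches[[g]] <- list(Xm = r$Xm, xgdim = dim(xg))
        off <- off + layer$groups[g]
      }
      list(y = y, cache = caches, layer = layer)
    },
    pw = {
      r <- pw_fwd(x, p$w, p$b)
      list(y = r$y, cache = list(xm = r$xm, xdim = dim(x)), layer = layer)
    },
    bn = {
      r <- bn_fwd(x, p$gamma, p$beta, layer$buffers$rm, layer$buffers$rv, training,
                  momentum = layer$momentum %||% 0.1)
      layer$buffers$rm <- r$rm
      layer$buffers$rv <- r$rv
      list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd, xdim = dim(x),
                                 training = training), layer = layer)
    },
    relu = {
      r <- relu_fwd(x)
      list(y = r$y, cache = r$mask, layer = layer)
    },
    eca = {
      d <- dim(x)
      s <- gap_fwd(x)
      cv <- conv1d_ch_fwd(s, p$w)
      a <- sigmoid(cv$t)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      ym <- xm * as.vector(a)
      dim(ym) <- d
      list(y = ym, cache = list(a = a, sp = cv$sp, x = x, xdim = d), layer = layer)
    },
    pool = {
      r <- pool_fwd(x)
      list(y = r$y, cache = list(amax = r$amax, xdim = dim(x)), layer = layer)
    },
    gap = {
      list(y = gap_fwd(x), cache = list(xdim = dim(x)), layer = layer)
    },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(d[1], prod(d[-1]))
      list(y = y, cache = list(xdim = d), layer = layer)
    },
    fc = {
      r <- fc_fwd(x, p$w, p$b)
      list(y = r$y, cache = list(x = x), layer = layer)
    },
    dropout = {
      r <- dropout_fwd(x, layer$p, training)
      list(y = r$y, cache = r$mask, layer = layer)
    },
    abort(sprintf("unknown layer type %s", layer$type))
  )
}

layer_backward <- function(layer, cache, dy) {
  p <- layer$params
  switch(layer$type,
    conv = {
      r <- conv2d_bwd(dy, cache$Xm, p$w, layer$bias, cache$xdim)
      grads <- list(w = r$dw); if (layer$bias) grads$b <- r$db
      list(dx = r$dx, grads = grads)
    },
    pconv = {
      cp <- layer$cp
      dya <- dy[, seq_len(cp), , , drop = FALSE]
      r <- conv2d_bwd(dya, cache$Xm, p$w, FALSE, cache$xadim)
      dx <- dy
      dx[, seq_len(cp), , ] <- r$dx
      list(dx = dx, grads = list(w = r$dw))
    },
    pmconv = {
      dx <- dy
      grads <- list()
      off <- 0L
      for (g in seq_along(layer$kernels)) {
        idx <- off + seq_len(layer$groups[g])
        dyg <- dy[, idx, , , drop = FALSE]
        r <- conv2d_bwd(dyg, cache[[g]]$Xm, p[[paste0("w", g)]], FALSE,
                        cache[[g]]$xgdim)
        dx[, idx, , ] <- r$dx
        grads[[paste0("w", g)]] <- r$dw
        off <- off + layer$groups[g]
      }
      list(dx = dx, grads = grads)
    },
    pw = {
      r <- pw_bwd(dy, cache$xm, p$w, layer$bias, cache$xdim)
      grads <- list(w = r$dw); if (layer$bias) grads$b <- r$db
      list(dx = r$dx, grads = grads)
    },
    bn = {
      r <- bn_bwd(dy, cache, p$gamma, cache$xdim, cache$training)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = list(dx = relu_bwd(dy, cache), grads = NULL),
    eca = {
      d <- cache$xdim
      dym <- dy; dim(dym) <- c(d[1] * d[2], d[3] * d[4])
      xm <- cache$x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      da <- rowSums(dym * xm); dim(da) <- c(d[1], d[2])
      dt <- da * cache$a * (1 - cache$a)
      cb <- conv1d_ch_bwd(dt, cache$sp, p$w, d[2])
      dxm <- dym * as.vector(cache$a)
      dim(dxm) <- d
      dx <- dxm + gap_bwd(cb$ds, d)
      list(dx = dx, grads = list(w = cb$dw))
    },
    pool = list(dx = pool_bwd(dy, cache$amax, cache$xdim), grads = NULL),
    gap = list(dx = gap_bwd(dy, cache$xdim), grads = NULL),
    flatten = {
      dx <- dy; dim(dx) <- cache$xdim
      list(dx = dx, grads = NULL)
    },
    fc = {
      r <- fc_bwd(dy, cache$x, p$w)
      grads <- list(w = r$dw); if (layer$bias) grads$b <- r$db
      list(dx = r$dx, grads = grads)
    },
    dropout = {
      list(dx = if (is.null(cache)) dy else dy * cache, grads = NULL)
    },
    abort(sprintf("unknown layer type %s", layer$type))
  )
}
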