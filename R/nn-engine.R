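# Minimal CPU neural-network engine: explicit forward/backward passes over
# plain numeric arrays in (batch, channels, height, width) layout. Convolution
# is im2col + BLAS matrix multiply; every layer caches what its backward pass
# needs. Single-threaded and deterministic given fixed weights and inputs.

# ---- conv2d core (stride 1, same padding, odd kernel) ----------------------

pad_nchw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  xp[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  xp
}

# padded (N,C,Hp,Wp) -> (N*H*W, C*k*k) with per-offset column blocks,
# offsets ordered column-major over the k x k window
im2col <- function(xp, k, H, W) {
  d <- dim(xp); N <- d[1]; C <- d[2]
  blocks <- vector("list", k * k)
  idx <- 1L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      s <- xp[, , i:(i + H - 1), j:(j + W - 1), drop = FALSE]
      s <- aperm(s, c(1L, 3L, 4L, 2L))
      dim(s) <- c(N * H * W, C)
      blocks[[idx]] <- s
      idx <- idx + 1L
    }
  }
  do.call(cbind, blocks)
}

# (k,k,Cin,Cout) weight tensor -> (k*k*Cin, Cout) matrix matching im2col order
wmat_of <- function(w) {
  dw <- dim(w); k <- dw[1]; Cin <- dw[3]; Cout <- dw[4]
  m <- matrix(0, k * k * Cin, Cout)
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      m[idx * Cin + seq_len(Cin), ] <- matrix(w[i, j, , ], Cin, Cout)
      idx <- idx + 1L
    }
  }
  m
}

conv2d_fwd <- function(x, w, bias = NULL) {
  d <- dim(x); N <- d[1]; H <- d[3]; W <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  p <- (k - 1L) %/% 2L
  Xm <- im2col(pad_nchw(x, p), k, H, W)
  Y <- Xm %*% wmat_of(w)
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  dim(Y) <- c(N, H, W, Cout)
  list(y = aperm(Y, c(1L, 4L, 2L, 3L)), Xm = Xm)
}

conv2d_bwd <- function(dy, Xm, w, has_bias, xdim) {
  N <- xdim[1]; C <- xdim[2]; H <- xdim[3]; W <- xdim[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  p <- (k - 1L) %/% 2L
  dym <- aperm(dy, c(1L, 3L, 4L, 2L))
  dim(dym) <- c(N * H * W, Cout)
  dWm <- crossprod(Xm, dym)
  dw <- array(0, dim(w))
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      dw[i, j, , ] <- matrix(dWm[idx * C + seq_len(C), ], C, Cout)
      idx <- idx + 1L
    }
  }
  db <- if (has_bias) colSums(dym) else NULL
  dXm <- tcrossprod(dym, wmat_of(w))
  dxp <- array(0, c(N, C, H + 2 * p, W + 2 * p))
  idx <- 0L
  for (j in seq_len(k)) {
    for (i in seq_len(k)) {
      blk <- dXm[, idx * C + seq_len(C), drop = FALSE]
      dim(blk) <- c(N, H, W, C)
      dxp[, , i:(i + H - 1), j:(j + W - 1)] <-
        dxp[, , i:(i + H - 1), j:(j + W - 1), drop = FALSE] +
        aperm(blk, c(1L, 4L, 2L, 3L))
      idx <- idx + 1L
    }
  }
  list(dx = dxp[, , p + seq_len(H), p + seq_len(W), drop = FALSE], dw = dw, db = db)
}

# pointwise (1x1) convolution as a channel-mixing matrix multiply
pw_fwd <- function(x, w, bias = NULL) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  xm <- aperm(x, c(1L, 3L, 4L, 2L)); dim(xm) <- c(N * H * W, C)
  Y <- xm %*% w
  if (!is.null(bias)) Y <- sweep(Y, 2, bias, "+")
  dim(Y) <- c(N, H, W, ncol(w))
  list(y = aperm(Y, c(1L, 4L, 2L, 3L)), xm = xm)
}

pw_bwd <- function(dy, xm, w, has_bias, xdim) {
  N <- xdim[1]; C <- xdim[2]; H <- xdim[3]; W <- xdim[4]
  dym <- aperm(dy, c(1L, 3L, 4L, 2L)); dim(dym) <- c(N * H * W, ncol(w))
  dw <- crossprod(xm, dym)
  db <- if (has_bias) colSums(dym) else NULL
  dxm <- tcrossprod(dym, w)
  dim(dxm) <- c(N, H, W, C)
  list(dx = aperm(dxm, c(1L, 4L, 2L, 3L)), dw = dw, db = db)
}

# ---- batch normalisation ---------------------------------------------------

bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); N <- d[1]; C <- d[2]; M <- N * d[3] * d[4]
  xm <- aperm(x, c(2L, 1L, 3L, 4L)); dim(xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm^2) - mu^2          # biased batch variance
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * istd
  ym <- gamma * xhat + beta
  dim(ym) <- c(C, N, d[3], d[4])
  list(y = aperm(ym, c(2L, 1L, 3L, 4L)), xhat = xhat, istd = istd,
       rm = rm, rv = rv)
}

bn_bwd <- function(dy, cache, gamma, xdim, training) {
  C <- xdim[2]; M <- xdim[1] * xdim[3] * xdim[4]
  dym <- aperm(dy, c(2L, 1L, 3L, 4L)); dim(dym) <- c(C, M)
  s1 <- rowSums(dym)
  s2 <- rowSums(dym * cache$xhat)
  if (training) {
    dxm <- (gamma * cache$istd / M) * (M * dym - s1 - cache$xhat * s2)
  } else {
    dxm <- gamma * cache$istd * dym    # running stats are constants
  }
  dim(dxm) <- c(C, xdim[1], xdim[3], xdim[4])
  list(dx = aperm(dxm, c(2L, 1L, 3L, 4L)), dgamma = s2, dbeta = s1)
}

# ---- 2x2 max pooling, stride 2 ---------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  if (H %% 2L != 0L || W %% 2L != 0L) {
    abort(sprintf("max-pool needs even spatial dims, got %dx%d", H, W))
  }
  x6 <- x; dim(x6) <- c(N, C, 2L, H %/% 2L, 2L, W %/% 2L)
  sl <- function(a, b) {
    s <- x6[, , a, , b, , drop = FALSE]
    dim(s) <- c(N, C, H %/% 2L, W %/% 2L)
    s
  }
  s <- list(sl(1, 1), sl(2, 1), sl(1, 2), sl(2, 2))
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # first window position attaining the max (deterministic tie-break)
  amax <- 1L + (s[[2]] == y & s[[1]] < y) * 1L
  amax[s[[3]] == y & s[[1]] < y & s[[2]] < y] <- 3L
  amax[s[[4]] == y & s[[1]] < y & s[[2]] < y & s[[3]] < y] <- 4L
  list(y = y, amax = amax)
}

pool_bwd <- function(dy, amax, xdim) {
  N <- xdim[1]; C <- xdim[2]; H <- xdim[3]; W <- xdim[4]
  dx6 <- array(0, c(N, C, 2L, H %/% 2L, 2L, W %/% 2L))
  ab <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (q in 1:4) {
    m <- dy * (amax == q)
    dim(m) <- c(N, C, 1L, H %/% 2L, 1L, W %/% 2L)
    dx6[, , ab[[q]][1], , ab[[q]][2], ] <- m
  }
  dim(dx6) <- c(N, C, H, W)
  dx6
}

# ---- global average pooling -> (N, C) --------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 3L, 4L)); dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- rowMeans(xm); dim(y) <- c(d[1], d[2])
  y
}

gap_bwd <- function(dy, xdim) {
  scale <- 1 / (xdim[3] * xdim[4])
  dx <- array(0, xdim)
  dx[] <- rep(as.vector(dy) * scale, times = xdim[3] * xdim[4])
  dx
}

# ---- 1-D convolution across the channel axis (ECA core) --------------------
# s: (N, C); w: length-k kernel, zero same-padding, no bias

conv1d_ch_fwd <- function(s, w) {
  N <- nrow(s); C <- ncol(s); k <- length(w); h <- (k - 1L) %/% 2L
  sp <- matrix(0, N, C + 2L * h)
  sp[, h + seq_len(C)] <- s
  t <- matrix(0, N, C)
  for (u in seq_len(k)) t <- t + w[u] * sp[, u:(u + C - 1L), drop = FALSE]
  list(t = t, sp = sp)
}

conv1d_ch_bwd <- function(dt, sp, w, C) {
  k <- length(w); h <- (k - 1L) %/% 2L
  dw <- numeric(k)
  dsp <- matrix(0, nrow(dt), C + 2L * h)
  for (u in seq_len(k)) {
    dw[u] <- sum(dt * sp[, u:(u + C - 1L), drop = FALSE])
    dsp[, u:(u + C - 1L)] <- dsp[, u:(u + C - 1L)] + w[u] * dt
  }
  list(dw = dw, ds = dsp[, h + seq_len(C), drop = FALSE])
}

# ---- fully connected, relu, dropout, loss ----------------------------------

fc_fwd <- function(x, w, b) list(y = sweep(x %*% w, 2, b, "+"), x = x)

fc_bwd <- function(dy, x, w) {
  list(dx = tcrossprod(dy, w), dw = crossprod(x, dy), db = colSums(dy))
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, mask) dy * mask

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

# numerically stable softmax cross-entropy; y is an integer vector in 1..K
softmax_ce <- function(scores, y) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  p <- e / rowSums(e)
  n <- nrow(scores)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  list(loss = loss, probs = p, dscores = dscores / n)
}
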