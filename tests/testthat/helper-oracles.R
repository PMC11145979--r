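# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: convolution is a direct quadruple loop,
# metrics come straight from (label, prediction) pairs, and the attention
# kernel rule is re-evaluated scalar-by-scalar.

# direct-loop dense 2-D convolution, stride 1, same (zero) padding
naive_conv2d <- function(x, w, bias = NULL) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]; p <- (k - 1) %/% 2
  y <- array(0, c(N, Cout, H, W))
  for (n in seq_len(N)) for (o in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (c in seq_len(C)) for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- i + a - 1 - p; jj <- j + b - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + x[n, c, ii, jj] * w[a, b, c, o]
      }
    }
    y[n, o, i, j] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  y
}

# direct pointwise mix (1x1 convolution)
naive_pw <- function(x, w, bias = NULL) {
  d <- dim(x); Cout <- ncol(w)
  y <- array(0, c(d[1], Cout, d[3], d[4]))
  for (n in seq_len(d[1])) for (o in seq_len(Cout)) {
    acc <- array(0, d[3:4])
    for (c in seq_len(d[2])) acc <- acc + x[n, c, , ] * w[c, o]
    y[n, o, , ] <- acc + if (is.null(bias)) 0 else bias[o]
  }
  y
}

# eval-mode batch norm with explicit statistics
naive_bn_eval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[2])) {
    y[, c, , ] <- gamma[c] * (x[, c, , ] - rm[c]) / sqrt(rv[c] + eps) + beta[c]
  }
  y
}

# one-vs-rest confusion counts and metrics straight from label/pred pairs
naive_metrics <- function(truth, pred, k) {
  out <- data.frame(class = seq_len(k), tp = 0, fp = 0, tn = 0, fn = 0)
  for (c in seq_len(k)) {
    out$tp[c] <- sum(truth == c & pred == c)
    out$fp[c] <- sum(truth != c & pred == c)
    out$fn[c] <- sum(truth == c & pred != c)
    out$tn[c] <- sum(truth != c & pred != c)
  }
  out$precision <- ifelse(out$tp + out$fp > 0, out$tp / (out$tp + out$fp), 0)
  out$recall <- ifelse(out$tp + out$fn > 0, out$tp / (out$tp + out$fn), 0)
  pr <- out$precision + out$recall
  out$f1 <- ifelse(pr > 0, 2 * out$precision * out$recall / pr, 0)
  list(per_class = out, overall = mean(truth == pred))
}

# scalar re-evaluation of the adaptive odd-kernel rule
naive_eca_k <- function(C, gamma = 2, b = 1, k_min = 3) {
  t <- floor(abs(log2(C) + b) / gamma)
  if (t %% 2 == 0) t <- t + 1
  max(t, k_min)
}

# plain 3-nearest-neighbour classifier on feature rows (euclidean)
knn3_predict <- function(train_x, train_y, test_x) {
  apply(test_x, 1, function(q) {
    d2 <- colSums((t(train_x) - q)^2)
    nb <- train_y[order(d2)[1:3]]
    as.integer(names(which.max(table(nb))))
  })
}

# dominant stripe orientation (degrees in [0, 180)) via the 2-D FFT peak
fft_orientation <- function(channel) {
  S <- nrow(channel)
  f <- stats::fft(channel - mean(channel))
  mag <- Mod(f)
  mag[1, 1] <- 0
  idx <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  # convert matrix indices to signed frequencies
  ky <- idx[1] - 1; if (ky > S / 2) ky <- ky - S
  kx <- idx[2] - 1; if (kx > S / 2) kx <- kx - S
  (atan2(ky, kx) * 180 / pi) %% 180
}

rand_x <- function(n, c, h, w, sd = 1) array(rnorm(n * c * h * w, sd = sd), c(n, c, h, w))

expect_shape <- function(x, shape) testthat::expect_identical(dim(x), as.integer(shape))
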