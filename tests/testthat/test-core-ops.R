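# The family's building-block operators: shape contracts, degenerate
# equivalences against independent compositions, the adaptive attention
# kernel rule, and tensor-enumeration parameter counts.

test_that("partial convolution preserves the declared shape contract", {
  set.seed(201)
  spec <- pconv_spec(64, 64, partial_ratio = 1 / 4)
  expect_equal(spec$cp, 16L)
  x <- rand_x(2, 64, 56, 56)
  expect_shape(partial_conv(x, spec), c(2, 64, 56, 56))
  expect_error(partial_conv(rand_x(1, 32, 8, 8), spec), "channels")
  expect_error(pconv_spec(2, 4, partial_ratio = 1 / 4), "zero channels")
  expect_error(pconv_spec(8, 8, kernel = 4), "odd")
})

test_that("partial convolution with r = 1 equals dense conv then pointwise mix", {
  set.seed(202)
  spec <- pconv_spec(6, 5, partial_ratio = 1)
  x <- rand_x(2, 6, 16, 16)
  w_part <- array(rnorm(3 * 3 * 6 * 6, sd = 0.3), c(3, 3, 6, 6))
  w_mix <- matrix(rnorm(6 * 5, sd = 0.3), 6, 5)
  gamma <- runif(5, 0.5, 1.5); beta <- rnorm(5, sd = 0.2)
  got <- partial_conv(x, spec, weights = list(
    "pconv_part.w" = w_part, "pconv_mix.w" = w_mix,
    "pconv_bn.gamma" = gamma, "pconv_bn.beta" = beta))
  # independent composition: loop conv -> loop pointwise -> explicit eval-mode
  # batch norm (fresh running stats) -> relu
  want <- naive_conv2d(x, w_part)
  want <- naive_pw(want, w_mix)
  want <- naive_bn_eval(want, gamma, beta, rm = rep(0, 5), rv = rep(1, 5))
  want <- pmax(want, 0)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("single-kernel pmconv degenerates exactly to partial convolution", {
  set.seed(203)
  ps <- pconv_spec(16, 12, partial_ratio = 1 / 4)
  ms <- pmconv_spec(16, 12, partial_ratio = 1 / 4, kernel_set = 3L)
  x <- rand_x(2, 16, 10, 10)
  w_part <- array(rnorm(3 * 3 * 4 * 4), c(3, 3, 4, 4))
  w_mix <- matrix(rnorm(16 * 12), 16, 12)
  g <- runif(12, 0.5, 1.5); b <- rnorm(12)
  y1 <- partial_conv(x, ps, weights = list(
    "pconv_part.w" = w_part, "pconv_mix.w" = w_mix,
    "pconv_bn.gamma" = g, "pconv_bn.beta" = b))
  y2 <- pmconv(x, ms, weights = list(
    "pmconv_part.w1" = w_part, "pmconv_mix.w" = w_mix,
    "pmconv_bn.gamma" = g, "pmconv_bn.beta" = b))
  expect_identical(y1, y2)
})

test_that("pmconv validates kernels and group plans", {
  expect_error(pmconv_spec(64, 64, kernel_set = c(3, 4)), "odd")
  expect_error(pmconv_spec(64, 64, kernel_set = c(3, 3, 5)), "distinct")
  expect_error(pmconv_spec(64, 64, kernel_set = c(3, 5, 7),
                           group_plan = c(10, 10, 10)), "sum to cp")
  expect_shape(pmconv(rand_x(1, 256, 7, 7), pmconv_spec(256, 256)),
               c(1, 256, 7, 7))
})

test_that("attention kernel size matches an exhaustive scalar re-evaluation", {
  got <- eca_kernel_size(1:4096)
  want <- vapply(1:4096, naive_eca_k, numeric(1))
  expect_identical(got, as.integer(want))
  expect_true(all(got %% 2 == 1))
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(32), 3L)
  expect_identical(eca_kernel_size(4), 3L)  # raw value 1, clamped
})

test_that("channel attention gates are symmetric, bounded and invertible in the limit", {
  set.seed(204)
  cfg <- eca_config(8)
  # identical per-channel means -> identical gate values away from the
  # zero-padded channel borders (the k-wide window is truncated there)
  x_sym <- array(1.7, c(1, 8, 4, 2))
  y_sym <- eca_attention(x_sym, cfg, weights = rnorm(cfg$k))
  gates <- y_sym / x_sym
  h <- (cfg$k - 1) %/% 2
  interior <- gates[, (h + 1):(8 - h), , ]
  expect_lt(diff(range(interior)), 1e-12)
  # gates always in (0, 1): outputs shrink towards zero, never flip sign
  xr <- rand_x(2, 8, 5, 5)
  yr <- eca_attention(xr, cfg, weights = rnorm(cfg$k))
  ratio <- yr / xr
  expect_true(all(ratio > 0 & ratio < 1))
  expect_true(all(sign(yr) == sign(xr) | xr == 0))
  # saturating kernel -> gate ~ 1 recovers the input
  y_big <- eca_attention(abs(xr) + 0.5, cfg, weights = rep(50, cfg$k))
  expect_lt(max(abs(y_big - (abs(xr) + 0.5))), 1e-3)
})

test_that("classifier head maps feature maps to per-class scores", {
  set.seed(205)
  hs <- head_spec(256, 1024, 6)
  x <- rand_x(4, 256, 7, 7)
  expect_shape(fl2pw_head(x, hs), c(4, 6))
  # zero final weights -> constant score vector regardless of input
  w1 <- matrix(rnorm(256 * 1024, sd = 0.05), 256, 1024)
  y0 <- fl2pw_head(x, hs, weights = list(
    "head_pw1.w" = w1, "head_pw2.w" = matrix(0, 1024, 6)))
  expect_true(all(abs(y0) < 1e-12))
})

test_that("operator parameter counts follow from tensor enumeration", {
  # partial conv 64 -> 64, r = 1/4, k = 3: 9*16^2 kernel + 64*64 mix +
  # 2*64 bn affine = 6,528 learnable (+128 running stats)
  layers <- gppwvgg:::pconv_layers(pconv_spec(64, 64, 1 / 4))
  counts <- vapply(layers, gppwvgg:::n_params_layer, numeric(1))
  expect_equal(sum(counts), 9 * 16^2 + 64 * 64 + 2 * 64)
  expect_equal(sum(vapply(layers, gppwvgg:::n_stored_layer, numeric(1))),
               sum(counts) + 2 * 64)
  # mixed-kernel delta at cp = 64, groups 21/21/22 with kernels 3/5/7
  pm <- gppwvgg:::pmconv_layers(pmconv_spec(256, 256, 1 / 4))
  pc <- gppwvgg:::pconv_layers(pconv_spec(256, 256, 1 / 4))
  delta <- sum(vapply(pm, gppwvgg:::n_params_layer, numeric(1))) -
    sum(vapply(pc, gppwvgg:::n_params_layer, numeric(1)))
  expect_equal(delta, (9 * 21^2 + 25 * 21^2 + 49 * 22^2) - 9 * 64^2)
  expect_equal(delta, 1846)
  # pointwise head 256 -> 1024 -> 6, bias-free: 256*1024 + 1024*6
  hd <- gppwvgg:::head_layers(head_spec(256, 1024, 6))
  expect_equal(sum(vapply(hd, gppwvgg:::n_params_layer, numeric(1))),
               256 * 1024 + 1024 * 6)
  # one attention gate adds exactly k values
  expect_equal(gppwvgg:::n_params_layer(gppwvgg:::ly_eca("e", 256, 5)), 5)
})
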