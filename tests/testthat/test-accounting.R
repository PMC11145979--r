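# Budget accounting: tensor-enumeration equality with a materialised model,
# frozen family budgets, MAC conventions, and the reduction arithmetic.

test_that("shape-based counting equals brute-force enumeration of materialised tensors", {
  set.seed(401)
  for (nm in c("scheme2", "g_ppw_vgg11")) {
    m <- build_model(nm, num_classes = 6, input_size = 32)
    brute_params <- sum(vapply(m$layers, function(ly) {
      sum(vapply(ly$params %||% list(), length, numeric(1)))
    }, numeric(1)))
    brute_stored <- brute_params + sum(vapply(m$layers, function(ly) {
      sum(vapply(ly$buffers %||% list(), length, numeric(1)))
    }, numeric(1)))
    b <- count_parameters(m)
    expect_identical(b$total_params, brute_params)
    expect_identical(b$stored_values, brute_stored)
  }
})

test_that("per-layer budgets sum to the model totals (conservation)", {
  for (nm in c("vgg11", "re_vgg11", "scheme1", "scheme2", "scheme3",
               "g_ppw_vgg11")) {
    b <- count_parameters(nm)
    expect_identical(sum(b$layers$params), b$total_params)
    expect_identical(sum(b$layers$stored), b$stored_values)
  }
})

test_that("family budgets reproduce the published table", {
  expect_identical(count_parameters("vgg11")$total_params, 128790918)
  expect_equal(count_parameters("vgg11")$param_memory_mib, 491.29)
  expect_equal(count_parameters("re_vgg11")$param_memory_mib, 57.62,
               tolerance = 0.011)
  expect_equal(count_parameters("scheme2")$param_memory_mib, 1.78)
  expect_equal(count_parameters("scheme3")$param_memory_mib, 1.79)
  expect_equal(count_parameters("g_ppw_vgg11")$param_memory_mib, 1.79)
})

test_that("budgets shrink monotonically along the published reductions", {
  p <- vapply(c("g_ppw_vgg11", "re_vgg11", "vgg11"),
              function(nm) count_parameters(nm)$total_params, numeric(1))
  expect_true(p[1] < p[2] && p[2] < p[3])
})

test_that("head fraction follows the stored-value convention", {
  expect_equal(head_fraction("re_vgg11"), 92.03)
  # hand-built toy: head 30 of 40 stored values
  toy <- structure(list(layers = list(
    gppwvgg:::ly_fc("body_fc", 5, 2, bias = FALSE),       # 10 values
    gppwvgg:::ly_fc("head_fc", 10, 3, bias = FALSE)       # 30 values
  ), preset = NA_character_), class = "ppw_model")
  expect_equal(head_fraction(toy), 75)
})

test_that("MAC counting follows the documented closed forms", {
  # single 1x1 conv 4 -> 2 on a 3x3 grid with bias: 2*9*4 MACs + 2*9 adds
  ly <- gppwvgg:::ly_pw("p", 4, 2, bias = TRUE)
  ly$spatial <- 3L
  expect_equal(gppwvgg:::layer_macs(ly, mac_flags(act = FALSE)), 90)
  # dense 3x3 conv: out_elements * in * k^2 (+ bias adds)
  lc <- gppwvgg:::ly_conv("c", 3, 8, 3, bias = TRUE)
  lc$spatial <- 10L
  expect_equal(gppwvgg:::layer_macs(lc, mac_flags(act = FALSE)),
               100 * 8 * 3 * 9 + 100 * 8)
})

test_that("doubling the input size quadruples conv MACs and leaves linear MACs unchanged", {
  f <- mac_flags(bias = FALSE, act = FALSE, bn = FALSE)
  a <- count_macs("re_vgg11", input_size = 224, flags = f)$layers
  b <- count_macs("re_vgg11", input_size = 448, flags = f)$layers
  conv_a <- sum(a$macs[a$type == "conv"])
  conv_b <- sum(b$macs[b$type == "conv"])
  expect_equal(conv_b, 4 * conv_a)
  # the deeper fully connected layers see fixed-width features, so their
  # MACs are unchanged (only the flattening layer scales with the grid)
  expect_equal(b$macs[b$layer == "head_fc2"], a$macs[a$layer == "head_fc2"])
  expect_equal(b$macs[b$layer == "head_fc3"], a$macs[a$layer == "head_fc3"])
})

test_that("baseline complexity lands within half a percent of the published figure", {
  m <- count_macs("vgg11")
  expect_lt(abs(m$macs_m - 7618.57) / 7618.57, 0.005)
})

test_that("reduction arithmetic reproduces the worked examples", {
  expect_equal(percent_reduction(144.76, 93.45)$reduction_pct, 35.44)
  expect_equal(percent_reduction(140.49, 93.45)$reduction_pct, 33.48)
  expect_equal(percent_reduction(5, 5)$reduction_pct, 0)
  expect_error(percent_reduction(0, 1), "positive")
  expect_error(percent_reduction(-2, 1), "positive")
  # bounded above by 100 for non-negative improved quantities
  set.seed(402)
  x <- runif(100, 0.1, 50); x1 <- runif(100, 0, 50)
  expect_true(all(percent_reduction(x, x1)$reduction_pct <= 100))
})

test_that("budget table aggregates the family consistently", {
  bt <- budget_table(c("vgg11", "g_ppw_vgg11"))
  expect_equal(nrow(bt), 2)
  expect_equal(bt$memory_mib, c(491.29, 1.79))
  expect_true(all(c("params", "macs_m", "head_pct") %in% names(bt)))
})
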