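# The model family: preset grid, forward shape contracts, spatial plan,
# nesting of the ablation options, serialisation, and trainability.

test_that("preset option grid is nested as the ablation design requires", {
  p <- list_presets()
  expect_equal(p$name, c("vgg11", "re_vgg11", "scheme1", "scheme2",
                         "scheme3", "g_ppw_vgg11"))
  flags <- as.matrix(p[, c("a", "b", "c", "d")])
  expect_equal(unname(flags[p$name == "vgg11", ] * 1), c(0, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(flags[p$name == "scheme1", ] * 1), c(1, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(flags[p$name == "scheme2", ] * 1), c(1, 1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(unname(flags[p$name == "scheme3", ] * 1), c(1, 1, 1, 0),
               ignore_attr = TRUE)
  expect_equal(unname(flags[p$name == "g_ppw_vgg11", ] * 1), c(1, 1, 1, 1),
               ignore_attr = TRUE)
  # monotone nesting: each scheme keeps all options of its predecessor
  sel <- flags[3:6, ]
  for (i in 2:4) expect_true(all(sel[i, ] >= sel[i - 1, ]))
})

test_that("spatial grid follows the five-pool plan 224 -> 7", {
  m <- build_model("g_ppw_vgg11", materialize = FALSE)
  ms <- model_summary(m)
  pools <- ms[ms$type == "pool", ]
  expect_equal(pools$out_size, c(112, 56, 28, 14, 7))
  expect_equal(ms$out_size[nrow(ms)], 7)  # head pools over the 7x7 grid
})

test_that("vgg11 preset has 8 conv and 3 linear weight layers and no batch norm", {
  m <- build_model("vgg11", materialize = FALSE)
  types <- vapply(m$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv"), 8)
  expect_equal(sum(types == "fc"), 3)
  expect_equal(sum(types == "bn"), 0)
  expect_equal(sum(types == "dropout"), 2)
})

test_that("forward pass honours the batch/class shape contract", {
  set.seed(301)
  m <- build_model("g_ppw_vgg11", num_classes = 6, input_size = 32)
  for (n in c(1, 3)) {
    s <- model_forward(m, rand_x(n, 3, 32, 32))$scores
    expect_shape(s, c(n, 6))
    expect_true(all(is.finite(s)))
  }
  expect_error(model_forward(m, rand_x(1, 3, 64, 64)), "expects")
  expect_error(model_forward(m, rand_x(1, 1, 32, 32)), "3 channels")
})

test_that("full-resolution forward maps (2,3,224,224) to (2,classes)", {
  set.seed(302)
  m <- build_model("g_ppw_vgg11", num_classes = 6, input_size = 224)
  s <- model_forward(m, rand_x(2, 3, 224, 224, sd = 0.5))$scores
  expect_shape(s, c(2, 6))
})

test_that("re_vgg11 learnable total matches the frozen enumeration", {
  b <- count_parameters("re_vgg11")
  expect_identical(b$total_params, 15103750)
})

test_that("successive schemes differ only in the documented option's tensors", {
  lb2 <- layer_budget("scheme2")
  lb3 <- layer_budget("scheme3")
  # scheme3 swaps the deepest partial stage for the multi-kernel operator
  joined <- merge(lb2, lb3, by = "layer", all = TRUE)
  changed <- joined$layer[is.na(joined$params.x) | is.na(joined$params.y) |
                            joined$params.x != joined$params.y]
  expect_true(all(grepl("^stage8_part", changed)))
  lbg <- layer_budget("g_ppw_vgg11")
  extra <- setdiff(lbg$layer, lb3$layer)
  expect_true(all(grepl("_eca$", extra)))
  shared <- merge(lb3, lbg, by = "layer")
  expect_true(all(shared$params.x == shared$params.y))
})

test_that("architecture configs round-trip through YAML", {
  cfg <- preset_config("g_ppw_vgg11", num_classes = 4, input_size = 64)
  f <- tempfile(fileext = ".yaml")
  write_arch_config(cfg, f)
  cfg2 <- read_arch_config(f)
  expect_equal(cfg2$channel_plan, cfg$channel_plan)
  expect_equal(cfg2$stage_op, cfg$stage_op)
  expect_equal(cfg2$eca_stages, cfg$eca_stages)
  expect_equal(cfg2$num_classes, cfg$num_classes)
  expect_equal(cfg2$head, cfg$head)
  unlink(f)
})

test_that("a short fit drives training loss down by at least half for every preset", {
  spec <- synthetic_spec(num_classes = 4, n_per_class = 16, size = 32,
                         seed = 303, difficulty = "easy")
  d <- generate_batch(spec)
  cfg <- desk_train_config(epochs = 24, batch_size = 16, lr = 1e-3, seed = 303)
  for (nm in c("vgg11", "re_vgg11", "scheme1", "scheme2", "scheme3",
               "g_ppw_vgg11")) {
    set.seed(303)
    m <- build_model(nm, num_classes = 4, input_size = 32)
    fit <- ppw_train(m, d$x, d$y, cfg, steps = 48)
    log <- fit$log
    expect_lt(log$loss[nrow(log)], 0.5 * log$loss[1],
              label = sprintf("final loss for %s", nm))
  }
})
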