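# Dataset protocol: augmentation ranges and determinism, the app resize
# rule, stratified splitting, folder reading.

test_that("sampled augmentation factors stay inside their closed intervals", {
  cfg <- augment_config()
  set.seed(501)
  draws <- replicate(1e4, draw_augment_params(cfg), simplify = FALSE)
  rot <- vapply(draws, `[[`, numeric(1), "rotation")
  br <- vapply(draws, `[[`, numeric(1), "brightness")
  hu <- vapply(draws, `[[`, numeric(1), "hue")
  sa <- vapply(draws, `[[`, numeric(1), "saturation")
  expect_true(all(rot >= -30 & rot <= 30))
  expect_true(all(br >= 0.9 & br <= 1.1))
  expect_true(all(hu >= 0.9 & hu <= 1.1))
  expect_true(all(sa >= 0.9 & sa <= 1.1))
  # both flips actually occur
  expect_gt(mean(vapply(draws, `[[`, logical(1), "vflip")), 0.4)
  expect_gt(mean(vapply(draws, `[[`, logical(1), "hflip")), 0.4)
})

test_that("augmentation is deterministic under a seed and resizes to the final size", {
  set.seed(502)
  img <- array(runif(450 * 350 * 3), c(450, 350, 3))  # H x W >= 400 x 300 crop
  cfg <- augment_config()
  a1 <- augment_image(img, cfg, seed = 99)
  a2 <- augment_image(img, cfg, seed = 99)
  expect_identical(a1, a2)
  expect_shape(a1, c(224, 224, 3))
  a3 <- augment_image(img, cfg, seed = 100)
  expect_false(identical(a1, a3))
})

test_that("identity augmentation reduces to a plain resize", {
  set.seed(503)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  cfg <- augment_config(crop_size = NULL, final_size = 32)
  id <- list(vflip = FALSE, hflip = FALSE, rotation = 0,
             brightness = 1, hue = 1, saturation = 1)
  out <- augment_image(img, cfg, params = id)
  expect_equal(out, gppwvgg:::resize_img(img, 32, 32), tolerance = 1e-6)
})

test_that("augmentation refuses images smaller than the crop window", {
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))
  expect_error(augment_image(img, augment_config(), seed = 1), "at least 300x400")
})

test_that("app preprocessing applies the 300-px two-step rule", {
  set.seed(504)
  big <- array(runif(400 * 533 * 3), c(400, 533, 3))
  out <- app_preprocess(big)
  expect_shape(out, c(224, 224, 3))
  two_step <- gppwvgg:::resize_img(gppwvgg:::resize_img(big, 300, 300), 224, 224)
  expect_equal(out, two_step, tolerance = 1e-8)
  # small images skip the intermediate square
  small <- array(runif(250 * 299 * 3), c(250, 299, 3))
  expect_equal(app_preprocess(small), gppwvgg:::resize_img(small, 224, 224),
               tolerance = 1e-8)
  expect_false(isTRUE(all.equal(
    app_preprocess(small),
    gppwvgg:::resize_img(gppwvgg:::resize_img(small, 300, 300), 224, 224),
    tolerance = 1e-8)))
  # an already-square 224 input keeps its dimensions
  sq <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_shape(app_preprocess(sq), c(224, 224, 3))
})

test_that("stratified splitting is disjoint, exhaustive and balanced", {
  df <- tibble::tibble(idx = 1:100, label = rep(1:5, each = 20))
  sp <- split_dataset(df, prop = 0.6, seed = 11)
  expect_equal(sum(sp$split == "train"), 60)
  expect_equal(sum(sp$split == "test"), 40)
  expect_setequal(sp$idx, 1:100)
  per_class <- tapply(sp$split == "train", sp$label, sum)
  expect_true(all(abs(per_class - 12) <= 1))
  expect_identical(split_dataset(df, prop = 0.6, seed = 11)$split, sp$split)
  expect_false(identical(split_dataset(df, prop = 0.6, seed = 12)$split, sp$split))
})

test_that("k-fold assignment is stratified, disjoint and exhaustive", {
  df <- tibble::tibble(idx = 1:99, label = rep(1:3, each = 33))
  kf <- kfold_split(df, k = 3, seed = 21)
  expect_equal(as.vector(table(kf$fold)), c(33, 33, 33))
  for (f in 1:3) {
    per_class <- table(kf$label[kf$fold == f])
    expect_true(all(per_class == 11))
  }
  tiny <- tibble::tibble(idx = 1:4, label = c(1, 1, 1, 2))
  expect_error(kfold_split(tiny, k = 3), "at least 3")
})

test_that("folder reading is deterministic and tolerant of clutter", {
  root <- tempfile("ds")
  for (cl in c("b_class", "a_class", "c_class")) {
    dir.create(file.path(root, cl), recursive = TRUE)
    for (j in 1:3) {
      write_image(array(runif(8 * 8 * 3), c(8, 8, 3)),
                  file.path(root, cl, sprintf("im%d.png", j)))
    }
  }
  writeLines("not an image", file.path(root, "a_class", "notes.txt"))
  dir.create(file.path(root, "empty_class"))
  expect_warning(ds <- read_dataset(root), "empty_class")
  expect_equal(nrow(ds), 9)
  expect_equal(unique(ds$class), c("a_class", "b_class", "c_class"))
  expect_equal(ds$label, rep(1:3, each = 3))
  expect_error(read_dataset(tempfile("nope")), "not found")
  er <- tempfile("emptyroot"); dir.create(er)
  expect_warning(e <- read_dataset(er), "no class directories")
  expect_equal(nrow(e), 0)
  unlink(root, recursive = TRUE)
})

test_that("images round-trip through load_images into model layout", {
  root <- tempfile("imgs"); dir.create(root)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  p <- file.path(root, "a.png")
  write_image(img, p)
  x <- load_images(p, size = 16)
  expect_shape(x, c(1, 3, 16, 16))
  expect_equal(x[1, , , ], aperm(img, c(3, 1, 2)), tolerance = 1e-2)
  unlink(root, recursive = TRUE)
})
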