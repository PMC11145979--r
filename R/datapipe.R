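# Dataset protocol: class-per-folder reading, seeded augmentation with the
# published jitter ranges, the mobile-app resize rule, stratified 60/40
# splitting and stratified k-fold assignment.
#
# Images are numeric (height, width, 3) arrays in [0, 1]. EBImage handles
# file IO and resizing; rotation uses a custom bilinear sampler because the
# pipeline fills rotation borders by reflection, which stock rotations do
# not offer.

as_ebi <- function(a) EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
from_ebi <- function(im) {
  d <- EBImage::imageData(im)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]
  aperm(d, c(2L, 1L, 3L))
}

#' Read an image file as a (height, width, 3) array in [0, 1]
#' @param path a JPEG or PNG file.
#' @return numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image not found: %s", path))
  from_ebi(EBImage::readImage(path))
}

#' Write a (height, width, 3) array to PNG
#' @param img numeric array in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

resize_img <- function(img, width, height) {
  from_ebi(EBImage::resize(as_ebi(img), w = width, h = height))
}

# rotate about the image centre with bilinear sampling; out-of-frame samples
# are filled by reflecting the source across its borders
rotate_reflect <- function(img, degrees) {
  if (degrees == 0) return(img)
  d <- dim(img); H <- d[1]; W <- d[2]
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse map: source coords of each output pixel
  sy <- cy + gy * cos(th) - gx * sin(th)
  sx <- cx + gy * sin(th) + gx * cos(th)
  reflect_idx <- function(v, n) {
    period <- 2 * n
    v <- ((v - 1) %% period)
    ifelse(v >= n, period - 1 - v, v) + 1
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  iy0 <- reflect_idx(y0, H); iy1 <- reflect_idx(y0 + 1, H)
  ix0 <- reflect_idx(x0, W); ix1 <- reflect_idx(x0 + 1, W)
  out <- img
  for (c in 1:3) {
    ch <- img[, , c]
    out[, , c] <-
      ch[cbind(c(iy0), c(ix0))] * (1 - fy) * (1 - fx) +
      ch[cbind(c(iy1), c(ix0))] * fy * (1 - fx) +
      ch[cbind(c(iy0), c(ix1))] * (1 - fy) * fx +
      ch[cbind(c(iy1), c(ix1))] * fy * fx
  }
  out
}

jitter_hsv <- function(img, brightness, hue, saturation) {
  d <- dim(img)
  hsv <- rgb_to_hsv_mat(img[, , 1], img[, , 2], img[, , 3])
  # hue factor acts as a bounded shift proportional to (factor - 1);
  # saturation and brightness act multiplicatively on S and V
  h <- (hsv$h + (hue - 1) * 0.25) %% 1
  s <- pmin(hsv$s * saturation, 1)
  v <- pmin(hsv$v * brightness, 1)
  rgb <- hsv_to_rgb_mat(h, s, v)
  out <- img
  out[, , 1] <- rgb$r; out[, , 2] <- rgb$g; out[, , 3] <- rgb$b
  out
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Augmentation configuration
#'
#' Encodes the field-image augmentation protocol: independent vertical and
#' horizontal flips (probability 0.5 each), rotation uniform in
#' `rotation_range` degrees with reflected borders, brightness / hue /
#' saturation factors uniform in their closed ranges, a random crop to
#' `crop_size` (width x height; `NULL` skips the crop for images already at
#' working resolution), and a final resize to `final_size` pixels square.
#'
#' @param vflip,hflip enable the flips.
#' @param rotation_range degrees, length 2.
#' @param brightness,hue,saturation closed factor ranges, length 2.
#' @param crop_size integer `c(width, height)` or `NULL`.
#' @param final_size output side length in pixels.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(vflip = TRUE, hflip = TRUE,
                           rotation_range = c(-30, 30),
                           brightness = c(0.9, 1.1),
                           hue = c(0.9, 1.1),
                           saturation = c(0.9, 1.1),
                           crop_size = c(300L, 400L),
                           final_size = 224L) {
  structure(list(vflip = vflip, hflip = hflip,
                 rotation_range = rotation_range, brightness = brightness,
                 hue = hue, saturation = saturation,
                 crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
                 final_size = as.integer(final_size)),
            class = "augment_config")
}

#' Draw the random factors of one augmentation
#'
#' Exposed separately so the sampling ranges can be property-tested; all
#' draws come from the current RNG stream.
#'
#' @param cfg an [augment_config()].
#' @return named list of the sampled factors.
#' @export
draw_augment_params <- function(cfg) {
  list(
    vflip = cfg$vflip && runif(1) < 0.5,
    hflip = cfg$hflip && runif(1) < 0.5,
    rotation = runif(1, cfg$rotation_range[1], cfg$rotation_range[2]),
    brightness = runif(1, cfg$brightness[1], cfg$brightness[2]),
    hue = runif(1, cfg$hue[1], cfg$hue[2]),
    saturation = runif(1, cfg$saturation[1], cfg$saturation[2])
  )
}

#' Augment one image
#'
#' Pipeline order: flips, rotation, photometric jitter, random crop, resize.
#'
#' @param img (height, width, 3) array in [0, 1].
#' @param cfg an [augment_config()].
#' @param seed optional integer making this call self-contained; without it
#'   the current RNG stream is used.
#' @param params optional pre-drawn [draw_augment_params()] list (overrides
#'   random draws; the crop offset is still random unless the image equals
#'   the crop size).
#' @return `final_size` x `final_size` x 3 array.
#' @export
augment_image <- function(img, cfg = augment_config(), seed = NULL,
                          params = NULL) {
  with_local_seed(seed, {
    p <- params %||% draw_augment_params(cfg)
    if (isTRUE(p$vflip)) img <- img[dim(img)[1]:1, , , drop = FALSE]
    if (isTRUE(p$hflip)) img <- img[, dim(img)[2]:1, , drop = FALSE]
    img <- rotate_reflect(img, p$rotation)
    img <- jitter_hsv(img, p$brightness, p$hue, p$saturation)
    if (!is.null(cfg$crop_size)) {
      cw <- cfg$crop_size[1]; ch <- cfg$crop_size[2]
      H <- dim(img)[1]; W <- dim(img)[2]
      if (H < ch || W < cw) {
        abort(sprintf(
          "image (%dx%d px, width x height) smaller than crop size; need at least %dx%d",
          W, H, cw, ch))
      }
      y0 <- if (H == ch) 0L else sample.int(H - ch + 1L, 1L) - 1L
      x0 <- if (W == cw) 0L else sample.int(W - cw + 1L, 1L) - 1L
      img <- img[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE]
    }
    resize_img(img, cfg$final_size, cfg$final_size)
  })
}

#' Mobile-app preprocessing rule
#'
#' Images whose longer side exceeds 300 px are first resized to 300 x 300,
#' then to 224 x 224; smaller images go straight to 224 x 224. The two-step
#' shrink keeps large field photographs (e.g. 4000 x 3000) from aliasing
#' badly on-device.
#'
#' @param img (height, width, 3) array.
#' @param final_size output side length (default 224).
#' @param threshold longer-side trigger for the intermediate step.
#' @return square array `final_size` x `final_size` x 3.
#' @export
app_preprocess <- function(img, final_size = 224L, threshold = 300L) {
  stopifnot(length(dim(img)) == 3L)
  if (max(dim(img)[1:2]) > threshold) {
    img <- resize_img(img, threshold, threshold)
  }
  resize_img(img, final_size, final_size)
}

# ---- dataset reading and splitting -----------------------------------------

#' Read a class-per-folder image dataset
#'
#' Classes are the subdirectories of `root` in lexicographic order; files
#' within each class are ordered lexicographically too, so the index layout
#' is deterministic. Non-image files are ignored; empty class directories
#' produce a warning and are dropped.
#'
#' @param root dataset root directory.
#' @return a tibble with `path`, `class` (character), `label` (integer id).
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) abort(sprintf("dataset root not found: %s", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) {
    warn("dataset root has no class directories; returning empty dataset")
    return(tibble::tibble(path = character(), class = character(),
                          label = integer()))
  }
  rows <- purrr::map_dfr(seq_along(classes), function(i) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.(jpe?g|png)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      warn(sprintf("class directory '%s' has no images; excluded", classes[i]))
      return(NULL)
    }
    tibble::tibble(path = files, class = classes[i], label = i)
  })
  # relabel in case empty classes were dropped
  rows$label <- as.integer(factor(rows$class, levels = sort(unique(rows$class))))
  rows
}

#' Stratified train/test split
#'
#' @param data a data frame with a label column.
#' @param prop training fraction (default 0.60).
#' @param seed optional integer seed.
#' @param label_col name of the label column.
#' @return `data` with an added `split` column ("train"/"test"); per class the
#'   train count is `round(prop * n)`.
#' @export
split_dataset <- function(data, prop = 0.6, seed = NULL, label_col = "label") {
  stopifnot(label_col %in% names(data))
  with_local_seed(seed, {
    split <- character(nrow(data))
    for (lv in unique(data[[label_col]])) {
      idx <- which(data[[label_col]] == lv)
      n_train <- round(prop * length(idx))
      tr <- sample(idx, n_train)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "test"
    }
    data$split <- split
    data
  })
}

#' Stratified k-fold assignment
#'
#' @inheritParams split_dataset
#' @param k number of folds.
#' @return `data` with an added integer `fold` column in 1..k.
#' @export
kfold_split <- function(data, k = 3L, seed = NULL, label_col = "label") {
  stopifnot(label_col %in% names(data))
  counts <- table(data[[label_col]])
  if (any(counts < k)) {
    abort(sprintf("every class needs at least %d items for %d-fold assignment", k, k))
  }
  with_local_seed(seed, {
    fold <- integer(nrow(data))
    for (lv in unique(data[[label_col]])) {
      idx <- sample(which(data[[label_col]] == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    data$fold <- fold
    data
  })
}

#' Load images as a model-ready batch
#'
#' @param paths image files.
#' @param size square side length the images are resized to.
#' @return array (n, 3, size, size) in [0, 1].
#' @export
load_images <- function(paths, size = 224L) {
  n <- length(paths)
  x <- array(0, c(n, 3L, size, size))
  for (i in seq_len(n)) {
    img <- read_image(paths[i])
    if (any(dim(img)[1:2] != size)) img <- resize_img(img, size, size)
    x[i, , , ] <- aperm(img, c(3L, 1L, 2L))
  }
  x
}

#' Write a split manifest as CSV
#'
#' @param data tibble with at least `path` and `label` (plus `split`/`fold`).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
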