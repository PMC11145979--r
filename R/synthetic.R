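# Seeded generator of class-conditioned synthetic canopy images. Each class
# carries a distinct signature (stripe orientation, stripe frequency, hue
# centre) rendered as an oriented sinusoidal leaf texture in a green hue band
# over a brown cluttered background. The model is deliberately minimal: it
# emulates the premise that crop varieties differ by subtle, consistent
# texture/colour statistics, with difficulty tunable through signature
# spacing, clutter and pixel noise.

#' Specification for the synthetic canopy-image generator
#'
#' @param num_classes number of classes (default 6).
#' @param n_per_class images per class.
#' @param size output side length in pixels (scalar, square images).
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @param difficulty `"easy"` (wide hue band, little clutter/noise) or
#'   `"hard"` (compressed hue band, more clutter and noise).
#' @param noise_sd,clutter overrides of the per-pixel Gaussian noise standard
#'   deviation and the background clutter density in `[0, 1]`; `NULL` uses
#'   the difficulty defaults.
#' @param signatures optional data frame with columns `theta` (degrees),
#'   `freq` (cycles per image) and `hue` (in [0,1]), one row per class;
#'   rows must be pairwise distinct.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_classes = 6L, n_per_class = 20L, size = 224L,
                           seed = 1L, difficulty = c("easy", "hard"),
                           noise_sd = NULL, clutter = NULL,
                           signatures = NULL) {
  difficulty <- match.arg(difficulty)
  stopifnot(is_count(num_classes), is_count(n_per_class), is_count(size))
  if (is.null(noise_sd)) noise_sd <- if (difficulty == "easy") 0.03 else 0.08
  if (is.null(clutter)) clutter <- if (difficulty == "easy") 0.2 else 0.5
  if (is.null(signatures)) {
    k <- num_classes
    hue_band <- if (difficulty == "easy") c(0.16, 0.46) else c(0.26, 0.36)
    signatures <- tibble::tibble(
      class_id = seq_len(k),
      theta = (seq_len(k) - 1) * 180 / k,
      freq = 6 + 3 * ((seq_len(k) - 1) %% 3),
      hue = seq(hue_band[1], hue_band[2], length.out = max(k, 2))[seq_len(k)]
    )
  } else {
    signatures <- tibble::as_tibble(signatures)
    signatures$class_id <- seq_len(nrow(signatures))
  }
  if (nrow(signatures) != num_classes) {
    abort("`signatures` must have one row per class")
  }
  key <- paste(signatures$theta, signatures$freq, signatures$hue)
  if (anyDuplicated(key)) {
    abort("class signatures must be pairwise distinct (theta, freq, hue)")
  }
  structure(list(num_classes = as.integer(num_classes),
                 n_per_class = as.integer(n_per_class),
                 size = as.integer(size), seed = as.integer(seed),
                 difficulty = difficulty, noise_sd = noise_sd,
                 clutter = clutter, signatures = signatures),
            class = "synthetic_spec")
}

# smooth random field in [0,1]: coarse uniform grid upsampled bilinearly
smooth_field <- function(size, coarse = 8L) {
  g <- matrix(runif(coarse^2), coarse, coarse)
  f <- resize_img(array(rep(g, 3L), c(coarse, coarse, 3L)), size, size)[, , 1]
  (f - min(f)) / max(1e-9, diff(range(f)))
}

#' Render one synthetic canopy image
#'
#' Draws from the current RNG stream; wrap in `set.seed()` (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param class_id class index in 1..`spec$num_classes`.
#' @param spec a [synthetic_spec()].
#' @return (size, size, 3) array in [0, 1].
#' @export
generate_image <- function(class_id, spec) {
  if (class_id < 1 || class_id > spec$num_classes) {
    abort("`class_id` out of range for this spec")
  }
  sg <- spec$signatures[class_id, ]
  S <- spec$size
  u <- matrix(seq_len(S) / S, S, S, byrow = TRUE)   # x (column) coordinate
  v <- matrix(seq_len(S) / S, S, S)                 # y (row) coordinate
  th <- sg$theta * pi / 180
  phase <- runif(1, 0, 2 * pi)
  stripe <- sin(2 * pi * sg$freq * (u * cos(th) + v * sin(th)) + phase)
  # foreground: green leaf texture, value modulated by the stripes
  h <- (sg$hue + 0.01 * matrix(rnorm(S^2), S, S)) %% 1
  s_ch <- pmin(pmax(0.55 + 0.1 * stripe, 0), 1)
  val <- pmin(pmax(0.45 + 0.35 * stripe, 0), 1)
  # background clutter: brown soil patches where a smooth field exceeds the
  # clutter quantile
  if (spec$clutter > 0) {
    fld <- smooth_field(S)
    hole <- fld > stats::quantile(fld, 1 - spec$clutter)
    soil_v <- 0.25 + 0.2 * smooth_field(S, 6L)
    h[hole] <- 0.07 + 0.02 * fld[hole]
    s_ch[hole] <- 0.45
    val[hole] <- soil_v[hole]
  }
  rgb <- hsv_to_rgb_mat(h, s_ch, val)
  img <- array(0, c(S, S, 3L))
  img[, , 1] <- rgb$r; img[, , 2] <- rgb$g; img[, , 3] <- rgb$b
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim(img))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate an in-memory labelled batch
#'
#' @param spec a [synthetic_spec()].
#' @return list with `x` (n, 3, size, size), integer labels `y`, and the
#'   per-image `manifest` tibble.
#' @export
generate_batch <- function(spec) {
  with_local_seed(spec$seed, {
    n <- spec$num_classes * spec$n_per_class
    x <- array(0, c(n, 3L, spec$size, spec$size))
    y <- integer(n)
    i <- 0L
    manifest <- list()
    for (c_id in seq_len(spec$num_classes)) {
      for (j in seq_len(spec$n_per_class)) {
        i <- i + 1L
        img <- generate_image(c_id, spec)
        x[i, , , ] <- aperm(img, c(3L, 1L, 2L))
        y[i] <- c_id
        manifest[[i]] <- tibble::tibble(
          index = i, class_id = c_id,
          theta = spec$signatures$theta[c_id],
          freq = spec$signatures$freq[c_id],
          hue = spec$signatures$hue[c_id])
      }
    }
    list(x = x, y = y, manifest = dplyr::bind_rows(manifest))
  })
}

#' Generate a class-per-folder synthetic dataset on disk
#'
#' Writes `n_per_class` PNG images per class under
#' `out_dir/class_<id>/img_<j>.png` plus a `manifest.csv` with per-image
#' signature parameters. Byte-identical across runs with the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest tibble, invisibly.
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- with_local_seed(spec$seed, {
    rows <- list()
    i <- 0L
    for (c_id in seq_len(spec$num_classes)) {
      cls_dir <- file.path(out_dir, sprintf("class_%02d", c_id))
      dir.create(cls_dir, showWarnings = FALSE)
      for (j in seq_len(spec$n_per_class)) {
        i <- i + 1L
        img <- generate_image(c_id, spec)
        fn <- file.path(cls_dir, sprintf("img_%04d.png", j))
        write_image(img, fn)
        rows[[i]] <- tibble::tibble(
          path = fn, class = sprintf("class_%02d", c_id), label = c_id,
          theta = spec$signatures$theta[c_id],
          freq = spec$signatures$freq[c_id],
          hue = spec$signatures$hue[c_id])
      }
    }
    dplyr::bind_rows(rows)
  })
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Hue histogram of an image
#'
#' 32-bin (by default) histogram of the hue channel, weighted uniformly;
#' the simple per-class colour statistic used to check that generated
#' classes are separable.
#'
#' @param img (height, width, 3) array.
#' @param bins number of histogram bins.
#' @return numeric vector of length `bins`, summing to 1.
#' @export
hue_histogram <- function(img, bins = 32L) {
  h <- rgb_to_hsv_mat(img[, , 1], img[, , 2], img[, , 3])$h
  counts <- tabulate(pmin(floor(h * bins) + 1L, bins), nbins = bins)
  counts / sum(counts)
}
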