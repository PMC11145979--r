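# Building-block operators of the lightweight VGG family, exposed as pure
# functions on (batch, channels, height, width) arrays. Each operator takes a
# spec object describing its geometry and an optional weight list; omitted
# weights are drawn from the current RNG stream, so a surrounding set.seed()
# makes every call reproducible.

#' Specification for a partial convolution block
#'
#' A partial convolution convolves only the first `cp = floor(r * in_channels)`
#' channels with a dense `k x k` kernel (stride 1, same padding, no bias),
#' passes the remaining channels through unchanged, then mixes all channels
#' with a bias-free 1x1 pointwise convolution followed by batch normalisation
#' and ReLU. Convolving a contiguous quarter of the channels (the default
#' `partial_ratio = 1/4`) targets the redundancy among channel features while
#' keeping the receptive-field computation cheap.
#'
#' @param in_channels,out_channels positive integers.
#' @param partial_ratio fraction of input channels convolved, in (0, 1].
#' @param kernel odd spatial kernel size (default 3).
#' @return an object of class `pconv_spec`.
#' @export
pconv_spec <- function(in_channels, out_channels, partial_ratio = 1 / 4,
                       kernel = 3L) {
  stopifnot(is_count(in_channels), is_count(out_channels))
  if (partial_ratio <= 0 || partial_ratio > 1) {
    abort("`partial_ratio` must lie in (0, 1]")
  }
  if (kernel %% 2 == 0) abort("`kernel` must be odd")
  cp <- floor(partial_ratio * in_channels)
  if (cp < 1) abort("`partial_ratio` floors the convolved subset to zero channels")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 partial_ratio = partial_ratio, kernel = as.integer(kernel),
                 cp = as.integer(cp)),
            class = "pconv_spec")
}

#' Specification for a partially-mixed multi-kernel convolution block
#'
#' Like [pconv_spec()], but the convolved subset is partitioned into
#' contiguous, near-equal groups, each convolved densely within-group with a
#' different odd kernel size (ascending order), merging several receptive
#' fields before the pointwise mix.
#'
#' @inheritParams pconv_spec
#' @param kernel_set distinct odd kernel sizes, one per group.
#' @param group_plan optional integer sizes of the channel groups; must sum to
#'   `cp`. Default: `floor(cp/g)` per group with the remainder on the last
#'   (largest-kernel) group.
#' @return an object of class `pmconv_spec`.
#' @export
pmconv_spec <- function(in_channels, out_channels, partial_ratio = 1 / 4,
                        kernel_set = c(3L, 5L, 7L), group_plan = NULL) {
  base <- pconv_spec(in_channels, out_channels, partial_ratio)
  if (any(kernel_set %% 2 == 0)) abort("`kernel_set` must contain only odd kernels")
  if (anyDuplicated(kernel_set)) abort("`kernel_set` must be distinct")
  if (is.null(group_plan)) group_plan <- pm_group_plan(base$cp, length(kernel_set))
  if (length(group_plan) != length(kernel_set) || sum(group_plan) != base$cp) {
    abort("`group_plan` must have one size per kernel and sum to cp")
  }
  structure(c(unclass(base),
              list(kernel_set = as.integer(sort(kernel_set)),
                   group_plan = as.integer(group_plan))),
            class = "pmconv_spec")
}

#' Adaptive odd kernel size for efficient channel attention
#'
#' The attention kernel grows logarithmically with the channel count:
#' `t = floor(|log2(C) + b| / gamma)`, rounded up to the next odd integer and
#' clamped below at `k_min`. With the default `gamma = 2`, `b = 1` this gives
#' k = 3 up to C = 64 and k = 5 for C in 128..2048.
#'
#' @param C positive channel count (vectorised).
#' @param gamma,b integers controlling the channel-to-kernel scaling.
#' @param k_min odd lower clamp (attention over fewer than 3 neighbours
#'   degenerates to a per-channel gate).
#' @return odd integer kernel size(s).
#' @export
eca_kernel_size <- function(C, gamma = 2L, b = 1L, k_min = 3L) {
  if (any(C < 1)) abort("`C` must be positive")
  t <- floor(abs(log2(C) + b) / gamma)
  k <- ifelse(t %% 2 == 1, t, t + 1)
  as.integer(pmax(k, k_min))
}

#' Configuration for an efficient channel attention gate
#'
#' @param C channel count of the gated feature map.
#' @inheritParams eca_kernel_size
#' @return an object of class `eca_config` with the derived kernel size `k`.
#' @export
eca_config <- function(C, gamma = 2L, b = 1L, k_min = 3L) {
  stopifnot(is_count(C))
  structure(list(C = as.integer(C), gamma = as.integer(gamma),
                 b = as.integer(b), k_min = as.integer(k_min),
                 k = eca_kernel_size(C, gamma, b, k_min)),
            class = "eca_config")
}

#' Specification for the pointwise-convolution classifier head
#'
#' Replaces a VGG fully connected classifier with two 1x1 convolutions (no
#' bias) around a ReLU, followed by global average pooling: the first expands
#' `in_channels` to `hidden_width`, the second maps to `num_classes`, and the
#' pool reduces the spatial grid to a per-class score.
#'
#' @param in_channels input channels (256 in the reference plan).
#' @param hidden_width width of the expanded representation (default 1024).
#' @param num_classes number of output classes (default 6).
#' @return an object of class `head_spec`.
#' @export
head_spec <- function(in_channels = 256L, hidden_width = 1024L, num_classes = 6L) {
  stopifnot(is_count(in_channels), is_count(hidden_width), is_count(num_classes))
  structure(list(in_channels = as.integer(in_channels),
                 hidden_width = as.integer(hidden_width),
                 num_classes = as.integer(num_classes)),
            class = "head_spec")
}

# internal: turn an operator spec into its layer chain
pconv_layers <- function(spec, prefix = "pconv") {
  list(ly_pconv(paste0(prefix, "_part"), spec$in_channels, spec$cp, spec$kernel),
       ly_pw(paste0(prefix, "_mix"), spec$in_channels, spec$out_channels),
       ly_bn(paste0(prefix, "_bn"), spec$out_channels),
       ly_relu(paste0(prefix, "_relu"), spec$out_channels))
}

pmconv_layers <- function(spec, prefix = "pmconv") {
  list(ly_pmconv(paste0(prefix, "_part"), spec$in_channels, spec$cp,
                 spec$kernel_set, spec$group_plan),
       ly_pw(paste0(prefix, "_mix"), spec$in_channels, spec$out_channels),
       ly_bn(paste0(prefix, "_bn"), spec$out_channels),
       ly_relu(paste0(prefix, "_relu"), spec$out_channels))
}

head_layers <- function(spec, prefix = "head") {
  list(ly_pw(paste0(prefix, "_pw1"), spec$in_channels, spec$hidden_width),
       ly_relu(paste0(prefix, "_relu"), spec$hidden_width),
       ly_pw(paste0(prefix, "_pw2"), spec$hidden_width, spec$num_classes),
       ly_gap(paste0(prefix, "_gap"), spec$num_classes))
}

run_chain <- function(layers, x, training = FALSE) {
  for (ly in layers) {
    if (length(ly$shapes) > 0 && is.null(ly$params)) ly <- materialize_layer(ly)
    x <- layer_forward(ly, x, training)$y
  }
  x
}

check_channels <- function(x, expected) {
  stopifnot_4d(x)
  if (dim(x)[2] != expected) {
    abort(sprintf("input has %d channels, spec expects %d", dim(x)[2], expected))
  }
}

# replace a chain's weights from a named list keyed by "<layer name>.<param>"
apply_weights <- function(layers, weights) {
  if (is.null(weights)) {
    return(lapply(layers, function(ly) {
      if (length(ly$shapes) > 0) materialize_layer(ly) else ly
    }))
  }
  lapply(layers, function(ly) {
    ly <- materialize_layer(ly)
    for (pn in names(ly$params)) {
      key <- paste0(ly$name, ".", pn)
      if (key %in% names(weights)) {
        stopifnot(length(weights[[key]]) == length(ly$params[[pn]]))
        val <- weights[[key]]
        if (!is.null(dim(ly$params[[pn]]))) dim(val) <- dim(ly$params[[pn]])
        ly$params[[pn]] <- val
      }
    }
    ly
  })
}

#' Apply a partial convolution block
#'
#' @param x rank-4 array (batch, channels, height, width) with
#'   `spec$in_channels` channels.
#' @param spec a [pconv_spec()].
#' @param weights optional named list of weights, keyed `"<stage>.<param>"`,
#'   e.g. `pconv_part.w` (k,k,cp,cp), `pconv_mix.w` (in,out),
#'   `pconv_bn.gamma` / `pconv_bn.beta`; missing tensors are initialised from
#'   the current RNG stream.
#' @param training logical; batch statistics vs running statistics in the
#'   batch-norm stage.
#' @return rank-4 array (batch, out_channels, height, width).
#' @export
partial_conv <- function(x, spec, weights = NULL, training = FALSE) {
  stopifnot(inherits(spec, "pconv_spec"))
  check_channels(x, spec$in_channels)
  run_chain(apply_weights(pconv_layers(spec), weights), x, training)
}

#' Apply a partially-mixed multi-kernel convolution block
#'
#' @param x rank-4 array with `spec$in_channels` channels.
#' @param spec a [pmconv_spec()].
#' @inheritParams partial_conv
#' @return rank-4 array (batch, out_channels, height, width).
#' @export
pmconv <- function(x, spec, weights = NULL, training = FALSE) {
  stopifnot(inherits(spec, "pmconv_spec"))
  check_channels(x, spec$in_channels)
  run_chain(apply_weights(pmconv_layers(spec), weights), x, training)
}

#' Apply an efficient channel attention gate
#'
#' Global average pooling produces one descriptor per channel; a single
#' k-wide 1-D convolution across the channel axis (zero same-padding, no
#' bias, no dimensionality reduction) followed by a sigmoid yields per-channel
#' weights in (0, 1) that rescale the input.
#'
#' @param x rank-4 array with `cfg$C` channels.
#' @param cfg an [eca_config()].
#' @param weights optional length-`cfg$k` numeric kernel.
#' @return rank-4 array, same shape as `x`.
#' @export
eca_attention <- function(x, cfg, weights = NULL) {
  stopifnot(inherits(cfg, "eca_config"))
  check_channels(x, cfg$C)
  ly <- ly_eca("eca", cfg$C, cfg$k)
  ly <- materialize_layer(ly)
  if (!is.null(weights)) {
    stopifnot(length(weights) == cfg$k)
    ly$params$w <- as.numeric(weights)
  }
  layer_forward(ly, x, FALSE)$y
}

#' Apply the pointwise-convolution classifier head
#'
#' @param x rank-4 array with `spec$in_channels` channels and spatial dims
#'   of at least 1x1.
#' @param spec a [head_spec()].
#' @inheritParams partial_conv
#' @return matrix (batch, num_classes) of class scores.
#' @export
fl2pw_head <- function(x, spec, weights = NULL) {
  stopifnot(inherits(spec, "head_spec"))
  check_channels(x, spec$in_channels)
  if (any(dim(x)[3:4] < 1)) abort("spatial dimensions must be at least 1x1")
  layers <- apply_weights(head_layers(spec), weights)
  y <- x
  for (ly in layers) y <- layer_forward(ly, y, FALSE)$y
  y
}
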