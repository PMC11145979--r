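# Declarative model family: an arch_config fully describes a network; presets
# encode the baseline (vgg11), the channel-reconfigured baseline (re_vgg11),
# the nested ablation schemes and the final g_ppw_vgg11.

VGG_PLAN <- c(64L, 128L, 256L, 256L, 512L, 512L, 512L, 512L)
RE_PLAN <- c(32L, 64L, 64L, 64L, 128L, 128L, 256L, 256L)
POOL_AFTER <- c(1L, 2L, 4L, 6L, 8L)

#' Declarative architecture configuration
#'
#' Describes one member of the lightweight VGG family: eight convolutional
#' stages (channel plan + per-stage operator), the classic VGG11 pooling
#' layout (2x2 max-pool after stages 1, 2, 4, 6, 8), optional batch
#' normalisation and per-stage efficient channel attention, and one of two
#' classifier heads. Stage 1 is always a dense convolution: its three input
#' channels cannot be meaningfully split into a partial subset.
#'
#' @param channel_plan integer vector of 8 output widths.
#' @param stage_op per-stage operator, values in `dense`, `pconv`, `pmconv`
#'   (recycled if length 1). Stage 1 is forced to `dense`.
#' @param use_bn logical; batch normalisation after each stage operator.
#' @param eca_stages integer stages that receive a channel-attention gate
#'   after their activation (empty for none).
#' @param head `"fc_head"` (three fully connected layers with dropout) or
#'   `"fl2pw_head"` (two pointwise convolutions + global average pooling).
#' @param fc_widths hidden widths of the fully connected head.
#' @param hidden_width hidden width of the pointwise head.
#' @param num_classes number of output classes.
#' @param input_size square input resolution; must be divisible by 32 so the
#'   five pools land on an integer grid.
#' @param partial_ratio fraction of channels convolved in partial stages.
#' @param kernel_set odd kernel sizes of the multi-kernel (pmconv) stages.
#' @param dropout dropout probability between fully connected layers.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(channel_plan = RE_PLAN,
                        stage_op = "dense",
                        use_bn = TRUE,
                        eca_stages = integer(),
                        head = c("fl2pw_head", "fc_head"),
                        fc_widths = c(1024L, 1024L),
                        hidden_width = 1024L,
                        num_classes = 6L,
                        input_size = 224L,
                        partial_ratio = 1 / 4,
                        kernel_set = c(3L, 5L, 7L),
                        dropout = 0.5) {
  head <- match.arg(head)
  if (length(channel_plan) != 8L) abort("`channel_plan` must have exactly 8 stages")
  if (any(channel_plan < 1)) abort("channel widths must be positive")
  stage_op <- rep(stage_op, length.out = 8L)
  if (!all(stage_op %in% c("dense", "pconv", "pmconv"))) {
    abort("`stage_op` values must be dense, pconv or pmconv")
  }
  stage_op[1] <- "dense"
  if (input_size %% 32L != 0L || input_size < 32L) {
    abort("`input_size` must be a positive multiple of 32")
  }
  if (length(eca_stages) && !all(eca_stages %in% 1:8)) {
    abort("`eca_stages` must be a subset of stages 1..8")
  }
  structure(list(channel_plan = as.integer(channel_plan),
                 stage_op = stage_op,
                 pool_after = POOL_AFTER,
                 use_bn = isTRUE(use_bn),
                 eca_stages = as.integer(eca_stages),
                 head = head,
                 fc_widths = as.integer(fc_widths),
                 hidden_width = as.integer(hidden_width),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 partial_ratio = partial_ratio,
                 kernel_set = as.integer(kernel_set),
                 dropout = dropout),
            class = "arch_config")
}

preset_names <- function() {
  c("vgg11", "re_vgg11", "scheme1", "scheme2", "scheme3", "g_ppw_vgg11")
}

#' Resolve a named preset to its architecture configuration
#'
#' The ablation presets nest: scheme1 adds partial convolution to re_vgg11,
#' scheme2 additionally swaps in the pointwise head, scheme3 additionally
#' uses the multi-kernel operator in the deepest stage, and g_ppw_vgg11
#' additionally gates every stage with channel attention.
#'
#' @param name one of `vgg11`, `re_vgg11`, `scheme1`, `scheme2`, `scheme3`,
#'   `g_ppw_vgg11`.
#' @param num_classes,input_size overrides applied to the preset.
#' @return an [arch_config()].
#' @export
preset_config <- function(name, num_classes = 6L, input_size = 224L) {
  name <- match.arg(name, preset_names())
  pconv_ops <- c("dense", rep("pconv", 7L))
  pm_ops <- pconv_ops; pm_ops[8] <- "pmconv"
  cfg <- switch(name,
    vgg11 = arch_config(VGG_PLAN, "dense", use_bn = FALSE, head = "fc_head",
                        fc_widths = c(4096L, 4096L)),
    re_vgg11 = arch_config(RE_PLAN, "dense", head = "fc_head",
                           fc_widths = c(1024L, 1024L)),
    scheme1 = arch_config(RE_PLAN, pconv_ops, head = "fc_head",
                          fc_widths = c(1024L, 1024L)),
    scheme2 = arch_config(RE_PLAN, pconv_ops, head = "fl2pw_head"),
    scheme3 = arch_config(RE_PLAN, pm_ops, head = "fl2pw_head"),
    g_ppw_vgg11 = arch_config(RE_PLAN, pm_ops, eca_stages = 1:8,
                              head = "fl2pw_head")
  )
  cfg$num_classes <- as.integer(num_classes)
  cfg$input_size <- as.integer(input_size)
  cfg
}

#' List the model presets and their enabled options
#'
#' Options follow the ablation grid: (a) partial convolution, (b) pointwise
#' classifier head, (c) multi-kernel partial convolution, (d) efficient
#' channel attention.
#'
#' @return a tibble with one row per preset and logical columns `a`..`d`.
#' @export
list_presets <- function() {
  purrr::map_dfr(preset_names(), function(nm) {
    cfg <- preset_config(nm)
    tibble::tibble(
      name = nm,
      a = any(cfg$stage_op %in% c("pconv", "pmconv")),
      b = cfg$head == "fl2pw_head",
      c = any(cfg$stage_op == "pmconv"),
      d = length(cfg$eca_stages) > 0
    )
  })
}

# ---- builder ---------------------------------------------------------------

config_layers <- function(cfg) {
  layers <- list()
  s <- cfg$input_size
  in_ch <- 3L
  add <- function(ly, sp) {
    ly$spatial <- sp
    layers[[length(layers) + 1L]] <<- ly
  }
  for (i in 1:8) {
    out_ch <- cfg$channel_plan[i]
    op <- cfg$stage_op[i]
    nm <- sprintf("stage%d", i)
    if (op == "dense") {
      add(ly_conv(paste0(nm, "_conv"), in_ch, out_ch, 3L, bias = TRUE), s)
    } else {
      cp <- floor(cfg$partial_ratio * in_ch)
      if (op == "pconv") {
        add(ly_pconv(paste0(nm, "_part"), in_ch, cp, 3L), s)
      } else {
        add(ly_pmconv(paste0(nm, "_part"), in_ch, cp, cfg$kernel_set), s)
      }
      add(ly_pw(paste0(nm, "_mix"), in_ch, out_ch), s)
    }
    if (cfg$use_bn) add(ly_bn(paste0(nm, "_bn"), out_ch), s)
    add(ly_relu(paste0(nm, "_relu"), out_ch), s)
    if (i %in% cfg$eca_stages) {
      add(ly_eca(paste0(nm, "_eca"), out_ch, eca_kernel_size(out_ch)), s)
    }
    if (i %in% cfg$pool_after) {
      add(ly_pool(paste0(nm, "_pool"), out_ch), s %/% 2L)
      s <- s %/% 2L
    }
    in_ch <- out_ch
  }
  if (cfg$head == "fc_head") {
    flat <- in_ch * s * s
    add(ly_flatten("head_flatten", flat), 1L)
    widths <- c(cfg$fc_widths, cfg$num_classes)
    in_n <- flat
    for (j in seq_along(widths)) {
      add(ly_fc(sprintf("head_fc%d", j), in_n, widths[j]), 1L)
      if (j < length(widths)) {
        add(ly_relu(sprintf("head_fc%d_relu", j), widths[j]), 1L)
        if (cfg$dropout > 0) {
          add(ly_dropout(sprintf("head_fc%d_drop", j), widths[j], cfg$dropout), 1L)
        }
      }
      in_n <- widths[j]
    }
  } else {
    hs <- head_spec(in_ch, cfg$hidden_width, cfg$num_classes)
    for (ly in head_layers(hs)) add(ly, s)
  }
  layers
}

#' Build a model from a preset name or an architecture configuration
#'
#' @param x a preset name (see [list_presets()]) or an [arch_config()].
#' @param num_classes,input_size overrides when `x` is a preset name.
#' @param materialize logical; if `FALSE` only layer shapes are created
#'   (enough for budget accounting, not for a forward pass).
#' @return an object of class `ppw_model`.
#' @export
build_model <- function(x, num_classes = 6L, input_size = 224L,
                        materialize = TRUE) {
  cfg <- if (inherits(x, "arch_config")) x else
    preset_config(x, num_classes, input_size)
  layers <- config_layers(cfg)
  if (materialize) layers <- lapply(layers, function(ly) {
    if (length(ly$shapes) > 0) materialize_layer(ly) else ly
  })
  structure(list(config = cfg,
                 preset = if (is.character(x)) x else NA_character_,
                 layers = layers,
                 materialized = materialize),
            class = "ppw_model")
}

#' Forward pass through a model
#'
#' @param model a materialised [build_model()] result.
#' @param x rank-4 input array (batch, 3, input_size, input_size).
#' @param training logical; batch-norm batch statistics and dropout are only
#'   active when `TRUE`.
#' @return list with `scores` (batch x num_classes matrix) and `model` (with
#'   updated batch-norm running statistics when training).
#' @export
model_forward <- function(model, x, training = FALSE) {
  if (!model$materialized) abort("model was built with materialize = FALSE")
  stopifnot_4d(x)
  if (dim(x)[2] != 3L) abort("model input must have 3 channels")
  if (!all(dim(x)[3:4] == model$config$input_size)) {
    abort(sprintf("model expects %dx%d inputs", model$config$input_size,
                  model$config$input_size))
  }
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training)
    x <- r$y
    model$layers[[i]] <- r$layer
  }
  list(scores = x, model = model)
}

#' @export
predict.ppw_model <- function(object, newdata, type = c("class", "score", "prob"),
                              ...) {
  type <- match.arg(type)
  scores <- model_forward(object, newdata, training = FALSE)$scores
  if (type == "score") return(scores)
  p <- exp(scores - apply(scores, 1, max))
  p <- p / rowSums(p)
  if (type == "prob") return(p)
  # ties broken towards the lowest class index
  apply(scores, 1, which.max)
}

#' Per-layer summary of a model
#'
#' @param model a `ppw_model` (materialised or not).
#' @return a tibble with layer name, type, output shape, learnable parameter
#'   count and stored value count (parameters plus batch-norm statistics).
#' @export
model_summary <- function(model) {
  purrr::map_dfr(model$layers, function(ly) {
    tibble::tibble(layer = ly$name, type = ly$type,
                   out_channels = ly$out_ch,
                   out_size = ly$spatial,
                   params = n_params_layer(ly),
                   stored = n_stored_layer(ly))
  })
}

#' @export
print.ppw_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ppw_model%s> %d classes, input %dx%d\n",
              if (!is.na(x$preset)) paste0(": ", x$preset) else "",
              cfg$num_classes, cfg$input_size, cfg$input_size))
  cat(sprintf("  stages: %s\n", paste(cfg$channel_plan, collapse = "-")))
  cat(sprintf("  ops: %s | bn: %s | eca: %s | head: %s\n",
              paste(unique(cfg$stage_op), collapse = "/"), cfg$use_bn,
              if (length(cfg$eca_stages)) paste(range(cfg$eca_stages), collapse = "-") else "none",
              cfg$head))
  cat(sprintf("  learnable parameters: %s\n",
              format(sum(vapply(x$layers, n_params_layer, numeric(1))),
                     big.mark = ",")))
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

#' Write / read an architecture configuration as YAML
#'
#' @param cfg an [arch_config()].
#' @param path file path.
#' @return `write_arch_config` returns `path` invisibly; `read_arch_config`
#'   returns an [arch_config()].
#' @export
write_arch_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "arch_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_arch_config
#' @export
read_arch_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(arch_config, raw[setdiff(names(raw), "pool_after")])
}
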