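# Budget accounting: exact learnable-parameter counts by tensor enumeration,
# parameter memory under the fp32 stored-value convention, multiply-accumulate
# (MAC) counts under explicit flags, and the reduction arithmetic used to
# compare family members.
#
# Conventions (documented, deliberate):
#  * learnable values: conv/linear weights and biases, batch-norm affine
#    pairs (2C), attention 1-D kernels;
#  * stored values: learnable plus batch-norm running mean/variance (another
#    2C) -- everything a checkpoint holds;
#  * parameter memory: stored values x 4 bytes / 2^20, TRUNCATED to two
#    decimals (matching the family's published budget table, whose baseline
#    entry is the truncation, not the rounding, of the exact byte count);
#  * reduction percentages: rounded to two decimals.

resolve_model <- function(x, num_classes = 6L, input_size = 224L) {
  if (inherits(x, "ppw_model")) return(x)
  if (inherits(x, "arch_config")) return(build_model(x, materialize = FALSE))
  build_model(x, num_classes, input_size, materialize = FALSE)
}

#' Count learnable parameters and parameter memory
#'
#' Enumerates every tensor of the model (declared shape by declared shape) and
#' reports the learnable total, the stored-value total (adding batch-norm
#' running statistics), the fp32 parameter memory in MiB (truncated to two
#' decimals), and the classifier-head share.
#'
#' @param x a `ppw_model`, an [arch_config()], or a preset name.
#' @param num_classes,input_size used when `x` is a preset name.
#' @return an object of class `model_budget`.
#' @export
count_parameters <- function(x, num_classes = 6L, input_size = 224L) {
  model <- resolve_model(x, num_classes, input_size)
  lb <- layer_budget(model)
  total <- sum(lb$params)
  stored <- sum(lb$stored)
  head <- grepl("^head_", lb$layer)
  structure(list(
    total_params = total,
    stored_values = stored,
    param_memory_mib = trunc2(stored * 4 / 2^20),
    head_params = sum(lb$stored[head]),
    head_learnable = sum(lb$params[head]),
    layers = lb,
    preset = model$preset
  ), class = "model_budget")
}

#' Per-layer parameter budget
#'
#' @inheritParams count_parameters
#' @return a tibble with one row per layer: name, type, learnable `params`,
#'   `stored` values.
#' @export
layer_budget <- function(x, num_classes = 6L, input_size = 224L) {
  model <- resolve_model(x, num_classes, input_size)
  purrr::map_dfr(model$layers, function(ly) {
    tibble::tibble(layer = ly$name, type = ly$type,
                   params = n_params_layer(ly),
                   stored = n_stored_layer(ly))
  })
}

#' Classifier-head share of the parameter budget
#'
#' The head is every layer after the final pooling stage. Reported as a
#' two-decimal percentage of stored values.
#'
#' @inheritParams count_parameters
#' @return numeric percentage.
#' @export
head_fraction <- function(x, num_classes = 6L, input_size = 224L) {
  b <- count_parameters(x, num_classes, input_size)
  if (b$stored_values == 0) abort("model has no parameters; head fraction undefined")
  round(b$head_params / b$stored_values * 100, 2)
}

#' @export
print.model_budget <- function(x, ...) {
  cat(sprintf("<model_budget%s>\n",
              if (!is.na(x$preset %||% NA)) paste0(": ", x$preset) else ""))
  cat(sprintf("  learnable params: %s\n", format(x$total_params, big.mark = ",")))
  cat(sprintf("  stored values:    %s\n", format(x$stored_values, big.mark = ",")))
  cat(sprintf("  parameter memory: %.2f MiB (fp32)\n", x$param_memory_mib))
  cat(sprintf("  head share:       %.2f%%\n",
              round(x$head_params / x$stored_values * 100, 2)))
  invisible(x)
}

# ---- MAC counting ----------------------------------------------------------

#' Default MAC-counting flags
#'
#' `bias`: one add per output element of biased layers; `act`: one op per
#' element through ReLU/sigmoid/attention rescaling; `bn`: one op per
#' normalised element; `pool`: one op per pooled output element (off by
#' default -- pooling is comparison-only).
#'
#' @param bias,act,bn,pool logicals.
#' @return named list of flags.
#' @export
mac_flags <- function(bias = TRUE, act = TRUE, bn = TRUE, pool = FALSE) {
  list(bias = bias, act = act, bn = bn, pool = pool)
}

layer_macs <- function(ly, flags) {
  sp2 <- ly$spatial^2
  switch(ly$type,
    conv = sp2 * ly$out_ch * ly$in_ch * ly$k^2 +
      (if (ly$bias && flags$bias) sp2 * ly$out_ch else 0),
    pconv = sp2 * ly$cp * ly$cp * ly$k^2,
    pmconv = sum(sp2 * ly$groups^2 * ly$kernels^2),
    pw = sp2 * ly$out_ch * ly$in_ch +
      (if (ly$bias && flags$bias) sp2 * ly$out_ch else 0),
    fc = ly$in_ch * ly$out_ch + (if (ly$bias && flags$bias) ly$out_ch else 0),
    bn = if (flags$bn) sp2 * ly$out_ch else 0,
    relu = if (flags$act) sp2 * ly$out_ch else 0,
    eca = ly$out_ch * ly$k + (if (flags$act) ly$out_ch + sp2 * ly$out_ch else 0),
    pool = if (flags$pool) (ly$spatial)^2 * ly$out_ch else 0,
    gap = 0,
    flatten = 0,
    dropout = 0,
    0
  )
}

#' Count multiply-accumulate operations for one forward pass
#'
#' Convolution and linear layers contribute `output_elements x fan_in` MACs;
#' partial and grouped stages only count their convolved subset. Optional
#' flags add bias adds, elementwise activation ops and batch-norm ops;
#' pooling is excluded by default. The counting convention is explicit
#' because published complexity figures rarely name their tool.
#'
#' @inheritParams count_parameters
#' @param flags a [mac_flags()] list.
#' @return an object of class `mac_budget` with `total_macs`, `macs_m`
#'   (millions, two decimals) and a per-layer tibble.
#' @export
count_macs <- function(x, num_classes = 6L, input_size = 224L,
                       flags = mac_flags()) {
  model <- resolve_model(x, num_classes, input_size)
  per <- purrr::map_dfr(model$layers, function(ly) {
    tibble::tibble(layer = ly$name, type = ly$type,
                   out_size = ly$spatial, macs = layer_macs(ly, flags))
  })
  structure(list(total_macs = sum(per$macs),
                 macs_m = round(sum(per$macs) / 1e6, 2),
                 flags = flags, layers = per, preset = model$preset),
            class = "mac_budget")
}

#' @export
print.mac_budget <- function(x, ...) {
  cat(sprintf("<mac_budget%s> %.2f M MACs (flags: %s)\n",
              if (!is.na(x$preset %||% NA)) paste0(": ", x$preset) else "",
              x$macs_m,
              paste(names(Filter(isTRUE, x$flags)), collapse = "+")))
  invisible(x)
}

# ---- reduction arithmetic --------------------------------------------------

#' Relative reduction between a baseline and an improved quantity
#'
#' `(x - x1) / x * 100`, rounded to two decimals: the improvement metric used
#' for inference time, memory and complexity comparisons.
#'
#' @param x baseline quantity (must be positive).
#' @param x1 improved quantity.
#' @return a tibble with columns `x`, `x1`, `reduction_pct`.
#' @export
percent_reduction <- function(x, x1) {
  if (any(x <= 0)) abort("baseline `x` must be positive")
  tibble::tibble(x = x, x1 = x1, reduction_pct = round((x - x1) / x * 100, 2))
}

#' Table-style budget comparison across presets
#'
#' @param presets character vector of preset names.
#' @param num_classes,input_size forwarded to the builder.
#' @param flags a [mac_flags()] list for the complexity column.
#' @return a tibble: preset, learnable params, stored values, memory (MiB),
#'   MACs (millions), head share (percent).
#' @export
budget_table <- function(presets = preset_names(), num_classes = 6L,
                         input_size = 224L, flags = mac_flags()) {
  purrr::map_dfr(presets, function(nm) {
    b <- count_parameters(nm, num_classes, input_size)
    m <- count_macs(nm, num_classes, input_size, flags)
    tibble::tibble(preset = nm,
                   params = b$total_params,
                   stored = b$stored_values,
                   memory_mib = b$param_memory_mib,
                   macs_m = m$macs_m,
                   head_pct = round(b$head_params / b$stored_values * 100, 2))
  })
}
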