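#' Network architecture specification
#'
#' A MobileNetV2-style trunk adapted to 26 x 3 x 1 pseudo-images: a 3 x 3
#' stride-1 same-padding stem, a stack of inverted-residual bottleneck
#' blocks (1 x 1 expansion, depthwise 3 x 3, linear 1 x 1 projection, skip
#' connection when shape-preserving), a 1 x 1 projection to a small final
#' feature width (32 or 64), global average pooling, one hidden dense layer
#' of the final width, dropout, and a 4-way softmax head. Strides of 2 are
#' applied only along the 26-row (temporal) axis so the 3-wide feature axis
#' never collapses. Block widths are scaled to the tiny input; the default
#' keeps the canonical 16 bottleneck blocks.
#'
#' @param input_h,input_w Input rows (time steps) and columns (features).
#' @param stem_filters Filters in the stem convolution (default 32).
#' @param expansion Per-block expansion factor.
#' @param block_channels Integer vector of per-block output widths.
#' @param block_strides Integer vector of per-block row strides (1 or 2).
#' @param final_feature_width 32 or 64.
#' @param width_multiplier Scales stem and block widths (rounded, floor 4).
#' @return A \code{network_spec} list.
#' @export
network_spec <- function(input_h = 26L, input_w = 3L, stem_filters = 32L,
                         expansion = 4L,
                         block_channels = c(16L, 24L, 24L, 32L, 32L, 32L,
                                            48L, 48L, 48L, 48L, 64L, 64L,
                                            64L, 96L, 96L, 96L),
                         block_strides = c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L,
                                           1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
                         final_feature_width = 64L,
                         width_multiplier = 1.0) {
  stopifnot(length(block_channels) == length(block_strides))
  if (!final_feature_width %in% c(32L, 64L)) {
    vp_stop("final_feature_width must be 32 or 64")
  }
  scale_w <- function(c) as.integer(pmax(4, round(c * width_multiplier)))
  structure(list(
    input_h = as.integer(input_h), input_w = as.integer(input_w),
    stem_filters = scale_w(stem_filters), expansion = as.integer(expansion),
    block_channels = scale_w(block_channels),
    block_strides = as.integer(block_strides),
    final_feature_width = as.integer(final_feature_width),
    n_classes = 4L
  ), class = "network_spec")
}

#' Compact architecture for scaled-down experiments
#'
#' A shallower, narrower variant of \code{\link{network_spec}} used for the
#' desk-scale training runs in the examples, tests and evaluation harness.
#'
#' @return A \code{network_spec}.
#' @export
compact_network_spec <- function() {
  network_spec(stem_filters = 12L, expansion = 2L,
               block_channels = c(8L, 16L, 16L, 24L, 24L, 32L),
               block_strides = c(2L, 1L, 2L, 1L, 2L, 1L),
               final_feature_width = 32L)
}

#' Build the stage classifier network
#'
#' @param spec A \code{\link{network_spec}}.
#' @param dropout Dropout probability on the hidden dense layer.
#' @param kernel_size Stem kernel size, 3 or 5.
#' @param seed Integer seed for weight initialization.
#' @return A \code{vp_model}.
#' @export
build_network <- function(spec = network_spec(), dropout = 0.45,
                          kernel_size = 3L, seed = 1L) {
  if (!kernel_size %in% c(3L, 5L)) vp_stop("kernel_size must be 3 or 5")
  if (spec$input_h < 1L || spec$input_w < 1L) vp_stop("bad input shape")
  set.seed(as.integer(seed))
  layers <- list()
  push <- function(L) layers[[length(layers) + 1L]] <<- L

  H <- spec$input_h; W <- spec$input_w
  g_stem <- make_gather(H, W, kernel_size, kernel_size, 1L)
  push(layer_conv(g_stem, 1L, spec$stem_filters))
  push(layer_bn(spec$stem_filters, act = TRUE))
  cin <- spec$stem_filters

  for (bi in seq_along(spec$block_channels)) {
    cout <- spec$block_channels[bi]
    s <- spec$block_strides[bi]
    cmid <- cin * spec$expansion
    resid <- (s == 1L && cin == cout)
    id <- paste0("blk", bi)
    if (resid) push(layer_save(id))
    if (spec$expansion > 1L) {
      push(layer_conv1x1(cin, cmid))
      push(layer_bn(cmid, act = TRUE))
    } else cmid <- cin
    g_dw <- make_gather(H, W, 3L, 3L, s)
    push(layer_dwconv(g_dw, cmid))
    push(layer_bn(cmid, act = TRUE))
    push(layer_conv1x1(cmid, cout))
    push(layer_bn(cout))
    if (resid) push(layer_add(id))
    H <- g_dw$out_h
    cin <- cout
  }

  fw <- spec$final_feature_width
  push(layer_conv1x1(cin, fw))
  push(layer_bn(fw, act = TRUE))
  push(layer_gap(H * W))
  push(layer_dense(fw, fw))
  push(layer_relu6())
  push(layer_dropout(dropout))
  push(layer_dense(fw, spec$n_classes))

  structure(list(layers = layers, spec = spec, dropout = dropout,
                 kernel_size = as.integer(kernel_size)),
            class = "vp_model")
}

#' Number of trainable parameters
#'
#' @param model A \code{vp_model}.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(L) {
    fs <- param_fields(L$type)
    sum(vapply(fs, function(f) length(L[[f]]), numeric(1)))
  }, numeric(1)))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# X: n x (input_h * input_w) matrix of flattened pseudo-images
# (row-major positions); returns n x 4 class probabilities
model_probs <- function(model, X, training = FALSE) {
  B <- nrow(X)
  A <- matrix(as.vector(t(X)), ncol = 1)
  fw <- nn_forward(model, A, B, training = training)
  softmax_rows(fw$out)
}

#' @export
print.vp_model <- function(x, ...) {
  cat("<vp_model>", length(x$layers), "layers,",
      format(n_params(x), big.mark = ","), "parameters; input",
      x$spec$input_h, "x", x$spec$input_w, "x 1\n")
  invisible(x)
}
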