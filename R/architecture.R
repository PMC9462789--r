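# Convolutional architecture specifications with exact trainable-parameter
# accounting. Two built-in architectures over 500 bp one-hot windows:
#
# * conventional_cnn — four layers of 25 width-3 convolutions, each followed
#   by an average pooling layer halving the resolution, then global max
#   pooling and a dense softmax over the classes.
# * deep_mocca — parallel motif convolutions (25 x width 10) and
#   dinucleotide convolutions (25 x width 2) over the one-hot input,
#   concatenated; 10-fold average pooling; a fixed sliding-average
#   convolution of length 50 (constant weights 1/50, non-trainable) that
#   averages motif signal over a bidirectional pairing window; 25 width-1
#   pairing convolutions over the 50 channels; global max pooling; dense
#   softmax. The fixed averaging layer is what lets width-1 convolutions see
#   local motif co-occurrence.

arch_layer <- function(layer, kind, filters = NA, width = NA, in_channels = NA,
                       out_channels = NA, pool = NA, trainable = FALSE) {
  params <- if (!trainable) 0L
    else if (kind == "conv") as.integer(filters * width * in_channels + filters)
    else if (kind == "dense_softmax") as.integer(in_channels * out_channels + out_channels)
    else 0L
  tibble(layer = layer, kind = kind, filters = as.integer(filters),
         width = as.integer(width), in_channels = as.integer(in_channels),
         out_channels = as.integer(out_channels), pool = as.integer(pool),
         trainable = trainable, params = params)
}

#' Build a convolutional architecture specification
#'
#' Returns an ordered layer table (a `crescan_architecture` tibble) for one
#' of the two built-in DNA convolutional architectures. Shapes compose from
#' the 4-channel one-hot input to the softmax over `classes` labels;
#' incompatible overrides fail at construction.
#'
#' @param kind `"deep_mocca"` or `"conventional_cnn"`.
#' @param n_filters Convolutions per (trainable) layer (default 25).
#' @param classes Number of output classes (default 4).
#' @param window Input window length in bp (default 500).
#' @param motif_length Width of the motif convolutions (deep_mocca, default
#'   10).
#' @param pairing_window Width of the fixed averaging convolution in pooled
#'   units (deep_mocca, default 50, i.e. 500 bp at 10-fold pooling).
#' @param conv_width Convolution width (conventional_cnn, default 3).
#' @param n_layers Number of conv+pool blocks (conventional_cnn, default 4).
#' @return A `crescan_architecture` tibble with one row per layer and a
#'   `params` column; attributes `window` and `classes`.
#' @export
build_architecture <- function(kind = c("deep_mocca", "conventional_cnn"),
                               n_filters = 25, classes = 4, window = 500,
                               motif_length = 10, pairing_window = 50,
                               conv_width = 3, n_layers = 4) {
  kind <- match.arg(kind)
  stopifnot(n_filters >= 1, classes >= 2, window >= 1)
  if (kind == "deep_mocca") {
    if (window %% 10 != 0) abort("deep_mocca window must be divisible by the 10x pool")
    layers <- dplyr::bind_rows(
      arch_layer("motif_conv", "conv", filters = n_filters,
                 width = motif_length, in_channels = 4,
                 out_channels = n_filters, trainable = TRUE),
      arch_layer("dinucleotide_conv", "conv", filters = n_filters, width = 2,
                 in_channels = 4, out_channels = n_filters, trainable = TRUE),
      arch_layer("concat", "concat", out_channels = 2 * n_filters),
      arch_layer("downscale", "avg_pool", pool = 10,
                 out_channels = 2 * n_filters),
      arch_layer("pairing_average", "fixed_avg_conv", width = pairing_window,
                 in_channels = 2 * n_filters, out_channels = 2 * n_filters),
      arch_layer("pairing_conv", "conv", filters = n_filters, width = 1,
                 in_channels = 2 * n_filters, out_channels = n_filters,
                 trainable = TRUE),
      arch_layer("global_max", "global_max_pool", out_channels = n_filters),
      arch_layer("softmax", "dense_softmax", in_channels = n_filters,
                 out_channels = classes, trainable = TRUE))
  } else {
    stopifnot(n_layers >= 1, conv_width >= 1)
    blocks <- purrr::map(seq_len(n_layers), function(i) {
      dplyr::bind_rows(
        arch_layer(sprintf("conv_%d", i), "conv", filters = n_filters,
                   width = conv_width,
                   in_channels = if (i == 1) 4 else n_filters,
                   out_channels = n_filters, trainable = TRUE),
        arch_layer(sprintf("pool_%d", i), "avg_pool", pool = 2,
                   out_channels = n_filters))
    })
    layers <- dplyr::bind_rows(
      dplyr::bind_rows(blocks),
      arch_layer("global_max", "global_max_pool", out_channels = n_filters),
      arch_layer("softmax", "dense_softmax", in_channels = n_filters,
                 out_channels = classes, trainable = TRUE))
  }
  # shape check: channel counts must compose layer to layer
  ch <- 4
  for (i in seq_len(nrow(layers))) {
    k <- layers$kind[i]
    if (k %in% c("conv", "fixed_avg_conv", "dense_softmax")) {
      if (!is.na(layers$in_channels[i]) && k != "conv" &&
          layers$in_channels[i] != ch) {
        abort(sprintf("layer '%s' expects %d channels, gets %d",
                      layers$layer[i], layers$in_channels[i], ch))
      }
      if (k == "conv" && !layers$layer[i] %in% c("motif_conv", "dinucleotide_conv") &&
          layers$in_channels[i] != ch) {
        abort(sprintf("layer '%s' expects %d channels, gets %d",
                      layers$layer[i], layers$in_channels[i], ch))
      }
    }
    if (k == "concat") ch <- layers$out_channels[i]
    else if (!is.na(layers$out_channels[i])) ch <- layers$out_channels[i]
  }
  structure(layers, class = c("crescan_architecture", class(layers)),
            window = as.integer(window), classes = as.integer(classes))
}

#' Count the trainable parameters of an architecture
#'
#' Sums, over trainable layers only, `filters x width x in_channels +
#' filters` for convolutions and `in x out + out` for the dense layer; fixed
#' layers (the sliding-average convolution) contribute nothing.
#'
#' @param spec A `crescan_architecture`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(spec) {
  stopifnot(inherits(spec, "crescan_architecture"))
  sum(spec$params[spec$trainable])
}
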