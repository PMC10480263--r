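#' Generator architecture specification
#'
#' Describes the encoder-decoder generator: an 8-stage (by default)
#' strided-convolution encoder and a mirrored transposed-convolution
#' decoder with skip connections. Every decoder stage ends in a depth
#' concatenation with the encoder activation at the same resolution; the
#' outermost stage concatenates the network input itself. Dropout sits in
#' the first four decoder stages. At the clinical scale (512 px input,
#' 64 base filters, depth 8) the flattened layer listing has exactly 61
#' entries; reduced depths keep the same pattern for desk-scale runs.
#'
#' @param input_size square input size in px.
#' @param base_filters filters in the first encoder stage (doubled per
#'   stage, capped at 8x).
#' @param encoder_depth number of 2x down-sampling stages; the bottleneck
#'   spatial size `input_size / 2^encoder_depth` must be a whole number
#'   >= 1 (>= 2 recommended so the bottleneck normalisation keeps a
#'   usable gradient).
#' @param dropout_positions decoder stages (1 = innermost) that carry
#'   dropout; default the first four.
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param dropout_rate dropout probability.
#' @param output_activation `"tanh"` (matches the `[-1, 1]` intensity
#'   normalisation) or `"linear"`.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 512, base_filters = 64,
                           encoder_depth = 8, dropout_positions = 1:4,
                           leaky_slope = 0.2, dropout_rate = 0.5,
                           output_activation = c("tanh", "linear")) {
  output_activation <- match.arg(output_activation)
  bottleneck <- input_size / 2^encoder_depth
  if (bottleneck < 1 || bottleneck != floor(bottleneck))
    stop("bottleneck spatial size input_size / 2^encoder_depth must be a ",
         "whole number >= 1 (got ", bottleneck, ")")
  dropout_positions <- intersect(dropout_positions, seq_len(encoder_depth))
  structure(
    list(input_size = as.integer(input_size),
         base_filters = as.integer(base_filters),
         encoder_depth = as.integer(encoder_depth),
         dropout_positions = as.integer(dropout_positions),
         leaky_slope = leaky_slope, dropout_rate = dropout_rate,
         output_activation = output_activation),
    class = "generator_spec"
  )
}

#' Desk-scale generator specification
#'
#' Convenience profile for CPU-scale experiments: small inputs, 16 base
#' filters, and the encoder depth reduced so the bottleneck stays at
#' 2 x 2 px.
#'
#' @param input_size square input size in px (power of two, >= 16).
#' @param base_filters filters in the first encoder stage.
#' @export
desk_generator_spec <- function(input_size = 64, base_filters = 16) {
  depth <- as.integer(log2(input_size)) - 1L
  generator_spec(input_size = input_size, base_filters = base_filters,
                 encoder_depth = depth)
}

#' Build the conditional-adversarial generator
#'
#' Constructs the U-shaped generator as an explicit flattened layer
#' sequence: image input; encoder stages of convolution (4x4, stride 2),
#' batch normalisation (from stage 2) and leaky ReLU; decoder stages of
#' transposed convolution (4x4, stride 2), batch normalisation, dropout
#' (first four stages), leaky ReLU and depth concatenation with the
#' mirrored encoder activation; and a final 3x3 convolution to one
#' channel. Weight initialisation is N(0, 0.02), deterministic per seed.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for weight initialisation.
#' @return a network object (class `cbct_net`).
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  set.seed(derive_seed(seed, "init", 1L))
  d <- spec$encoder_depth
  f <- spec$base_filters
  enc_out <- pmin(f * 2^(seq_len(d) - 1), 8 * f)
  layers <- list(layer_input())
  skip_src <- integer(d)  # skip_src[i]: layer index of encoder stage i output
  cin <- 1L
  for (i in seq_len(d)) {
    layers <- c(layers, list(layer_conv(cin, enc_out[i])))
    if (i > 1) layers <- c(layers, list(layer_batchnorm(enc_out[i])))
    layers <- c(layers, list(layer_lrelu(spec$leaky_slope)))
    skip_src[i] <- length(layers)
    cin <- enc_out[i]
  }
  dec_out <- c(rev(enc_out)[-1], f)  # stage j output channels
  cur <- enc_out[d]
  for (j in seq_len(d)) {
    layers <- c(layers, list(layer_tconv(cur, dec_out[j]),
                             layer_batchnorm(dec_out[j])))
    if (j %in% spec$dropout_positions)
      layers <- c(layers, list(layer_dropout(spec$dropout_rate)))
    layers <- c(layers, list(layer_lrelu(spec$leaky_slope)))
    src <- if (j < d) skip_src[d - j] else 1L  # outermost: the input image
    layers <- c(layers, list(layer_concat(src)))
    skip_ch <- if (j < d) enc_out[d - j] else 1L
    cur <- dec_out[j] + skip_ch
  }
  layers <- c(layers, list(layer_conv(cur, 1L, k = 3, stride = 1, pad = 1)))
  new_net(layers, kind = "generator", spec = spec)
}

#' Flattened generator layer listing
#'
#' @param model a generator network or `pix2pix` model.
#' @return character vector of layer kind names in order (e.g.
#'   `"Image Input Layer"`, `"Convolution 2D Layer"`, ...).
#' @export
generator_layer_kinds <- function(model) {
  net <- if (inherits(model, "pix2pix")) model$generator else model
  kind_names <- c(image_input = "Image Input Layer",
                  conv = "Convolution 2D Layer",
                  batchnorm = "Batch Normalization Layer",
                  leaky_relu = "Leaky ReLU Layer",
                  dropout = "Dropout Layer",
                  transposed_conv = "Transposed Convolution 2D Layer",
                  depth_concat = "Depth Concatenation Layer")
  unname(kind_names[vapply(net$layers, `[[`, "", "kind")])
}

#' Build the patch discriminator
#'
#' Conditional patch-level discriminator consuming the channel-wise
#' concatenation of the conditioning image and a candidate image:
#' 4x4 convolutions of stride 2, 2, 2, 1, 1 with batch normalisation and
#' leaky ReLU between, producing a grid of realness logits whose
#' receptive field is 70 px per output unit.
#'
#' @param input_size square input size in px.
#' @param base_filters filters in the first stage.
#' @param in_channels input channels (2: condition + candidate).
#' @param seed integer seed for weight initialisation.
#' @return a network object (class `cbct_net`).
#' @export
build_discriminator <- function(input_size = 512, base_filters = 64,
                                in_channels = 2L, seed = 1L) {
  set.seed(derive_seed(seed, "init", 2L))
  f <- base_filters
  layers <- list(
    layer_input(),
    layer_conv(in_channels, f), layer_lrelu(0.2),
    layer_conv(f, 2 * f), layer_batchnorm(2 * f), layer_lrelu(0.2),
    layer_conv(2 * f, 4 * f), layer_batchnorm(4 * f), layer_lrelu(0.2),
    layer_conv(4 * f, 8 * f, stride = 1), layer_batchnorm(8 * f),
    layer_lrelu(0.2),
    layer_conv(8 * f, 1L, stride = 1)
  )
  new_net(layers, kind = "discriminator",
          spec = list(input_size = input_size, base_filters = base_filters))
}

#' Analytic receptive field of a network's output units
#'
#' Walks the convolutional layers backwards accumulating
#' `rf <- rf * stride + (kernel - stride)`.
#'
#' @param net a `cbct_net`.
#' @return receptive field in px.
#' @export
receptive_field <- function(net) {
  rf <- 1
  convs <- Filter(function(ly) ly$kind %in% c("conv", "transposed_conv"),
                  net$layers)
  for (ly in rev(convs)) {
    k <- dim(ly$w)[1]
    rf <- rf * ly$stride + (k - ly$stride)
  }
  rf
}

#' Map Hounsfield units to the network's unit scale (and back)
#'
#' Affine map of the full HU span `[-1024, 3071]` onto `[-1, 1]`.
#' Field-of-view-exterior pixels stored as 0 map through the same affine
#' (to about -0.5); the network sees them as a distinct flat level.
#'
#' @param img numeric matrix or array.
#' @return matrix/array on the target scale.
#' @export
normalize_hu <- function(img) (img - hu_min) / ((hu_max - hu_min) / 2) - 1

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(img) (img + 1) * ((hu_max - hu_min) / 2) + hu_min
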