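# Model specifications and builders for the three network cores.

#' Convolutional feature-extractor specification
#'
#' Two convolutional layers with 1-D vertical kernels (each followed by
#' dropout) and one max-pooling layer. The kernel counts default to the
#' 32-channel preset (32 and 64); the 62-channel preset uses (8, 16).
#'
#' @param kernels_per_layer integer vector of length 2.
#' @param kernel_len kernel length `i` of the `(i x 1)` kernels (default 3);
#'   must be smaller than the input height.
#' @param pool pooling window (default `c(3, 3)`).
#' @param dropout_rate dropout after each conv layer (default 0.25).
#' @param activation `"relu"` (default) or `"softplus"`.
#' @return object of class `conv_spec`.
#' @export
conv_spec <- function(kernels_per_layer = c(32, 64), kernel_len = 3,
                      pool = c(3, 3), dropout_rate = 0.25,
                      activation = c("relu", "softplus")) {
  activation <- match.arg(activation)
  if (length(kernels_per_layer) != 2) stopf("exactly two conv layers are configured")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  structure(list(kernels_per_layer = as.integer(kernels_per_layer),
                 kernel_len = as.integer(kernel_len), pool = as.integer(pool),
                 dropout_rate = dropout_rate, activation = activation),
            class = "conv_spec")
}

#' Sparse-autoencoder specification
#'
#' Encoder `input -> encode_units -> hidden_units`, decoder
#' `hidden_units -> decode_units -> input` with a sigmoid reconstruction
#' layer scored by binary crossentropy, plus the Bernoulli-KL sparsity
#' penalty on the hidden layer's mean activation.
#'
#' @param encode_units,hidden_units,decode_units layer sizes
#'   (defaults 512, 128, 512).
#' @param rho target sparsity level in (0, 1) (default 0.05).
#' @param beta sparsity-penalty weight `>= 0` (default 3).
#' @param activation hidden activation (default `"relu"`).
#' @return object of class `sae_spec`.
#' @export
sae_spec <- function(encode_units = 512, hidden_units = 128,
                     decode_units = 512, rho = 0.05, beta = 3,
                     activation = c("relu", "softplus")) {
  activation <- match.arg(activation)
  if (rho <= 0 || rho >= 1) stopf("rho must be strictly inside (0, 1)")
  if (beta < 0) stopf("beta must be >= 0")
  structure(list(encode_units = as.integer(encode_units),
                 hidden_units = as.integer(hidden_units),
                 decode_units = as.integer(decode_units),
                 rho = rho, beta = beta, activation = activation),
            class = "sae_spec")
}

#' Classifier-head specification
#'
#' Fully connected layers ending in `n_out` output units: 2 sigmoid units
#' with one-hot targets under binary crossentropy for the binary task, or a
#' 3-unit softmax under categorical crossentropy. A single sigmoid unit
#' (`n_out = 1`, 0/1 targets) is available as the documented alternative
#' binary head.
#'
#' @param layer_units hidden layer sizes (default `c(512, 256)`).
#' @param n_out 1, 2 or 3 output units.
#' @param activation hidden activation (default `"relu"`).
#' @return object of class `dnn_spec`.
#' @export
dnn_spec <- function(layer_units = c(512, 256), n_out = 2,
                     activation = c("relu", "softplus")) {
  activation <- match.arg(activation)
  if (!n_out %in% 1:3) stopf("n_out must be 1, 2 or 3")
  structure(list(layer_units = as.integer(layer_units), n_out = as.integer(n_out),
                 output_activation = if (n_out == 3) "softmax" else "sigmoid",
                 loss = if (n_out == 3) "categorical_ce" else "binary_ce",
                 activation = activation),
            class = "dnn_spec")
}

# conv trunk shared by the extractor and the baseline
conv_trunk_layers <- function(cs) {
  list(
    layer_conv(cs$kernels_per_layer[1], cs$kernel_len, cs$activation),
    layer_dropout(cs$dropout_rate),
    layer_conv(cs$kernels_per_layer[2], cs$kernel_len, cs$activation),
    layer_dropout(cs$dropout_rate),
    layer_maxpool(cs$pool),
    layer_flatten()
  )
}

build_extractor_with_head <- function(input_shape, cs, ds, seed) {
  layers <- c(conv_trunk_layers(cs),
              list(layer_dense(ds$n_out, ds$output_activation)))
  net_init(layers, input_shape, seed)
}

drop_head <- function(net) {
  n <- length(net$layers)
  flat_dim <- nrow(net$params[[n]]$W)  # trunk output dim, seen by the head
  net$layers <- net$layers[-n]
  net$params <- net$params[-n]
  net$output_shape <- flat_dim
  net
}

build_sae <- function(input_dim, ss, seed) {
  layers <- list(
    layer_dense(ss$encode_units, ss$activation),
    layer_dense(ss$hidden_units, ss$activation),
    layer_dense(ss$decode_units, ss$activation),
    layer_dense(input_dim, "sigmoid")
  )
  net_init(layers, input_dim, seed)
}

build_dnn <- function(input_dim, ds, seed) {
  layers <- c(
    lapply(ds$layer_units, function(u) layer_dense(u, ds$activation)),
    list(layer_dense(ds$n_out, ds$output_activation))
  )
  net_init(layers, input_dim, seed)
}

build_baseline <- function(input_shape, cs, ds, seed) {
  layers <- c(conv_trunk_layers(cs),
              lapply(ds$layer_units, function(u) layer_dense(u, ds$activation)),
              list(layer_dense(ds$n_out, ds$output_activation)))
  net_init(layers, input_shape, seed)
}

#' Encode features with a trained autoencoder
#'
#' Applies the encoder half (input -> encode -> hidden) and returns the
#' hidden-layer representation.
#'
#' @param sae a trained autoencoder (from [train_sae_stage()]).
#' @param x matrix `samples x input_dim`, scaled to `[0, 1]`.
#' @return matrix `samples x hidden_units`.
#' @export
encode <- function(sae, x) {
  net <- if (inherits(sae, "eegsae_net")) sae else sae$net
  half <- net
  half$layers <- net$layers[1:2]
  half$params <- net$params[1:2]
  net_forward(half, x, train = FALSE)$out
}

#' Decode a hidden representation
#'
#' Applies the decoder half and returns both the 512-unit export features
#' (the penultimate layer, which feeds the classifier head) and the
#' sigmoid reconstruction (same dimension as the autoencoder input).
#'
#' @param sae a trained autoencoder.
#' @param h matrix `samples x hidden_units`.
#' @return list with `features` (`samples x decode_units`) and
#'   `reconstruction` (`samples x input_dim`).
#' @export
decode <- function(sae, h) {
  net <- if (inherits(sae, "eegsae_net")) sae else sae$net
  half <- net
  half$layers <- net$layers[3:4]
  half$params <- net$params[3:4]
  fwd <- net_forward(half, h, train = FALSE)
  list(features = fwd$caches[[1]]$a, reconstruction = fwd$out)
}
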