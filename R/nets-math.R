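# Mathematical primitives of the network cores: activations, losses, and the
# Bernoulli-KL sparsity penalty. All are pure functions; the layer framework
# in nets-layers.R composes them.

#' Elementwise activation functions
#'
#' `relu` is the rectifier `max(0, x)`. `softplus` is its smooth variant
#' `ln(1 + e^x)`, computed stably for large `|x|`. `sigmoid` is the logistic
#' function. Softplus is provided because some descriptions of the rectifier
#' print the softplus formula under the ReLU name; both are selectable
#' wherever an activation is configured.
#'
#' @param x numeric vector/array.
#' @param kind one of `"relu"`, `"softplus"`, `"sigmoid"`, `"linear"`.
#' @return array of the same shape.
#' @export
activation <- function(x, kind = c("relu", "softplus", "sigmoid", "linear")) {
  kind <- match.arg(kind)
  switch(kind,
    relu = pmax(x, 0),
    softplus = ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
    sigmoid = 1 / (1 + exp(-x)),
    linear = x
  )
}

# derivative of the activation wrt its preactivation z (a = activation(z))
activation_grad <- function(z, a, kind) {
  switch(kind,
    relu = (z > 0) * 1,
    softplus = 1 / (1 + exp(-z)),
    sigmoid = a * (1 - a),
    linear = array(1, dim = dim(z) %||% length(z)),
    stopf("no elementwise gradient for activation '%s'", kind)
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary crossentropy loss
#'
#' Mean over samples and output units of
#' `-(y log(yhat) + (1 - y) log(1 - yhat))`. Predicted probabilities are
#' clipped to `(eps, 1 - eps)` before the logs. With a multi-unit sigmoid
#' output layer and one-hot targets this is the training loss of the binary
#' classification head and of the autoencoder's reconstruction.
#'
#' @param y targets in `[0, 1]` (vector or matrix).
#' @param yhat predicted probabilities, same shape as `y`.
#' @param eps clipping constant (default `1e-7`).
#' @return nonnegative scalar.
#' @export
binary_crossentropy <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) stopf("y and yhat shapes differ")
  p <- clip_prob(yhat, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Categorical crossentropy loss
#'
#' Mean over samples of `-sum_c y_c log(yhat_c)` for one-hot targets and
#' softmax-output rows. Rows of `yhat` must sum to 1 within `tol`.
#'
#' @param y one-hot target matrix `samples x classes`.
#' @param yhat predicted probability matrix, rows on the simplex.
#' @param eps clipping constant.
#' @param tol allowed deviation of row sums from 1.
#' @return nonnegative scalar.
#' @export
categorical_crossentropy <- function(y, yhat, eps = 1e-7, tol = 1e-5) {
  if (!all(dim(y) == dim(yhat))) stopf("y and yhat shapes differ")
  if (any(abs(rowSums(yhat) - 1) > tol)) {
    stopf("yhat rows must sum to 1 (max deviation %g)", max(abs(rowSums(yhat) - 1)))
  }
  p <- clip_prob(yhat, eps)
  -mean(rowSums(y * log(p)))
}

# gradient of the loss wrt the output layer's preactivation, for the
# canonical pairings sigmoid+binary_ce and softmax+categorical_ce
loss_delta <- function(kind, y, a) {
  n <- nrow(a) %||% length(a)
  switch(kind,
    binary_ce = (a - y) / (n * (ncol(a) %||% 1)),
    categorical_ce = (a - y) / n,
    stopf("unknown loss '%s'", kind)
  )
}

#' Mean hidden activation per unit
#'
#' The observed sparsity level: per-unit mean of the hidden-layer
#' activations over a batch, clipped into `(eps, 1 - eps)` so the
#' Kullback-Leibler penalty stays finite.
#'
#' @param h activation matrix `samples x units` (a vector is one unit's
#'   activations).
#' @param eps clipping constant.
#' @return numeric vector, one mean per unit.
#' @export
mean_activation <- function(h, eps = 1e-7) {
  if (is.vector(h)) h <- matrix(h, ncol = 1)
  if (nrow(h) < 1) stopf("empty batch")
  clip_prob(colMeans(h), eps)
}

#' Bernoulli Kullback-Leibler divergence
#'
#' `KL(rho || rho_hat) = rho log(rho/rho_hat) +
#' (1 - rho) log((1 - rho)/(1 - rho_hat))`: the divergence between a target
#' sparsity level and the observed mean activation, nonnegative and zero iff
#' they agree. Vectorized over `rho_hat`.
#'
#' @param rho target sparsity level in (0, 1).
#' @param rho_hat observed mean activation(s) in (0, 1).
#' @return nonnegative divergence, same length as `rho_hat`.
#' @export
kl_bernoulli <- function(rho, rho_hat) {
  if (any(rho <= 0 | rho >= 1) || any(rho_hat <= 0 | rho_hat >= 1)) {
    stopf("rho and rho_hat must lie strictly inside (0, 1)")
  }
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

#' Sparse-autoencoder cost
#'
#' Total cost `J + beta * sum_j KL(rho || rho_hat_j)`: reconstruction loss
#' plus the weighted sparsity penalty summed over hidden units. `beta = 0`
#' recovers the plain autoencoder cost.
#'
#' @param J reconstruction loss (scalar).
#' @param rho_hat per-unit mean activations.
#' @param rho target sparsity level.
#' @param beta penalty weight, `>= 0`.
#' @return scalar cost.
#' @export
sparse_cost <- function(J, rho_hat, rho, beta) {
  if (beta < 0) stopf("beta must be >= 0")
  J + beta * sum(kl_bernoulli(rho, rho_hat))
}
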