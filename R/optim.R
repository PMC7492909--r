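# First-order optimizers over the nested parameter lists of a net.
# State is kept per parameter array and updated functionally.

#' Construct an optimizer
#'
#' `adadelta` follows the accumulator form with a learning-rate multiplier
#' (decay `rho`, numerical floor `eps`); it is the default optimizer of the
#' binary classification and autoencoder stages. `adam` (bias-corrected
#' first/second moments) is used for the 3-class head. Plain `sgd` is kept
#' for tests.
#'
#' @param kind `"adadelta"`, `"adam"` or `"sgd"`.
#' @param lr learning rate (the stage configs default to 0.01).
#' @param rho adadelta accumulator decay.
#' @param eps numerical stabilizer.
#' @param beta1,beta2 adam moment decays.
#' @return optimizer object.
#' @export
optimizer <- function(kind = c("adadelta", "adam", "sgd"), lr = 0.01,
                      rho = 0.95, eps = 1e-6, beta1 = 0.9, beta2 = 0.999) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, rho = rho, eps = eps,
                 beta1 = beta1, beta2 = beta2, t = 0L, state = NULL),
            class = "eegsae_optimizer")
}

opt_leaf_update <- function(opt, s, p, g) {
  if (opt$kind == "sgd") {
    return(list(p = p - opt$lr * g, s = s))
  }
  if (opt$kind == "adadelta") {
    if (is.null(s)) s <- list(Eg = p * 0, Edx = p * 0)
    s$Eg <- opt$rho * s$Eg + (1 - opt$rho) * g^2
    dx <- -sqrt(s$Edx + opt$eps) / sqrt(s$Eg + opt$eps) * g
    s$Edx <- opt$rho * s$Edx + (1 - opt$rho) * dx^2
    return(list(p = p + opt$lr * dx, s = s))
  }
  # adam
  if (is.null(s)) s <- list(m = p * 0, v = p * 0)
  s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
  s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
  mhat <- s$m / (1 - opt$beta1^opt$t)
  vhat <- s$v / (1 - opt$beta2^opt$t)
  list(p = p - opt$lr * mhat / (sqrt(vhat) + opt$eps), s = s)
}

# one update step; params/grads are the per-layer lists of a net
opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  if (is.null(opt$state)) opt$state <- vector("list", length(params))
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    if (is.null(opt$state[[i]])) opt$state[[i]] <- list(W = NULL, b = NULL)
    for (nm in c("W", "b")) {
      r <- opt_leaf_update(opt, opt$state[[i]][[nm]], params[[i]][[nm]], grads[[i]][[nm]])
      params[[i]][[nm]] <- r$p
      opt$state[[i]][[nm]] <- r$s
    }
  }
  list(opt = opt, params = params)
}
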