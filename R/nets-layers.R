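# Minimal layer framework: valid 1-D convolution (im2col + BLAS), max
# pooling, dropout, flatten, dense layers, with exact backprop. Forward
# passes are pure functions of (params, input); dropout is the only layer
# that consumes RNG, and only with train = TRUE.

layer_conv <- function(kernels, kernel_len = 3, activation = "relu") {
  list(type = "conv", kernels = kernels, klen = kernel_len, activation = activation)
}
layer_maxpool <- function(pool = c(3, 3)) list(type = "maxpool", pool = pool)
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(units, activation = "relu") {
  list(type = "dense", units = units, activation = activation)
}

glorot_uniform <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# input_shape: c(channels, H, W) for conv nets, scalar D for dense nets
net_init <- function(layers, input_shape, seed = 1L) {
  with_seed(seed, {
    shape <- input_shape
    params <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type == "conv") {
        if (length(shape) != 3) stopf("conv layer %d needs a (channels, H, W) input", i)
        if (ly$klen > shape[2]) {
          stopf("kernel length %d exceeds input height %d", ly$klen, shape[2])
        }
        din <- shape[1] * ly$klen
        params[[i]] <- list(
          W = glorot_uniform(din, ly$kernels, din, ly$kernels),
          b = rep(0, ly$kernels)
        )
        shape <- c(ly$kernels, shape[2] - ly$klen + 1, shape[3])
      } else if (ly$type == "maxpool") {
        if (shape[2] < ly$pool[1] || shape[3] < ly$pool[2]) {
          stopf("pooling window %dx%d exceeds map size %dx%d",
                ly$pool[1], ly$pool[2], shape[2], shape[3])
        }
        shape <- c(shape[1], shape[2] %/% ly$pool[1], shape[3] %/% ly$pool[2])
      } else if (ly$type == "flatten") {
        shape <- prod(shape)
      } else if (ly$type == "dense") {
        if (length(shape) != 1) stopf("dense layer %d needs flat input", i)
        params[[i]] <- list(
          W = glorot_uniform(shape, ly$units, shape, ly$units),
          b = rep(0, ly$units)
        )
        shape <- ly$units
      }
      # dropout leaves shape and params untouched
    }
    structure(list(layers = layers, params = params,
                   input_shape = input_shape, output_shape = shape),
              class = "eegsae_net")
  })
}

# ---- conv helpers ----------------------------------------------------------
# Patch extraction / layout conversion / pooling run in C++ (src/conv_ops.cpp);
# the matrix products use R's BLAS.

conv_fwd_batch <- function(x, W, b, act) {
  d <- dim(x)
  klen <- nrow(W) / d[2]
  h_out <- d[3] - klen + 1
  if (h_out < 1) stopf("kernel length %d exceeds input height %d", klen, d[3])
  P <- cpp_im2col(x, klen)
  Z <- P %*% W
  if (act == "relu") {
    # fused bias + relu; backward recovers the mask from a > 0, so z is
    # not stored (halves the cache for the large conv maps)
    a <- cpp_mat_to_maps(cpp_bias_relu(Z, b), d[1], h_out, d[4])
    return(list(z = NULL, a = a, P = P, in_dim = d))
  }
  Z <- Z + rep(b, each = nrow(Z))
  maps <- cpp_mat_to_maps(Z, d[1], h_out, d[4])
  list(z = maps, a = activation(maps, act), P = P, in_dim = d)
}

conv_bwd_batch <- function(cache, W, dz) {
  # dz: gradient wrt preactivation, [N, K, H_out, W]
  dzm <- cpp_maps_to_mat(dz)
  dW <- crossprod(cache$P, dzm)
  db <- colSums(dzm)
  dP <- dzm %*% t(W)
  klen <- nrow(W) / cache$in_dim[2]
  dx <- cpp_col2im(dP, as.integer(cache$in_dim), klen)
  list(dW = dW, db = db, dx = dx)
}

pool_fwd_batch <- function(x, pool) {
  d <- dim(x)
  if (d[3] < pool[1] || d[4] < pool[2]) {
    stopf("map %dx%d smaller than pooling window %dx%d", d[3], d[4], pool[1], pool[2])
  }
  r <- cpp_pool_fwd(x, pool[1], pool[2])
  list(a = r$a, argmax = r$argmax, in_dim = d, pool = pool)
}

pool_bwd_batch <- function(cache, da) {
  cpp_pool_bwd(da, cache$argmax, as.integer(cache$in_dim))
}

# ---- whole-net forward / backward -----------------------------------------

net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    p <- net$params[[i]]
    if (ly$type == "conv") {
      cc <- conv_fwd_batch(a, p$W, p$b, ly$activation)
      caches[[i]] <- cc
      a <- cc$a
    } else if (ly$type == "maxpool") {
      cc <- pool_fwd_batch(a, ly$pool)
      caches[[i]] <- cc
      a <- cc$a
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        dp <- cpp_dropout(a, ly$rate)
        caches[[i]] <- list(mask = dp$mask)
        a <- dp$a
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(in_dim = dim(a))
      dim(a) <- c(dim(a)[1], prod(dim(a)[-1]))
    } else if (ly$type == "dense") {
      z <- sweep(a %*% p$W, 2, p$b, `+`)
      aa <- if (ly$activation == "softmax") softmax_rows(z) else activation(z, ly$activation)
      caches[[i]] <- list(a_prev = a, z = z, a = aa)
      a <- aa
    }
  }
  list(out = a, caches = caches)
}

# cache-free forward pass in chunks of samples; bounds peak memory when
# evaluating on a full sample set (the im2col patch matrix scales with N)
net_predict <- function(net, x, chunk = 128L) {
  is4d <- length(dim(x)) == 4
  n <- if (is4d) dim(x)[1] else nrow(x)
  if (n <= chunk) return(net_forward(net, x, train = FALSE)$out)
  parts <- lapply(split(seq_len(n), ceiling(seq_len(n) / chunk)), function(i) {
    xi <- if (is4d) x[i, , , , drop = FALSE] else x[i, , drop = FALSE]
    net_forward(net, xi, train = FALSE)$out
  })
  do.call(rbind, parts)
}

# delta_last: gradient of the loss wrt the LAST layer's preactivation
# (the canonical sigmoid+BCE / softmax+CCE shortcut). extra_da: optional
# named list mapping layer index -> gradient added to that layer's
# activation output (used for the sparsity penalty on the SAE hidden layer).
net_backward <- function(net, caches, delta_last, extra_da = NULL) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  cur <- NULL          # gradient wrt current layer's activation output
  dz <- delta_last     # at the last (dense) layer, wrt preactivation
  for (i in rev(seq_len(nl))) {
    ly <- net$layers[[i]]
    cc <- caches[[i]]
    if (i < nl) {
      dz <- NULL
      if (!is.null(extra_da) && !is.null(extra_da[[as.character(i)]])) {
        cur <- cur + extra_da[[as.character(i)]]
      }
    }
    if (ly$type == "dense") {
      if (is.null(dz)) {
        dz <- cur * activation_grad(cc$z, cc$a, ly$activation)
      }
      grads[[i]] <- list(W = crossprod(cc$a_prev, dz), b = colSums(dz))
      cur <- dz %*% t(net$params[[i]]$W)
    } else if (ly$type == "flatten") {
      dim(cur) <- cc$in_dim
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) cur <- cpp_mul(cur, cc$mask)
    } else if (ly$type == "maxpool") {
      cur <- pool_bwd_batch(cc, cur)
    } else if (ly$type == "conv") {
      dzc <- if (ly$activation == "relu") {
        cpp_relu_bwd(cur, cc$a)
      } else {
        cur * activation_grad(cc$z, cc$a, ly$activation)
      }
      bw <- conv_bwd_batch(cc, net$params[[i]]$W, dzc)
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      cur <- bw$dx
    }
  }
  grads
}

# flatten all trainable parameters to a single vector (for gradient checks)
net_get_params <- function(net) {
  unlist(lapply(net$params, function(p) {
    if (is.null(p)) NULL else c(as.vector(p$W), p$b)
  }))
}

net_set_params <- function(net, theta) {
  k <- 0L
  for (i in seq_along(net$params)) {
    p <- net$params[[i]]
    if (is.null(p)) next
    nw <- length(p$W)
    net$params[[i]]$W <- array(theta[(k + 1):(k + nw)], dim = dim(p$W))
    k <- k + nw
    nb <- length(p$b)
    net$params[[i]]$b <- theta[(k + 1):(k + nb)]
    k <- k + nb
  }
  net
}

grads_to_vector <- function(net, grads) {
  unlist(lapply(seq_along(grads), function(i) {
    g <- grads[[i]]
    if (is.null(g)) NULL else c(as.vector(g$W), g$b)
  }))
}

#' Number of trainable parameters of a model
#'
#' @param net a network as returned by the stage-training functions (or an
#'   internal model object).
#' @return integer parameter count (weights plus biases).
#' @export
count_params <- function(net) length(net_get_params(net))

# ---- exported functional wrappers (single image/map) -----------------------

#' Valid 1-D convolution of a multi-band image
#'
#' Convolves a `(bands, H, W)` image (a single `(H, W)` matrix is treated as
#' one band) with `K` one-dimensional vertical kernels of length `klen` that
#' span all input bands, adds the bias, and applies the activation. The
#' convolution is "valid" (no padding), stride 1, so each output map has
#' height `H - klen + 1` and unchanged width. Columns are never mixed: the
#' 1-D kernels preserve the electrode (column) layout of the feature image.
#'
#' @param image numeric array `(bands, H, W)` or matrix `(H, W)`.
#' @param kernels array `(klen, bands, K)` of kernel weights (a matrix
#'   `(klen, bands)` or vector of length `klen` describes a single kernel).
#' @param bias numeric length `K` (default zeros).
#' @param act activation kind (default `"relu"`).
#' @return array `(K, H - klen + 1, W)` of feature maps.
#' @export
conv_forward <- function(image, kernels, bias = NULL, act = "relu") {
  if (is.matrix(image)) {
    image <- array(image, dim = c(1, dim(image)))
  }
  if (is.vector(kernels) && is.null(dim(kernels))) {
    kernels <- array(kernels, dim = c(length(kernels), 1, 1))
  } else if (is.matrix(kernels)) {
    kernels <- array(kernels, dim = c(dim(kernels), 1))
  }
  kd <- dim(kernels)
  d <- dim(image)
  if (kd[2] != d[1]) stopf("kernel band count %d != image band count %d", kd[2], d[1])
  if (kd[1] > d[2]) stopf("kernel length %d exceeds input height %d", kd[1], d[2])
  if (is.null(bias)) bias <- rep(0, kd[3])
  # weight matrix rows ordered channel-fastest within kernel offset
  W <- matrix(aperm(kernels, c(2, 1, 3)), nrow = kd[1] * kd[2], ncol = kd[3])
  x <- array(image, dim = c(1, d))
  out <- conv_fwd_batch(x, W, bias, act)$a
  array(out[1, , , ], dim = dim(out)[-1])
}

#' Max pooling of a feature map
#'
#' Non-overlapping block maximum: stride equals the pooling window, and
#' partial blocks at the right/bottom edges are truncated, so an `(H, W)`
#' map pools to `(floor(H/ph), floor(W/pw))` (e.g. 32 x 32 -> 10 x 10 with
#' the default 3 x 3 window).
#'
#' @param map numeric matrix `(H, W)` or array `(K, H, W)` of maps.
#' @param pool integer pooling window `c(ph, pw)` (default `c(3, 3)`).
#' @return pooled matrix/array.
#' @export
maxpool <- function(map, pool = c(3, 3)) {
  if (is.matrix(map)) {
    x <- array(map, dim = c(1, 1, dim(map)))
    out <- pool_fwd_batch(x, pool)$a
    return(matrix(out[1, 1, , ], dim(out)[3], dim(out)[4]))
  }
  x <- array(map, dim = c(1, dim(map)))
  out <- pool_fwd_batch(x, pool)$a
  array(out[1, , , ], dim = dim(out)[-1])
}
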