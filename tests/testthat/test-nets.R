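test_that("activations evaluate their defining formulas", {
  expect_equal(activation(c(-1, 2), "relu"), c(0, 2))
  expect_equal(activation(0, "softplus"), log(2))
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(activation(x, "softplus") > activation(x, "relu")))
  expect_lt(activation(30, "softplus") - activation(30, "relu"), 1e-9)
  # numerically stable far from the origin
  expect_equal(activation(1000, "softplus"), 1000)
})

test_that("valid 1-D convolution matches hand examples and the brute-force oracle", {
  # identity-like kernel leaves interior rows of a nonnegative image unchanged
  img <- matrix(abs(rnorm(5 * 4)), 5, 4)
  out <- conv_forward(img, c(0, 1, 0))
  expect_equal(out[1, , ], img[2:4, ])

  ones <- matrix(1, 4, 3)
  expect_equal(conv_forward(ones, c(1, 1, 1)),
               array(3, c(1, 2, 3)))

  # boundary: kernel length equal to input height
  expect_equal(dim(conv_forward(matrix(1, 3, 2), c(1, 1, 1))), c(1, 1, 2))
  expect_error(conv_forward(matrix(1, 2, 2), c(1, 1, 1)), "exceeds")

  set.seed(6)
  image <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  kernels <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  bias <- rnorm(4)
  expect_equal(conv_forward(image, kernels, bias, "relu"),
               conv_oracle(image, kernels, bias, "relu"), tolerance = 1e-12)
})

test_that("max pooling matches the block-max oracle with truncated edges", {
  m <- matrix(5, 6, 6)
  expect_equal(maxpool(m), matrix(5, 2, 2))
  set.seed(7)
  m32 <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(dim(maxpool(m32)), c(10, 10))
  expect_equal(maxpool(m32), pool_oracle(m32))
  m3 <- matrix(0, 3, 3); m3[2, 2] <- 9
  expect_equal(maxpool(m3), matrix(9, 1, 1))
  m34 <- matrix(rnorm(12), 3, 4)  # width 4 truncates to one block
  expect_equal(maxpool(m34), pool_oracle(m34))
})

test_that("crossentropies evaluate canonical values and symmetries", {
  expect_equal(binary_crossentropy(1, 0.5), log(2))
  expect_equal(binary_crossentropy(0, 0.5), log(2))
  expect_lt(binary_crossentropy(1, 1 - 1e-9), 1e-6)
  expect_error(binary_crossentropy(c(1, 0), 0.5), "shapes differ")

  y <- matrix(c(0, 1, 0), 1)
  expect_lt(categorical_crossentropy(y, matrix(c(1e-9, 1 - 2e-9, 1e-9), 1)), 1e-6)
  expect_equal(categorical_crossentropy(y, matrix(1 / 3, 1, 3)), log(3))
  perm <- c(2, 3, 1)
  yhat <- matrix(c(0.2, 0.5, 0.3), 1)
  expect_equal(categorical_crossentropy(y[, perm, drop = FALSE], yhat[, perm, drop = FALSE]),
               categorical_crossentropy(y, yhat))
  expect_error(categorical_crossentropy(y, matrix(c(0.5, 0.4, 0.3), 1)), "sum to 1")
})

test_that("mean activation and the Bernoulli KL follow their formulas", {
  expect_equal(mean_activation(matrix(0.5, 4, 3)), rep(0.5, 3))
  expect_equal(mean_activation(matrix(c(0.2, 0.4, 0.6), 3, 1)), 0.4)
  expect_equal(mean_activation(matrix(0.3, 1, 2)), rep(0.3, 2))
  expect_error(mean_activation(matrix(0, 0, 2)), "empty")

  expect_equal(kl_bernoulli(0.3, 0.3), 0)
  # frozen from direct arithmetic: .05*log(.05/.5) + .95*log(.95/.5)
  expect_equal(kl_bernoulli(0.05, 0.5), 0.4946321, tolerance = 1e-6)
  grid <- seq(0.05, 0.95, by = 0.05)
  kl <- kl_bernoulli(0.3, grid)
  expect_true(all(diff(kl[grid > 0.3]) > 0))
  expect_true(all(diff(kl[grid < 0.3]) < 0))
  expect_error(kl_bernoulli(0.3, 1), "inside")
})

test_that("sparse cost composes reconstruction loss and penalty", {
  expect_equal(sparse_cost(1, c(0.5, 0.5), rho = 0.5, beta = 3), 1)
  expect_equal(sparse_cost(2.5, c(0.1, 0.9), rho = 0.2, beta = 0), 2.5)
  # J = 1, two units with KL 0.1 and 0.2, beta = 3 -> 1.9, built from
  # rho_hat values solved numerically for those divergences
  rho <- 0.05
  rh <- vapply(c(0.1, 0.2), function(target) {
    stats::uniroot(function(r) kl_bernoulli(rho, r) - target, c(rho, 0.999),
                   tol = 1e-12)$root
  }, numeric(1))
  expect_equal(sparse_cost(1, rh, rho, 3), 1.9, tolerance = 1e-6)
})

test_that("encoder and decoder halves expose the documented dimensions", {
  ss <- small_sae_spec()
  sae <- ns$build_sae(20, ss, seed = 1)
  x <- matrix(runif(5 * 20), 5, 20)
  h <- encode(sae, x)
  expect_equal(dim(h), c(5, 16))
  dec <- decode(sae, h)
  expect_equal(dim(dec$features), c(5, 32))
  expect_equal(dim(dec$reconstruction), c(5, 20))
  # zero hidden vector through zero-bias sigmoid output gives 0.5 everywhere
  sae0 <- sae
  for (i in seq_along(sae0$params)) {
    if (!is.null(sae0$params[[i]])) {
      sae0$params[[i]]$W[] <- 0
      sae0$params[[i]]$b[] <- 0
    }
  }
  expect_equal(decode(sae0, matrix(0, 2, 16))$reconstruction,
               matrix(0.5, 2, 20))
  expect_equal(encode(sae0, x), matrix(0, 5, 16))
})

test_that("analytic gradients match central finite differences", {
  # smooth activations give clean finite differences; the relu forward path
  # is covered by the convolution oracle above
  cs <- conv_spec(c(3, 4), dropout_rate = 0, activation = "softplus")
  ds <- dnn_spec(c(7, 5), n_out = 2, activation = "softplus")
  net <- ns$build_baseline(c(2, 8, 6), cs, ds, seed = 5)
  set.seed(8)
  x <- array(runif(3 * 2 * 8 * 6), c(3, 2, 8, 6))
  y <- ns$one_hot(c(0, 1, 0), 2)
  cost <- function(theta) {
    nn <- ns$net_set_params(net, theta)
    binary_crossentropy(y, ns$net_forward(nn, x)$out)
  }
  theta <- ns$net_get_params(net)
  fwd <- ns$net_forward(net, x)
  g <- ns$grads_to_vector(net, ns$net_backward(net, fwd$caches,
                                               ns$loss_delta("binary_ce", y, fwd$out)))
  idx <- sample(length(theta), 50)
  ng <- numeric_grad(cost, theta, idx)
  rel <- abs(g[idx] - ng) / pmax(abs(g[idx]) + abs(ng), 1e-8)
  expect_lt(max(rel), 1e-4)

  # 3-class softmax head under categorical crossentropy
  ds3 <- dnn_spec(c(6), n_out = 3, activation = "softplus")
  dnn <- ns$build_dnn(10, ds3, seed = 6)
  xf <- matrix(runif(4 * 10), 4, 10)
  y3 <- ns$one_hot(c(0, 1, 2, 1), 3)
  cost3 <- function(theta) {
    nn <- ns$net_set_params(dnn, theta)
    categorical_crossentropy(y3, ns$net_forward(nn, xf)$out)
  }
  theta3 <- ns$net_get_params(dnn)
  fwd3 <- ns$net_forward(dnn, xf)
  g3 <- ns$grads_to_vector(dnn, ns$net_backward(dnn, fwd3$caches,
                                                ns$loss_delta("categorical_ce", y3, fwd3$out)))
  idx3 <- sample(length(theta3), 40)
  ng3 <- numeric_grad(cost3, theta3, idx3)
  expect_lt(max(abs(g3[idx3] - ng3) / pmax(abs(g3[idx3]) + abs(ng3), 1e-8)), 1e-4)
})

test_that("sparse-cost gradients (including the KL penalty path) match finite differences", {
  ss <- sae_spec(encode_units = 9, hidden_units = 5, decode_units = 9,
                 rho = 0.05, beta = 3, activation = "softplus")
  sae <- ns$build_sae(6, ss, seed = 9)
  set.seed(10)
  xb <- matrix(runif(4 * 6), 4, 6)
  cost <- function(theta) {
    nn <- ns$net_set_params(sae, theta)
    f <- ns$net_forward(nn, xb)
    sparse_cost(binary_crossentropy(xb, f$out),
                mean_activation(f$caches[[2]]$a), ss$rho, ss$beta)
  }
  theta <- ns$net_get_params(sae)
  f <- ns$net_forward(sae, xb)
  h <- f$caches[[2]]$a
  rho_hat <- mean_activation(h)
  dkl <- ss$beta * (-ss$rho / rho_hat + (1 - ss$rho) / (1 - rho_hat)) / nrow(h)
  dkl[colMeans(h) <= 1e-7 | colMeans(h) >= 1 - 1e-7] <- 0  # clipped units
  extra <- list("2" = matrix(dkl, nrow(h), ncol(h), byrow = TRUE))
  g <- ns$grads_to_vector(sae, ns$net_backward(sae, f$caches,
                                               ns$loss_delta("binary_ce", xb, f$out),
                                               extra_da = extra))
  idx <- sample(length(theta), 50)
  ng <- numeric_grad(cost, theta, idx)
  expect_lt(max(abs(g[idx] - ng) / pmax(abs(g[idx]) + abs(ng), 1e-8)), 1e-4)
})

test_that("a large sparsity weight lowers the mean hidden activation", {
  segs <- tiny_segments(effect_size = 1, seed = 2)
  ft <- featurize(segs, "pcc")
  flat <- matrix(ft$data, dim(ft$data)[1])
  cfgs <- smoke_stage_config(epochs = 15, seed = 3)
  plain <- train_sae_stage(flat, cfgs, small_sae_spec(beta = 0))
  sparse <- train_sae_stage(flat, cfgs, small_sae_spec(beta = 20, rho = 0.01))
  mean_act <- function(fit) mean(encode(fit$net, flat))
  expect_lt(mean_act(sparse), mean_act(plain))
})

test_that("model specs validate their fields", {
  expect_error(conv_spec(c(8, 16, 32)), "two conv layers")
  expect_error(sae_spec(rho = 0), "inside")
  expect_error(sae_spec(beta = -1), ">= 0")
  expect_error(dnn_spec(n_out = 4), "1, 2 or 3")
  expect_equal(dnn_spec(n_out = 3)$output_activation, "softmax")
  expect_equal(dnn_spec(n_out = 2)$output_activation, "sigmoid")
  expect_equal(dnn_spec(n_out = 1)$loss, "binary_ce")
})
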