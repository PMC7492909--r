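# Three-stage training protocol (conv extractor -> sparse autoencoder ->
# classifier head), the end-to-end baseline CNN, and the evaluation metrics.

#' Per-stage training configuration
#'
#' Epochs, batch size, learning rate and optimizer per stage, plus the
#' train/test split. Defaults are the full-scale protocol: conv stage
#' 50 epochs / batch 128 / lr 0.01 / adadelta; autoencoder 100 / 64 / 0.01 /
#' adadelta; classifier head 100 / 128 / 0.01 with adadelta for the binary
#' task and adam for the 3-class task; baseline CNN 100 / 128 / 0.01.
#' `mode = "paper"` trains the conv and autoencoder stages on all samples
#' before the split (the protocol reproduced here, which leaks unsupervised
#' representation information into the test split); `mode = "strict"` fits
#' every stage on the training split only.
#'
#' @param cnn,sae,dnn,baseline lists with `epochs`, `batch`, `lr`,
#'   `optimizer`.
#' @param split_fraction fraction of samples used for training (default 0.8).
#' @param split_seed,init_seed integer seeds for the split and for weight
#'   initialization / shuffling / dropout.
#' @param mode `"paper"` or `"strict"`.
#' @return object of class `stage_config`.
#' @export
stage_config <- function(cnn = list(epochs = 50, batch = 128, lr = 0.01, optimizer = "adadelta"),
                         sae = list(epochs = 100, batch = 64, lr = 0.01, optimizer = "adadelta"),
                         dnn = list(epochs = 100, batch = 128, lr = 0.01, optimizer = NULL),
                         baseline = list(epochs = 100, batch = 128, lr = 0.01, optimizer = NULL),
                         split_fraction = 0.8, split_seed = 1L, init_seed = 1L,
                         mode = c("paper", "strict")) {
  mode <- match.arg(mode)
  if (split_fraction <= 0 || split_fraction >= 1) stopf("split_fraction must be in (0, 1)")
  for (st in list(cnn, sae, dnn, baseline)) {
    if (st$epochs < 1) stopf("epochs must be >= 1")
  }
  structure(list(cnn = cnn, sae = sae, dnn = dnn, baseline = baseline,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 init_seed = as.integer(init_seed), mode = mode),
            class = "stage_config")
}

one_hot <- function(labels, n_out) {
  if (n_out == 1) return(matrix(as.numeric(labels), ncol = 1))
  y <- matrix(0, length(labels), n_out)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

predicted_class <- function(a, n_out) {
  if (n_out == 1) as.integer(a[, 1] > 0.5) else max.col(a, ties.method = "first") - 1L
}

net_eval <- function(net, x, y, labels, loss_kind, n_out) {
  a <- net_predict(net, x)
  loss <- if (loss_kind == "binary_ce") binary_crossentropy(y, a) else categorical_crossentropy(y, a)
  list(loss = loss, acc = mean(predicted_class(a, n_out) == labels))
}

batch_indices <- function(idx, batch) {
  split(idx, ceiling(seq_along(idx) / batch))
}

# supervised training loop shared by the conv stage, classifier head and
# baseline; deterministic given (net init, seed, data order)
train_supervised <- function(net, x, labels, loss_kind, epochs, batch, opt,
                             seed, test = NULL) {
  subset_x <- function(xx, i) {
    if (length(dim(xx)) == 4) xx[i, , , , drop = FALSE] else xx[i, , drop = FALSE]
  }
  n_out <- net$output_shape
  y <- one_hot(labels, n_out)
  n <- if (length(dim(x)) == 4) dim(x)[1] else nrow(x)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), test_loss = numeric(0),
                     test_acc = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      # train metrics are the running mean over minibatches (the usual
      # deep-learning-framework convention), so no extra full-train pass
      loss_sum <- acc_sum <- 0
      for (bi in batch_indices(idx, batch)) {
        xb <- subset_x(x, bi)
        yb <- y[bi, , drop = FALSE]
        fwd <- net_forward(net, xb, train = TRUE)
        if (!all(is.finite(fwd$out))) {
          stopf("non-finite network output at epoch %d (loss diverged)", ep)
        }
        loss_sum <- loss_sum + length(bi) *
          (if (loss_kind == "binary_ce") binary_crossentropy(yb, fwd$out)
           else categorical_crossentropy(yb, fwd$out))
        acc_sum <- acc_sum + sum(predicted_class(fwd$out, n_out) == labels[bi])
        delta <- loss_delta(loss_kind, yb, fwd$out)
        grads <- net_backward(net, fwd$caches, delta)
        st <- opt_step(opt, net$params, grads)
        opt <- st$opt
        net$params <- st$params
      }
      tr <- list(loss = loss_sum / n, acc = acc_sum / n)
      te <- list(loss = NA_real_, acc = NA_real_)
      if (!is.null(test)) {
        te <- net_eval(net, test$x, one_hot(test$labels, n_out), test$labels,
                       loss_kind, n_out)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr$loss,
                                     train_acc = tr$acc, test_loss = te$loss,
                                     test_acc = te$acc))
    }
  })
  list(net = net, history = hist)
}

#' Train the convolutional feature extractor
#'
#' Trains the conv trunk with a temporary classifier head, then discards the
#' head and returns the trunk only. In `"paper"` mode the stage sees all
#' samples; in `"strict"` mode only the training split (pass `train_idx`).
#'
#' @param ft a `feature_tensor`.
#' @param config a [stage_config()].
#' @param cspec a [conv_spec()].
#' @param dspec a [dnn_spec()] describing the temporary head's output.
#' @param train_idx sample indices to train on (default: all, the
#'   `"paper"` protocol).
#' @return list with `extractor` (head removed), `history`, and the head's
#'   `n_out`.
#' @export
train_cnn_stage <- function(ft, config, cspec, dspec, train_idx = NULL) {
  stopifnot(inherits(ft, "feature_tensor"))
  d <- dim(ft$data)
  net <- build_extractor_with_head(input_shape = d[2:4], cspec, dspec,
                                   seed = derive_seed(config$init_seed, 1L))
  idx <- train_idx %||% seq_len(d[1])
  x <- ft$data[idx, , , , drop = FALSE]
  labels <- ft$labels[idx]
  opt <- optimizer(config$cnn$optimizer %||% "adadelta", lr = config$cnn$lr)
  res <- train_supervised(net, x, labels, dspec$loss,
                          epochs = config$cnn$epochs, batch = config$cnn$batch,
                          opt = opt, seed = derive_seed(config$init_seed, 11L))
  list(extractor = drop_head(res$net), history = res$history, n_out = dspec$n_out)
}

#' Extract flattened pooled features
#'
#' Runs the trained conv trunk on every sample, takes the flattened
#' max-pooling output, and min-max scales each feature column to `[0, 1]`
#' for the autoencoder stage (constant columns map to 0).
#'
#' @param extractor trained trunk from [train_cnn_stage()].
#' @param ft the `feature_tensor` to transform.
#' @return matrix `samples x flat_dim` with attributes `scale_min`,
#'   `scale_max`.
#' @export
extract_pooled <- function(extractor, ft) {
  ext <- if (is.list(extractor) && !inherits(extractor, "eegsae_net")) {
    extractor$extractor
  } else extractor
  flat <- net_predict(ext, ft$data)
  sc <- minmax_scale_cols(flat)
  out <- sc$data
  attr(out, "scale_min") <- sc$min
  attr(out, "scale_max") <- sc$max
  out
}

#' Train the sparse autoencoder stage
#'
#' Unsupervised training of the autoencoder on the flattened pooled
#' features under the sparse cost (reconstruction binary crossentropy plus
#' the weighted Bernoulli-KL penalty on the hidden layer's batch mean
#' activation). Returns the 512-unit export features (the decoder's
#' penultimate layer) for every sample.
#'
#' @param flat matrix `samples x flat_dim` in `[0, 1]`.
#' @param config a [stage_config()].
#' @param sspec a [sae_spec()].
#' @param train_idx sample indices to train on (default: all).
#' @return list with `net`, `features` (`samples x decode_units`),
#'   `history` (per-epoch reconstruction loss and total cost).
#' @export
train_sae_stage <- function(flat, config, sspec = sae_spec(), train_idx = NULL) {
  if (min(flat) < -1e-9 || max(flat) > 1 + 1e-9) {
    stopf("autoencoder input must be scaled to [0, 1]")
  }
  n <- nrow(flat)
  idx <- train_idx %||% seq_len(n)
  net <- build_sae(ncol(flat), sspec, seed = derive_seed(config$init_seed, 2L))
  opt <- optimizer(config$sae$optimizer %||% "adadelta", lr = config$sae$lr)
  hidden_layer <- 2L
  hist <- data.frame(epoch = integer(0), recon_loss = numeric(0),
                     total_cost = numeric(0))
  with_seed(derive_seed(config$init_seed, 12L), {
    for (ep in seq_len(config$sae$epochs)) {
      ord <- idx[sample.int(length(idx))]
      for (bi in batch_indices(ord, config$sae$batch)) {
        xb <- flat[bi, , drop = FALSE]
        fwd <- net_forward(net, xb, train = TRUE)
        if (!all(is.finite(fwd$out))) stopf("autoencoder loss diverged at epoch %d", ep)
        delta <- loss_delta("binary_ce", xb, fwd$out)
        extra <- NULL
        if (sspec$beta > 0) {
          h <- fwd$caches[[hidden_layer]]$a
          rho_hat <- mean_activation(h)
          interior <- colMeans(h) > 1e-7 & colMeans(h) < 1 - 1e-7
          dkl <- sspec$beta * (-sspec$rho / rho_hat + (1 - sspec$rho) / (1 - rho_hat)) / nrow(h)
          dkl[!interior] <- 0  # clipped units contribute no gradient
          extra <- list()
          extra[[as.character(hidden_layer)]] <-
            matrix(dkl, nrow(h), ncol(h), byrow = TRUE)
        }
        grads <- net_backward(net, fwd$caches, delta, extra_da = extra)
        st <- opt_step(opt, net$params, grads)
        opt <- st$opt
        net$params <- st$params
      }
      fwd <- net_forward(net, flat[idx, , drop = FALSE], train = FALSE)
      recon <- binary_crossentropy(flat[idx, , drop = FALSE], fwd$out)
      rho_hat <- mean_activation(fwd$caches[[hidden_layer]]$a)
      hist <- rbind(hist, data.frame(
        epoch = ep, recon_loss = recon,
        total_cost = sparse_cost(recon, rho_hat, sspec$rho, sspec$beta)))
    }
  })
  h_all <- encode(net, flat)
  feats <- decode(net, h_all)$features
  # same stage-boundary contract as extract_pooled: rescale per feature to
  # [0, 1] so the next stage's optimizer sees a unit dynamic range
  sc <- minmax_scale_cols(feats)
  feats <- sc$data
  attr(feats, "scale_min") <- sc$min
  attr(feats, "scale_max") <- sc$max
  list(net = net, features = feats, history = hist, spec = sspec)
}

split_train_test <- function(n, labels, fraction, seed) {
  n_train <- round(n * fraction)
  idx <- with_seed(seed, sample.int(n))
  train_idx <- sort(idx[seq_len(n_train)])
  test_idx <- sort(idx[(n_train + 1):n])
  missing <- setdiff(unique(labels), unique(labels[train_idx]))
  if (length(missing) > 0) {
    stopf("train split is missing class(es): %s", paste(missing, collapse = ", "))
  }
  list(train = train_idx, test = test_idx)
}

#' Train the classifier head on autoencoder features
#'
#' Random train/test split (recorded seed), per-epoch test accuracy, and the
#' final metric defined as the mean test accuracy over the last 10 epochs.
#'
#' @param features matrix `samples x feature_dim` (autoencoder export
#'   features).
#' @param labels integer class labels.
#' @param config a [stage_config()].
#' @param dspec a [dnn_spec()].
#' @return a `train_result`: list with `net`, `history`, `final_accuracy`
#'   (last-10-epoch mean test accuracy; `NA` for runs shorter than 10
#'   epochs), `convergence_epoch`, `split` (train/test indices), `n_out`.
#' @export
train_dnn_stage <- function(features, labels, config, dspec = dnn_spec()) {
  n <- nrow(features)
  sp <- split_train_test(n, labels, config$split_fraction, config$split_seed)
  stopifnot(length(intersect(sp$train, sp$test)) == 0)  # data hygiene
  net <- build_dnn(ncol(features), dspec, seed = derive_seed(config$init_seed, 3L))
  opt_kind <- config$dnn$optimizer %||% (if (dspec$n_out == 3) "adam" else "adadelta")
  opt <- optimizer(opt_kind, lr = config$dnn$lr)
  res <- train_supervised(
    net, features[sp$train, , drop = FALSE], labels[sp$train], dspec$loss,
    epochs = config$dnn$epochs, batch = config$dnn$batch, opt = opt,
    seed = derive_seed(config$init_seed, 13L),
    test = list(x = features[sp$test, , drop = FALSE], labels = labels[sp$test]))
  finalize_result(res, sp, dspec)
}

#' Train the baseline end-to-end CNN
#'
#' A single network with the same conv trunk and the same fully connected
#' layer sizes as the composite model, trained end-to-end on the 80/20
#' split with the same last-10-epoch metric. Serves as the comparison
#' model.
#'
#' @param ft a `feature_tensor`.
#' @param config a [stage_config()].
#' @param cspec a [conv_spec()].
#' @param dspec a [dnn_spec()].
#' @return a `train_result` (see [train_dnn_stage()]).
#' @export
train_baseline_cnn <- function(ft, config, cspec = conv_spec(), dspec = dnn_spec()) {
  stopifnot(inherits(ft, "feature_tensor"))
  d <- dim(ft$data)
  sp <- split_train_test(d[1], ft$labels, config$split_fraction, config$split_seed)
  net <- build_baseline(d[2:4], cspec, dspec, seed = derive_seed(config$init_seed, 4L))
  opt_kind <- config$baseline$optimizer %||% (if (dspec$n_out == 3) "adam" else "adadelta")
  opt <- optimizer(opt_kind, lr = config$baseline$lr)
  res <- train_supervised(
    net, ft$data[sp$train, , , , drop = FALSE], ft$labels[sp$train], dspec$loss,
    epochs = config$baseline$epochs, batch = config$baseline$batch, opt = opt,
    seed = derive_seed(config$init_seed, 14L),
    test = list(x = ft$data[sp$test, , , , drop = FALSE], labels = ft$labels[sp$test]))
  finalize_result(res, sp, dspec)
}

finalize_result <- function(res, sp, dspec) {
  acc <- res$history$test_acc
  final <- if (length(acc) >= 10) last10_mean(acc) else NA_real_
  conv_ep <- if (is.na(final)) NA_integer_ else convergence_epoch(acc, final)
  structure(list(net = res$net, history = res$history, final_accuracy = final,
                 convergence_epoch = conv_ep, split = sp, n_out = dspec$n_out),
            class = "train_result")
}

#' Mean test accuracy over the last 10 epochs
#'
#' The reporting metric of every experiment: the arithmetic mean of the
#' final 10 per-epoch test accuracies. Histories shorter than 10 epochs are
#' an error, never silently truncated.
#'
#' @param history numeric vector of per-epoch accuracies.
#' @return scalar mean accuracy.
#' @export
last10_mean <- function(history) {
  if (length(history) < 10) {
    stopf("history has %d epochs; the last-10 metric needs at least 10", length(history))
  }
  mean(utils::tail(history, 10))
}

#' First epoch reaching 95% of the accuracy plateau
#'
#' Operationalizes "convergence": the first epoch whose test accuracy is at
#' least 95% of the plateau (the last-10-epoch mean).
#'
#' @param acc per-epoch test accuracies.
#' @param plateau plateau level (default: [last10_mean()] of `acc`).
#' @return integer epoch index.
#' @export
convergence_epoch <- function(acc, plateau = last10_mean(acc)) {
  which(acc >= 0.95 * plateau)[1]
}

#' Run the composite three-stage model
#'
#' Chains [train_cnn_stage()], [extract_pooled()], [train_sae_stage()] and
#' [train_dnn_stage()]. In `"paper"` mode the first two (feature-extraction)
#' stages see all samples and only the classifier head respects the split;
#' in `"strict"` mode all three stages fit on the training split only.
#'
#' @param ft a `feature_tensor`.
#' @param config a [stage_config()].
#' @param cspec,sspec,dspec model specifications.
#' @return list with `result` (the head's `train_result`), `cnn`, `sae`
#'   stage outputs, and `mode`.
#' @export
train_composite <- function(ft, config, cspec = conv_spec(), sspec = sae_spec(),
                            dspec = dnn_spec()) {
  n <- dim(ft$data)[1]
  unsup_idx <- if (config$mode == "strict") {
    split_train_test(n, ft$labels, config$split_fraction, config$split_seed)$train
  } else NULL
  cnn <- train_cnn_stage(ft, config, cspec, dspec, train_idx = unsup_idx)
  flat <- extract_pooled(cnn$extractor, ft)
  sae <- train_sae_stage(flat, config, sspec, train_idx = unsup_idx)
  dnn <- train_dnn_stage(sae$features, ft$labels, config, dspec)
  list(result = dnn, cnn = cnn, sae = sae, mode = config$mode)
}

#' Comparison experiment over models, features and window settings
#'
#' Trains the baseline CNN and the composite model for every requested
#' feature kind and window/step setting on one recording, and tabulates the
#' last-10-epoch mean accuracy and convergence epoch per run.
#'
#' @param rec an `eeg_recording` (already trimmed/downsampled as desired).
#' @param config a [stage_config()].
#' @param windows list of `c(window_s, step_s)` pairs.
#' @param feature_kinds character subset of `c("pcc", "pca", "sc")`.
#' @param models character subset of `c("baseline", "composite")`.
#' @param cspec,sspec,dspec model specifications (the head's `n_out` should
#'   match the recording's class count).
#' @param band_edges band decomposition (default [default_bands()]).
#' @return list with `report` (data.frame: model, feature, window_s, step_s,
#'   mode, accuracy, convergence_epoch, n_segments) and `runs` (the full
#'   stage outputs, named `model:feature:window`).
#' @export
run_experiment <- function(rec, config, windows = list(c(8, 4)),
                           feature_kinds = "pcc",
                           models = c("baseline", "composite"),
                           cspec = conv_spec(), sspec = sae_spec(),
                           dspec = dnn_spec(), band_edges = default_bands()) {
  stack <- decompose_bands(rec, band_edges)
  report <- NULL
  runs <- list()
  for (w in windows) {
    segs <- segment_windows(stack, w[1], w[2])
    for (fk in feature_kinds) {
      ft <- featurize(segs, fk)
      for (model in models) {
        run <- if (model == "baseline") {
          train_baseline_cnn(ft, config, cspec, dspec)
        } else {
          train_composite(ft, config, cspec, sspec, dspec)
        }
        res <- if (model == "baseline") run else run$result
        key <- sprintf("%s:%s:%gs/%gs", model, fk, w[1], w[2])
        runs[[key]] <- run
        report <- rbind(report, data.frame(
          model = model, feature = fk, window_s = w[1], step_s = w[2],
          mode = config$mode, accuracy = res$final_accuracy,
          convergence_epoch = res$convergence_epoch,
          n_segments = dim(ft$data)[1]))
      }
    }
  }
  list(report = report, runs = runs)
}
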