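test_that("the last-10-epoch metric is exact arithmetic and refuses short histories", {
  expect_equal(last10_mean(rep(0.9, 100)), 0.9)
  expect_equal(last10_mean(c(0.5, rep(0.8, 5), rep(0.9, 5))), 0.85)
  expect_equal(last10_mean(seq(0.90, 0.99, by = 0.01)), 0.945)
  expect_error(last10_mean(rep(0.9, 9)), "at least 10")
  hist <- c(rep(0.3, 3), rep(0.96, 17))
  expect_equal(convergence_epoch(hist), 4L)
  expect_equal(convergence_epoch(rep(0.7, 12)), 1L)
})

test_that("the 80/20 split reproduces the protocol's sample counts and stays disjoint", {
  labels <- rep(0:1, length.out = 17920)
  sp <- ns$split_train_test(17920, labels, 0.8, seed = 1)
  expect_equal(length(sp$train), 14336)
  expect_equal(length(sp$test), 3584)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(17920))
  # a split that strands the only minority sample in the test set errors
  rare <- c(rep(0L, 99), 1L)
  bad_seed <- Find(function(s) {
    idx <- ns$with_seed(s, sample.int(100))
    !(100 %in% idx[1:80])
  }, 1:50)
  expect_error(ns$split_train_test(100, rare, 0.8, seed = bad_seed), "missing class")
})

test_that("the conv stage discards its temporary head and exports flattened pooled features", {
  segs <- tiny_segments(seed = 4)
  ft <- featurize(segs, "pcc")
  cfg <- smoke_stage_config(epochs = 1, seed = 4)
  cs <- small_conv_spec()
  fit <- train_cnn_stage(ft, cfg, cs, dnn_spec(n_out = 2))
  types <- vapply(fit$extractor$layers, `[[`, "", "type")
  expect_false("dense" %in% types)
  expect_equal(nrow(fit$history), 1)
  # 8x8 image: conv 8 -> 6 -> 4 rows, 3x3 pool -> 1 x 2 blocks per map
  flat <- extract_pooled(fit$extractor, ft)
  expect_equal(nrow(flat), dim(ft$data)[1])
  expect_equal(ncol(flat), fit$extractor$output_shape)
  expect_gte(min(flat), 0)
  expect_lte(max(flat), 1)
})

test_that("the flattened dimension follows the conv/pool contract", {
  # 32-channel image stack: 32 -> 30 -> 28 rows after two length-3 kernels,
  # 3x3 pooling truncates to 9 x 10 blocks over 64 maps
  net <- ns$build_extractor_with_head(c(4, 32, 32), conv_spec(), dnn_spec(), seed = 1)
  expect_equal(nrow(net$params[[7]]$W), 64 * 9 * 10)
  x <- array(runif(2 * 4 * 32 * 32), c(2, 4, 32, 32))
  ext <- ns$drop_head(net)
  expect_equal(dim(ns$net_forward(ext, x)$out), c(2, 5760))
  # zero input stays zero through relu conv and pooling
  expect_equal(ns$net_forward(ext, array(0, c(1, 4, 32, 32)))$out,
               matrix(0, 1, 5760), ignore_attr = TRUE)
})

test_that("autoencoder stage reduces to a plain autoencoder at beta zero and exports 512-wide features", {
  segs <- tiny_segments(seed = 5)
  ft <- featurize(segs, "pcc")
  flat <- matrix(ft$data, dim(ft$data)[1])
  cfg <- smoke_stage_config(epochs = 3, seed = 5)
  fit0 <- train_sae_stage(flat, cfg, small_sae_spec(beta = 0))
  expect_equal(fit0$history$recon_loss, fit0$history$total_cost)
  fitb <- train_sae_stage(flat, cfg, small_sae_spec(beta = 2))
  expect_true(all(fitb$history$total_cost > fitb$history$recon_loss))
  expect_equal(ncol(fitb$features), 32)  # decode_units of the small spec
  full <- train_sae_stage(flat, cfg, sae_spec())
  expect_equal(ncol(full$features), 512)
  expect_error(train_sae_stage(flat * 3, cfg), "\\[0, 1\\]")
})

test_that("classifier stage tracks per-epoch test accuracy on a clean split", {
  segs <- tiny_segments(seed = 6)
  ft <- featurize(segs, "pcc")
  feats <- matrix(ft$data, dim(ft$data)[1])
  cfg <- smoke_stage_config(epochs = 12, seed = 6)
  res <- train_dnn_stage(feats, ft$labels, cfg, dnn_spec(c(16, 8), n_out = 2))
  expect_s3_class(res, "train_result")
  expect_equal(nrow(res$history), 12)
  expect_false(any(is.na(res$history$test_acc)))
  expect_equal(res$final_accuracy, last10_mean(res$history$test_acc))
  expect_equal(length(intersect(res$split$train, res$split$test)), 0)
  expect_equal(length(res$split$train), round(0.8 * nrow(feats)))
})

test_that("stage training is bit-reproducible under fixed seeds", {
  segs <- tiny_segments(seed = 7)
  ft <- featurize(segs, "pcc")
  cfg <- smoke_stage_config(epochs = 2, seed = 7)
  cs <- small_conv_spec()
  a <- train_cnn_stage(ft, cfg, cs, dnn_spec(n_out = 2))
  b <- train_cnn_stage(ft, cfg, cs, dnn_spec(n_out = 2))
  expect_identical(ns$net_get_params(a$extractor), ns$net_get_params(b$extractor))
  base1 <- train_baseline_cnn(ft, cfg, cs, dnn_spec(c(16, 8), n_out = 2))
  base2 <- train_baseline_cnn(ft, cfg, cs, dnn_spec(c(16, 8), n_out = 2))
  expect_identical(base1$history, base2$history)
  expect_identical(ns$net_get_params(base1$net), ns$net_get_params(base2$net))
})

test_that("the composite runs end to end in both leakage modes", {
  segs <- tiny_segments(seed = 8)
  ft <- featurize(segs, "pcc")
  cs <- small_conv_spec()
  ss <- small_sae_spec()
  ds <- dnn_spec(c(16, 8), n_out = 2)
  run_p <- train_composite(ft, smoke_stage_config(epochs = 2, seed = 8, mode = "paper"),
                           cs, ss, ds)
  expect_equal(run_p$mode, "paper")
  run_s <- train_composite(ft, smoke_stage_config(epochs = 2, seed = 8, mode = "strict"),
                           cs, ss, ds)
  expect_equal(run_s$mode, "strict")
  expect_equal(nrow(run_s$result$history), 2)
})

test_that("the experiment report has one row per model/feature/window combination", {
  rec <- generate_recording(tiny_spec(seed = 9))
  rec <- trim_lead(rec, 3)
  out <- run_experiment(rec, smoke_stage_config(epochs = 2, seed = 9),
                        windows = list(c(8, 4), c(10, 10)),
                        feature_kinds = c("pcc", "sc"),
                        models = c("baseline", "composite"),
                        cspec = small_conv_spec(), sspec = small_sae_spec(),
                        dspec = dnn_spec(c(16, 8), n_out = 2),
                        band_edges = list(c(1, 7), c(8, 13)))
  expect_equal(nrow(out$report), 2 * 2 * 2)
  expect_equal(sort(unique(out$report$model)), c("baseline", "composite"))
  expect_equal(out$report$n_segments[out$report$window_s == 8][1], 8 * 4)
})
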