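# Shared fixtures and independent oracles. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

ns <- asNamespace("eegsae")

# a small recording: 2 subjects x 4 trials x 8 channels, 23-s trials @ 32 Hz
# (8 channels is the smallest image that still fits two length-3 kernels
# followed by a 3x3 pooling window)
tiny_spec <- function(effect_size = 1, seed = 1L, n_classes = 2,
                      n_channels = 8, fs = 32, duration = 23) {
  synth_spec(n_subjects = 2, n_trials_per_subject = 4,
             n_channels = n_channels, fs = fs, duration = duration,
             n_classes = n_classes, n_latent_sources = 3,
             band_edges = list(c(1, 7), c(8, 13)),
             effect_size = effect_size, noise_sd = 1, seed = seed)
}

tiny_segments <- function(...) {
  rec <- generate_recording(tiny_spec(...))
  rec <- trim_lead(rec, 3)
  segment_windows(decompose_bands(rec, rec$spec$band_edges), 8, 4)
}

# brute-force valid 1-D convolution: triple loop over kernels/offsets/bands
conv_oracle <- function(image, kernels, bias, act = "relu") {
  kd <- dim(kernels)  # (klen, bands, K)
  d <- dim(image)     # (bands, H, W)
  hout <- d[2] - kd[1] + 1
  out <- array(0, dim = c(kd[3], hout, d[3]))
  for (k in seq_len(kd[3])) {
    for (h in seq_len(hout)) {
      for (w in seq_len(d[3])) {
        s <- bias[k]
        for (cc in seq_len(d[1])) {
          for (r in seq_len(kd[1])) {
            s <- s + kernels[r, cc, k] * image[cc, h + r - 1, w]
          }
        }
        out[k, h, w] <- activation(s, act)
      }
    }
  }
  out
}

# brute-force block max pooling
pool_oracle <- function(m, pool = c(3, 3)) {
  ph <- nrow(m) %/% pool[1]
  pw <- ncol(m) %/% pool[2]
  out <- matrix(0, ph, pw)
  for (i in seq_len(ph)) {
    for (j in seq_len(pw)) {
      out[i, j] <- max(m[(pool[1] * (i - 1) + 1):(pool[1] * i),
                         (pool[2] * (j - 1) + 1):(pool[2] * j)])
    }
  }
  out
}

# central finite differences of a scalar function at theta (sampled entries)
numeric_grad <- function(f, theta, idx, h = 1e-5) {
  vapply(idx, function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# total band energy of a single-channel signal
signal_energy <- function(x) sum(x^2)

# smallest stage_config used in smoke tests
smoke_stage_config <- function(epochs = 2, seed = 1L, mode = "paper") {
  stage_config(
    cnn = list(epochs = epochs, batch = 16, lr = 0.01, optimizer = "adadelta"),
    sae = list(epochs = epochs, batch = 16, lr = 0.01, optimizer = "adadelta"),
    dnn = list(epochs = epochs, batch = 16, lr = 0.01, optimizer = NULL),
    baseline = list(epochs = epochs, batch = 16, lr = 0.01, optimizer = NULL),
    split_seed = seed, init_seed = seed, mode = mode
  )
}

small_conv_spec <- function() conv_spec(kernels_per_layer = c(4, 8))
small_sae_spec <- function(...) {
  sae_spec(encode_units = 32, hidden_units = 16, decode_units = 32, ...)
}
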