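test_that("leading-trim shortens trials from the front and rejects over-trimming", {
  rec <- generate_recording(tiny_spec())
  n0 <- dim(rec$data)[4]
  trimmed <- trim_lead(rec, 3)
  expect_equal(dim(trimmed$data)[4], n0 - 3 * rec$fs)
  expect_equal(trimmed$data[1, 1, 1, 1], rec$data[1, 1, 1, 3 * rec$fs + 1])
  expect_identical(trim_lead(rec, 0)$data, rec$data)
  expect_error(trim_lead(rec, 23), "cannot trim")
})

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  tone10 <- sin(2 * pi * 10 * t)
  inband <- bandpass_filter(tone10, fs, 8, 13)[1, ]
  outband <- bandpass_filter(tone10, fs, 30, 45)[1, ]
  expect_gte(signal_energy(inband) / signal_energy(tone10), 0.9)
  expect_lte(signal_energy(outband) / signal_energy(tone10), 0.05)
  expect_equal(bandpass_filter(rep(0, 512), fs, 8, 13)[1, ], rep(0, 512))
  expect_error(bandpass_filter(tone10, fs, 30, 70), "Nyquist|invalid")
})

test_that("filtering is linear and zero-phase", {
  fs <- 128
  set.seed(2)
  x <- rnorm(512)
  y <- rnorm(512)
  lhs <- bandpass_filter(2 * x + 3 * y, fs, 8, 13)
  rhs <- 2 * bandpass_filter(x, fs, 8, 13) + 3 * bandpass_filter(y, fs, 8, 13)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # a windowed in-band tone burst keeps its envelope peak location
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  burst <- sin(2 * pi * 10 * t) * exp(-((t - 2)^2) / 0.1)
  filt <- bandpass_filter(burst, fs, 8, 13)[1, ]
  env_in <- which.max(abs(stats::filter(burst^2, rep(1, 13), sides = 2)))
  env_out <- which.max(abs(stats::filter(filt^2, rep(1, 13), sides = 2)))
  expect_lte(abs(env_in - env_out), 1)
})

test_that("band decomposition yields one aligned copy per band with provenance", {
  rec <- generate_recording(tiny_spec(fs = 128))  # all four default bands fit
  stack <- decompose_bands(rec, default_bands())
  expect_s3_class(stack, "band_stack")
  expect_equal(dim(stack$data), c(8, 4, 8, dim(rec$data)[4]))
  expect_equal(stack$labels, as.vector(t(rec$labels)))
  expect_equal(stack$provenance$subject, rep(1:2, each = 4))
  single <- decompose_bands(rec, list(c(4, 15)))
  expect_equal(dim(single$data)[2], 1)
})

test_that("band energies of a pure tone concentrate in its own band", {
  fs <- 128
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- structure(list(
    data = array(rep(sin(2 * pi * 10 * t), each = 1), c(1, 1, 1, length(t))),
    fs = fs, labels = matrix(0L, 1, 1), preset_name = "tone",
    spec = NULL), class = "eeg_recording")
  stack <- decompose_bands(rec, default_bands())
  energies <- sapply(1:4, function(b) signal_energy(stack$data[1, b, 1, ]))
  expect_equal(sum(energies), energies[2], tolerance = 0.05)
})

test_that("downsampling follows the polyphase length rule and refuses upsampling", {
  spec <- synth_spec(n_subjects = 1, n_trials_per_subject = 1, n_channels = 2,
                     fs = 512, duration = 63, n_classes = 2,
                     band_edges = list(c(8, 13)), seed = 2)
  rec <- generate_recording(spec)
  down <- downsample_recording(rec, 128)
  expect_equal(down$fs, 128)
  expect_equal(dim(down$data)[4], 8064)
  expect_identical(downsample_recording(rec, 512), rec)
  expect_error(downsample_recording(rec, 1024), "upsampling")
  # non-integer ratio: length = ceiling(n * p/q), cross-checked against the
  # resampler itself on one channel
  spec2 <- synth_spec(n_subjects = 1, n_trials_per_subject = 1, n_channels = 1,
                      fs = 200, duration = 63, n_classes = 2,
                      band_edges = list(c(8, 13)), seed = 2)
  rec2 <- generate_recording(spec2)
  down2 <- downsample_recording(rec2, 128)
  expect_equal(dim(down2$data)[4], ceiling(63 * 200 * 16 / 25))
  direct <- signal::resample(rec2$data[1, 1, 1, ], 16, 25)
  expect_equal(down2$data[1, 1, 1, ], direct)
})

test_that("window counts match the printed protocol and brute-force enumeration", {
  expect_equal(n_segments(60, 8, 4), 14L)
  expect_equal(n_segments(60, 12, 8), 7L)
  expect_equal(n_segments(80, 8, 4), 19L)
  expect_equal(n_segments(80, 12, 8), 9L)
  expect_equal(n_segments(20, 6, 3), 5L)
  expect_equal(n_segments(8, 8, 4), 1L)
  expect_error(n_segments(10, 12, 4), "longer than trial")

  brute <- function(dur, win, step) {
    starts <- 0
    k <- 0
    while (starts + win <= dur + 1e-9) {
      k <- k + 1
      starts <- starts + step
    }
    k
  }
  set.seed(4)
  for (i in 1:50) {
    dur <- sample(10:120, 1)
    win <- sample(2:dur, 1)
    step <- sample(1:10, 1)
    expect_equal(n_segments(dur, win, step), brute(dur, win, step))
  }
})

test_that("segmentation inherits labels and records window starts", {
  segs <- tiny_segments()
  # 20-s trimmed trials, 8-s window, 4-s step -> 4 segments x 8 trials
  expect_equal(dim(segs$data)[1], 4 * 8)
  expect_equal(dim(segs$data)[4], 8 * 32)
  per_trial <- split(segs$labels, paste(segs$provenance$subject, segs$provenance$trial))
  expect_true(all(vapply(per_trial, function(l) length(unique(l)) == 1, TRUE)))
  expect_equal(unique(segs$provenance$window_start_s), c(0, 4, 8, 12))
  rec <- generate_recording(tiny_spec())
  stack <- decompose_bands(rec, rec$spec$band_edges)
  expect_error(segment_windows(stack, 40, 4), "longer than trial")
  one <- segment_windows(stack, 23, 23)
  expect_equal(dim(one$data)[1], 8)
})
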