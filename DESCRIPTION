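Package: eegsae
Title: Staged CNN-SAE-DNN Pipeline for EEG Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emotion classification from multichannel EEG via band
    decomposition, sliding-window segmentation, per-band 2D feature images
    (channel-pair Pearson correlation, per-segment PCA scores, and per-channel
    statistical characteristics), and a three-stage deep model: a
    convolutional feature extractor with 1-D kernels, a sparse autoencoder
    with a Bernoulli Kullback-Leibler sparsity penalty, and a fully connected
    classifier head, each trained separately. Includes a synthetic EEG
    generator that encodes the class label in band-specific inter-channel
    correlation structure, so the full pipeline is testable without access to
    restricted EEG corpora, plus a baseline end-to-end CNN for comparison
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
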