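#' Channel-pair Pearson correlation matrix
#'
#' Entry (i, j) is the Pearson correlation of channels i and j over the
#' segment, giving a symmetric `channels x channels` "connectivity image"
#' with unit diagonal. A zero-variance channel has no defined correlation;
#' by convention its whole row/column (diagonal included) is set to 0 and the
#' result carries a `degenerate_channels` attribute listing it.
#'
#' @param segment numeric matrix `channels x time` (`time >= 2`).
#' @return `channels x channels` correlation matrix, entries in `[-1, 1]`.
#' @export
pcc_matrix <- function(segment) {
  segment <- as.matrix(segment)
  if (ncol(segment) < 2) stopf("need at least 2 time samples for correlation")
  sds <- apply(segment, 1, stats::sd)
  degenerate <- which(sds == 0)
  out <- matrix(0, nrow(segment), nrow(segment))
  ok <- setdiff(seq_len(nrow(segment)), degenerate)
  if (length(ok) > 0) {
    out[ok, ok] <- stats::cor(t(segment[ok, , drop = FALSE]))
  }
  if (length(degenerate) > 0) attr(out, "degenerate_channels") <- degenerate
  out
}

#' Per-segment PCA score image
#'
#' Treats the segment's channels as observations and its time points as
#' variables, and returns the first `k` principal-component scores per
#' channel (a `channels x k` image). The PCA is fitted per segment, so no
#' information crosses segment boundaries. Components are ordered by
#' decreasing variance; the sign of each component is fixed by making its
#' largest-magnitude loading positive. With centered data the channel
#' covariance has rank at most `channels - 1`, so trailing score columns
#' beyond the rank are exactly zero.
#'
#' @param segment numeric matrix `channels x time`.
#' @param k number of components (default and maximum: `channels`).
#' @return `channels x k` score matrix.
#' @export
pca_features <- function(segment, k = nrow(segment)) {
  segment <- as.matrix(segment)
  nc <- nrow(segment)
  if (k > nc) stopf("k = %d exceeds the number of channels (%d)", k, nc)
  xc <- sweep(segment, 2, colMeans(segment))
  eg <- eigen(tcrossprod(xc), symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  dvals <- sqrt(d2)
  tol <- max(dvals) * 1e-10
  scores <- matrix(0, nc, k)
  for (j in seq_len(k)) {
    if (dvals[j] <= tol) next
    u <- eg$vectors[, j]
    loading <- crossprod(xc, u) / dvals[j]
    if (loading[which.max(abs(loading))] < 0) u <- -u
    scores[, j] <- u * dvals[j]
  }
  scores
}

#' Per-channel statistical characteristics
#'
#' Four summary statistics per channel, in the fixed column order
#' (variance, mean, kurtosis, skewness). Moments use population (n)
#' denominators and kurtosis is Fisher excess kurtosis (0 for a normal
#' distribution). A zero-variance channel gets kurtosis and skewness 0 and
#' is listed in a `degenerate_channels` attribute.
#'
#' @param segment numeric matrix `channels x time` (`time >= 4`).
#' @return `channels x 4` matrix with columns
#'   `variance`, `mean`, `kurtosis`, `skewness`.
#' @export
sc_features <- function(segment) {
  segment <- as.matrix(segment)
  if (ncol(segment) < 4) stopf("need at least 4 time samples for 4th-order moments")
  m <- rowMeans(segment)
  xc <- segment - m
  v <- rowMeans(xc^2)
  degenerate <- which(v == 0)
  sk <- ku <- numeric(nrow(segment))
  ok <- v > 0
  sk[ok] <- rowMeans(xc[ok, , drop = FALSE]^3) / v[ok]^1.5
  ku[ok] <- rowMeans(xc[ok, , drop = FALSE]^4) / v[ok]^2 - 3
  out <- cbind(variance = v, mean = m, kurtosis = ku, skewness = sk)
  if (length(degenerate) > 0) attr(out, "degenerate_channels") <- degenerate
  out
}

segment_feature <- function(segment, kind, k = nrow(segment)) {
  switch(kind,
    pcc = pcc_matrix(segment),
    pca = pca_features(segment, k),
    sc = sc_features(segment),
    stopf("unknown feature kind '%s'", kind)
  )
}

#' Stack per-band feature images into a feature tensor
#'
#' Assembles one feature image per (segment, band) into a
#' `samples x bands x H x W` array, aligns labels, and min-max scales the
#' whole tensor to `[0, 1]` (the autoencoder stage reconstructs under binary
#' crossentropy, which needs unit-interval targets). The scaling constants
#' are stored so the transform is invertible.
#'
#' @param band_images list (over bands) of lists (over segments) of equal-size
#'   feature matrices.
#' @param labels integer labels, one per segment.
#' @param kind one of `"pcc"`, `"pca"`, `"sc"`.
#' @param band_edges band edges carried through for provenance.
#' @param provenance optional per-segment provenance data.frame.
#' @return object of class `feature_tensor`: list with `data`
#'   (`[samples, bands, H, W]`, scaled to `[0,1]`), `labels`, `kind`,
#'   `band_edges`, `provenance`, `scale_min`, `scale_max`.
#' @export
stack_bands <- function(band_images, labels, kind, band_edges = NULL,
                        provenance = NULL) {
  nb <- length(band_images)
  n <- length(band_images[[1]])
  if (!all(vapply(band_images, length, 0L) == n)) {
    stopf("all bands must contribute the same number of segments")
  }
  dims <- dim(band_images[[1]][[1]])
  tensor <- array(0, dim = c(n, nb, dims[1], dims[2]))
  for (b in seq_len(nb)) {
    for (i in seq_len(n)) {
      img <- band_images[[b]][[i]]
      if (!all(dim(img) == dims)) stopf("feature image shape mismatch across bands/segments")
      tensor[i, b, , ] <- img
    }
  }
  if (length(labels) != n) stopf("labels length (%d) != sample count (%d)", length(labels), n)
  sc <- minmax_scale(tensor)
  structure(list(
    data = sc$data, labels = as.integer(labels), kind = kind,
    band_edges = band_edges, provenance = provenance,
    scale_min = sc$min, scale_max = sc$max
  ), class = "feature_tensor")
}

#' Compute a feature tensor from a segment set
#'
#' Applies [pcc_matrix()], [pca_features()] or [sc_features()] to every
#' (segment, band) slice of a [segment_windows()] result and stacks the
#' images with [stack_bands()]. For `n` channels the per-band image is
#' `n x n` (pcc, pca) or `n x 4` (sc).
#'
#' @param segs a `segment_set`.
#' @param kind `"pcc"`, `"pca"` or `"sc"`.
#' @return a `feature_tensor`.
#' @export
featurize <- function(segs, kind = c("pcc", "pca", "sc")) {
  stopifnot(inherits(segs, "segment_set"))
  kind <- match.arg(kind)
  d <- dim(segs$data)
  band_images <- lapply(seq_len(d[2]), function(b) {
    lapply(seq_len(d[1]), function(i) {
      segment_feature(segs$data[i, b, , ], kind)
    })
  })
  stack_bands(band_images, segs$labels, kind,
              band_edges = segs$band_edges, provenance = segs$provenance)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_tensor %s> %d samples x %d bands x %d x %d (scaled to [0,1])\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}
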