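# Frozen convolutional feature extractor. The default "tiny_cnn" backbone
# is a three-block convolutional texture encoder with deterministic filter
# banks (fixed at construction from a seed, never trained): conv3x3 ->
# ReLU -> 2x2 max-pool, repeated three times (8, 16, 32 channels), then
# global mean- and max-pooling per channel, giving d = 64 features per
# tile. Training in this package is the linear-probe regime: the
# aggregator's scorer and the classifier learn on top of these frozen
# features. Named deep backbones (resnet18/resnet50/vit) are accepted as
# configuration pass-through for users with their own weights; they are
# not bundled.

#' Backbone configuration
#'
#' @param name `"tiny_cnn"` (bundled, deterministic, no weights to
#'   download) or a pass-through name (`"resnet18"`, `"resnet50"`,
#'   `"vit"`) recording the standard penultimate width.
#' @param input_size side length the backbone expects (tiles are resized
#'   to this before feature extraction); default 64 for `tiny_cnn`, 224
#'   otherwise.
#' @param seed filter-bank seed for `tiny_cnn`.
#' @return a `backbone_config` list with `name`, `d` (feature dimension),
#'   `input_size`, and `filters` for `tiny_cnn`.
#' @export
backbone_config <- function(name = c("tiny_cnn", "resnet18", "resnet50", "vit"),
                            input_size = NULL, seed = 42) {
  name <- match.arg(name)
  d <- switch(name, tiny_cnn = 64L, resnet18 = 512L, resnet50 = 2048L, vit = 768L)
  if (is.null(input_size)) input_size <- if (name == "tiny_cnn") 64L else 224L
  filters <- NULL
  if (name == "tiny_cnn") {
    chans <- c(3L, 8L, 16L, 32L)
    filters <- with_seed(seed, lapply(1:3, function(b) {
      cin <- chans[b]; cout <- chans[b + 1]
      # He-style scaling keeps activations in a stable range
      matrix(stats::rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
    }))
  }
  structure(list(name = name, d = d, input_size = as.integer(input_size),
                 seed = seed, filters = filters),
            class = "backbone_config")
}

# valid 3x3 convolution via im2col: x is H x W x Cin, W_mat is (9*Cin) x Cout
conv3x3 <- function(x, W_mat) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- h - 2L; ow <- w - 2L
  cols <- matrix(0, oh * ow, 9L * cin)
  k <- 1L
  for (ch in seq_len(cin)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        cols[, k] <- as.vector(x[(1 + dy):(oh + dy), (1 + dx):(ow + dx), ch])
        k <- k + 1L
      }
    }
  }
  out <- cols %*% W_mat
  array(out, c(oh, ow, ncol(W_mat)))
}

maxpool2 <- function(x) {
  h <- 2L * (dim(x)[1] %/% 2L); w <- 2L * (dim(x)[2] %/% 2L)
  x <- x[seq_len(h), seq_len(w), , drop = FALSE]
  oi <- seq(1L, h, by = 2L); oj <- seq(1L, w, by = 2L)
  pmax(x[oi, oj, , drop = FALSE], x[oi + 1L, oj, , drop = FALSE],
       x[oi, oj + 1L, , drop = FALSE], x[oi + 1L, oj + 1L, , drop = FALSE])
}

tiny_cnn_features <- function(px, backbone) {
  x <- px / 255
  for (b in 1:3) {
    x <- conv3x3(x, backbone$filters[[b]])
    x <- pmax(x, 0)
    x <- maxpool2(x)
  }
  nchan <- dim(x)[3]
  c(apply(x, 3, mean), apply(x, 3, max))
}

#' Extract instance features for a bag of tiles
#'
#' Runs the backbone over each tile (after resizing to the backbone's
#' input size and scaling intensities to \[0, 1\]) and stacks the feature
#' vectors into an n x d instance-feature matrix. Deterministic: two calls
#' on the same tiles are identical.
#'
#' @param tiles list of H x W x 3 arrays (or `wsi_tile` objects).
#' @param backbone a [backbone_config()]; only `"tiny_cnn"` can be
#'   evaluated by this package (deep backbones are configuration
#'   pass-through for external feature pipelines).
#' @return n x d numeric matrix, one row per tile.
#' @export
extract_features <- function(tiles, backbone = backbone_config()) {
  if (backbone$name != "tiny_cnn") {
    stop(sprintf("backbone '%s' is a pass-through configuration; supply precomputed features or use 'tiny_cnn'",
                 backbone$name), call. = FALSE)
  }
  rows <- lapply(tiles, function(t) {
    px <- if (inherits(t, "wsi_tile")) t$pixels else t
    if (dim(px)[1] != backbone$input_size || dim(px)[2] != backbone$input_size) {
      px <- resize_lanczos(px, backbone$input_size, backbone$input_size)
    }
    tiny_cnn_features(px, backbone)
  })
  do.call(rbind, rows)
}
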