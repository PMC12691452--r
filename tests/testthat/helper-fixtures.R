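# Shared fixtures, all generated in code.

# flat-color H x W x 3 image
flat_img <- function(h, w, value = 128) array(value, c(h, w, 3))

# random RGB image with reproducible content
rand_img <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

# synthetic gaussian feature bags: each class has its own mean vector and
# `n_informative` of the n instances carry it; the rest are background noise
make_feature_bags <- function(n_per_class = 4, n = 10, d = 8,
                              n_informative = 3, sep = 3, seed = 1,
                              classes = histotype_classes(),
                              n_domains = 2) {
  set.seed(seed)
  centers <- matrix(rnorm(length(classes) * d, sd = sep), length(classes), d)
  bags <- list()
  i <- 0L
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      F <- matrix(rnorm(n * d, sd = 1), n, d)
      inf <- seq_len(n_informative)
      F[inf, ] <- F[inf, ] + matrix(centers[ci, ], n_informative, d, byrow = TRUE)
      bags[[i]] <- list(wsi_id = sprintf("bag_%03d", i), label = classes[ci],
                        domain_id = as.integer((r - 1L) %% n_domains) + 1L, features = F)
    }
  }
  bags
}

# random confusion matrix with given class count
rand_cm <- function(C = 5, n = 60, seed = 1) {
  set.seed(seed)
  truth <- sample(letters[1:C], n, replace = TRUE)
  pred <- sample(letters[1:C], n, replace = TRUE)
  confusion_matrix(truth, pred, classes = letters[1:C])
}

# a 513-slide manifest with the curated per-class slide counts
curated_manifest <- function() {
  counts <- c(MC = 41, LGSC = 42, CC = 94, EC = 119, HGSC = 217)
  data.frame(image_id = sprintf("wsi_%03d", seq_len(sum(counts))),
             label = rep(names(counts), counts),
             image_width = 2048L, image_height = 2048L,
             is_tma = FALSE, domain_id = NA_integer_, path = "",
             stringsAsFactors = FALSE)
}
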