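# MIL bag assembly, training augmentations, and dataset / domain splits.

#' Assemble MIL bags from a kept-tile manifest
#'
#' For each slide, `N` brightness-passing tiles are drawn uniformly at
#' random without replacement; a slide with fewer than `N` kept tiles is
#' sampled with replacement and flagged, and a slide with no kept tiles is
#' excluded (with a warning) and listed in the exclusion report. Each bag
#' inherits the single slide-level label (weak supervision).
#'
#' @param tile_manifest data frame with one row per tile and columns
#'   `image_id`, `label`, `domain_id` plus a tile reference column
#'   (`tile_index` or `path`); when a logical `kept` column is present
#'   (as written by [tile_wsi()]), only kept rows are sampled.
#' @param N bag size (default 50).
#' @param seed sampling seed; bags are deterministic in
#'   (manifest, N, seed).
#' @return list with `bags` (list of `wsi_id`, `label`, `domain_id`,
#'   `tile_rows` — row indices into `tile_manifest` —,
#'   `with_replacement`) and `excluded` (character vector of slide ids
#'   with zero kept tiles).
#' @export
build_bags <- function(tile_manifest, N = 50, seed = 1) {
  stopifnot(all(c("image_id", "label") %in% names(tile_manifest)))
  ids <- unique(tile_manifest$image_id)
  keep_row <- if ("kept" %in% names(tile_manifest)) tile_manifest$kept else rep(TRUE, nrow(tile_manifest))
  with_seed(seed, {
    bags <- list()
    excluded <- character(0)
    for (id in ids) {
      rows <- which(tile_manifest$image_id == id & keep_row)
      if (length(rows) == 0L) {
        excluded <- c(excluded, id)
        next
      }
      with_repl <- length(rows) < N
      pick <- if (with_repl) {
        rows[sample.int(length(rows), N, replace = TRUE)]
      } else {
        rows[sample.int(length(rows), N)]
      }
      bags[[length(bags) + 1L]] <- list(
        wsi_id = id,
        label = tile_manifest$label[rows[1]],
        domain_id = if ("domain_id" %in% names(tile_manifest)) tile_manifest$domain_id[rows[1]] else NA_integer_,
        tile_rows = pick,
        with_replacement = with_repl)
    }
    if (length(excluded)) {
      warning("excluded slide(s) with zero kept tiles: ", paste(excluded, collapse = ", "))
    }
    list(bags = bags, excluded = excluded)
  })
}

#' Augmentation configuration
#'
#' Defaults for the training-time transforms (rotation, flips, color
#' jitter, random crop, Gaussian blur). Setting every probability to 0
#' makes training mode identical to evaluation mode.
#'
#' @param p_rotate,rotate_range rotation probability and max |angle| in
#'   degrees.
#' @param p_flip probability of each of horizontal / vertical flip.
#' @param p_jitter,brightness,contrast,saturation color-jitter probability
#'   and maximum relative strengths.
#' @param p_crop,crop_scale random-crop probability and area-scale range.
#' @param p_blur,blur_sigma Gaussian-blur probability and sigma range (px).
#' @return an `augment_config` list.
#' @export
augment_config <- function(p_rotate = 0.5, rotate_range = 90,
                           p_flip = 0.5,
                           p_jitter = 0.5, brightness = 0.2, contrast = 0.2, saturation = 0.2,
                           p_crop = 0.5, crop_scale = c(0.8, 1),
                           p_blur = 0.3, blur_sigma = c(0.1, 2)) {
  structure(as.list(environment()), class = "augment_config")
}

#' Augment one tile and resize it to the model input size
#'
#' Evaluation mode (`training = FALSE`) applies the Lanczos resize to
#' `out_size` only and is fully deterministic. Training mode additionally
#' applies, under `seed`, random rotation, horizontal/vertical flips,
#' color jitter, random crop and Gaussian blur before the resize. Output
#' stays in \[0, 255\]; input normalization is the model's concern.
#'
#' @param tile H x W x 3 array (typically a downscaled 256 x 256 tile) or
#'   `wsi_tile`.
#' @param training apply the stochastic transforms?
#' @param seed RNG seed for training mode (reproducible when given).
#' @param out_size output side length (default 224).
#' @param config an [augment_config()].
#' @return `out_size x out_size x 3` array in \[0, 255\].
#' @export
augment <- function(tile, training = FALSE, seed = NULL, out_size = 224,
                    config = augment_config()) {
  px <- if (inherits(tile, "wsi_tile")) tile$pixels else tile
  if (!training) {
    return(resize_lanczos(px, out_size, out_size))
  }
  apply_transforms <- function() {
    if (stats::runif(1) < config$p_rotate) {
      px <<- rotate_bilinear(px, stats::runif(1, -config$rotate_range, config$rotate_range))
    }
    if (stats::runif(1) < config$p_flip) px <<- px[, dim(px)[2]:1, , drop = FALSE]
    if (stats::runif(1) < config$p_flip) px <<- px[dim(px)[1]:1, , , drop = FALSE]
    if (stats::runif(1) < config$p_jitter) {
      b <- stats::runif(1, 1 - config$brightness, 1 + config$brightness)
      cfac <- stats::runif(1, 1 - config$contrast, 1 + config$contrast)
      sfac <- stats::runif(1, 1 - config$saturation, 1 + config$saturation)
      px <<- px * b
      m <- mean(px)
      px <<- (px - m) * cfac + m
      g <- img_gray(px)
      for (ch in 1:3) px[, , ch] <<- g + (px[, , ch] - g) * sfac
      px <<- pmin(pmax(px, 0), 255)
    }
    if (stats::runif(1) < config$p_crop) {
      sc <- sqrt(stats::runif(1, config$crop_scale[1], config$crop_scale[2]))
      h <- dim(px)[1]; w <- dim(px)[2]
      ch_ <- max(1L, round(h * sc)); cw <- max(1L, round(w * sc))
      y0 <- sample.int(h - ch_ + 1L, 1); x0 <- sample.int(w - cw + 1L, 1)
      px <<- px[y0:(y0 + ch_ - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
    }
    if (stats::runif(1) < config$p_blur) {
      px <<- gaussian_blur(px, stats::runif(1, config$blur_sigma[1], config$blur_sigma[2]))
    }
  }
  if (is.null(seed)) apply_transforms() else with_seed(seed, apply_transforms())
  resize_lanczos(px, out_size, out_size)
}

# largest-remainder allocation of n items over targets proportional to w
largest_remainder <- function(n, w) {
  if (sum(w) == 0) return(rep(0L, length(w)))
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a cohort into train / validation / test
#'
#' Either by ratio (length-2 `c(train, test)` with no validation split, or
#' length-3 `c(train, val, test)`) or by explicit counts (always
#' `c(train, val, test)`). Stratified mode preserves per-class proportions
#' within one slide via largest-remainder allocation.
#'
#' @param manifest cohort manifest (one row per slide; needs `image_id`
#'   and `label`).
#' @param ratio fractional split, ignored when `counts` is given.
#' @param counts explicit integer `c(train, val, test)`; must sum to at
#'   most the cohort size.
#' @param stratify stratify by class label?
#' @param seed assignment seed.
#' @return a `dataset_split` list: `train`, `val`, `test` (disjoint
#'   `image_id` vectors) and `provenance`.
#' @export
make_split <- function(manifest, ratio = c(0.8, 0.2), counts = NULL,
                       stratify = TRUE, seed = 1) {
  n <- nrow(manifest)
  if (is.null(counts)) {
    if (length(ratio) == 2L) ratio <- c(ratio[1], 0, ratio[2])
    if (abs(sum(ratio) - 1) > 1e-8) stop("`ratio` must sum to 1", call. = FALSE)
    counts <- largest_remainder(n, ratio)
  } else {
    counts <- as.integer(counts)
    if (length(counts) != 3L) stop("`counts` must be c(train, val, test)", call. = FALSE)
    if (sum(counts) > n) {
      stop(sprintf("requested %d slides but the cohort has %d", sum(counts), n), call. = FALSE)
    }
  }
  with_seed(seed, {
    assign_pool <- function(ids, k3) {
      ids <- sample(ids)
      list(train = ids[seq_len(k3[1])],
           val = ids[k3[1] + seq_len(k3[2])],
           test = ids[k3[1] + k3[2] + seq_len(k3[3])])
    }
    if (stratify) {
      # class-by-class largest-remainder allocation against remaining pool
      # capacities: pool cardinalities are met exactly while each class
      # stays within one slide of its proportional share per pool
      classes <- unique(manifest$label)
      capacity <- counts
      parts <- list(train = character(0), val = character(0), test = character(0))
      for (cl in classes) {
        ids <- manifest$image_id[manifest$label == cl]
        share <- round(length(ids) * sum(counts) / max(1, nrow(manifest)))
        k3 <- largest_remainder(min(share, length(ids)), capacity)
        if (sum(k3) > length(ids)) k3 <- largest_remainder(length(ids), capacity)
        p <- assign_pool(ids, k3)
        parts$train <- c(parts$train, p$train)
        parts$val <- c(parts$val, p$val)
        parts$test <- c(parts$test, p$test)
        capacity <- capacity - k3
      }
      # top up any shortfall (when sum(counts) < cohort size) from slides
      # not yet assigned
      if (any(capacity > 0)) {
        left <- setdiff(manifest$image_id, unlist(parts))
        left <- sample(left)
        pos <- 1L
        for (j in seq_along(capacity)) {
          if (capacity[j] > 0) {
            nm <- c("train", "val", "test")[j]
            parts[[nm]] <- c(parts[[nm]], left[pos:(pos + capacity[j] - 1L)])
            pos <- pos + capacity[j]
          }
        }
      }
    } else {
      parts <- assign_pool(manifest$image_id, counts)
    }
    structure(list(train = parts$train, val = parts$val, test = parts$test,
                   provenance = list(counts = counts, stratify = stratify, seed = seed)),
              class = "dataset_split")
  })
}

#' Stratified domain splits for intra-domain generalization
#'
#' Assigns slides to `n_domains` institutional domains with per-class
#' stratification (largest remainder: every domain's class histogram is
#' within one slide of the cohort proportions), and records a train/test
#' partition inside each domain. Pool sizes follow the floor-and-remainder
#' rule: the held-out test pool is `ceiling((1 - train_frac) * N)` slides,
#' each pool is divided as `floor(pool / n_domains)` per domain, and the
#' last domain absorbs the remainder — for a 513-slide cohort at 80/20
#' this gives train 102/102/102/104, test 25/25/25/28, domain totals
#' 127/127/127/132.
#'
#' @param manifest cohort manifest (needs `image_id` and `label`).
#' @param n_domains number of domains (default 4).
#' @param train_frac within-domain training fraction (default 0.8).
#' @param seed assignment seed.
#' @return a `domain_split` list: `domains` (per-domain `image_id`
#'   vectors), `train`, `test` (per-domain), `sizes`, `class_histograms`.
#' @export
make_domain_splits <- function(manifest, n_domains = 4, train_frac = 0.8, seed = 1) {
  n <- nrow(manifest)
  classes <- unique(manifest$label)
  if (n < n_domains * length(classes)) {
    deficient <- classes[which.min(vapply(classes, function(cl) sum(manifest$label == cl), integer(1)))]
    stop(sprintf("cohort too small to stratify %d classes over %d domains (class %s is scarcest)",
                 length(classes), n_domains, deficient), call. = FALSE)
  }
  n_test <- as.integer(ceiling((1 - train_frac) * n))
  n_train <- n - n_test
  pool_sizes <- function(total) {
    base <- total %/% n_domains
    c(rep(base, n_domains - 1L), total - base * (n_domains - 1L))
  }
  test_sizes <- pool_sizes(n_test)
  train_sizes <- pool_sizes(n_train)
  sizes <- train_sizes + test_sizes
  with_seed(seed, {
    # class-by-class largest-remainder allocation against the *remaining*
    # domain capacities: domain totals land exactly on `sizes` (the last
    # class fills whatever capacity is left) while every class stays
    # within one slide of its proportional share per domain
    domains <- replicate(n_domains, character(0), simplify = FALSE)
    capacity <- sizes
    for (cl in classes) {
      ids <- sample(manifest$image_id[manifest$label == cl])
      alloc <- largest_remainder(length(ids), capacity)
      pos <- 1L
      for (d in seq_len(n_domains)) {
        if (alloc[d] > 0) {
          domains[[d]] <- c(domains[[d]], ids[pos:(pos + alloc[d] - 1L)])
          pos <- pos + alloc[d]
        }
      }
      capacity <- capacity - alloc
    }
    train <- vector("list", n_domains)
    test <- vector("list", n_domains)
    for (d in seq_len(n_domains)) {
      sub <- manifest[manifest$image_id %in% domains[[d]], , drop = FALSE]
      cl_n <- vapply(classes, function(cl) sum(sub$label == cl), integer(1))
      te_alloc <- largest_remainder(test_sizes[d], cl_n)
      te <- character(0)
      for (ci in seq_along(classes)) {
        ids <- sample(sub$image_id[sub$label == classes[ci]])
        te <- c(te, ids[seq_len(min(te_alloc[ci], length(ids)))])
      }
      # top up if stratified allocation fell short
      short <- test_sizes[d] - length(te)
      if (short > 0) te <- c(te, sample(setdiff(domains[[d]], te), short))
      test[[d]] <- te
      train[[d]] <- setdiff(domains[[d]], te)
    }
    hist <- lapply(domains, function(ids) {
      table(factor(manifest$label[manifest$image_id %in% ids], levels = classes))
    })
    structure(list(domains = domains, train = train, test = test,
                   sizes = sizes, train_sizes = lengths(train), test_sizes = lengths(test),
                   class_histograms = hist,
                   provenance = list(n_domains = n_domains, train_frac = train_frac, seed = seed)),
              class = "domain_split")
  })
}
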