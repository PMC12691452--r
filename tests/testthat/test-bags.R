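tile_manifest_for <- function(ids, kept_per_id, labels = "CC", domains = 1L) {
  labels <- rep_len(labels, length(ids))
  domains <- rep_len(domains, length(ids))
  do.call(rbind, lapply(seq_along(ids), function(i) {
    if (kept_per_id[i] == 0) return(NULL)
    data.frame(image_id = ids[i], label = labels[i], domain_id = domains[i],
               tile_index = seq_len(kept_per_id[i]))
  }))
}

test_that("bag sampling is deterministic, exhaustive at N tiles, flagged below N", {
  tm <- tile_manifest_for(c("w1", "w2", "w3"), c(200, 50, 10), labels = c("CC", "MC", "EC"))
  b1 <- build_bags(tm, N = 50, seed = 7)
  b2 <- build_bags(tm, N = 50, seed = 7)
  expect_identical(b1, b2)
  b3 <- build_bags(tm, N = 50, seed = 8)
  expect_false(identical(b1$bags[[1]]$tile_rows, b3$bags[[1]]$tile_rows))

  # exactly N kept tiles: the bag holds all of them, any seed
  w2rows <- which(tm$image_id == "w2")
  expect_setequal(b1$bags[[2]]$tile_rows, w2rows)
  expect_false(b1$bags[[2]]$with_replacement)
  expect_false(anyDuplicated(b1$bags[[1]]$tile_rows) > 0)

  # fewer than N: sampled with replacement and flagged
  expect_true(b1$bags[[3]]$with_replacement)
  expect_length(b1$bags[[3]]$tile_rows, 50)
  expect_equal(b1$bags[[3]]$label, "EC")
})

test_that("slides with zero kept tiles are excluded with a report", {
  tm <- rbind(cbind(tile_manifest_for("w1", 5), kept = TRUE),
              data.frame(image_id = "w2", label = "CC", domain_id = 1L,
                         tile_index = 1:3, kept = FALSE))
  expect_warning(res <- build_bags(tm, N = 5, seed = 1), "zero kept tiles")
  expect_equal(res$excluded, "w2")
  expect_length(res$bags, 1)
})

test_that("bag-size accounting scales as slides times N", {
  tm <- tile_manifest_for(sprintf("w%02d", 1:12), rep(80, 12))
  res <- build_bags(tm, N = 50, seed = 2)
  expect_equal(sum(lengths(lapply(res$bags, `[[`, "tile_rows"))), 12 * 50)
})

test_that("augmentation is identity-deterministic in eval mode and seeded in training", {
  tile <- rand_img(64, 64, seed = 11)
  e1 <- augment(tile, training = FALSE, out_size = 32)
  e2 <- augment(tile, training = FALSE, out_size = 32)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(32, 32, 3))
  expect_true(all(e1 >= 0 & e1 <= 255))

  # all-zero probabilities: training equals evaluation
  cfg0 <- augment_config(p_rotate = 0, p_flip = 0, p_jitter = 0, p_crop = 0, p_blur = 0)
  t0 <- augment(tile, training = TRUE, seed = 5, out_size = 32, config = cfg0)
  expect_equal(t0, e1)

  # fixed seed reproduces the stochastic transform chain
  a1 <- augment(tile, training = TRUE, seed = 99, out_size = 32)
  a2 <- augment(tile, training = TRUE, seed = 99, out_size = 32)
  expect_identical(a1, a2)
  a3 <- augment(tile, training = TRUE, seed = 100, out_size = 32)
  expect_false(identical(a1, a3))
})

test_that("explicit-count splits reproduce cardinalities exactly and stay disjoint", {
  m <- curated_manifest()
  sp <- make_split(m, counts = c(328, 82, 103), seed = 3)
  expect_length(sp$train, 328)
  expect_length(sp$val, 82)
  expect_length(sp$test, 103)
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(all_ids, m$image_id)

  sp2 <- make_split(m, counts = c(128, 128, 257), seed = 3)
  expect_equal(lengths(sp2[c("train", "val", "test")]),
               c(train = 128, val = 128, test = 257))

  expect_error(make_split(m, counts = c(500, 50, 50)), "has 513")
})

test_that("ratio splits cover the cohort and stratify within one slide", {
  m <- curated_manifest()
  sp <- make_split(m, ratio = c(1, 0), seed = 1)
  expect_length(sp$train, 513)
  expect_length(sp$test, 0)

  # perfectly balanced cohort: per-split class histograms are equal
  bal <- data.frame(image_id = sprintf("b%02d", 1:40),
                    label = rep(histotype_classes(), each = 8))
  spb <- make_split(bal, ratio = c(0.5, 0.5), stratify = TRUE, seed = 2)
  h_train <- table(bal$label[bal$image_id %in% spb$train])
  h_test <- table(bal$label[bal$image_id %in% spb$test])
  expect_equal(as.vector(h_train), rep(4, 5))
  expect_equal(as.vector(h_train), as.vector(h_test))

  # stratification within +/- 1 of proportional share on the skewed cohort
  sp3 <- make_split(m, ratio = c(0.8, 0.2), stratify = TRUE, seed = 4)
  for (cl in unique(m$label)) {
    n_cl <- sum(m$label == cl)
    got <- sum(m$label[m$image_id %in% sp3$train] == cl)
    expect_lt(abs(got - n_cl * length(sp3$train) / 513), 1 + 1e-9)
  }
})

test_that("domain splits reproduce the floor-and-remainder pool sizes", {
  m <- curated_manifest()
  ds <- make_domain_splits(m, n_domains = 4, train_frac = 0.8, seed = 5)
  expect_equal(unname(ds$sizes), c(127, 127, 127, 132))
  expect_equal(unname(ds$train_sizes), c(102, 102, 102, 104))
  expect_equal(unname(ds$test_sizes), c(25, 25, 25, 28))
  expect_equal(sum(ds$train_sizes) + sum(ds$test_sizes), 513)
  expect_equal(sum(ds$train_sizes), 410)
  expect_equal(sum(ds$test_sizes), 103)

  # conservation and disjointness
  all_ids <- unlist(ds$domains)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(all_ids, m$image_id)
  for (d in 1:4) {
    expect_setequal(c(ds$train[[d]], ds$test[[d]]), ds$domains[[d]])
  }
})

test_that("domain assignment is class-stratified within one slide", {
  m <- curated_manifest()
  for (s in 1:3) {
    ds <- make_domain_splits(m, n_domains = 4, seed = s)
    for (d in 1:4) {
      hist_d <- ds$class_histograms[[d]]
      for (cl in names(hist_d)) {
        expected <- ds$sizes[d] * sum(m$label == cl) / nrow(m)
        expect_lt(abs(hist_d[[cl]] - expected), 1 + 1e-9,
                  label = sprintf("seed %d domain %d class %s", s, d, cl))
      }
    }
  }

  # balanced 20-slide cohort over 4 domains: 5 per domain, one per class
  bal <- data.frame(image_id = sprintf("b%02d", 1:20),
                    label = rep(histotype_classes(), each = 4))
  dsb <- make_domain_splits(bal, n_domains = 4, seed = 1)
  expect_equal(unname(lengths(dsb$domains)), rep(5L, 4))
  for (d in 1:4) expect_true(all(dsb$class_histograms[[d]] == 1))

  expect_error(make_domain_splits(bal[1:10, ], n_domains = 4), "too small")
})
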