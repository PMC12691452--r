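test_that("mean and max pooling match brute-force column statistics", {
  F <- rbind(c(1, 3), c(3, 1))
  expect_equal(mean_pool(F)$representation, c(2, 2))
  expect_equal(max_pool(F)$representation, c(3, 3))

  single <- matrix(c(4, 7, 1), 1)
  expect_equal(mean_pool(single)$representation, c(4, 7, 1))
  expect_equal(max_pool(single)$representation, c(4, 7, 1))

  set.seed(1)
  F <- matrix(rnorm(100 * 7), 100, 7)
  oracle_mean <- vapply(1:7, function(j) sum(F[, j]) / 100, numeric(1))
  oracle_max <- vapply(1:7, function(j) max(F[, j]), numeric(1))
  expect_equal(mean_pool(F)$representation, oracle_mean)
  expect_equal(max_pool(F)$representation, oracle_max)

  expect_error(mean_pool(matrix(numeric(0), 0, 3)), "empty")
  expect_error(max_pool(matrix(numeric(0), 0, 3)), "empty")
  expect_error(mean_pool(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("attention scores are a softmax of the gated-tanh scorer", {
  set.seed(2)
  F <- matrix(rnorm(6 * 4), 6, 4)
  P <- attention_params(4, m = 3, seed = 1)

  # w = 0 gives uniform weights regardless of features
  P0 <- P; P0$w[] <- 0
  expect_equal(as.numeric(attention_scores(F, P0)), rep(1 / 6, 6))

  # raw scores (ln 2, 0) -> weights (2/3, 1/3): with d = m = 1, V = 1,
  # w = 1 and zero biases the raw score is tanh(f), so pick f = atanh(.)
  P1 <- structure(list(V = matrix(1, 1, 1), b1 = 0, w = 1, b2 = 0),
                  class = "attention_params")
  F1 <- matrix(c(atanh(log(2)), 0), 2, 1)
  a <- attention_scores(F1, P1, tau = 1)
  expect_equal(attr(a, "raw_scores"), c(log(2), 0))
  expect_equal(as.numeric(a), c(2 / 3, 1 / 3))

  # tau -> large flattens to uniform
  a_flat <- attention_scores(F, P, tau = 1e6)
  expect_lt(max(abs(a_flat - 1 / 6)), 1e-4)

  expect_error(attention_scores(F, P, tau = 0), "positive")
})

test_that("attention pooling equals the explicit weighted sum", {
  set.seed(3)
  F <- matrix(rnorm(8 * 5), 8, 5)
  P <- attention_params(5, m = 4, seed = 2)
  br <- attention_pool(F, P)
  expect_equal(sum(br$attention_weights), 1, tolerance = 1e-9)
  oracle <- colSums(br$attention_weights * F)
  expect_equal(br$representation, oracle, tolerance = 1e-12)

  # identical instances: output equals the common row, weights uniform
  Fi <- matrix(rep(c(1, -2, 0.5, 3, 7), each = 6), 6, 5)
  bri <- attention_pool(Fi, P)
  expect_equal(bri$representation, c(1, -2, 0.5, 3, 7))
  expect_equal(bri$attention_weights, rep(1 / 6, 6))

  # zero scorer reduces to mean pooling
  P0 <- P; P0$w[] <- 0
  expect_equal(attention_pool(F, P0)$representation, mean_pool(F)$representation,
               tolerance = 1e-12)
})

test_that("top-K pooling reduces to attention and mean at K = n", {
  set.seed(4)
  for (rep_i in 1:5) {
    F <- matrix(rnorm(12 * 6), 12, 6)
    P <- attention_params(6, m = 4, seed = rep_i)
    expect_equal(ktop_pool(F, P, K = 12, weighting = "renormalized")$representation,
                 attention_pool(F, P)$representation, tolerance = 1e-6)
    expect_equal(ktop_pool(F, P, K = 12, weighting = "uniform")$representation,
                 mean_pool(F)$representation, tolerance = 1e-6)
  }
})

test_that("top-K selection ranks by raw score with index tie-break", {
  set.seed(5)
  F <- matrix(rnorm(10 * 4), 10, 4)
  P <- attention_params(4, m = 3, seed = 9)
  s <- attr(attention_scores(F, P), "raw_scores")
  br <- ktop_pool(F, P, K = 1)
  expect_equal(br$selected, which.max(s))
  expect_equal(br$representation, F[which.max(s), ])

  # duplicate the top-scoring row: the tie resolves to the lower index
  jmax <- which.max(s)
  Fd <- F[c(jmax, jmax, setdiff(1:10, jmax)[1:2]), ]
  bd <- ktop_pool(Fd, P, K = 1)
  expect_equal(bd$selected, 1L)

  # uniform weighting averages the selected rows
  bu <- ktop_pool(F, P, K = 3, weighting = "uniform")
  expect_equal(bu$representation, colMeans(F[bu$selected, ]))
  expect_equal(sum(bu$attention_weights), 1)

  expect_error(ktop_pool(F, P, K = 11), "K = 11 exceeds the bag size n = 10")
  expect_error(ktop_pool(F, P, K = 0), "positive integer")
})

test_that("aggregators are permutation invariant", {
  set.seed(6)
  F <- matrix(rnorm(9 * 5), 9, 5)
  P <- attention_params(5, m = 4, seed = 3)
  perm <- sample(9)
  Fp <- F[perm, ]
  expect_equal(mean_pool(Fp)$representation, mean_pool(F)$representation)
  expect_equal(max_pool(Fp)$representation, max_pool(F)$representation)
  expect_equal(attention_pool(Fp, P)$representation,
               attention_pool(F, P)$representation, tolerance = 1e-12)
  # no ties among raw scores, so top-K is permutation invariant too
  expect_equal(ktop_pool(Fp, P, K = 3)$representation,
               ktop_pool(F, P, K = 3)$representation, tolerance = 1e-12)
})

test_that("prediction-level max pooling takes per-class maxima", {
  expect_equal(score_max_pool(matrix(c(2, -1, 4), 1)), c(2, -1, 4))
  expect_equal(score_max_pool(rbind(c(5, 0), c(0, 5))), c(5, 5))
  set.seed(7)
  L <- matrix(rnorm(20 * 5), 20, 5)
  expect_equal(score_max_pool(L), vapply(1:5, function(j) max(L[, j]), numeric(1)))
  expect_error(score_max_pool(matrix(numeric(0), 0, 5)), "non-empty")
})

test_that("temperature softmax is normalized, stable, and tau-monotone in entropy", {
  expect_equal(temperature_softmax(c(0, 0), 3.7), c(0.5, 0.5))
  z <- c(1.2, -0.4, 0.3)
  expect_equal(temperature_softmax(z, 1), exp(z) / sum(exp(z)))

  p_big <- temperature_softmax(c(1000, 0), 1)
  expect_true(all(is.finite(p_big)))
  expect_equal(p_big[1], 1, tolerance = 1e-10)

  expect_error(temperature_softmax(z, -1), "positive")

  set.seed(8)
  for (i in 1:10) {
    zz <- rnorm(5, sd = 3)
    ent <- vapply(c(0.1, 0.3, 0.5, 1, 2, 5), function(tt) {
      p <- temperature_softmax(zz, tt)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      -sum(ifelse(p > 0, p * log(p), 0))
    }, numeric(1))
    expect_true(all(diff(ent) >= -1e-12))
  }
})

test_that("the scorer receives gradient through renormalized top-K pooling", {
  # finite-difference contract: perturbing w changes the pooled output
  # whenever K < n and the scores are non-degenerate
  set.seed(9)
  F <- matrix(rnorm(10 * 6), 10, 6)
  P <- attention_params(6, m = 4, seed = 4)
  base <- ktop_pool(F, P, K = 4, weighting = "renormalized")$representation
  Pp <- P
  Pp$w <- P$w + 1e-4
  pert <- ktop_pool(F, Pp, K = 4, weighting = "renormalized")$representation
  expect_gt(max(abs(pert - base)), 0)
  # uniform weighting is locally flat in the scorer (no weight gradient)
  bu <- ktop_pool(F, P, K = 4, weighting = "uniform")$representation
  bu_p <- ktop_pool(F, Pp, K = 4, weighting = "uniform")$representation
  expect_equal(bu, bu_p)
})
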