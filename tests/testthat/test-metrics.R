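test_that("confusion matrix counts exactly", {
  cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"), classes = c("a", "b"))
  expect_equal(unclass(cm)[1, 1], 2)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # binary with one false positive: rows truth, cols predicted
  cm2 <- confusion_matrix(c("p", "p", "n", "n"), c("p", "n", "n", "n"),
                          classes = c("p", "n"))
  expect_equal(unname(unclass(cm2)), rbind(c(1, 1), c(0, 2)))

  set.seed(1)
  truth <- sample(letters[1:4], 200, replace = TRUE)
  pred <- sample(letters[1:4], 200, replace = TRUE)
  cm3 <- confusion_matrix(truth, pred, letters[1:4])
  for (i in 1:4) for (j in 1:4) {
    expect_equal(unclass(cm3)[i, j], sum(truth == letters[i] & pred == letters[j]))
  }
  expect_error(confusion_matrix("a", "z", classes = "a"), "unknown label")
  expect_error(confusion_matrix(c("a", "b"), "a"), "equal length")
})

test_that("basic metrics agree with hand computation from one-vs-rest counts", {
  diagd <- confusion_matrix(rep(letters[1:3], 5), rep(letters[1:3], 5))
  bm <- basic_metrics(diagd)
  expect_equal(unlist(bm[c("accuracy", "precision", "recall", "specificity", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1, f1 = 1))

  # binary cm [[8,2],[3,7]]
  cm <- structure(rbind(c(8, 2), c(3, 7)),
                  dimnames = list(truth = c("x", "y"), predicted = c("x", "y")),
                  class = c("conf_mat", "matrix"))
  bm <- basic_metrics(cm)
  expect_equal(bm$accuracy, 0.75)
  # hand: precision x = 8/11, y = 7/9; recall x = 0.8, y = 0.7 (weighted, equal support)
  expect_equal(bm$precision, (8 / 11 + 7 / 9) / 2)
  expect_equal(bm$recall, 0.75)
  expect_equal(bm$specificity, (7 / 10 + 8 / 10) / 2)

  # macro vs weighted differ on unbalanced matrices
  cmu <- structure(rbind(c(30, 0), c(5, 5)),
                   dimnames = list(truth = c("x", "y"), predicted = c("x", "y")),
                   class = c("conf_mat", "matrix"))
  expect_equal(basic_metrics(cmu, "macro")$recall, (1 + 0.5) / 2)
  expect_equal(basic_metrics(cmu, "weighted")$recall, (30 * 1 + 10 * 0.5) / 40)
})

test_that("accuracy equals support-weighted recall for any confusion matrix", {
  for (s in 1:10) {
    cm <- rand_cm(C = 5, n = 80, seed = s)
    bm <- basic_metrics(cm, averaging = "weighted")
    expect_equal(bm$accuracy, bm$recall, tolerance = 1e-12)
  }
})

test_that("balanced accuracy is the mean of per-class recalls", {
  perfect <- structure(diag(c(50, 50)),
                       dimnames = list(truth = c("x", "y"), predicted = c("x", "y")),
                       class = c("conf_mat", "matrix"))
  expect_equal(balanced_accuracy(perfect), 1)

  onesided <- structure(rbind(c(50, 0), c(50, 0)),
                        dimnames = list(truth = c("x", "y"), predicted = c("x", "y")),
                        class = c("conf_mat", "matrix"))
  expect_equal(balanced_accuracy(onesided), 0.5)

  for (s in 1:5) {
    cm <- rand_cm(C = 5, n = 100, seed = s + 20)
    recalls <- diag(cm) / rowSums(cm)
    expect_equal(balanced_accuracy(cm), mean(recalls))
  }
})

test_that("Cohen's kappa matches the marginal-product definition", {
  perfect <- rand_cm(C = 3, n = 30, seed = 1)
  diag_cm <- structure(diag(c(10, 10, 10)),
                       dimnames = list(truth = letters[1:3], predicted = letters[1:3]),
                       class = c("conf_mat", "matrix"))
  expect_equal(cohens_kappa(diag_cm), 1)

  chance <- structure(matrix(25, 2, 2),
                      dimnames = list(truth = c("x", "y"), predicted = c("x", "y")),
                      class = c("conf_mat", "matrix"))
  expect_equal(cohens_kappa(chance), 0)

  for (s in 1:8) {
    cm <- rand_cm(C = 4, n = 60, seed = s + 5)
    n <- sum(cm)
    po <- sum(diag(cm)) / n
    pe <- sum(rowSums(cm) / n * colSums(cm) / n)
    expect_equal(cohens_kappa(cm), (po - pe) / (1 - pe))
    expect_gte(cohens_kappa(cm), -1)
    expect_lte(cohens_kappa(cm), 1)
  }
})

test_that("binary AUROC equals exhaustive pair counting for n <= 8", {
  set.seed(3)
  for (rep_i in 1:25) {
    n <- sample(3:8, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounding forces occasional ties
    # oracle: fraction of (pos, neg) pairs ranked correctly, ties half credit
    pairs <- expand.grid(i = which(y), j = which(!y))
    oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                          ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(ktopmil:::binary_auroc(s, y), oracle,
                 info = sprintf("rep %d", rep_i))
  }
})

test_that("multiclass AUROC/AUPRC behave at the extremes and match pROC", {
  # perfectly separated
  truth <- rep(c("a", "b"), each = 5)
  probs <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
                 b = c(rep(0.1, 5), rep(0.9, 5)))
  aa <- auroc_auprc(truth, probs)
  expect_equal(aa$auroc, 1)
  expect_equal(aa$auprc, 1)

  # label-independent scores hover near 1/2 (and AUPRC near prevalence)
  set.seed(4)
  n <- 4000
  truth2 <- sample(c("a", "b"), n, replace = TRUE)
  p <- runif(n)
  aa2 <- auroc_auprc(truth2, cbind(a = p, b = 1 - p))
  expect_lt(abs(aa2$auroc - 0.5), 0.05)

  skip_if_not_installed("pROC")
  set.seed(5)
  truth3 <- sample(c("a", "b"), 60, replace = TRUE)
  score <- rnorm(60) + (truth3 == "a")
  ours <- ktopmil:::binary_auroc(score, truth3 == "a")
  ref <- as.numeric(pROC::auc(pROC::roc(truth3 == "a", score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)

  expect_error(auroc_auprc(rep("a", 4), probs[1:4, ]), "fewer than 2")
})

test_that("average precision matches a small hand-worked case", {
  # scores descending: pos, neg, pos, neg -> AP = 1/2 * 1 + 1/2 * 2/3
  s <- c(0.9, 0.8, 0.7, 0.1)
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(ktopmil:::binary_auprc(s, y), 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("class order permutation leaves averaged metrics unchanged", {
  set.seed(6)
  truth <- sample(letters[1:4], 120, replace = TRUE)
  pred <- sample(letters[1:4], 120, replace = TRUE)
  probs <- matrix(runif(120 * 4), 120, 4)
  probs <- probs / rowSums(probs)
  colnames(probs) <- letters[1:4]
  r1 <- metric_report(truth, pred, probs, classes = letters[1:4])
  perm <- c("c", "a", "d", "b")
  r2 <- metric_report(truth, pred, probs[, perm], classes = perm)
  for (f in c("accuracy", "precision", "recall", "f1", "balanced_accuracy",
              "cohens_kappa", "auroc", "auprc")) {
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-12, info = f)
  }
})

test_that("reports serialize to JSON and CSV in the standard column order", {
  dir <- withr::local_tempdir()
  r <- metric_report(c("a", "b", "a", "b"), c("a", "b", "b", "b"))
  csv <- file.path(dir, "rep.csv")
  write_metric_report(r, csv)
  got <- read.csv(csv, check.names = FALSE)
  expect_equal(names(got), c("Accuracy", "Precision", "Recall", "F1-Score",
                             "BlAcc", "Ch. Kappa", "AUROC", "AUPRC"))
  expect_equal(got$Accuracy, 0.75)
  js <- file.path(dir, "rep.json")
  write_metric_report(r, js)
  expect_equal(jsonlite::read_json(js)$Accuracy, 0.75)
})
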