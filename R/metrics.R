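# Confusion-matrix evaluation suite: accuracy, precision, recall,
# specificity, F1, balanced accuracy, Cohen's kappa, and one-vs-rest
# AUROC / AUPRC for the five-class bag-level task.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `classes`.
#'
#' @param truth,pred vectors of class labels (character or factor), equal
#'   length.
#' @param classes class order; defaults to the union of observed levels.
#' @return C x C integer matrix of counts with class `conf_mat`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) stop("truth and pred must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(truth = classes, predicted = classes)
  structure(cm, class = c("conf_mat", class(cm)))
}

# per-class one-vs-rest counts from a confusion matrix
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  data.frame(class = rownames(cm), tp = tp, fp = fp, fn = fn, tn = tn,
             support = rowSums(cm), row.names = NULL)
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Confusion-matrix metrics
#'
#' Per-class one-vs-rest precision, recall (TPR), specificity (TNR) and F1
#' are derived from the confusion matrix and then averaged, weighted by
#' class support by default (under which the averaged recall equals the
#' overall accuracy, an algebraic identity) or unweighted (`"macro"`).
#' Zero-denominator cases contribute 0.
#'
#' @param cm a [confusion_matrix()].
#' @param averaging `"weighted"` (by support) or `"macro"`.
#' @return list with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`, the `per_class` data frame and the averaging scheme.
#' @export
basic_metrics <- function(cm, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  k <- ovr_counts(cm)
  k$precision <- safe_div(k$tp, k$tp + k$fp)
  k$recall <- safe_div(k$tp, k$tp + k$fn)
  k$specificity <- safe_div(k$tn, k$tn + k$fp)
  k$f1 <- safe_div(2 * k$precision * k$recall, k$precision + k$recall)
  w <- if (averaging == "weighted") k$support / sum(k$support) else rep(1 / nrow(k), nrow(k))
  list(accuracy = sum(diag(cm)) / sum(cm),
       precision = sum(w * k$precision),
       recall = sum(w * k$recall),
       specificity = sum(w * k$specificity),
       f1 = sum(w * k$f1),
       per_class = k,
       averaging = averaging)
}

#' Balanced accuracy
#'
#' Unweighted mean of the per-class recalls; in the binary case this is
#' exactly (TPR + TNR) / 2. A class with zero support contributes recall 0
#' (with a warning), which keeps the identity accuracy = weighted recall
#' intact.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  k <- ovr_counts(cm)
  if (any(k$support == 0)) {
    warning("class(es) with zero support contribute recall 0: ",
            paste(k$class[k$support == 0], collapse = ", "))
  }
  mean(safe_div(k$tp, k$tp + k$fn))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` where `Po` is the
#' observed agreement (accuracy) and `Pe` the expected agreement from the
#' row/column marginals. The degenerate case `Pe = 1` is defined as 1 if
#' `Po = 1` and 0 otherwise, with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return numeric scalar in \[-1, 1\].
#' @export
cohens_kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) {
    warning("chance agreement Pe = 1; kappa degenerate")
    return(if (abs(po - 1) < 1e-12) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

# Binary AUROC from scores: Mann-Whitney statistic with 1/2 credit for
# ties, identical to the trapezoidal area under the ROC curve.
binary_auroc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Binary average precision (step-wise PR integration, ties grouped).
binary_auprc <- function(scores, positive) {
  n_pos <- sum(positive)
  if (n_pos == 0 || all(positive)) return(NA_real_)
  o <- order(-scores)
  s <- scores[o]; y <- positive[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Multiclass AUROC and AUPRC (one-vs-rest, macro-averaged)
#'
#' Per-class one-vs-rest areas computed from the probability columns and
#' macro-averaged. Classes absent from the truth are skipped with a
#' warning.
#'
#' @param truth vector of true labels.
#' @param probs n x C probability matrix with columns named (or ordered) by
#'   `classes`; rows should sum to 1.
#' @param classes class order; defaults to `colnames(probs)`.
#' @return list with elements `auroc` and `auprc`.
#' @export
auroc_auprc <- function(truth, probs, classes = colnames(probs)) {
  truth <- as.character(truth)
  if (is.null(classes)) stop("`classes` required when probs has no column names", call. = FALSE)
  if (length(unique(truth)) < 2L) {
    stop("AUROC undefined: fewer than 2 distinct classes in truth", call. = FALSE)
  }
  probs <- as.matrix(probs)
  missing_cls <- setdiff(classes, unique(truth))
  if (length(missing_cls)) {
    warning("class(es) absent from truth skipped: ", paste(missing_cls, collapse = ", "))
  }
  present <- intersect(classes, unique(truth))
  roc <- vapply(present, function(cl) {
    binary_auroc(probs[, match(cl, classes)], truth == cl)
  }, numeric(1))
  pr <- vapply(present, function(cl) {
    binary_auprc(probs[, match(cl, classes)], truth == cl)
  }, numeric(1))
  list(auroc = mean(roc, na.rm = TRUE), auprc = mean(pr, na.rm = TRUE))
}

#' Full metric report
#'
#' Convenience wrapper computing the whole evaluation suite from labels,
#' predictions and (optionally) class probabilities.
#'
#' @param truth,pred label vectors.
#' @param probs optional n x C probability matrix for AUROC/AUPRC.
#' @param classes class order.
#' @return a `metric_report` list with fields `accuracy`, `precision`,
#'   `recall`, `specificity`, `f1`, `balanced_accuracy`, `cohens_kappa`,
#'   `auroc`, `auprc`, the confusion matrix, and the averaging scheme.
#' @export
metric_report <- function(truth, pred, probs = NULL, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (!is.null(probs) && !is.null(colnames(probs))) colnames(probs) else sort(unique(as.character(truth)))
  }
  cm <- confusion_matrix(truth, pred, classes)
  bm <- basic_metrics(cm)
  ba <- suppressWarnings(balanced_accuracy(cm))
  kap <- cohens_kappa(cm)
  aa <- if (!is.null(probs)) suppressWarnings(auroc_auprc(truth, probs, classes)) else list(auroc = NA_real_, auprc = NA_real_)
  structure(list(accuracy = bm$accuracy, precision = bm$precision,
                 recall = bm$recall, specificity = bm$specificity, f1 = bm$f1,
                 balanced_accuracy = ba, cohens_kappa = kap,
                 auroc = aa$auroc, auprc = aa$auprc,
                 confusion = cm, averaging = bm$averaging),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("MIL evaluation report (averaging:", x$averaging, ")\n")
  vals <- unlist(x[c("accuracy", "precision", "recall", "f1",
                     "balanced_accuracy", "cohens_kappa", "auroc", "auprc")])
  print(round(vals, 4))
  invisible(x)
}

#' Serialize a metric report
#'
#' Writes the scalar metrics as JSON or a single-row CSV in the standard
#' column order (Accuracy, Precision, Recall, F1-Score, BlAcc, Ch. Kappa,
#' AUROC, AUPRC).
#'
#' @param report a [metric_report()].
#' @param path output file; format from extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  row <- data.frame(Accuracy = report$accuracy, Precision = report$precision,
                    Recall = report$recall, `F1-Score` = report$f1,
                    BlAcc = report$balanced_accuracy,
                    `Ch. Kappa` = report$cohens_kappa,
                    AUROC = report$auroc, AUPRC = report$auprc,
                    check.names = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(row, path, row.names = FALSE)
  }
  invisible(path)
}
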