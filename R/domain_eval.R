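# Leave-one-domain-out intra-domain generalization protocol: per-domain
# metric quadruples, domain gaps against the best-performing domain,
# delta tables against a source domain and a best reference accuracy, and
# mean +/- sd summaries.

#' Leave-one-domain-out cross-domain evaluation
#'
#' For each domain D, a fresh model is trained on the bags of every other
#' domain and evaluated on D's bags, giving one
#' (accuracy, balanced accuracy, AUROC, F1) quadruple per domain, in
#' percent.
#'
#' @param bags list of feature bags (each with `features`, `label`,
#'   `wsi_id`, `domain_id`).
#' @param model_factory function(seed) returning a fresh [mil_model()]
#'   matched to the bag feature dimension.
#' @param config a [train_config()].
#' @return data frame with columns `domain_id`, `accuracy`,
#'   `balanced_accuracy`, `auroc`, `f1` (percentages), one row per domain.
#' @export
run_cross_domain <- function(bags, model_factory, config = train_config()) {
  doms <- vapply(bags, function(b) as.integer(b$domain_id), integer(1))
  u <- sort(unique(doms))
  if (length(u) < 2L) stop("need at least 2 domains", call. = FALSE)
  rows <- lapply(u, function(d) {
    test_idx <- which(doms == d)
    train_bags <- bags[doms != d]
    if (!length(test_idx)) stop(sprintf("domain %d has no test bags", d), call. = FALSE)
    fit <- train_mil(train_bags, model_factory(config$seed + d), config)
    ev <- evaluate_mil(fit$model, bags[test_idx])
    data.frame(domain_id = d,
               accuracy = 100 * ev$report$accuracy,
               balanced_accuracy = 100 * ev$report$balanced_accuracy,
               auroc = 100 * ev$report$auroc,
               f1 = 100 * ev$report$f1)
  })
  do.call(rbind, rows)
}

#' Domain gaps against the best-performing domain
#'
#' The gap of domain D is the best domain's accuracy minus D's accuracy,
#' in percentage points; the reference (best) domain's own gap is NA
#' (printed "-"). The maximum gap equals the range of the accuracies.
#'
#' @param results data frame with `domain_id` and `accuracy` (percent), or
#'   a named numeric accuracy vector.
#' @return list with `reference_domain`, `reference_accuracy`, `gaps`
#'   (data frame: domain_id, accuracy, gap) and `max_gap`.
#' @export
domain_gaps <- function(results) {
  if (!is.data.frame(results)) {
    results <- data.frame(domain_id = seq_along(results), accuracy = as.numeric(results))
  }
  if (nrow(results) < 2L) stop("need at least 2 domain results", call. = FALSE)
  ref <- which.max(results$accuracy)
  gap <- results$accuracy[ref] - results$accuracy
  gap[ref] <- NA_real_
  list(reference_domain = results$domain_id[ref],
       reference_accuracy = results$accuracy[ref],
       gaps = data.frame(domain_id = results$domain_id,
                         accuracy = results$accuracy, gap = gap),
       max_gap = results$accuracy[ref] - min(results$accuracy))
}

consistency_label <- function(delta) {
  ifelse(is.na(delta), "-", ifelse(delta <= 9, "high", "medium"))
}

#' Delta table against a source domain and a best reference accuracy
#'
#' `Delta1(D)` is the source domain's accuracy minus D's accuracy (the
#' source row itself gets NA, printed "-"); `Delta2(D)` is an externally
#' supplied best reference accuracy minus D's accuracy. Each delta is
#' labelled `high` consistency when it lies in \[0, 9\] percentage points
#' and `medium` above 9.
#'
#' @param results data frame with `domain_id` and `accuracy` (percent).
#' @param source_domain the source domain id (its accuracy anchors
#'   Delta1).
#' @param best_accuracy reference accuracy for Delta2 (percent), e.g. the
#'   best accuracy observed across a whole study.
#' @return data frame: domain_id, accuracy, delta1, delta2,
#'   consistency (the "(Delta1-label, Delta2-label)" pair).
#' @export
delta_table <- function(results, source_domain, best_accuracy) {
  src <- match(source_domain, results$domain_id)
  if (is.na(src)) stop("source domain not present in results", call. = FALSE)
  d1 <- results$accuracy[src] - results$accuracy
  d1[src] <- NA_real_
  d2 <- best_accuracy - results$accuracy
  data.frame(domain_id = results$domain_id, accuracy = results$accuracy,
             delta1 = d1, delta2 = d2,
             consistency = paste0("(", consistency_label(d1), ", ",
                                  consistency_label(d2), ")"))
}

#' Mean and sample standard deviation per domain metric
#'
#' The "Average" row of a per-domain results table: arithmetic mean and
#' sample (n-1) standard deviation for each metric column, and for the
#' gap column with the reference domain's NA entry excluded.
#'
#' @param results data frame of per-domain metrics (percent).
#' @param gaps optional gap vector or the `gaps` data frame from
#'   [domain_gaps()]; NA entries are dropped.
#' @return data frame: metric, mean, sd.
#' @export
summarize_domains <- function(results, gaps = NULL) {
  cols <- setdiff(names(results), "domain_id")
  cols <- cols[vapply(results[cols], is.numeric, logical(1))]
  out <- data.frame(metric = cols,
                    mean = vapply(cols, function(cl) mean(results[[cl]]), numeric(1)),
                    sd = vapply(cols, function(cl) stats::sd(results[[cl]]), numeric(1)),
                    row.names = NULL)
  if (!is.null(gaps)) {
    g <- if (is.data.frame(gaps)) gaps$gap else gaps
    g <- g[!is.na(g)]
    out <- rbind(out, data.frame(metric = "gap", mean = mean(g), sd = stats::sd(g)))
  }
  out
}
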