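# MIL aggregation operators. An instance-feature matrix F is n x d (one row
# per tile); an aggregator maps it to a single d-vector bag representation,
# optionally with per-instance attention weights.

check_feature_matrix <- function(F) {
  if (!is.matrix(F) || !is.numeric(F)) stop("instance features must be a numeric matrix", call. = FALSE)
  if (nrow(F) < 1L) stop("instance feature matrix is empty (n must be >= 1)", call. = FALSE)
  if (!all(is.finite(F))) stop("instance features contain non-finite values", call. = FALSE)
  invisible(F)
}

bag_repr <- function(rep, weights = NULL, selected = NULL) {
  structure(list(representation = as.numeric(rep),
                 attention_weights = weights,
                 selected = selected),
            class = "bag_repr")
}

softmax_stable <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Mean pooling over bag instances
#'
#' The bag representation is the column mean of the instance features:
#' every tile contributes equally, so sparse diagnostic signal is diluted
#' by background instances.
#'
#' @param F n x d numeric instance-feature matrix.
#' @return a `bag_repr`: list with `representation` (d-vector),
#'   `attention_weights` (NULL here) and `selected` (NULL here).
#' @export
mean_pool <- function(F) {
  check_feature_matrix(F)
  bag_repr(colMeans(F))
}

#' Element-wise max pooling over bag instances
#'
#' Each coordinate of the bag representation is the maximum of that feature
#' over all instances (coordinates may come from different tiles).
#'
#' @inheritParams mean_pool
#' @return a `bag_repr`.
#' @export
max_pool <- function(F) {
  check_feature_matrix(F)
  bag_repr(apply(F, 2, max))
}

#' Gated-tanh attention scorer parameters
#'
#' The instance scorer is a two-layer network
#' `s_j = w' tanh(V f_j + b1) + b2` with hidden width `m`; `b2` and `b1`
#' default to zero at initialization so the bias-free form is recovered
#' exactly when they stay zero.
#'
#' @param d feature dimension.
#' @param m attention hidden dimension.
#' @param seed integer seed for the random initialization.
#' @return an `attention_params` list with elements `V` (m x d), `b1`
#'   (m-vector), `w` (m-vector), `b2` (scalar).
#' @export
attention_params <- function(d, m = 64, seed = 1) {
  stopifnot_scalar_number(d, "d", positive = TRUE)
  stopifnot_scalar_number(m, "m", positive = TRUE)
  with_seed(seed, {
    structure(list(
      V = matrix(stats::rnorm(m * d, sd = 1 / sqrt(d)), m, d),
      b1 = numeric(m),
      w = stats::rnorm(m, sd = 1 / sqrt(m)),
      b2 = 0
    ), class = "attention_params")
  })
}

# Raw (pre-softmax) instance scores s_j = w' tanh(V f_j + b1) + b2.
attention_raw_scores <- function(F, params) {
  h <- tanh(F %*% t(params$V) + matrix(params$b1, nrow(F), length(params$b1), byrow = TRUE))
  as.vector(h %*% params$w) + params$b2
}

#' Attention weights over bag instances
#'
#' Computes raw scores `s_j = w' tanh(V f_j + b1) + b2` and converts them to
#' weights `alpha = softmax(s / tau)` across the bag. The weights are
#' non-negative and sum to one.
#'
#' @inheritParams mean_pool
#' @param params an [attention_params()] object.
#' @param tau positive softmax temperature (default 1).
#' @return numeric n-vector of weights summing to 1; raw scores attached as
#'   attribute `"raw_scores"`.
#' @export
attention_scores <- function(F, params, tau = 1) {
  check_feature_matrix(F)
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  s <- attention_raw_scores(F, params)
  structure(softmax_stable(s / tau), raw_scores = s)
}

#' Attention pooling
#'
#' Weighted instance average `B = sum_j alpha_j f_j` with weights from
#' [attention_scores()]. With a zero scorer (`w = 0`) the weights are
#' uniform and the result equals [mean_pool()].
#'
#' @inheritParams attention_scores
#' @return a `bag_repr` with `attention_weights` filled in.
#' @export
attention_pool <- function(F, params, tau = 1) {
  alpha <- attention_scores(F, params, tau)
  bag_repr(as.vector(t(F) %*% as.numeric(alpha)), weights = as.numeric(alpha))
}

#' Top-K attention pooling over a learned instance scorer
#'
#' Instances are ranked by the raw scorer `s_j` (descending; ties broken by
#' lower instance index) and the top `K` are aggregated:
#' \describe{
#'   \item{`renormalized` (default)}{softmax weights over the selected
#'     scores (equivalently, the full-bag softmax renormalized over the
#'     selected set), so the scorer keeps receiving gradient;}
#'   \item{`uniform`}{plain mean of the selected feature rows.}
#' }
#' With `K = n`, `renormalized` reduces exactly to [attention_pool()] and
#' `uniform` to [mean_pool()].
#'
#' @inheritParams attention_scores
#' @param K number of instances to keep (1 <= K <= n).
#' @param weighting `"renormalized"` or `"uniform"`.
#' @return a `bag_repr`; `attention_weights` is a full n-vector (zero off
#'   the selected set) and `selected` holds the selected instance indices
#'   in rank order.
#' @export
ktop_pool <- function(F, params, K = 5, tau = 1,
                      weighting = c("renormalized", "uniform")) {
  check_feature_matrix(F)
  weighting <- match.arg(weighting)
  n <- nrow(F)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("`K` must be a positive integer", call. = FALSE)
  }
  if (K > n) stop(sprintf("K = %d exceeds the bag size n = %d", K, n), call. = FALSE)
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  s <- attention_raw_scores(F, params)
  sel <- order(-s, seq_len(n))[seq_len(K)]
  w_full <- numeric(n)
  if (weighting == "renormalized") {
    a <- softmax_stable(s[sel] / tau)
  } else {
    a <- rep(1 / K, K)
  }
  w_full[sel] <- a
  rep <- as.vector(t(F[sel, , drop = FALSE]) %*% a)
  bag_repr(rep, weights = w_full, selected = sel)
}

#' Prediction-level max pooling
#'
#' The no-attention baseline: instance-level class logits are computed
#' first and the bag logit for each class is the maximum over instances.
#' This operates on predictions, unlike the feature-level [max_pool()].
#'
#' @param instance_logits n x C numeric matrix of per-instance class logits.
#' @return numeric C-vector of bag logits.
#' @export
score_max_pool <- function(instance_logits) {
  if (!is.matrix(instance_logits) || nrow(instance_logits) < 1L) {
    stop("`instance_logits` must be a non-empty n x C matrix", call. = FALSE)
  }
  apply(instance_logits, 2, max)
}

#' Temperature-scaled softmax
#'
#' `p_i = exp(z_i / tau) / sum_j exp(z_j / tau)`, stabilized by subtracting
#' the maximum before exponentiation. `tau = 1` is the ordinary softmax;
#' larger `tau` flattens the distribution (higher entropy), smaller `tau`
#' sharpens it.
#'
#' @param z numeric logit vector.
#' @param tau positive temperature.
#' @return probability vector summing to 1.
#' @export
temperature_softmax <- function(z, tau = 1) {
  stopifnot_scalar_number(tau, "tau", positive = TRUE)
  softmax_stable(z / tau)
}

#' Aggregator configuration
#'
#' @param kind one of `"ktop"`, `"mean"`, `"max"`, `"attention"`,
#'   `"score_max"`.
#' @param k top-K cutoff (used by `"ktop"`).
#' @param temperature classifier softmax temperature tau.
#' @param ktop_weighting `"renormalized"` or `"uniform"`.
#' @param attention_temperature temperature applied inside the attention
#'   softmax (kept at 1 by default; calibration sweeps scale the classifier
#'   softmax only).
#' @return an `aggregator_config` list.
#' @export
aggregator_config <- function(kind = c("ktop", "mean", "max", "attention", "score_max"),
                              k = 5, temperature = 1,
                              ktop_weighting = c("renormalized", "uniform"),
                              attention_temperature = 1) {
  kind <- match.arg(kind)
  ktop_weighting <- match.arg(ktop_weighting)
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  stopifnot_scalar_number(attention_temperature, "attention_temperature", positive = TRUE)
  if (kind == "ktop") stopifnot_scalar_number(k, "k", positive = TRUE)
  structure(list(kind = kind, k = as.integer(k), temperature = temperature,
                 ktop_weighting = ktop_weighting,
                 attention_temperature = attention_temperature),
            class = "aggregator_config")
}
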