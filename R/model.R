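# End-to-end MIL classifier: frozen-backbone instance features ->
# aggregator -> linear classifier -> temperature-scaled softmax, trained
# with cross-entropy, AdamW and a one-cycle learning-rate schedule. The
# trainable parameters are the gated-tanh scorer (V, b1, w, b2) and the
# linear classifier (W, b); gradients are computed analytically.

#' MIL model
#'
#' The scorer head `w` is initialized near zero, so the initial attention
#' distribution is effectively uniform and attention/top-K pooling starts
#' out as mean pooling, sharpening only as the loss demands; the linear
#' classifier starts at zero (standard for a linear probe). Both choices
#' stabilize the early training of attention-style aggregators.
#'
#' @param d instance feature dimension.
#' @param classes class labels (default the five histotypes).
#' @param aggregator an [aggregator_config()].
#' @param m attention hidden width.
#' @param seed parameter initialization seed.
#' @return a `mil_model` list: `params` (V, b1, w, b2, W, b), `classes`,
#'   `aggregator`, `d`, `m`.
#' @export
mil_model <- function(d, classes = histotype_classes(),
                      aggregator = aggregator_config(), m = 64, seed = 1) {
  C <- length(classes)
  ap <- attention_params(d, m, seed = seed)
  structure(list(params = list(V = ap$V, b1 = ap$b1, w = 0.01 * ap$w, b2 = ap$b2,
                               W = matrix(0, C, d), b = numeric(C)),
                 classes = classes, aggregator = aggregator,
                 d = d, m = m),
            class = "mil_model")
}

model_attention_params <- function(model) {
  structure(model$params[c("V", "b1", "w", "b2")], class = "attention_params")
}

#' Forward pass for one bag
#'
#' Aggregates the instance features per the model's aggregator, applies
#' the linear classifier, and converts logits to probabilities with the
#' temperature-scaled softmax. In `score_max` mode, per-instance logits
#' are computed first and the bag logit per class is their maximum.
#'
#' @param model a [mil_model()].
#' @param F n x d instance-feature matrix.
#' @param tau optional temperature overriding the aggregator config
#'   (calibration sweeps).
#' @return list with `logits` (C-vector), `prob` (probabilities),
#'   `pred` (class label), `attention_weights` (or NULL), `selected`
#'   (top-K indices or NULL), `bag_repr`.
#' @export
forward_bag <- function(model, F, tau = NULL) {
  check_feature_matrix(F)
  if (ncol(F) != model$d) {
    stop(sprintf("feature dimension %d does not match model d = %d", ncol(F), model$d), call. = FALSE)
  }
  cfg <- model$aggregator
  if (is.null(tau)) tau <- cfg$temperature
  p <- model$params
  ap <- model_attention_params(model)
  if (cfg$kind == "score_max") {
    inst_logits <- F %*% t(p$W) + matrix(p$b, nrow(F), length(p$b), byrow = TRUE)
    z <- score_max_pool(inst_logits)
    br <- NULL; aw <- NULL; sel <- NULL; B <- NULL
  } else {
    br <- switch(cfg$kind,
      mean = mean_pool(F),
      max = max_pool(F),
      attention = attention_pool(F, ap, cfg$attention_temperature),
      ktop = ktop_pool(F, ap, K = min(cfg$k, nrow(F)), tau = cfg$attention_temperature,
                       weighting = cfg$ktop_weighting))
    B <- br$representation
    aw <- br$attention_weights
    sel <- br$selected
    z <- as.vector(p$W %*% B) + p$b
  }
  prob <- temperature_softmax(z, tau)
  names(z) <- names(prob) <- model$classes
  list(logits = z, prob = prob, pred = model$classes[which.max(prob)],
       attention_weights = aw, selected = sel, bag_repr = B)
}

#' Mean cross-entropy over a batch of bags
#'
#' `L = (1/N) sum_i -log p_i[y_i]`: the average bag-level cross-entropy
#' between predicted class probabilities and the true bag labels. A
#' uniform 5-class predictor scores exactly `log(5)`.
#'
#' @param predictions N x C probability matrix (rows sum to 1), columns
#'   named or ordered by `classes`.
#' @param truth vector of true bag labels.
#' @param classes class order (default: column names of `predictions`).
#' @return mean cross-entropy (non-negative scalar).
#' @export
bag_loss <- function(predictions, truth, classes = colnames(predictions)) {
  predictions <- rbind(predictions)
  if (is.null(classes)) stop("`classes` required when predictions has no column names", call. = FALSE)
  idx <- match(as.character(truth), classes)
  if (anyNA(idx)) {
    stop(sprintf("label(s) outside class set: %s",
                 paste(unique(truth[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  p <- predictions[cbind(seq_along(idx), idx)]
  mean(-log(pmax(p, 1e-300)))
}

# loss and analytic gradients for one bag; returns list(loss, grads)
bag_grad <- function(model, F, label_idx) {
  cfg <- model$aggregator
  p <- model$params
  tau <- cfg$temperature
  n <- nrow(F); C <- nrow(p$W)
  g <- list(V = 0 * p$V, b1 = 0 * p$b1, w = 0 * p$w, b2 = 0,
            W = 0 * p$W, b = 0 * p$b)
  onehot <- numeric(C); onehot[label_idx] <- 1

  if (cfg$kind == "score_max") {
    inst <- F %*% t(p$W) + matrix(p$b, n, C, byrow = TRUE)
    jstar <- apply(inst, 2, which.max)
    z <- inst[cbind(jstar, seq_len(C))]
    zs <- z / tau
    prob <- softmax_stable(zs)
    loss <- -zs[label_idx] + log(sum(exp(zs - max(zs)))) + max(zs)
    dz <- (prob - onehot) / tau
    for (cc in seq_len(C)) {
      g$W[cc, ] <- dz[cc] * F[jstar[cc], ]
      g$b[cc] <- dz[cc]
    }
    return(list(loss = loss, grads = g))
  }

  ap <- model_attention_params(model)
  ta <- cfg$attention_temperature
  h <- NULL; alpha <- NULL; sel <- NULL
  if (cfg$kind == "mean") {
    B <- colMeans(F)
  } else if (cfg$kind == "max") {
    B <- apply(F, 2, max)
  } else {
    h <- tanh(F %*% t(p$V) + matrix(p$b1, n, model$m, byrow = TRUE))
    s <- as.vector(h %*% p$w) + p$b2
    if (cfg$kind == "attention") {
      sel <- seq_len(n)
      alpha <- softmax_stable(s[sel] / ta)
    } else {
      K <- min(cfg$k, n)
      sel <- order(-s, seq_len(n))[seq_len(K)]
      alpha <- if (cfg$ktop_weighting == "renormalized") {
        softmax_stable(s[sel] / ta)
      } else {
        rep(1 / K, K)
      }
    }
    B <- as.vector(t(F[sel, , drop = FALSE]) %*% alpha)
  }

  z <- as.vector(p$W %*% B) + p$b
  zs <- z / tau
  prob <- softmax_stable(zs)
  loss <- -zs[label_idx] + log(sum(exp(zs - max(zs)))) + max(zs)
  dz <- (prob - onehot) / tau
  g$W <- dz %o% B
  g$b <- dz
  dB <- as.vector(t(p$W) %*% dz)

  scorer_grad <- cfg$kind %in% c("attention", "ktop") &&
    !(cfg$kind == "ktop" && cfg$ktop_weighting == "uniform")
  if (scorer_grad) {
    Fsel <- F[sel, , drop = FALSE]
    dalpha <- as.vector(Fsel %*% dB)
    ds_sel <- alpha * (dalpha - sum(alpha * dalpha)) / ta
    hsel <- h[sel, , drop = FALSE]
    g$w <- as.vector(t(hsel) %*% ds_sel)
    g$b2 <- sum(ds_sel)
    dpre <- (ds_sel %o% p$w) * (1 - hsel^2)
    g$V <- t(dpre) %*% Fsel
    g$b1 <- colSums(dpre)
  }
  list(loss = loss, grads = g)
}

# One-cycle learning rate: cosine warmup to max_lr over pct_start of the
# run, then cosine annealing down to max_lr / final_div.
onecycle_lr <- function(step, total_steps, max_lr, pct_start = 0.3,
                        div_factor = 25, final_div = 1e4) {
  if (total_steps <= 1) return(max_lr)
  frac <- (step - 1) / (total_steps - 1)
  cos_interp <- function(a, b, t) b + (a - b) * (1 + cos(pi * t)) / 2
  if (frac <= pct_start) {
    cos_interp(max_lr / div_factor, max_lr, frac / pct_start)
  } else {
    cos_interp(max_lr, max_lr / final_div, (frac - pct_start) / (1 - pct_start))
  }
}

#' Training configuration
#'
#' The default recipe: AdamW (beta1 = 0.9, beta2 = 0.999, weight decay
#' 1e-4), learning rate 2e-4 under a one-cycle schedule, cross-entropy
#' loss, 25 epochs, early-stopping patience 10.
#'
#' @param learning_rate peak learning rate.
#' @param epochs training epochs.
#' @param batch_size bags per optimizer step.
#' @param weight_decay decoupled weight decay (applied to weight matrices,
#'   not biases).
#' @param betas AdamW momentum coefficients.
#' @param schedule `"onecycle"` or `"constant"`.
#' @param patience early-stopping patience in epochs on validation
#'   accuracy (ignored without a validation set).
#' @param warmup_epochs for top-K models only: number of initial epochs
#'   trained with the full-bag attention softmax before hard top-K
#'   selection is switched on. Hard selection makes the loss locally
#'   independent of non-selected instances, so a scorer that starts out
#'   ranking the informative instances low can never discover them (a
#'   cold-start pathology of top-K MIL); a short full-attention warm-up
#'   lets the scorer localize the signal first.
#' @param seed RNG seed for shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, epochs = 25, batch_size = 8,
                         weight_decay = 1e-4, betas = c(0.9, 0.999),
                         schedule = c("onecycle", "constant"),
                         patience = 10, warmup_epochs = 0, seed = 1) {
  schedule <- match.arg(schedule)
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1, warmup_epochs >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), weight_decay = weight_decay,
                 betas = betas, eps = 1e-8, schedule = schedule,
                 patience = patience, warmup_epochs = as.integer(warmup_epochs),
                 seed = seed),
            class = "train_config")
}

#' Train a MIL model on feature bags
#'
#' Mini-batch AdamW with analytic gradients; per-epoch training loss and
#' accuracy, and validation loss / accuracy / AUROC when a validation set
#' is supplied, are logged to the history. The checkpoint with the best
#' validation accuracy is returned (the final model when there is no
#' validation set). `epochs = 0` returns the initialized model with an
#' empty history. Deterministic under the config seed.
#'
#' @param bags list of feature bags: each a list with `features` (n x d
#'   matrix), `label`, `wsi_id`.
#' @param model a [mil_model()].
#' @param config a [train_config()].
#' @param train_ids,val_ids `wsi_id` subsets; default trains on all bags
#'   with no validation.
#' @return a `mil_fit` list: `model` (best checkpoint), `history` (data
#'   frame: epoch, lr, train_loss, train_acc, val_loss, val_acc,
#'   val_auroc), `config`.
#' @export
train_mil <- function(bags, model, config = train_config(),
                      train_ids = NULL, val_ids = NULL) {
  ids <- vapply(bags, `[[`, character(1), "wsi_id")
  train_idx <- if (is.null(train_ids)) seq_along(bags) else which(ids %in% train_ids)
  val_idx <- if (is.null(val_ids)) integer(0) else which(ids %in% val_ids)
  if (!length(train_idx)) stop("empty training split", call. = FALSE)
  labels_idx <- match(vapply(bags, `[[`, character(1), "label"), model$classes)
  if (anyNA(labels_idx)) stop("bag label outside the model's class set", call. = FALSE)

  hist_rows <- list()
  if (config$epochs == 0L) {
    return(structure(list(model = model, history = data.frame(), config = config),
                     class = "mil_fit"))
  }
  n_batches <- ceiling(length(train_idx) / config$batch_size)
  total_steps <- config$epochs * n_batches
  pn <- names(model$params)
  decayed <- c("V", "w", "W")
  mstate <- lapply(model$params, function(x) 0 * x)
  vstate <- lapply(model$params, function(x) 0 * x)
  step <- 0L
  best <- list(metric = -Inf, model = model)
  bad_epochs <- 0L

  with_seed(config$seed, {
    warmup <- if (model$aggregator$kind == "ktop") config$warmup_epochs %||% 0L else 0L
    for (epoch in seq_len(config$epochs)) {
      grad_model <- model
      if (epoch <= warmup) {
        grad_model$aggregator <- aggregator_config(
          "attention", attention_temperature = model$aggregator$attention_temperature)
      }
      order_idx <- sample(train_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (bi in seq_len(n_batches)) {
        batch <- order_idx[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, length(order_idx))]
        batch <- batch[!is.na(batch)]
        acc_grads <- NULL
        for (i in batch) {
          grad_model$params <- model$params
          bg <- bag_grad(grad_model, bags[[i]]$features, labels_idx[i])
          if (!is.finite(bg$loss)) {
            stop(sprintf("training diverged: non-finite loss at epoch %d (bag %s)",
                         epoch, bags[[i]]$wsi_id), call. = FALSE)
          }
          ep_loss <- ep_loss + bg$loss
          pred <- which.max(forward_bag(model, bags[[i]]$features)$prob)
          ep_correct <- ep_correct + as.integer(pred == labels_idx[i])
          if (is.null(acc_grads)) {
            acc_grads <- bg$grads
          } else {
            for (nm in pn) acc_grads[[nm]] <- acc_grads[[nm]] + bg$grads[[nm]]
          }
        }
        step <- step + 1L
        lr <- if (config$schedule == "onecycle") {
          onecycle_lr(step, total_steps, config$learning_rate)
        } else {
          config$learning_rate
        }
        for (nm in pn) {
          gr <- acc_grads[[nm]] / length(batch)
          mstate[[nm]] <- config$betas[1] * mstate[[nm]] + (1 - config$betas[1]) * gr
          vstate[[nm]] <- config$betas[2] * vstate[[nm]] + (1 - config$betas[2]) * gr^2
          mhat <- mstate[[nm]] / (1 - config$betas[1]^step)
          vhat <- vstate[[nm]] / (1 - config$betas[2]^step)
          upd <- mhat / (sqrt(vhat) + config$eps)
          if (nm %in% decayed) upd <- upd + config$weight_decay * model$params[[nm]]
          model$params[[nm]] <- model$params[[nm]] - lr * upd
        }
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        train_loss = ep_loss / length(train_idx),
                        train_acc = ep_correct / length(train_idx),
                        val_loss = NA_real_, val_acc = NA_real_, val_auroc = NA_real_)
      if (length(val_idx)) {
        ev <- evaluate_mil(model, bags[val_idx])
        row$val_loss <- ev$loss
        row$val_acc <- ev$report$accuracy
        row$val_auroc <- ev$report$auroc
        if (row$val_acc > best$metric) {
          best$metric <- row$val_acc
          best$model <- model
          bad_epochs <- 0L
        } else {
          bad_epochs <- bad_epochs + 1L
        }
      }
      hist_rows[[epoch]] <- row
      if (length(val_idx) && bad_epochs >= config$patience) break
    }
  })
  final <- if (length(val_idx)) best$model else model
  structure(list(model = final, history = do.call(rbind, hist_rows), config = config),
            class = "mil_fit")
}

#' Evaluate a MIL model on feature bags
#'
#' @param model a [mil_model()] (or `mil_fit`, whose model is used).
#' @param bags list of feature bags.
#' @param tau optional calibration temperature overriding the model's
#'   configured softmax temperature.
#' @return list with `report` (a [metric_report()]), `loss` (mean
#'   cross-entropy), `prob` (bag x class probability matrix), `pred`,
#'   `truth`.
#' @export
evaluate_mil <- function(model, bags, tau = NULL) {
  if (inherits(model, "mil_fit")) model <- model$model
  truth <- vapply(bags, `[[`, character(1), "label")
  prob <- t(vapply(bags, function(b) forward_bag(model, b$features, tau = tau)$prob,
                   numeric(length(model$classes))))
  colnames(prob) <- model$classes
  pred <- model$classes[apply(prob, 1, which.max)]
  report <- suppressWarnings(metric_report(truth, pred, probs = prob, classes = model$classes))
  list(report = report, loss = bag_loss(prob, truth), prob = prob,
       pred = pred, truth = truth)
}

#' Temperature-calibration sweep
#'
#' Re-evaluates a trained model under each temperature, reproducing the
#' calibration-table layout (one metric row per tau). Accuracy is
#' invariant in tau (rescaling logits never changes the argmax); AUROC and
#' loss can change.
#'
#' @param model a trained [mil_model()] or `mil_fit`.
#' @param bags feature bags to evaluate.
#' @param taus temperatures to sweep (default `c(0.1, 0.3, 0.5, 1, 2, 5)`).
#' @return data frame: tau, accuracy, auroc, f1, loss.
#' @export
calibration_sweep <- function(model, bags, taus = c(0.1, 0.3, 0.5, 1, 2, 5)) {
  rows <- lapply(taus, function(tt) {
    ev <- evaluate_mil(model, bags, tau = tt)
    data.frame(tau = tt, accuracy = ev$report$accuracy, auroc = ev$report$auroc,
               f1 = ev$report$f1, loss = ev$loss)
  })
  do.call(rbind, rows)
}
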