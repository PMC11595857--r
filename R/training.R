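#' Training protocol configuration
#'
#' Every hyperparameter of the training protocol as an explicit field.
#' The defaults are the protocol used for the published experiments: Adam
#' with learning rate 0.001 and weight decay 1e-4, batch size 128, at most
#' 200 epochs, a reduce-on-plateau schedule (factor 0.5) driven by the
#' validation loss, early stopping after 50 consecutive epochs without a
#' validation-accuracy improvement, and random seed 2022.
#'
#' @param learning_rate initial Adam learning rate.
#' @param weight_decay L2 penalty added to the gradients.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param early_stop_patience consecutive non-improving epochs tolerated
#'   before halting.
#' @param lr_reduce_factor multiplier applied to the learning rate on a
#'   plateau; in (0, 1).
#' @param scheduler_patience plateau length (epochs) before the learning
#'   rate is reduced.
#' @param scheduler_monitor quantity driving the plateau schedule
#'   (minimized): `"validation_loss"` (default) or `"validation_accuracy"`
#'   (maximized).
#' @param early_stop_monitor quantity driving early stopping; validation
#'   accuracy by default.
#' @param seed global random seed fixed at the start of training.
#' @param class_weights optional per-class loss weights (length
#'   `num_classes`); `NULL` (default) trains unweighted, matching the
#'   published protocol even though the real dataset is imbalanced.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001,
                            weight_decay = 1e-4,
                            batch_size = 128L,
                            max_epochs = 200L,
                            early_stop_patience = 50L,
                            lr_reduce_factor = 0.5,
                            scheduler_patience = 10L,
                            scheduler_monitor = c("validation_loss",
                                                  "validation_accuracy"),
                            early_stop_monitor = c("validation_accuracy",
                                                   "validation_loss"),
                            seed = 2022L,
                            class_weights = NULL) {
  scheduler_monitor <- match.arg(scheduler_monitor)
  early_stop_monitor <- match.arg(early_stop_monitor)
  if (learning_rate <= 0 || weight_decay < 0)
    stop("rates must be positive", call. = FALSE)
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1)
    stop("`lr_reduce_factor` must lie in (0, 1)", call. = FALSE)
  assert_positive_int(batch_size, "batch_size")
  assert_positive_int(max_epochs, "max_epochs")
  assert_positive_int(early_stop_patience, "early_stop_patience")
  # a patience >= max_epochs is allowed: early stopping then never fires
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_monitor = scheduler_monitor,
                 early_stop_monitor = early_stop_monitor,
                 seed = as.integer(seed),
                 class_weights = class_weights),
            class = "training_config")
}

#' Fix every source of randomness
#'
#' All stochastic components of the package (weight initialization, batch
#' shuffling, dropout, data synthesis, augmentation) draw from R's global
#' random number generator, so seeding it once makes a whole run
#' reproducible.
#'
#' @param seed integer seed.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

#' Multiclass cross-entropy loss
#'
#' `L = -(1/N) * sum_i log p[i, y_i]`: the mean negative log predicted
#' probability of the true class, equivalently the full one-hot double sum
#' since only the true-class term survives.
#'
#' @param prob `N x M` matrix of predicted class probabilities; each row
#'   must sum to 1 (within tolerance).
#' @param labels integer vector of true classes in `[0, M)`.
#' @param weights optional per-class weights (length `M`).
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(prob, labels, weights = NULL) {
  if (!is.matrix(prob)) stop("`prob` must be an N x M matrix", call. = FALSE)
  n <- nrow(prob)
  m <- ncol(prob)
  check_labels(labels, m, n)
  if (any(abs(rowSums(prob) - 1) > 1e-6))
    stop("rows of `prob` must sum to 1", call. = FALSE)
  p_true <- prob[cbind(seq_len(n), labels + 1L)]
  if (any(p_true <= 0))
    stop("zero probability at a true class; use logits with ",
         "`softmax_cross_entropy()` for a numerically safe path",
         call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else weights[labels + 1L]
  sum(w * -log(p_true)) / sum(w)
}

#' Cross-entropy from raw scores (log-sum-exp formulation)
#'
#' Numerically stable companion of [cross_entropy_loss()] operating on
#' unnormalized logits; also returns the gradient with respect to the
#' logits, which is what the training loop consumes.
#'
#' @param logits `N x M` matrix of raw class scores.
#' @param labels integer vector of true classes in `[0, M)`.
#' @param weights optional per-class weights.
#' @return list with `loss`, `grad` (`N x M`), and `prob`.
#' @export
softmax_cross_entropy <- function(logits, labels, weights = NULL) {
  n <- nrow(logits)
  m <- ncol(logits)
  check_labels(labels, m, n)
  mx <- apply(logits, 1, max)
  z <- logits - mx
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  w <- if (is.null(weights)) rep(1, n) else weights[labels + 1L]
  sw <- sum(w)
  loss <- sum(w * -logp[cbind(seq_len(n), labels + 1L)]) / sw
  prob <- exp(logp)
  grad <- prob * (w / sw)
  grad[cbind(seq_len(n), labels + 1L)] <-
    grad[cbind(seq_len(n), labels + 1L)] - w / sw
  list(loss = loss, grad = grad, prob = prob)
}

check_labels <- function(labels, m, n = NULL) {
  if (!is.null(n) && length(labels) != n)
    stop("length of `labels` does not match the number of rows",
         call. = FALSE)
  bad <- which(labels < 0 | labels >= m | labels != floor(labels))
  if (length(bad))
    stop(sprintf("label out of range [0, %d) at index %d (value %s)",
                 m, bad[1], labels[bad[1]]), call. = FALSE)
  invisible(TRUE)
}

#' Plateau detector state machines
#'
#' `plateau_scheduler()` mirrors a reduce-on-plateau learning-rate rule:
#' when the monitored quantity has not improved for `patience` consecutive
#' updates, it signals a reduction by `factor`.  `early_stopper()` signals
#' a halt after `patience` consecutive updates without improvement.
#' Improvement is a strict comparison (`min_delta = 0`).  Both are exposed
#' as closures with an `update(value)` method so the rules can be driven
#' by scripted curves in tests as well as by live training.
#'
#' @param factor learning-rate multiplier, in (0, 1).
#' @param patience consecutive non-improving updates tolerated.
#' @param mode `"min"` (loss-like) or `"max"` (accuracy-like).
#' @return a list with `update(value)` and `state()`.  For the scheduler,
#'   `update` returns the current multiplier (cumulative); for the
#'   stopper, `update` returns `TRUE` when training should halt.
#' @export
plateau_scheduler <- function(factor = 0.5, patience = 10L,
                              mode = c("min", "max")) {
  mode <- match.arg(mode)
  best <- if (mode == "min") Inf else -Inf
  bad <- 0L
  mult <- 1
  list(
    update = function(value) {
      improved <- if (mode == "min") value < best else value > best
      if (improved) {
        best <<- value
        bad <<- 0L
      } else {
        bad <<- bad + 1L
        if (bad >= patience) {
          mult <<- mult * factor
          bad <<- 0L
        }
      }
      mult
    },
    state = function() list(best = best, bad = bad, mult = mult)
  )
}

#' @rdname plateau_scheduler
#' @export
early_stopper <- function(patience = 50L, mode = c("max", "min")) {
  mode <- match.arg(mode)
  best <- if (mode == "min") Inf else -Inf
  best_at <- 0L
  n <- 0L
  list(
    update = function(value) {
      n <<- n + 1L
      improved <- if (mode == "min") value < best else value > best
      if (improved) {
        best <<- value
        best_at <<- n
      }
      (n - best_at) >= patience
    },
    state = function() list(best = best, best_epoch = best_at, epoch = n)
  )
}

dataset_size <- function(data) {
  if (is.null(data$x) || is.null(data$y))
    stop("a dataset is a list with elements `x` (N x C x H x W array) ",
         "and `y` (integer labels)", call. = FALSE)
  n <- dim(data$x)[1]
  if (n == 0 || length(data$y) == 0) stop("empty dataset", call. = FALSE)
  if (length(data$y) != n)
    stop("`y` length does not match the number of images", call. = FALSE)
  n
}

#' Evaluate a classifier on a labeled dataset
#'
#' @param model an initialized `nn_model`.
#' @param data list with `x` (array `N x C x H x W`) and `y` (integer
#'   labels in `[0, M)`).
#' @param batch_size evaluation batch size.
#' @return list with `loss`, `accuracy` and the `predictions` vector
#'   (0-based).
#' @export
evaluate_model <- function(model, data, batch_size = 64L) {
  dataset_size(data)
  logits <- predict(model, data$x, batch_size = batch_size)
  ce <- softmax_cross_entropy(logits, data$y)
  pred <- max.col(logits, ties.method = "first") - 1L
  list(loss = ce$loss, accuracy = mean(pred == data$y), predictions = pred)
}

#' Train a classifier
#'
#' Runs the full protocol: Adam with the configured learning rate and
#' weight decay, per-epoch validation, a reduce-on-plateau learning-rate
#' schedule on the monitored quantity, early stopping when the monitored
#' accuracy has not improved for `early_stop_patience` consecutive epochs,
#' and restoration of the parameters from the best epoch (not the last).
#' The configured seed is fixed at entry, so two runs with an identical
#' configuration produce identical histories.
#'
#' @param model an initialized `nn_model` whose head matches the label
#'   space.
#' @param train_set,validation_set datasets: lists with `x`
#'   (`N x C x H x W` array) and `y` (integer labels in `[0, M)`).
#' @param config a [training_config()].
#' @param verbose print a one-line summary per epoch.
#' @return list with `model` (parameters from the best epoch), `history`
#'   (one data.frame row per epoch), `best_epoch`, `stopped_epoch` and
#'   `stop_reason` (`"early_stop"` or `"max_epochs"`).
#' @export
train_model <- function(model, train_set, validation_set,
                        config = training_config(), verbose = FALSE) {
  n_train <- dataset_size(train_set)
  dataset_size(validation_set)
  m_classes <- model$graph$nodes[["head.fc"]]$out_features %||%
    max(c(train_set$y, validation_set$y)) + 1L
  check_labels(train_set$y, m_classes)
  check_labels(validation_set$y, m_classes)

  set_global_seed(config$seed)
  if (is.null(model$params)) model <- init_model_params(model)
  opt <- adam_init(model$params)
  sched <- plateau_scheduler(config$lr_reduce_factor,
                             config$scheduler_patience,
                             mode = if (config$scheduler_monitor ==
                                        "validation_loss") "min" else "max")
  stopper <- early_stopper(config$early_stop_patience,
                           mode = if (config$early_stop_monitor ==
                                      "validation_accuracy") "max" else "min")
  history <- list()
  best_metric <- -Inf
  best_epoch <- 0L
  best_params <- model$params
  best_state <- model$state
  stop_reason <- "max_epochs"
  stopped_epoch <- config$max_epochs
  lr <- config$learning_rate

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot_loss <- 0
    tot_correct <- 0
    for (ix in batches) {
      xb <- train_set$x[ix, , , , drop = FALSE]
      yb <- train_set$y[ix]
      fwd <- model_forward(model, xb, mode = "train", keep_caches = TRUE)
      ce <- softmax_cross_entropy(fwd$output, yb, config$class_weights)
      if (!is.finite(ce$loss)) {
        stop(sprintf(paste0("non-finite training loss at epoch %d; ",
                            "aborting (history has %d complete epochs)"),
                     epoch, length(history)), call. = FALSE)
      }
      grads <- model_backward(model, fwd, ce$grad)
      model$state <- fwd$state
      step <- adam_step(model$params, grads, opt, lr = lr,
                        weight_decay = config$weight_decay)
      model$params <- step$params
      opt <- step$opt
      tot_loss <- tot_loss + ce$loss * length(ix)
      pred <- max.col(fwd$output, ties.method = "first") - 1L
      tot_correct <- tot_correct + sum(pred == yb)
    }
    train_loss <- tot_loss / n_train
    train_acc <- tot_correct / n_train
    val <- evaluate_model(model, validation_set,
                          batch_size = config$batch_size)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                   train_accuracy = train_acc,
                                   validation_loss = val$loss,
                                   validation_accuracy = val$accuracy,
                                   learning_rate = lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %g",
        epoch, train_loss, train_acc, val$loss, val$accuracy, lr))

    monitored_acc <- if (config$early_stop_monitor == "validation_accuracy")
      val$accuracy else -val$loss
    if (monitored_acc > best_metric) {
      best_metric <- monitored_acc
      best_epoch <- epoch
      best_params <- model$params
      best_state <- model$state
    }
    sched_value <- if (config$scheduler_monitor == "validation_loss")
      val$loss else val$accuracy
    lr <- config$learning_rate * sched$update(sched_value)
    stop_now <- stopper$update(if (config$early_stop_monitor ==
                                   "validation_accuracy") val$accuracy
                               else val$loss)
    if (stop_now) {
      stop_reason <- "early_stop"
      stopped_epoch <- epoch
      break
    }
    stopped_epoch <- epoch
  }
  model$params <- best_params
  model$state <- best_state
  list(model = model, history = do.call(rbind, history),
       best_epoch = best_epoch, stopped_epoch = stopped_epoch,
       stop_reason = stop_reason)
}

#' Persist a training history
#'
#' Writes the per-epoch record as CSV (one row per epoch) and, when
#' `json_path` is given, as JSON.
#'
#' @param history data.frame from [train_model()].
#' @param csv_path,json_path output file paths (`NULL` to skip).
#' @export
write_history <- function(history, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(history, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(history, json_path, dataframe = "rows",
                         digits = NA, pretty = TRUE)
  invisible(history)
}
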