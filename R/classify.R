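#' MLP classifier configuration
#'
#' The benchmark's fixed classifier: a feed-forward network with two
#' hidden layers of 500 ReLU neurons, a sigmoid output unit trained with
#' Adam on cross-entropy for at most `max_epochs` epochs (default 1000),
#' stopping early once the training loss improves by less than `tol` for
#' `patience` consecutive epochs.
#'
#' @param hidden_layers Integer vector of hidden-layer sizes.
#' @param max_epochs Epoch cap.
#' @param batch_size,lr Adam minibatch size and learning rate.
#' @param tol,patience Plateau early-stopping parameters.
#' @param seed Seed (weight initialisation + shuffling).
#' @return A list of class `"mlp_config"`.
#' @export
mlp_config <- function(hidden_layers = c(500L, 500L), max_epochs = 1000L,
                       batch_size = 32L, lr = 1e-3, tol = 1e-4,
                       patience = 10L, seed = 1L) {
  stopifnot(all(hidden_layers >= 1), max_epochs >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 tol = tol, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the fixed MLP classifier
#'
#' @param train_X n x d feature matrix.
#' @param train_y Binary labels (1 = mutagenic), both classes present.
#' @param config An [mlp_config()].
#' @return An `"mlp_classifier"` usable with [predict_mlp()] and
#'   [evaluate()]. Deterministic given `config$seed`.
#' @export
train_mlp <- function(train_X, train_y, config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"))
  train_X <- as.matrix(train_X)
  stopifnot(nrow(train_X) == length(train_y))
  if (length(unique(train_y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  sizes <- c(ncol(train_X), config$hidden_layers, 1L)
  activations <- c(rep("relu", length(config$hidden_layers)), "sigmoid")
  net <- nn_init(sizes, activations, seed = config$seed)
  net <- nn_train(net, train_X, matrix(train_y, ncol = 1), loss = "bce",
                  epochs = config$max_epochs,
                  batch_size = config$batch_size, lr = config$lr,
                  seed = config$seed, tol = config$tol,
                  patience = config$patience)
  structure(list(net = net, config = config, input_dim = ncol(train_X)),
            class = "mlp_classifier")
}

#' @rdname train_mlp
#' @param object A fitted `"mlp_classifier"`.
#' @param X Feature matrix to predict.
#' @return `predict_mlp()` returns 0/1 predictions (threshold 0.5 on the
#'   sigmoid output).
#' @export
predict_mlp <- function(object, X) {
  stopifnot(inherits(object, "mlp_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != object$input_dim) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  p <- nn_forward(object$net, X)$out
  as.integer(p >= 0.5)
}

#' Confusion counts and the five evaluation metrics
#'
#' Mutagenic predictions count as positive. Overall accuracy is the
#' prevalence-weighted average of sensitivity and specificity,
#' (P * sens + N * spec) / (P + N), which is algebraically identical to
#' plain accuracy (TP + TN) / total. Metrics whose denominator is zero
#' (for example sensitivity on a test set with no mutagenic molecules)
#' are reported as `NA`, never as zero.
#'
#' @param predictions,truth Equal-length 0/1 vectors, or pass a fitted
#'   classifier and matrices through [evaluate()].
#' @return A one-row `data.frame`: `tp, fp, tn, fn, sensitivity,
#'   specificity, ppv, npv, overall_accuracy`.
#' @export
metrics_record <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth differ in length", call. = FALSE)
  }
  tp <- sum(predictions == 1 & truth == 1)
  fp <- sum(predictions == 1 & truth == 0)
  tn <- sum(predictions == 0 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  P <- tp + fn; N <- tn + fp
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(tp, P)
  spec <- safe_div(tn, N)
  overall <- if (P > 0 && N > 0) (P * sens + N * spec) / (P + N)
             else safe_div(tp + tn, P + N)
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sens, specificity = spec,
             ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
             overall_accuracy = overall)
}

#' @rdname metrics_record
#' @param classifier A fitted `"mlp_classifier"`.
#' @param test_X,test_y Test features and labels.
#' @return `evaluate()` returns the metrics row with the prediction
#'   vector attached as attribute `"predictions"`.
#' @export
evaluate <- function(classifier, test_X, test_y) {
  pred <- predict_mlp(classifier, test_X)
  rec <- metrics_record(pred, test_y)
  attr(rec, "predictions") <- pred
  rec
}
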