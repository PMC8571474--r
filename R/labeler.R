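# The automatic difficulty labeler: a 4-layer fully connected classifier
# (50, 30, 20, 2 units) over the 10 similarity features, trained on manually
# labeled gold/auto pairs and then used to label the remaining blocks.

#' Labeler architecture and training hyper-parameters
#'
#' Layer widths follow the published labeler (50, 30, 20, 2 on a 10-wide
#' input). Optimizer settings are package defaults (the original report
#' omits them) and are echoed in the training report.
#'
#' @param widths hidden/output layer widths
#' @param input_width number of similarity features
#' @param epochs,batch_size,lr,weight_decay Adam training parameters
#' @param holdout fraction held out for the test split
#' @param seed RNG seed
#' @return named list
#' @export
labeler_spec <- function(widths = c(50, 30, 20, 2), input_width = 10,
                         epochs = 200, batch_size = 30, lr = 0.001,
                         weight_decay = 0, holdout = 0.3, seed = 1) {
  stopifnot(tail(widths, 1) == 2)
  list(widths = widths, input_width = input_width, epochs = epochs,
       batch_size = batch_size, lr = lr, weight_decay = weight_decay,
       holdout = holdout, seed = seed)
}

.label_levels <- c("low", "high")

#' One-hot encode difficulty labels
#'
#' `low` maps to (1, 0) and `high` to (0, 1).
#'
#' @param labels character vector of `"low"` / `"high"`
#' @return 2 x n matrix
#' @export
label_one_hot <- function(labels) {
  stopifnot(all(labels %in% .label_levels))
  rbind(low = as.numeric(labels == "low"), high = as.numeric(labels == "high"))
}

# generic minibatch Adam training of an MLP with softmax cross-entropy
.train_mlp <- function(X, Y, widths, epochs, batch_size, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.99) {
  net <- mlp_new(widths)
  opt <- adam_new(net$layers, lr = lr, beta1 = beta1, beta2 = beta2,
                  weight_decay = weight_decay)
  n <- ncol(X)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1, n)]
      fw <- mlp_fw(net, X[, idx, drop = FALSE])
      ce <- softmax_ce(fw$Z, Y[, idx, drop = FALSE])
      bw <- mlp_bw(net, fw, ce$dZ)
      st <- adam_step(opt, net$layers, bw$grads, no_decay = c("b"))
      opt <- st$opt; net$layers <- st$params
      tot <- tot + ce$loss * length(idx)
    }
    losses[ep] <- tot / n
  }
  list(net = net, losses = losses)
}

#' Train the automatic difficulty labeler
#'
#' Standardizes the 10 similarity features (statistics from the training
#' split only), trains the 4-layer classifier with Adam and softmax
#' cross-entropy on a random 70/30 split, and reports held-out accuracy and
#' F1 (positive class `high`).
#'
#' @param features 10 x n matrix (or data frame rows) of similarity features
#' @param labels character vector of `"low"` / `"high"` of length n
#' @param spec a [labeler_spec()]
#' @return object of class `difficulty_labeler` with fields `net`, `scaler`,
#'   `spec`, `report` (train/test accuracy and F1, split sizes, losses)
#' @export
train_auto_labeler <- function(features, labels, spec = labeler_spec()) {
  X <- as.matrix(features)
  if (nrow(X) != spec$input_width && ncol(X) == spec$input_width) X <- t(X)
  if (nrow(X) != spec$input_width) {
    stop("train_auto_labeler: feature width must be ", spec$input_width)
  }
  n <- ncol(X)
  if (n < 2) stop("train_auto_labeler: need at least 2 samples")
  if (length(unique(labels)) < 2) {
    stop("train_auto_labeler: both classes must be present")
  }
  set.seed(spec$seed)
  test_idx <- sample.int(n, size = max(1, round(spec$holdout * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  scaler <- scaler_fit(X[, train_idx, drop = FALSE])
  Xs <- scaler_apply(scaler, X)
  Y <- label_one_hot(labels)
  fit <- .train_mlp(Xs[, train_idx, drop = FALSE], Y[, train_idx, drop = FALSE],
                    c(spec$input_width, spec$widths), spec$epochs,
                    spec$batch_size, spec$lr, spec$weight_decay)
  predict_split <- function(idx) {
    P <- softmax_cols(mlp_fw(fit$net, Xs[, idx, drop = FALSE])$Z)
    .label_levels[apply(P, 2, which.max)]
  }
  rep_metrics <- function(idx) {
    pred <- predict_split(idx)
    classification_metrics(labels[idx], pred)
  }
  model <- structure(list(net = fit$net, scaler = scaler, spec = spec),
                     class = "difficulty_labeler")
  model$report <- list(train = rep_metrics(train_idx), test = rep_metrics(test_idx),
                       n_train = length(train_idx), n_test = length(test_idx),
                       losses = fit$losses, spec = spec)
  model
}

#' Predict difficulty labels from similarity features
#'
#' @param object a trained `difficulty_labeler`
#' @param features 10 x m matrix (or a single length-10 vector)
#' @param ... unused
#' @return character vector of `"low"` / `"high"`
#' @export
predict.difficulty_labeler <- function(object, features, ...) {
  if (is.null(object$net)) stop("predict: untrained labeler")
  X <- if (is.null(dim(features))) matrix(features, ncol = 1) else as.matrix(features)
  if (nrow(X) != object$spec$input_width && ncol(X) == object$spec$input_width) {
    X <- t(X)
  }
  if (nrow(X) != object$spec$input_width) {
    stop("predict: feature width must be ", object$spec$input_width)
  }
  P <- softmax_cols(mlp_fw(object$net, scaler_apply(object$scaler, X))$Z)
  .label_levels[apply(P, 2, which.max)]
}

#' Accuracy and F1 of a difficulty classification
#'
#' F1 uses `high` as the positive class.
#'
#' @param truth,pred character vectors of `"low"` / `"high"`
#' @return named numeric vector `(accuracy, f1, tp, fp, fn, tn)`
#' @export
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == "high" & pred == "high")
  fp <- sum(truth == "low" & pred == "high")
  fn <- sum(truth == "high" & pred == "low")
  tn <- sum(truth == "low" & pred == "low")
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = (tp + tn) / length(truth), f1 = f1,
    tp = tp, fp = fp, fn = fn, tn = tn)
}
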