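# Minimal deterministic neural-network machinery (no external framework is
# available in this environment). Samples are matrix columns. Every layer has
# an explicit forward (returning a cache) and backward (returning input
# gradients and parameter gradients). Training is full-precision, seeded and
# single-threaded.

# ---- initializers -----------------------------------------------------------

.he_init <- function(nout, nin, fan_in = nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / fan_in)), nout, nin)
}

# ---- dense ------------------------------------------------------------------

dense_new <- function(nin, nout) {
  list(W = .he_init(nout, nin), b = numeric(nout))
}

dense_fw <- function(layer, X) {
  list(Y = layer$W %*% X + layer$b, X = X)
}

dense_bw <- function(layer, cache, dY) {
  list(dX = t(layer$W) %*% dY,
       dW = dY %*% t(cache$X),
       db = rowSums(dY))
}

# ---- softmax cross-entropy --------------------------------------------------

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# mean cross-entropy over columns; `target` is a one-hot matrix (2 x N)
softmax_ce <- function(Z, target) {
  P <- softmax_cols(Z)
  loss <- -mean(colSums(target * log(pmax(P, 1e-12))))
  list(loss = loss, dZ = (P - target) / ncol(Z), P = P)
}

# backward of Y = softmax(Z) given dL/dY: dZ = P * (dY - colSums(dY * P))
softmax_bw <- function(P, dY) {
  P * sweep(dY, 2, colSums(dY * P))
}

# ---- MLP (dense stack, ReLU between layers, linear last layer) -------------

#' @keywords internal
mlp_new <- function(widths) {
  stopifnot(length(widths) >= 2)
  layers <- list()
  for (i in seq_len(length(widths) - 1)) {
    layers[[i]] <- dense_new(widths[i], widths[i + 1])
  }
  structure(list(layers = layers, widths = widths), class = "tdb_mlp")
}

mlp_fw <- function(net, X) {
  caches <- list()
  A <- X
  nl <- length(net$layers)
  for (i in seq_len(nl)) {
    c_i <- dense_fw(net$layers[[i]], A)
    Z <- c_i$Y
    A <- if (i < nl) pmax(Z, 0) else Z
    caches[[i]] <- list(dense = c_i, Z = Z)
  }
  list(Z = A, caches = caches)
}

mlp_bw <- function(net, fw, dZ) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  d <- dZ
  for (i in rev(seq_len(nl))) {
    if (i < nl) d <- d * (fw$caches[[i]]$Z > 0)
    g <- dense_bw(net$layers[[i]], fw$caches[[i]]$dense, d)
    grads[[i]] <- list(W = g$dW, b = g$db)
    d <- g$dX
  }
  list(grads = grads, dX = d)
}

# ---- Adam -------------------------------------------------------------------

# params/grads are arbitrarily nested lists of numeric arrays with identical
# shape; weight decay is classic L2 added to the gradient (as in Adam with a
# weight_decay argument, not decoupled)
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.99,
                     eps = 1e-8, weight_decay = 0) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weight_decay,
       m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(opt, params, grads, no_decay = NULL) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        nm <- if (is.null(nms)) "" else nms[i]
        res <- walk(p[[i]], g[[i]], m[[i]], v[[i]], c(path, nm))
        p[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    decay <- opt$wd
    if (!is.null(no_decay) && length(path) &&
        path[length(path)] %in% no_decay) decay <- 0
    g <- g + decay * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, opt$m, opt$v, character())
  opt$m <- res$m; opt$v <- res$v
  list(opt = opt, params = res$p)
}

# In-place Adam for huge parameter trees (the volumetric branch): updates
# p/m/v buffers directly through C++, avoiding whole-tree copies per step.
# Callers must own the buffers exclusively (true for networks built by this
# package; snapshots taken by callers would be mutated too).
adam_step_inplace <- function(opt, params, grads, no_decay = NULL) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  walk <- function(p, g, m, v, leaf) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        walk(p[[i]], g[[i]], m[[i]], v[[i]],
             if (is.null(nms)) "" else nms[i])
      }
      return(invisible(NULL))
    }
    wd <- if (!is.null(no_decay) && leaf %in% no_decay) 0 else opt$wd
    cpp_adam_inplace(p, g, m, v, opt$lr, opt$beta1, opt$beta2, bc1, bc2,
                     opt$eps, wd)
    invisible(NULL)
  }
  walk(params, grads, opt$m, opt$v, "")
  opt
}

# in-place gradient accumulation: a's leaves are modified (a must be owned)
grads_add_inplace <- function(a, b) {
  if (is.null(a)) return(b)
  walk <- function(x, y) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]], y[[i]])
    } else {
      cpp_axpy_inplace(x, y)
    }
    invisible(NULL)
  }
  walk(a, b)
  a
}

# sum two grad trees (for gradient accumulation)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- grads_add(a[[i]], b[[i]])
    return(a)
  }
  a + b
}

# ---- training-config --------------------------------------------------------

#' Optimizer and training hyper-parameters
#'
#' Defaults follow the published protocol: Adam with beta1 = 0.9,
#' beta2 = 0.99, batch size 30, learning rate 0.001, weight decay 0.01, five
#' repeat runs. Per-stage epoch counts are desk-scale defaults sized so a
#' full staged run fits a single-CPU budget; the cheap dense/LSTM branches
#' get many epochs, the volumetric branch few.
#'
#' @param lr learning rate
#' @param beta1,beta2 Adam moment decays
#' @param weight_decay L2 coefficient added to gradients
#' @param batch_size minibatch size
#' @param epochs_sfe_image stage-1 epochs for the volumetric network
#' @param epochs_sfe_auto stage-1 epochs for the morphometrics network
#' @param epochs_sie stage-2 epochs for the two LSTMs
#' @param epochs_mf warm-start epochs for the fusion head on cached sequence
#'   outputs (the joint stage then fine-tunes everything)
#' @param epochs_joint stage-3 joint epochs through the fusion head
#' @param runs number of repeat runs for mean/sd reporting
#' @param seed integer seed controlling all randomness
#' @return named list
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.99,
                         weight_decay = 0.01, batch_size = 30,
                         epochs_sfe_image = 3, epochs_sfe_auto = 200,
                         epochs_sie = 120, epochs_mf = 150, epochs_joint = 1,
                         runs = 5, seed = 1) {
  stopifnot(lr > 0, batch_size >= 1)
  list(lr = lr, beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
       batch_size = as.integer(batch_size),
       epochs_sfe_image = as.integer(epochs_sfe_image),
       epochs_sfe_auto = as.integer(epochs_sfe_auto),
       epochs_sie = as.integer(epochs_sie),
       epochs_mf = as.integer(epochs_mf),
       epochs_joint = as.integer(epochs_joint),
       runs = as.integer(runs), seed = as.integer(seed))
}

# ---- standardization --------------------------------------------------------

scaler_fit <- function(X) { # X: features x samples
  mu <- rowMeans(X)
  sdv <- apply(X, 1, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

scaler_apply <- function(scaler, X) {
  (X - scaler$mu) / scaler$sd
}
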