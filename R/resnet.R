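# The volumetric residual network of the image branch.
#
# Architecture (input 1 x 32 x 64 x 64, axis order (z, y, x)):
#   conv 3x3x3, 64 ch, stride (1,2,2), pad 1; BN; ReLU   -> 64 x 32x32x32
#   max pool 3x3x3, stride 2, pad 1                      -> 64 x 16x16x16
#   residual layer 1: dropout 0.2, unit-A(64), unit-A(64)   -> 16x16x16
#   residual layer 2: dropout 0.2, unit-B(128), unit-A(128) -> 8x8x8
#   residual layer 3: dropout 0.2, unit-B(256), unit-A(256) -> 4x4x4
#   residual layer 4: dropout 0.2, unit-B(512), unit-A(512) -> 2x2x2
#   avg pool 2x2x2, stride 2                             -> 512 x 1x1x1
#   fully connected 512 -> 2 (softmax applied by callers)
# Unit-A(n): two 3x3x3 convolutions (stride 1), each BN, identity skip.
# Unit-B(n): same but first convolution stride 2x2x2 and a 1x1x1 stride-2
# projection skip.

.conv_new <- function(cin, cout, k) {
  list(W = .he_init(cout, cin * k^3, fan_in = cin * k^3), b = numeric(cout))
}

.bn_new <- function(c) list(gamma = rep(1, c), beta = numeric(c))

.bn_state_new <- function(c) list(rmean = numeric(c), rvar = rep(1, c))

.unit_new <- function(cin, cout, stride) {
  p <- list(conv1 = .conv_new(cin, cout, 3), bn1 = .bn_new(cout),
            conv2 = .conv_new(cout, cout, 3), bn2 = .bn_new(cout))
  s <- list(bn1 = .bn_state_new(cout), bn2 = .bn_state_new(cout))
  if (stride != 1 || cin != cout) {
    p$proj <- .conv_new(cin, cout, 1)
    p$bnp <- .bn_new(cout)
    s$bnp <- .bn_state_new(cout)
  }
  list(params = p, state = s, cin = cin, cout = cout, stride = stride)
}

#' Build the image-branch volumetric residual network
#'
#' @param input_shape block extents (z, y, x)
#' @param channels channel widths of the four residual layers
#' @param dropout dropout rate applied at the entry of each residual layer
#'   during training
#' @return network object of class `sfe_image_net`
#' @export
sfe_image_new <- function(input_shape = c(32, 64, 64),
                          channels = c(64, 128, 256, 512), dropout = 0.2) {
  params <- list(stem_conv = .conv_new(1, channels[1], 3),
                 stem_bn = .bn_new(channels[1]))
  state <- list(stem_bn = .bn_state_new(channels[1]))
  units <- list()
  cin <- channels[1]
  for (l in 1:4) {
    cout <- channels[l]
    u1 <- .unit_new(cin, cout, stride = if (l == 1) 1 else 2)
    u2 <- .unit_new(cout, cout, stride = 1)
    params[[paste0("layer", l, "_u1")]] <- u1$params
    params[[paste0("layer", l, "_u2")]] <- u2$params
    state[[paste0("layer", l, "_u1")]] <- u1$state
    state[[paste0("layer", l, "_u2")]] <- u2$state
    cin <- cout
  }
  params$fc <- dense_new(channels[4], 2)
  structure(list(params = params, state = state, input_shape = input_shape,
                 channels = channels, dropout = dropout,
                 bn_momentum = 0.1, bn_eps = 1e-5),
            class = "sfe_image_net")
}

.unit_dims <- function(dims, stride) {
  c(dims[1], floor((dims[2] + 2 - 3) / stride) + 1,
    floor((dims[3] + 2 - 3) / stride) + 1,
    floor((dims[4] + 2 - 3) / stride) + 1)
}

.unit_fw <- function(p, st, X, dims, stride, training, mom, eps) {
  cin <- dims[1]; cout <- length(p$bn1$gamma)
  c1 <- cpp_conv3d_fw(X, p$conv1$W, p$conv1$b, cin, dims[2], dims[3], dims[4],
                      3L, stride, stride, stride, 1L)
  od <- .unit_dims(c(cout, dims[2:4]), stride)
  V <- prod(od[2:4])
  b1 <- cpp_bn_fw(c1, cout, V, p$bn1$gamma, p$bn1$beta,
                  st$bn1$rmean, st$bn1$rvar, mom, eps, training, TRUE)
  st$bn1$rmean <- b1$rmean; st$bn1$rvar <- b1$rvar
  c2 <- cpp_conv3d_fw(b1$Y, p$conv2$W, p$conv2$b, cout, od[2], od[3], od[4],
                      3L, 1L, 1L, 1L, 1L)
  b2 <- cpp_bn_fw(c2, cout, V, p$bn2$gamma, p$bn2$beta,
                  st$bn2$rmean, st$bn2$rvar, mom, eps, training, FALSE)
  st$bn2$rmean <- b2$rmean; st$bn2$rvar <- b2$rvar
  if (!is.null(p$proj)) {
    cp <- cpp_conv3d_fw(X, p$proj$W, p$proj$b, cin, dims[2], dims[3], dims[4],
                        1L, stride, stride, stride, 0L)
    bp <- cpp_bn_fw(cp, cout, V, p$bnp$gamma, p$bnp$beta,
                    st$bnp$rmean, st$bnp$rvar, mom, eps, training, FALSE)
    st$bnp$rmean <- bp$rmean; st$bnp$rvar <- bp$rvar
    skip <- bp$Y
  } else {
    cp <- NULL; bp <- NULL
    skip <- X
  }
  Y <- pmax(b2$Y + skip, 0)
  list(Y = Y, dims_out = od, state = st,
       cache = list(X = X, c1 = c1, b1 = b1, c2 = c2, b2 = b2,
                    cp = cp, bp = bp, Y = Y, dims = dims, stride = stride))
}

.unit_bw <- function(p, cache, dY, training, eps) {
  dims <- cache$dims; stride <- cache$stride
  cin <- dims[1]; cout <- length(p$bn1$gamma)
  dS <- dY * (cache$Y > 0)
  g2 <- cpp_bn_bw(cache$c2, dS, cache$b2$Y, p$bn2$gamma,
                  cache$b2$mu, cache$b2$var, eps, training, FALSE)
  od <- .unit_dims(c(cout, dims[2:4]), stride)
  gc2 <- cpp_conv3d_bw(cache$b1$Y, p$conv2$W, g2$dX, cout, od[2], od[3], od[4],
                       3L, 1L, 1L, 1L, 1L, TRUE)
  g1 <- cpp_bn_bw(cache$c1, gc2$dX, cache$b1$Y, p$bn1$gamma,
                  cache$b1$mu, cache$b1$var, eps, training, TRUE)
  gc1 <- cpp_conv3d_bw(cache$X, p$conv1$W, g1$dX, cin, dims[2], dims[3], dims[4],
                       3L, stride, stride, stride, 1L, TRUE)
  grads <- list(conv1 = list(W = gc1$dW, b = gc1$db),
                bn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                conv2 = list(W = gc2$dW, b = gc2$db),
                bn2 = list(gamma = g2$dgamma, beta = g2$dbeta))
  if (!is.null(p$proj)) {
    gp <- cpp_bn_bw(cache$cp, dS, cache$bp$Y, p$bnp$gamma,
                    cache$bp$mu, cache$bp$var, eps, training, FALSE)
    gcp <- cpp_conv3d_bw(cache$X, p$proj$W, gp$dX, cin, dims[2], dims[3], dims[4],
                         1L, stride, stride, stride, 0L, TRUE)
    grads$proj <- list(W = gcp$dW, b = gcp$db)
    grads$bnp <- list(gamma = gp$dgamma, beta = gp$dbeta)
    dX <- gc1$dX + gcp$dX
  } else {
    dX <- gc1$dX + dS
  }
  list(grads = grads, dX = dX)
}

# Forward pass. X: (prod(input_shape) x N) matrix, one flattened block per
# column (x fastest, then y, then z). Returns logits (2 x N), the cache for
# backward, and the network with refreshed BN running statistics.
resnet_fw <- function(net, X, training = FALSE) {
  p <- net$params; st <- net$state
  mom <- net$bn_momentum; eps <- net$bn_eps
  ish <- net$input_shape
  dims <- c(1, ish)
  c0 <- cpp_conv3d_fw(X, p$stem_conv$W, p$stem_conv$b, 1L, ish[1], ish[2], ish[3],
                      3L, 1L, 2L, 2L, 1L)
  dims <- c(net$channels[1], ish[1],
            floor((ish[2] - 1) / 2) + 1, floor((ish[3] - 1) / 2) + 1)
  V <- prod(dims[2:4])
  b0 <- cpp_bn_fw(c0, dims[1], V, p$stem_bn$gamma, p$stem_bn$beta,
                  st$stem_bn$rmean, st$stem_bn$rvar, mom, eps, training, TRUE)
  st$stem_bn$rmean <- b0$rmean; st$stem_bn$rvar <- b0$rvar
  mp <- cpp_maxpool3d_fw(b0$Y, dims[1], dims[2], dims[3], dims[4], 3L, 2L, 1L)
  dims <- c(dims[1], floor((dims[2] - 1) / 2) + 1,
            floor((dims[3] - 1) / 2) + 1, floor((dims[4] - 1) / 2) + 1)
  A <- mp$Y
  cache <- list(X = X, c0 = c0, b0 = b0, mp = mp, stages = list(),
                drop_masks = list(), dims_chain = list(stem = dims))
  for (l in 1:4) {
    if (training && net$dropout > 0) {
      mask <- matrix((runif(length(A)) >= net$dropout) / (1 - net$dropout),
                     nrow(A), ncol(A))
      A <- A * mask
      cache$drop_masks[[l]] <- mask
    }
    for (u in 1:2) {
      key <- paste0("layer", l, "_u", u)
      stride <- if (u == 1 && l > 1) 2L else 1L
      r <- .unit_fw(p[[key]], st[[key]], A, dims, stride, training, mom, eps)
      st[[key]] <- r$state
      cache$stages[[key]] <- r$cache
      A <- r$Y
      dims <- r$dims_out
    }
    cache$dims_chain[[paste0("layer", l)]] <- dims
  }
  ap <- cpp_avgpool3d_fw(A, dims[1], dims[2], dims[3], dims[4], 2L, 2L)
  cache$ap_in_dims <- dims
  fcc <- dense_fw(p$fc, ap)
  cache$fc <- fcc
  net$state <- st
  list(Z = fcc$Y, cache = cache, net = net)
}

resnet_bw <- function(net, cache, dZ, training = TRUE) {
  p <- net$params; eps <- net$bn_eps
  grads <- list()
  gfc <- dense_bw(p$fc, cache$fc, dZ)
  grads$fc <- list(W = gfc$dW, b = gfc$db)
  dims <- cache$ap_in_dims
  d <- cpp_avgpool3d_bw(gfc$dX, dims[1], dims[2], dims[3], dims[4], 2L, 2L)
  for (l in 4:1) {
    for (u in 2:1) {
      key <- paste0("layer", l, "_u", u)
      r <- .unit_bw(p[[key]], cache$stages[[key]], d, training, eps)
      grads[[key]] <- r$grads
      d <- r$dX
    }
    if (training && length(cache$drop_masks) >= l && !is.null(cache$drop_masks[[l]])) {
      d <- d * cache$drop_masks[[l]]
    }
  }
  ish <- net$input_shape
  dims0 <- c(net$channels[1], ish[1],
             floor((ish[2] - 1) / 2) + 1, floor((ish[3] - 1) / 2) + 1)
  d <- cpp_maxpool3d_bw(d, cache$mp$idx, length(cache$b0$Y) / ncol(cache$b0$Y))
  g0 <- cpp_bn_bw(cache$c0, d, cache$b0$Y, p$stem_bn$gamma,
                  cache$b0$mu, cache$b0$var, eps, training, TRUE)
  gc0 <- cpp_conv3d_bw(cache$X, p$stem_conv$W, g0$dX, 1L, ish[1], ish[2], ish[3],
                       3L, 1L, 2L, 2L, 1L, FALSE)
  grads$stem_conv <- list(W = gc0$dW, b = gc0$db)
  grads$stem_bn <- list(gamma = g0$dgamma, beta = g0$dbeta)
  # order grads to match net$params for the optimizer walk
  grads[names(net$params)]
}

# Recalibrate batch-norm running statistics ("precise BN"): with micro-batch
# statistics of only a few samples, the exponential running averages drift
# from the population statistics and the error compounds across layers.
# One pass over (a subset of) the training data with momentum 1/k replaces
# them with the arithmetic mean of the chunk statistics.
resnet_refresh_stats <- function(net, X, max_samples = 48) {
  n <- ncol(X)
  if (n > max_samples) {
    X <- X[, sort(sample.int(n, max_samples)), drop = FALSE]
    n <- max_samples
  }
  mom0 <- net$bn_momentum
  drop0 <- net$dropout
  net$dropout <- 0 # statistics must reflect inference-time activations
  k <- 0L
  for (cs in seq(1, n, by = .sfe_chunk)) {
    ci <- cs:min(cs + .sfe_chunk - 1, n)
    k <- k + 1L
    net$bn_momentum <- 1 / k
    fw <- resnet_fw(net, X[, ci, drop = FALSE], training = TRUE)
    net$state <- fw$net$state
  }
  net$bn_momentum <- mom0
  net$dropout <- drop0
  net
}

#' Stage-wise output shapes of the image branch
#'
#' Forwards one block through the network and records the spatial extent
#' after every stage, for checking the printed architecture table.
#'
#' @param net a network from [sfe_image_new()] (one is built if missing)
#' @return data frame with columns `stage` and `output_size`
#' @export
sfe_image_shape_chain <- function(net = NULL) {
  if (is.null(net)) net <- sfe_image_new()
  X <- matrix(rnorm(prod(net$input_shape)), ncol = 1)
  fw <- resnet_fw(net, X, training = FALSE)
  dims <- fw$cache$dims_chain
  stem_conv <- c(net$input_shape[1], floor((net$input_shape[2] - 1) / 2) + 1,
                 floor((net$input_shape[3] - 1) / 2) + 1)
  rows <- list(c("convolution", stem_conv),
               c("max_pooling", dims$stem[2:4]),
               c("residual_layer_1", dims$layer1[2:4]),
               c("residual_layer_2", dims$layer2[2:4]),
               c("residual_layer_3", dims$layer3[2:4]),
               c("residual_layer_4", dims$layer4[2:4]),
               c("average_pooling", floor(dims$layer4[2:4] / 2)),
               c("classification", length(fw$Z), "", ""))
  data.frame(stage = vapply(rows, `[`, "", 1),
             output_size = vapply(rows, function(r) {
               paste(r[-1][r[-1] != ""], collapse = "x")
             }, ""))
}

# flatten a (z, y, x) array into the column layout the network expects
flatten_block <- function(img) {
  as.vector(aperm(img, c(3, 2, 1)))
}
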