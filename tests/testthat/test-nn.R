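# numerical gradient checks for every hand-written operator, plus forward
# contracts of the network builders

tb <- asNamespace("traceblocks")

num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  array(g, dim = if (is.null(dim(x))) length(x) else dim(x))
}

test_that("conv3d forward/backward match numerical gradients", {
  set.seed(1)
  C <- 2; D <- 4; H <- 5; W <- 4; k <- 3; Cout <- 3
  X <- matrix(rnorm(C * D * H * W * 2), ncol = 2)
  Wm <- matrix(rnorm(Cout * C * k^3), Cout)
  b <- rnorm(Cout)
  fwd <- function(Xv, Wv, bv) {
    tb$cpp_conv3d_fw(matrix(Xv, nrow(X)), matrix(Wv, Cout), bv,
                     C, D, H, W, k, 2L, 1L, 2L, 1L)
  }
  Y <- fwd(X, Wm, b)
  g <- tb$cpp_conv3d_bw(X, Wm, Y, C, D, H, W, k, 2L, 1L, 2L, 1L, TRUE)
  loss <- function(Y) sum(Y^2) / 2 # dY = Y
  # the convolution runs in float internally: central differences need a
  # large step (forward noise ~1e-4) and a correspondingly loose tolerance
  eps <- 0.01
  relerr <- function(a, b) max(abs(a - b)) / max(1, max(abs(b)))
  expect_lt(relerr(num_grad(function(x) loss(fwd(x, Wm, b)), X, eps), g$dX), 0.02)
  expect_lt(relerr(num_grad(function(w) loss(fwd(X, w, b)), Wm, eps), g$dW), 0.02)
  expect_lt(relerr(num_grad(function(bb) loss(fwd(X, Wm, bb)), b, eps),
                   as.vector(g$db)), 0.02)
})

test_that("batchnorm forward/backward match numerical gradients", {
  set.seed(2)
  C <- 3; V <- 7; N <- 4
  X <- matrix(rnorm(C * V * N), C * V, N)
  gam <- runif(C, 0.5, 1.5); bet <- rnorm(C)
  dY <- matrix(rnorm(C * V * N), C * V, N)
  fwd <- function(Xv, g2, b2) {
    tb$cpp_bn_fw(matrix(Xv, C * V), C = C, V = V, gamma = g2, beta = b2,
                 rmean = numeric(C), rvar = rep(1, C), momentum = 0.1,
                 eps = 1e-5, training = TRUE, relu = TRUE)$Y
  }
  r <- tb$cpp_bn_fw(X, C = C, V = V, gamma = gam, beta = bet,
                    rmean = numeric(C), rvar = rep(1, C), momentum = 0.1,
                    eps = 1e-5, training = TRUE, relu = TRUE)
  bw <- tb$cpp_bn_bw(X, dY, r$Y, gam, r$mu, r$var, 1e-5, TRUE, TRUE)
  lf <- function(Y) sum(Y * dY)
  expect_lt(max(abs(bw$dX - num_grad(function(x) lf(fwd(x, gam, bet)), X))), 1e-6)
  expect_lt(max(abs(as.vector(bw$dgamma) - num_grad(function(g) lf(fwd(X, g, bet)), gam))), 1e-6)
  expect_lt(max(abs(as.vector(bw$dbeta) - num_grad(function(b) lf(fwd(X, gam, b)), bet))), 1e-6)
  # eval mode uses running statistics: different result from training mode
  ev <- tb$cpp_bn_fw(X, C = C, V = V, gamma = gam, beta = bet,
                     rmean = numeric(C), rvar = rep(1, C), momentum = 0.1,
                     eps = 1e-5, training = FALSE, relu = FALSE)
  expect_false(isTRUE(all.equal(ev$Y, r$Y)))
})

test_that("pooling operators match numerical gradients", {
  set.seed(3)
  C <- 2; D <- 5; H <- 6; W <- 5
  X <- matrix(rnorm(C * D * H * W * 3), ncol = 3)
  mp <- tb$cpp_maxpool3d_fw(X, C, D, H, W, 3L, 2L, 1L)
  dY <- matrix(rnorm(length(mp$Y)), nrow(mp$Y))
  dX <- tb$cpp_maxpool3d_bw(dY, mp$idx, nrow(X))
  ng <- num_grad(function(x) {
    sum(tb$cpp_maxpool3d_fw(matrix(x, nrow(X)), C, D, H, W, 3L, 2L, 1L)$Y * dY)
  }, X)
  expect_lt(max(abs(dX - matrix(ng, nrow(X)))), 1e-8)
  D <- 4; H <- 4; W <- 4
  X <- matrix(rnorm(C * D * H * W * 2), ncol = 2)
  ap <- tb$cpp_avgpool3d_fw(X, C, D, H, W, 2L, 2L)
  dY <- matrix(rnorm(length(ap)), nrow(ap))
  dX <- tb$cpp_avgpool3d_bw(dY, C, D, H, W, 2L, 2L)
  ng <- num_grad(function(x) {
    sum(tb$cpp_avgpool3d_fw(matrix(x, nrow(X)), C, D, H, W, 2L, 2L) * dY)
  }, X)
  expect_lt(max(abs(dX - matrix(ng, nrow(X)))), 1e-8)
})

test_that("LSTM BPTT matches numerical gradients (params and inputs)", {
  set.seed(4)
  net <- lstm_new(4, 10, 2, 2)
  xs <- lapply(1:3, function(t) matrix(rnorm(4 * 5), 4, 5))
  tgt <- matrix(0, 2, 5); tgt[cbind(sample(1:2, 5, TRUE), 1:5)] <- 1
  lstm_loss <- function(n2, xs2) tb$softmax_ce(tb$lstm_fw(n2, xs2)$Z, tgt)$loss
  fw <- tb$lstm_fw(net, xs)
  ce <- tb$softmax_ce(fw$Z, tgt)
  bw <- tb$lstm_bw(net, fw, ce$dZ)
  for (key in c("l1", "l2", "proj")) {
    for (pn in names(net$params[[key]])) {
      p0 <- net$params[[key]][[pn]]
      ng <- num_grad(function(pv) {
        n2 <- net
        n2$params[[key]][[pn]] <- if (is.null(dim(p0))) as.vector(pv) else
          matrix(pv, nrow(p0))
        lstm_loss(n2, xs)
      }, p0)
      expect_lt(max(abs(bw$grads[[key]][[pn]] - ng)), 1e-7)
    }
  }
  ngx <- num_grad(function(xv) {
    xs2 <- xs; xs2[[2]] <- matrix(xv, 4, 5); lstm_loss(net, xs2)
  }, xs[[2]])
  expect_lt(max(abs(bw$dXs[[2]] - matrix(ngx, 4, 5))), 1e-7)
})

test_that("full volumetric network backprop matches numerical gradients", {
  set.seed(5)
  net <- sfe_image_new(input_shape = c(16, 32, 32), channels = c(4, 6, 8, 10),
                       dropout = 0)
  X <- matrix(rnorm(prod(net$input_shape) * 2), ncol = 2)
  tgt <- matrix(0, 2, 2); tgt[cbind(c(1, 2), 1:2)] <- 1
  lossf <- function(n2) {
    fw <- tb$resnet_fw(n2, X, training = TRUE)
    tb$softmax_ce(fw$Z, tgt)$loss
  }
  fw <- tb$resnet_fw(net, X, training = TRUE)
  ce <- tb$softmax_ce(fw$Z, tgt)
  gr <- tb$resnet_bw(fw$net, fw$cache, ce$dZ, training = TRUE)
  probes <- list(c("stem_conv", "W"), c("fc", "W"))
  for (pr in probes) {
    p0 <- net$params[[pr[1]]][[pr[2]]]
    idx <- c(1, length(p0) %/% 2, length(p0))
    for (i in idx) {
      eps <- 1e-4
      n2 <- net
      n2$params[[pr[1]]][[pr[2]]][i] <- p0[i] + eps; lp <- lossf(n2)
      n2$params[[pr[1]]][[pr[2]]][i] <- p0[i] - eps; lm <- lossf(n2)
      expect_lt(abs((lp - lm) / (2 * eps) - gr[[pr[1]]][[pr[2]]][i]), 5e-3)
    }
  }
  # nested unit parameters (conv inside a residual unit, projection skip)
  for (pr in list(c("layer2_u1", "proj", "W"), c("layer3_u2", "conv2", "W"),
                  c("layer1_u1", "bn1", "gamma"))) {
    p0 <- net$params[[pr[1]]][[pr[2]]][[pr[3]]]
    i <- min(5, length(p0))
    eps <- 1e-4
    n2 <- net
    n2$params[[pr[1]]][[pr[2]]][[pr[3]]][i] <- p0[i] + eps; lp <- lossf(n2)
    n2$params[[pr[1]]][[pr[2]]][[pr[3]]][i] <- p0[i] - eps; lm <- lossf(n2)
    expect_lt(abs((lp - lm) / (2 * eps) - gr[[pr[1]]][[pr[2]]][[pr[3]]][i]), 5e-3)
  }
})

test_that("softmax, MLP and Adam basics", {
  set.seed(6)
  Z <- matrix(rnorm(10), 2, 5)
  P <- tb$softmax_cols(Z)
  expect_equal(colSums(P), rep(1, 5))
  # softmax backward vs numeric
  dP <- matrix(rnorm(10), 2, 5)
  dZ <- tb$softmax_bw(P, dP)
  ng <- num_grad(function(zv) sum(tb$softmax_cols(matrix(zv, 2)) * dP), Z)
  expect_lt(max(abs(dZ - matrix(ng, 2))), 1e-8)
  # MLP gradient check
  net <- tb$mlp_new(c(3, 4, 2))
  X <- matrix(rnorm(9), 3, 3)
  tgt <- matrix(0, 2, 3); tgt[1, ] <- 1
  fw <- tb$mlp_fw(net, X)
  ce <- tb$softmax_ce(fw$Z, tgt)
  bw <- tb$mlp_bw(net, fw, ce$dZ)
  p0 <- net$layers[[1]]$W
  ng <- num_grad(function(pv) {
    n2 <- net; n2$layers[[1]]$W <- matrix(pv, nrow(p0))
    tb$softmax_ce(tb$mlp_fw(n2, X)$Z, tgt)$loss
  }, p0)
  expect_lt(max(abs(bw$grads[[1]]$W - ng)), 1e-7)
  # Adam decreases a quadratic
  params <- list(w = c(5, -3))
  opt <- tb$adam_new(params, lr = 0.1)
  for (i in 1:200) {
    st <- tb$adam_step(opt, params, list(w = 2 * params$w))
    opt <- st$opt; params <- st$params
  }
  expect_lt(sum(params$w^2), 1e-2)
})
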