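# Stacked LSTM with a linear output projection, used by the sequence stage.
# Both sequence networks have 2 layers x 10 hidden units; the per-step input
# is the one-hot label context (2) concatenated with the structure-branch
# output (2). Hand-written BPTT; gate order (i, f, g, o).

#' Build a stacked LSTM classifier
#'
#' @param input_size per-step input width
#' @param hidden hidden units per layer
#' @param layers number of stacked layers
#' @param output output projection width
#' @return network object of class `tdb_lstm`
#' @export
lstm_new <- function(input_size = 4, hidden = 10, layers = 2, output = 2) {
  r <- 1 / sqrt(hidden)
  mk <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
  params <- list()
  for (l in seq_len(layers)) {
    nin <- if (l == 1) input_size else hidden
    params[[paste0("l", l)]] <- list(W = mk(4 * hidden, nin),
                                     U = mk(4 * hidden, hidden),
                                     b = numeric(4 * hidden))
  }
  params$proj <- list(W = mk(output, hidden), b = numeric(output))
  structure(list(params = params, input_size = input_size, hidden = hidden,
                 layers = layers, output = output),
            class = "tdb_lstm")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# xs: list over time of (input_size x B) matrices
lstm_fw <- function(net, xs) {
  H <- net$hidden; L <- net$layers
  s <- length(xs)
  B <- ncol(xs[[1]])
  p <- net$params
  h <- lapply(seq_len(L), function(l) matrix(0, H, B))
  cc <- lapply(seq_len(L), function(l) matrix(0, H, B))
  cache <- vector("list", s)
  for (t in seq_len(s)) {
    inp <- xs[[t]]
    step <- vector("list", L)
    for (l in seq_len(L)) {
      pl <- p[[paste0("l", l)]]
      a <- pl$W %*% inp + pl$U %*% h[[l]] + pl$b
      i <- .sigmoid(a[1:H, , drop = FALSE])
      f <- .sigmoid(a[(H + 1):(2 * H), , drop = FALSE])
      g <- tanh(a[(2 * H + 1):(3 * H), , drop = FALSE])
      o <- .sigmoid(a[(3 * H + 1):(4 * H), , drop = FALSE])
      c_new <- f * cc[[l]] + i * g
      h_new <- o * tanh(c_new)
      step[[l]] <- list(inp = inp, h_prev = h[[l]], c_prev = cc[[l]],
                        i = i, f = f, g = g, o = o, c = c_new)
      h[[l]] <- h_new
      cc[[l]] <- c_new
      inp <- h_new
    }
    cache[[t]] <- step
  }
  proj <- dense_fw(p$proj, h[[L]])
  list(Z = proj$Y, cache = cache, proj_cache = proj, h_last = h[[L]])
}

# dZ: gradient wrt the projection output (output x B).
# Returns parameter grads and per-step input grads dXs (list over time).
lstm_bw <- function(net, fw, dZ) {
  H <- net$hidden; L <- net$layers
  s <- length(fw$cache)
  B <- ncol(dZ)
  p <- net$params
  grads <- rapply(p, function(x) x * 0, how = "replace")
  gp <- dense_bw(p$proj, fw$proj_cache, dZ)
  grads$proj$W <- gp$dW; grads$proj$b <- gp$db
  dh <- lapply(seq_len(L), function(l) matrix(0, H, B))
  dc <- lapply(seq_len(L), function(l) matrix(0, H, B))
  dh[[L]] <- gp$dX
  dXs <- vector("list", s)
  for (t in rev(seq_len(s))) {
    d_lower <- NULL
    for (l in rev(seq_len(L))) {
      cc <- fw$cache[[t]][[l]]
      pl <- p[[paste0("l", l)]]
      dht <- dh[[l]]
      if (l < L && !is.null(d_lower)) dht <- dht + d_lower
      tc <- tanh(cc$c)
      do <- dht * tc
      dct <- dc[[l]] + dht * cc$o * (1 - tc^2)
      di <- dct * cc$g
      df <- dct * cc$c_prev
      dg <- dct * cc$i
      dc[[l]] <- dct * cc$f
      da <- rbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2),
                  do * cc$o * (1 - cc$o))
      key <- paste0("l", l)
      grads[[key]]$W <- grads[[key]]$W + da %*% t(cc$inp)
      grads[[key]]$U <- grads[[key]]$U + da %*% t(cc$h_prev)
      grads[[key]]$b <- grads[[key]]$b + rowSums(da)
      dh[[l]] <- t(pl$U) %*% da
      d_lower <- t(pl$W) %*% da
    }
    dXs[[t]] <- d_lower
  }
  list(grads = grads, dXs = dXs)
}
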