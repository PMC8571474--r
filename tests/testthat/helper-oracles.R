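# Fixture builders and independent oracles. Oracles are deliberately naive
# (loops, enumeration) and share no code with the implementation they check.

make_chain <- function(n, origin = c(0, 0, 0), step = c(1, 0, 0), type = 3L) {
  # origin/step are SWC (x, y, z)
  neuron_forest(data.frame(
    id = seq_len(n), type = c(if (n > 0) 1L else integer(), rep(type, max(0, n - 1))),
    x = origin[1] + (seq_len(n) - 1) * step[1],
    y = origin[2] + (seq_len(n) - 1) * step[2],
    z = origin[3] + (seq_len(n) - 1) * step[3],
    radius = 1, parent = c(-1L, seq_len(n - 1))[seq_len(n)]))
}

# root(1) - stem(2) - two daughter branches of `arm` nodes each
make_y_tree <- function(arm = 2, origin = c(0, 0, 0)) {
  ids <- 1:(2 + 2 * arm)
  par <- c(-1L, 1L,
           2L, if (arm > 1) 2L + seq_len(arm - 1),
           2L, if (arm > 1) 2L + arm + seq_len(arm - 1))
  xs <- c(0, 1, 1 + seq_len(arm), 1 + seq_len(arm))
  ys <- c(0, 0, seq_len(arm), -seq_len(arm))
  neuron_forest(data.frame(id = ids, type = c(1L, rep(3L, length(ids) - 1)),
                           x = origin[1] + xs, y = origin[2] + ys,
                           z = origin[3], radius = 1, parent = par))
}

# random tree: node i's parent drawn uniformly among 1..i-1
make_random_tree <- function(n, seed, spread = 20) {
  set.seed(seed)
  par <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1), 0L))
  neuron_forest(data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1)),
                           x = runif(n, 0, spread), y = runif(n, 0, spread),
                           z = runif(n, 0, spread), radius = runif(n, .5, 2),
                           parent = par))
}

# preorder oracle: recursive, children in ascending id order
oracle_preorder <- function(forest, root_id) {
  nodes <- forest$nodes
  kids_of <- function(id) sort(nodes$id[nodes$parent == id])
  walk <- function(id) {
    out <- id
    for (k in kids_of(id)) out <- c(out, walk(k))
    out
  }
  walk(root_id)
}

# per-node nearest distance oracle: explicit double loop
oracle_nearest <- function(a, b) {
  pa <- cbind(a$nodes$x, a$nodes$y, a$nodes$z)
  pb <- cbind(b$nodes$x, b$nodes$y, b$nodes$z)
  out <- numeric(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    best <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# full 7-distance-feature oracle built on oracle_nearest
oracle_distance_features <- function(gold, auto) {
  d12 <- oracle_nearest(gold, auto)
  d21 <- oracle_nearest(auto, gold)
  pool <- c(d12, d21)
  far <- pool[pool > 2]
  c(esa12 = mean(d12), esa21 = mean(d21), esa = (mean(d12) + mean(d21)) / 2,
    dsa2 = if (length(far)) mean(far) else 0,
    pds12 = sum(d12 >= 2) / length(d12), pds21 = sum(d21 >= 2) / length(d21),
    pds = (sum(d12 >= 2) + sum(d21 >= 2)) / length(pool))
}

# connected components of the parent graph, by naive union-find
oracle_components <- function(forest) {
  nodes <- forest$nodes
  n <- nrow(nodes)
  if (n == 0) return(0L)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) {
    p <- match(nodes$parent[i], nodes$id)
    if (!is.na(p)) comp[find(i)] <- find(p)
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# bifurcation count oracle: count children per node explicitly
oracle_bifurcations <- function(forest) {
  nodes <- forest$nodes
  sum(vapply(nodes$id, function(id) sum(nodes$parent == id) >= 2, logical(1)))
}

# a tiny labeled feature corpus: two Gaussian classes in 10-D whose labels
# follow a known rule on the features, plus optional label noise
make_feature_corpus <- function(n, seed, noise = 0.03, shift = 2.5) {
  set.seed(seed)
  y <- sample(c("low", "high"), n, replace = TRUE)
  X <- matrix(rnorm(10 * n), 10, n)
  X[, y == "high"] <- X[, y == "high"] + shift * (1:10 %in% c(1, 3, 5, 7)) # esa-ish dims
  flip <- runif(n) < noise
  y[flip] <- ifelse(y[flip] == "low", "high", "low")
  list(X = X, y = y)
}
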