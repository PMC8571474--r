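# Reconstruction-similarity metrics between gold and auto fragment forests.
#
# The 7 distance features follow the ESA/DSA/PDS family used for comparing
# neuron reconstructions: bidirectional mean nearest-node distances, the mean
# over node pairs farther than 2 voxels apart (DSA2), and the fraction of
# nodes at distance >= 2 voxels (PDS). Thresholds intentionally differ:
# DSA2 uses strictly > 2, PDS uses >= 2.

.node_positions <- function(forest) {
  cbind(forest$nodes$z, forest$nodes$y, forest$nodes$x)
}

#' Nearest-node distances from one forest to another
#'
#' @param a,b non-empty [neuron_forest()] objects
#' @return numeric vector, one entry per node of `a`: the Euclidean distance
#'   to the nearest node of `b`
#' @export
nearest_distances <- function(a, b) {
  if (n_nodes(a) == 0 || n_nodes(b) == 0) {
    stop("nearest_distances: both forests must be non-empty")
  }
  pa <- .node_positions(a)
  pb <- .node_positions(b)
  # explicit differences: the |a|^2+|b|^2-2ab form loses ~1e-6 of precision
  # to cancellation for near-coincident nodes, which matters at the stated
  # 1e-9 oracle tolerance
  b1 <- pb[, 1]; b2 <- pb[, 2]; b3 <- pb[, 3]
  vapply(seq_len(nrow(pa)), function(i) {
    sqrt(min((b1 - pa[i, 1])^2 + (b2 - pa[i, 2])^2 + (b3 - pa[i, 3])^2))
  }, 0)
}

#' Seven neuron-distance features between a gold and an auto block
#'
#' `esa12` / `esa21` are mean nearest-node distances gold-to-auto and
#' auto-to-gold; `esa` is their average. `dsa2` is the mean of all pooled
#' distances strictly above 2 voxels (0 when none). `pds12` / `pds21` are the
#' fractions of nodes at distance >= 2 voxels from the other reconstruction,
#' and `pds` is the pooled fraction over all nodes of both.
#'
#' @param gold,auto non-empty [neuron_forest()] objects
#' @return named numeric vector
#'   `(esa12, esa21, esa, dsa2, pds12, pds21, pds)`
#' @export
neuron_distance_features <- function(gold, auto) {
  d12 <- nearest_distances(gold, auto)
  d21 <- nearest_distances(auto, gold)
  pooled <- c(d12, d21)
  far <- pooled[pooled > 2]
  c(esa12 = mean(d12),
    esa21 = mean(d21),
    esa   = (mean(d12) + mean(d21)) / 2,
    dsa2  = if (length(far)) mean(far) else 0,
    pds12 = mean(d12 >= 2),
    pds21 = mean(d21 >= 2),
    pds   = (sum(d12 >= 2) + sum(d21 >= 2)) / (length(d12) + length(d21)))
}

#' Morphology-count differences between gold and auto blocks
#'
#' @param gold,auto [neuron_forest()] objects (empty allowed; counts are 0)
#' @return named numeric vector
#'   `(d_bifurcations, d_nodes, d_fragments)` of absolute count differences
#' @export
morphology_difference <- function(gold, auto) {
  c(d_bifurcations = abs(count_bifurcations(gold) - count_bifurcations(auto)),
    d_nodes = abs(n_nodes(gold) - n_nodes(auto)),
    d_fragments = abs(count_fragments(gold) - count_fragments(auto)))
}

#' Ten similarity features for one gold/auto block pair
#'
#' Concatenation of [neuron_distance_features()] and
#' [morphology_difference()], in that order. This 10-vector is the input of
#' the automatic difficulty labeler.
#'
#' @param gold,auto non-empty [neuron_forest()] objects
#' @return named numeric vector of length 10
#' @export
similarity_features <- function(gold, auto) {
  c(neuron_distance_features(gold, auto), morphology_difference(gold, auto))
}

# ---- L-Measure-style morphometrics ------------------------------------------

#' Names of the 32 morphometric features, in output order
#' @return character vector of length 32
#' @export
lmeasure_feature_names <- function() {
  c("n_stems", "n_bifurcations", "n_branches", "n_tips", "n_fragments",
    "total_branch_length", "mean_branch_length", "max_branch_length",
    "total_length", "width", "height", "depth",
    "mean_radius", "max_radius", "total_surface", "total_volume",
    "mean_euclidean_distance", "max_euclidean_distance",
    "mean_path_distance", "max_path_distance",
    "mean_contraction", "fragmentation",
    "mean_branch_order", "max_branch_order",
    "partition_asymmetry", "bif_angle_local", "bif_angle_remote",
    "parent_child_length_ratio", "daughter_radius_ratio",
    "tortuosity_mean", "tortuosity_max", "n_terminal_segments")
}

# Decompose a forest into branches: maximal paths between critical nodes
# (roots, bifurcations, tips). Returns a list of integer row-index paths,
# each starting at a critical node (or root) and ending at the next one.
.forest_branches <- function(nodes) {
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  nkids <- tabulate(pidx[!is.na(pidx)], nbins = n)
  is_root <- is.na(pidx)
  is_crit <- is_root | nkids >= 2
  # child lists sorted by id
  kids <- vector("list", n)
  ch_rows <- which(!is.na(pidx))
  if (length(ch_rows)) {
    ord <- order(pidx[ch_rows], nodes$id[ch_rows])
    ch_rows <- ch_rows[ord]
    sp <- split(ch_rows, pidx[ch_rows])
    kids[as.integer(names(sp))] <- sp
  }
  branches <- list()
  for (start in which(is_crit)) {
    for (first in kids[[start]]) {
      path <- c(start, first)
      cur <- first
      while (!is_crit[cur] && nkids[cur] == 1) {
        cur <- kids[[cur]][1]
        path <- c(path, cur)
      }
      branches[[length(branches) + 1L]] <- path
    }
  }
  branches
}

.edge_lengths <- function(nodes) {
  pidx <- match(nodes$parent, nodes$id)
  has <- !is.na(pidx)
  dx <- nodes$x[has] - nodes$x[pidx[has]]
  dy <- nodes$y[has] - nodes$y[pidx[has]]
  dz <- nodes$z[has] - nodes$z[pidx[has]]
  len <- sqrt(dx^2 + dy^2 + dz^2)
  list(child = which(has), parent = pidx[has], len = len)
}

.safe_mean <- function(x) if (length(x)) mean(x) else 0
.safe_max <- function(x) if (length(x)) max(x) else 0

#' Morphometric feature vector of an auto block
#'
#' Evaluates the fixed 32-feature registry (see [lmeasure_feature_names()])
#' on a fragment forest: counts (stems, bifurcations, branches, tips,
#' fragments), lengths, spatial extents, radii, frustum surface/volume,
#' Euclidean and path distances from each fragment root, contraction and
#' tortuosity (chord/path and path/chord per branch), branch orders,
#' partition asymmetry, bifurcation angles and ratio statistics. All values
#' are finite for any non-empty forest.
#'
#' @param auto non-empty [neuron_forest()]
#' @return named numeric vector of length 32
#' @export
lmeasure_features <- function(auto) {
  nodes <- auto$nodes
  if (nrow(nodes) == 0) stop("lmeasure_features: empty forest")
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  nkids <- tabulate(pidx[!is.na(pidx)], nbins = n)
  is_root <- is.na(pidx)
  frag <- fragment_ids(auto)

  el <- .edge_lengths(nodes)
  total_length <- sum(el$len)

  branches <- .forest_branches(nodes)
  blen <- vapply(branches, function(p) {
    sum(sqrt(diff(nodes$x[p])^2 + diff(nodes$y[p])^2 + diff(nodes$z[p])^2))
  }, numeric(1))
  bchord <- vapply(branches, function(p) {
    a <- p[1]; b <- p[length(p)]
    sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2 +
         (nodes$z[a] - nodes$z[b])^2)
  }, numeric(1))
  ok <- blen > 0
  contraction <- ifelse(ok, bchord / blen, 1)
  tortuosity <- ifelse(ok & bchord > 0, blen / bchord, 1)

  # per-node Euclidean and path distance from the fragment root
  rootpos <- cbind(nodes$z[frag], nodes$y[frag], nodes$x[frag])
  pos <- cbind(nodes$z, nodes$y, nodes$x)
  eud <- sqrt(rowSums((pos - rootpos)^2))
  pathd <- numeric(n)
  edge_len_by_child <- numeric(n)
  edge_len_by_child[el$child] <- el$len
  # accumulate along preorder: parents always precede children there
  for (r in which(is_root)) {
    ord <- match(traversal_order(auto, nodes$id[r]), nodes$id)
    for (i in ord[-1]) pathd[i] <- pathd[pidx[i]] + edge_len_by_child[i]
  }

  # branch order: number of bifurcations strictly above the node
  border <- integer(n)
  for (r in which(is_root)) {
    ord <- match(traversal_order(auto, nodes$id[r]), nodes$id)
    for (i in ord[-1]) border[i] <- border[pidx[i]] + as.integer(nkids[pidx[i]] >= 2)
  }

  # subtree tip counts for partition asymmetry
  tipcount <- as.integer(nkids == 0)
  for (r in which(is_root)) {
    ord <- rev(match(traversal_order(auto, nodes$id[r]), nodes$id))
    for (i in ord) if (!is.na(pidx[i])) tipcount[pidx[i]] <- tipcount[pidx[i]] + tipcount[i]
  }
  bif_rows <- which(nkids >= 2)
  pa <- vapply(bif_rows, function(b) {
    ch <- which(!is.na(pidx) & pidx == b)
    ch <- ch[order(nodes$id[ch])][1:2]
    l <- tipcount[ch[1]]; r <- tipcount[ch[2]]
    if (l + r <= 2) 0 else abs(l - r) / (l + r - 2)
  }, numeric(1))

  # bifurcation angles: local (to immediate children), remote (to branch ends)
  angle <- function(v1, v2) {
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) return(0)
    acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1))
  }
  branch_end <- function(start_row, first_row) {
    cur <- first_row
    while (nkids[cur] == 1) {
      nxt <- which(!is.na(pidx) & pidx == cur)
      cur <- nxt[1]
    }
    cur
  }
  ang_local <- numeric(0); ang_remote <- numeric(0)
  for (b in bif_rows) {
    ch <- which(!is.na(pidx) & pidx == b)
    ch <- ch[order(nodes$id[ch])][1:2]
    p0 <- c(nodes$x[b], nodes$y[b], nodes$z[b])
    v1 <- c(nodes$x[ch[1]], nodes$y[ch[1]], nodes$z[ch[1]]) - p0
    v2 <- c(nodes$x[ch[2]], nodes$y[ch[2]], nodes$z[ch[2]]) - p0
    ang_local <- c(ang_local, angle(v1, v2))
    e1 <- branch_end(b, ch[1]); e2 <- branch_end(b, ch[2])
    w1 <- c(nodes$x[e1], nodes$y[e1], nodes$z[e1]) - p0
    w2 <- c(nodes$x[e2], nodes$y[e2], nodes$z[e2]) - p0
    ang_remote <- c(ang_remote, angle(w1, w2))
  }

  # daughter radius ratio (larger/smaller) at bifurcations
  dratio <- vapply(bif_rows, function(b) {
    ch <- which(!is.na(pidx) & pidx == b)
    ch <- ch[order(nodes$id[ch])][1:2]
    r1 <- nodes$radius[ch[1]]; r2 <- nodes$radius[ch[2]]
    lo <- min(r1, r2); hi <- max(r1, r2)
    if (lo <= 0) 1 else hi / lo
  }, numeric(1))

  # parent/child branch length ratio: daughter branch length over the length
  # of the branch ending at its starting bifurcation
  binto <- integer(n) # branch index ending at node row (by last path element)
  for (i in seq_along(branches)) binto[branches[[i]][length(branches[[i]])]] <- i
  pc_ratio <- numeric(0)
  for (i in seq_along(branches)) {
    start <- branches[[i]][1]
    pb <- binto[start]
    if (pb > 0 && blen[pb] > 0) pc_ratio <- c(pc_ratio, blen[i] / blen[pb])
  }

  # frustum surface / volume over edges
  rad_c <- nodes$radius[el$child]; rad_p <- nodes$radius[el$parent]
  slant <- sqrt(el$len^2 + (rad_p - rad_c)^2)
  surface <- sum(pi * (rad_c + rad_p) * slant)
  volume <- sum(pi / 3 * el$len * (rad_p^2 + rad_p * rad_c + rad_c^2))

  tips <- which(nkids == 0)
  # terminal segments: branches ending at a tip
  term_seg <- sum(vapply(branches, function(p) nkids[p[length(p)]] == 0, logical(1)))
  stems <- sum(!is.na(pidx) & is_root[pidx]) # children of roots

  out <- c(
    n_stems = stems,
    n_bifurcations = length(bif_rows),
    n_branches = length(branches),
    n_tips = length(tips),
    n_fragments = length(unique(frag)),
    total_branch_length = sum(blen),
    mean_branch_length = .safe_mean(blen),
    max_branch_length = .safe_max(blen),
    total_length = total_length,
    width = diff(range(nodes$x)),
    height = diff(range(nodes$y)),
    depth = diff(range(nodes$z)),
    mean_radius = mean(nodes$radius),
    max_radius = max(nodes$radius),
    total_surface = surface,
    total_volume = volume,
    mean_euclidean_distance = mean(eud),
    max_euclidean_distance = max(eud),
    mean_path_distance = mean(pathd),
    max_path_distance = max(pathd),
    mean_contraction = .safe_mean(contraction),
    fragmentation = n,
    mean_branch_order = mean(border),
    max_branch_order = max(border),
    partition_asymmetry = .safe_mean(pa),
    bif_angle_local = .safe_mean(ang_local),
    bif_angle_remote = .safe_mean(ang_remote),
    parent_child_length_ratio = .safe_mean(pc_ratio),
    daughter_radius_ratio = .safe_mean(dratio),
    tortuosity_mean = .safe_mean(tortuosity),
    tortuosity_max = .safe_max(tortuosity),
    n_terminal_segments = term_seg
  )
  stopifnot(length(out) == 32, all(is.finite(out)))
  out
}
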