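# Seed-reproducible synthetic corpora: random neuron trees, tube-rendered
# noisy volumes, and fidelity-controlled "auto" reconstructions whose
# perturbation regime defines a known low/high tracing difficulty.
#
# Difficulty is generative, not feature-thresholded: a 2-state Markov chain
# along each neuron's anchor order picks the regime per 100-node segment;
# high segments are rendered dimmer (weak signal) and their auto
# reconstruction is jittered harder, loses subtrees, breaks into fragments
# and grows spurious branches. Downstream classifiers therefore face real
# (if simplified) signal, and label recovery is non-circular.

#' Synthetic-corpus configuration
#'
#' @param n_neurons number of neurons to simulate
#' @param nodes_per_neuron nodes in each gold tree (anchors every
#'   `anchor step` of them)
#' @param step_length inter-node spacing in voxels
#' @param angle_jitter_sd std dev of the per-step direction perturbation
#' @param radial_drift outward bias away from the soma (in the y/x plane
#'   only; depth wanders freely within the slab-shaped volume), keeping
#'   neurites radiating instead of re-visiting already-innervated territory
#' @param segment_length_range node-count range of one neurite growth
#'   segment before the walker yields to a queued branch seed
#' @param max_radius growth leash: a tip terminates when it strays this far
#'   from the soma, so the arbor fills a ball instead of crawling along the
#'   volume walls
#' @param branch_prob per-node probability of spawning a side branch
#' @param volume_shape rendered volume extents (z, y, x)
#' @param tube_radius neurite tube radius in voxels
#' @param fg_low,fg_high foreground intensity in low/high-difficulty
#'   segments (high-difficulty signal is weaker)
#' @param bg_mean,noise_sd background level and additive Gaussian noise
#' @param n_distractors independent short tubes rendered but absent from the
#'   reconstructions (crossing signals from other neurons)
#' @param jitter_low,jitter_high auto-reconstruction coordinate jitter (voxels)
#' @param branch_drop_high probability that a small high-regime side branch
#'   (subtree of at most `branch_drop_max_nodes` nodes) is lost entirely
#' @param branch_drop_max_nodes size cap for whole-subtree drops, keeping
#'   tracer failures local to their segment
#' @param gap_prob_high per-node probability that a high-segment node opens
#'   a tracing gap: a short downstream run disappears and the remainder
#'   continues as a separate fragment
#' @param gap_len_range node-count range of a tracing gap
#' @param break_prob_high per-node probability of snapping the auto tree in
#'   high segments without losing nodes (fragments)
#' @param spurious_rate_high per-node probability of growing a spurious
#'   branch in high segments
#' @param persistence probability that consecutive anchors share a
#'   difficulty label (0.5 = independent); default emulates the observed
#'   ~60% adjacent-label agreement
#' @param node_radius,soma_radius SWC radii in voxels
#' @return named list of parameters
#' @export
synth_config <- function(n_neurons = 8, nodes_per_neuron = 2600,
                         step_length = 1.0, angle_jitter_sd = 0.08,
                         radial_drift = 0.08,
                         branch_prob = 0.012, volume_shape = c(96, 576, 576),
                         segment_length_range = c(100, 250), max_radius = 250,
                         tube_radius = 1.6, fg_low = 160, fg_high = 70,
                         bg_mean = 40, noise_sd = 12, n_distractors = 6,
                         jitter_low = 0.15, jitter_high = 3.0,
                         branch_drop_high = 0.5, branch_drop_max_nodes = 40,
                         gap_prob_high = 0.03, gap_len_range = c(8, 25),
                         break_prob_high = 0.008,
                         spurious_rate_high = 0.03, persistence = 0.6,
                         node_radius = 1.2, soma_radius = 4) {
  stopifnot(branch_prob >= 0, branch_prob <= 1,
            persistence >= 0, persistence <= 1,
            nodes_per_neuron >= 1, step_length > 0)
  as.list(environment())
}

.unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

#' Simulate one random neuron tree
#'
#' A biased random walk from a soma near the volume centre; at each step the
#' growth direction is jittered, and with probability `branch_prob` a side
#' branch with a rotated direction is spawned. Growth is steered back inward
#' near the volume faces so the tree stays inside.
#'
#' @param cfg a [synth_config()]
#' @return a [neuron_forest()] with a soma-typed root (positions are SWC
#'   (x, y, z) columns in the volume frame)
#' @export
simulate_neuron_tree <- function(cfg) {
  if (cfg$nodes_per_neuron < 1) stop("simulate_neuron_tree: degenerate config")
  shp <- cfg$volume_shape # (z, y, x)
  margin <- 4
  n_target <- cfg$nodes_per_neuron
  pos <- matrix(NA_real_, n_target, 3) # (z, y, x)
  parent <- integer(n_target)
  # soma somewhere around the middle of the volume
  pos[1, ] <- shp / 2 + runif(3, -0.1, 0.1) * shp
  parent[1] <- -1L
  n <- 1L
  # depth-first growth: one neurite extends at a time for a random segment
  # length; branch seeds spawned along the way are grown later (LIFO). This
  # yields long radiating paths rather than a dense ball around the soma.
  rand_dir <- function() .unit_vec(rnorm(3) * c(0.3, 1, 1)) # mostly planar
  seeds <- list(list(at = 1L, dir = rand_dir()))
  while (n < n_target) {
    seed <- seeds[[length(seeds)]]
    seeds[[length(seeds)]] <- NULL
    seg_len <- sample(cfg$segment_length_range[1]:cfg$segment_length_range[2], 1)
    at <- seed$at
    dir <- seed$dir
    for (step in seq_len(seg_len)) {
      if (n >= n_target) break
      radial <- .unit_vec(c(0, pos[at, 2:3] - pos[1, 2:3]))
      dir <- .unit_vec(dir + rnorm(3, sd = cfg$angle_jitter_sd) +
                         cfg$radial_drift * radial)
      p <- pos[at, ] + dir * cfg$step_length
      if (sqrt(sum((p - pos[1, ])^2)) > cfg$max_radius ||
          any(p < margin | p > shp - margin)) {
        if (length(seeds) > 0) break
        # nothing else can grow: steer this tip back toward the soma rather
        # than terminating (keeps branch_prob = 0 an unbranched chain, since
        # the soma is never re-seeded)
        dir <- .unit_vec(dir + 2 * .unit_vec(pos[1, ] - pos[at, ]))
        p <- pos[at, ] + dir * cfg$step_length
        p <- pmin(pmax(p, 1), shp - 1)
      }
      n <- n + 1L
      pos[n, ] <- p
      parent[n] <- at
      at <- n
      if (n < n_target && runif(1) < cfg$branch_prob) {
        # branches leave the parent path quickly
        seeds[[length(seeds) + 1L]] <- list(at = n, dir = rand_dir())
      }
    }
    if (length(seeds) == 0 && n < n_target) {
      # segment budget exhausted with an empty queue: the neurite keeps
      # extending from its current tip
      seeds <- list(list(at = at, dir = dir))
    }
  }
  nodes <- data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
                      x = pos[1:n, 3], y = pos[1:n, 2], z = pos[1:n, 1],
                      radius = c(cfg$soma_radius, rep(cfg$node_radius, n - 1L)),
                      parent = parent[1:n])
  neuron_forest(nodes)
}

# stamp a tube of given intensity around each edge of `forest` into vol
# (max-composited); intensity is per-node (child node of each edge)
.render_tubes <- function(vol, forest, intensity, radius) {
  shp <- dim(vol)
  r <- ceiling(radius)
  off <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  off <- off[sqrt(off$dz^2 + off$dy^2 + off$dx^2) <= radius + 0.2, ]
  off <- as.matrix(off)
  nodes <- forest$nodes
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    p1 <- c(nodes$z[i], nodes$y[i], nodes$x[i])
    ints <- intensity[i]
    if (is.na(pidx[i])) {
      pts <- matrix(p1, 1)
    } else {
      p0 <- c(nodes$z[pidx[i]], nodes$y[pidx[i]], nodes$x[pidx[i]])
      seg <- p1 - p0
      len <- sqrt(sum(seg^2))
      ts <- seq(0, 1, length.out = max(2L, ceiling(len / 0.7) + 1L))
      pts <- t(sapply(ts, function(t) p0 + t * seg))
    }
    for (j in seq_len(nrow(pts))) {
      vox <- sweep(off, 2, round(pts[j, ]), "+")
      ok <- vox[, 1] >= 0 & vox[, 1] < shp[1] &
            vox[, 2] >= 0 & vox[, 2] < shp[2] &
            vox[, 3] >= 0 & vox[, 3] < shp[3]
      if (!any(ok)) next
      v <- vox[ok, , drop = FALSE]
      lin <- v[, 1] + 1 + v[, 2] * shp[1] + v[, 3] * shp[1] * shp[2] # (z,y,x) array
      cur <- vol[lin]
      vol[lin] <- pmax(cur, ints)
    }
  }
  vol
}

#' Render a noisy volume from a neuron tree
#'
#' Neurite edges are rasterized as tubes of foreground intensity over a flat
#' background; independent distractor tubes (crossing signal not in any
#' reconstruction) are added, then i.i.d. Gaussian noise. Intensities are
#' clipped at zero.
#'
#' @param tree a [neuron_forest()] inside the volume bounds
#' @param cfg a [synth_config()]
#' @param node_intensity optional per-node foreground intensity (defaults to
#'   `fg_low` everywhere)
#' @return an [image_volume()]
#' @export
render_volume <- function(tree, cfg, node_intensity = NULL) {
  shp <- cfg$volume_shape
  pos <- cbind(tree$nodes$z, tree$nodes$y, tree$nodes$x)
  if (nrow(pos) && (any(pos < 0) || any(sweep(pos, 2, shp) >= 0))) {
    stop("render_volume: tree outside volume bounds")
  }
  if (is.null(node_intensity)) node_intensity <- rep(cfg$fg_low, n_nodes(tree))
  vol <- array(0, dim = shp)
  vol <- .render_tubes(vol, tree, node_intensity, cfg$tube_radius)
  if (cfg$n_distractors > 0) {
    for (d in seq_len(cfg$n_distractors)) {
      start <- runif(3) * (shp - 20) + 10
      dir <- .unit_vec(rnorm(3))
      npts <- 25
      pts <- t(sapply(seq_len(npts), function(i) start + dir * (i - 1) * 1.5))
      pts <- pmin(pmax(pts, 1), matrix(shp - 1, npts, 3, byrow = TRUE))
      dn <- data.frame(id = seq_len(npts), type = 3L,
                       x = pts[, 3], y = pts[, 2], z = pts[, 1],
                       radius = cfg$node_radius,
                       parent = c(-1L, seq_len(npts - 1L)))
      vol <- .render_tubes(vol, neuron_forest(dn),
                           rep(cfg$fg_low, npts), cfg$tube_radius)
    }
  }
  bg <- vol == 0
  vol[bg] <- cfg$bg_mean
  if (cfg$noise_sd > 0) {
    vol <- vol + array(rnorm(length(vol), sd = cfg$noise_sd), dim = shp)
  }
  vol[vol < 0] <- 0
  image_volume(vol)
}

#' Perturb a gold reconstruction into a synthetic "auto" reconstruction
#'
#' Low difficulty applies small coordinate jitter only. High difficulty
#' additionally drops whole branches, snaps the tree into fragments and
#' grows short spurious branches, emulating how automatic tracers fail on
#' weak or ambiguous signal.
#'
#' @param gold a [neuron_forest()]
#' @param difficulty `"low"`, `"high"`, or a per-node character vector
#'   aligned with the gold nodes
#' @param cfg a [synth_config()]
#' @return a [neuron_forest()] clipped to the volume bounds
#' @export
perturb_to_auto <- function(gold, difficulty, cfg) {
  nodes <- gold$nodes
  n <- nrow(nodes)
  if (n == 0) return(gold)
  if (length(difficulty) == 1) difficulty <- rep(difficulty, n)
  stopifnot(length(difficulty) == n, all(difficulty %in% c("low", "high")))
  hi <- difficulty == "high"
  sd_vec <- ifelse(hi, cfg$jitter_high, cfg$jitter_low)
  nodes$x <- nodes$x + rnorm(n, sd = sd_vec)
  nodes$y <- nodes$y + rnorm(n, sd = sd_vec)
  nodes$z <- nodes$z + rnorm(n, sd = sd_vec)

  pidx <- match(nodes$parent, nodes$id)
  nkids <- tabulate(pidx[!is.na(pidx)], nbins = n)
  # subtree sizes (iterate child->parent to fixpoint)
  subtree <- rep(1L, n)
  ordn <- order(nodes$id) # ids were assigned in growth order: parents first
  for (i in rev(seq_len(n))) {
    r <- ordn[i]
    if (!is.na(pidx[r])) subtree[pidx[r]] <- subtree[pidx[r]] + subtree[r]
  }
  # (a) lose small high-regime side branches entirely (with all descendants);
  # the size cap keeps tracer failures local to their segment
  branch_children <- which(!is.na(pidx) & nkids[pidx] >= 2 &
                           subtree <= cfg$branch_drop_max_nodes)
  drop_roots <- branch_children[hi[branch_children] &
                                runif(length(branch_children)) < cfg$branch_drop_high]
  drop_a <- logical(n)
  drop_a[drop_roots] <- TRUE
  haspar <- which(!is.na(pidx))
  repeat {
    newly <- haspar[!drop_a[haspar] & drop_a[pidx[haspar]]]
    if (length(newly) == 0) break
    drop_a[newly] <- TRUE
  }
  # (b) tracing gaps: from a high node, a short downstream run disappears
  # and whatever follows becomes a new fragment (via the parent re-link)
  drop_gap <- logical(n)
  gap_starts <- which(hi & runif(n) < cfg$gap_prob_high)
  for (g in gap_starts) {
    len <- sample(cfg$gap_len_range[1]:cfg$gap_len_range[2], 1)
    cur <- g
    for (k in seq_len(len)) {
      drop_gap[cur] <- TRUE
      ch <- which(!is.na(pidx) & pidx == cur)
      if (length(ch) == 0) break
      cur <- ch[1]
    }
  }
  dropped <- drop_a | drop_gap
  if (any(dropped)) {
    nodes <- nodes[!dropped, , drop = FALSE]
    hi <- hi[!dropped]
    nodes$parent[!(nodes$parent %in% nodes$id)] <- -1L
    n <- nrow(nodes)
    pidx <- match(nodes$parent, nodes$id)
  }
  # snap edges in high segments: the child becomes a fragment root
  if (n > 0) {
    snap <- hi & nodes$parent != -1 & runif(n) < cfg$break_prob_high
    nodes$parent[snap] <- -1L
  }
  # spurious short branches sprouting from high-regime nodes
  if (n > 0) {
    sprout <- which(hi & runif(n) < cfg$spurious_rate_high)
    if (length(sprout)) {
      next_id <- max(nodes$id) + 1L
      extra <- list()
      for (sidx in sprout) {
        len <- sample(3:8, 1)
        dir <- .unit_vec(rnorm(3)) # (z, y, x)
        base <- c(nodes$z[sidx], nodes$y[sidx], nodes$x[sidx])
        par <- nodes$id[sidx]
        for (i in seq_len(len)) {
          p <- base + dir * i * cfg$step_length + rnorm(3, sd = 0.2)
          extra[[length(extra) + 1L]] <- data.frame(
            id = next_id, type = 3L, x = p[3], y = p[2], z = p[1],
            radius = cfg$node_radius, parent = par)
          par <- next_id
          next_id <- next_id + 1L
        }
      }
      nodes <- rbind(nodes, do.call(rbind, extra))
    }
  }
  shp <- cfg$volume_shape
  nodes$x <- pmin(pmax(nodes$x, 0), shp[3] - 1e-6)
  nodes$y <- pmin(pmax(nodes$y, 0), shp[2] - 1e-6)
  nodes$z <- pmin(pmax(nodes$z, 0), shp[1] - 1e-6)
  rownames(nodes) <- NULL
  neuron_forest(nodes)
}

#' Generate a fully labeled synthetic block corpus
#'
#' Runs simulate -> label segments by a Markov chain -> render -> perturb ->
#' build blocks for `cfg$n_neurons` neurons. Each 100-node segment of the
#' gold traversal carries one difficulty regime; consecutive segments agree
#' with probability `cfg$persistence`. Block labels are the regime of their
#' anchor segment (known by construction).
#'
#' @param cfg a [synth_config()]
#' @param seed integer seed; the corpus is a pure function of (cfg, seed)
#' @param block_cfg a [block_config()]
#' @param keep_volumes keep rendered volumes in the result (memory-hungry)
#' @return list with `blocks` (list of labeled blocks), `manifest`
#'   (data frame: neuron_id, block_index, anchor coordinates,
#'   anchor_order_index, label), `config`, `seed`
#' @export
generate_labeled_corpus <- function(cfg = synth_config(), seed = 1,
                                    block_cfg = block_config(),
                                    keep_volumes = FALSE) {
  set.seed(seed)
  blocks <- list()
  volumes <- list()
  rows <- list()
  for (ni in seq_len(cfg$n_neurons)) {
    neuron_id <- sprintf("synth%02d", ni)
    gold <- simulate_neuron_tree(cfg)
    ord <- traversal_order(gold, soma_root(gold))
    n_seg <- ceiling(length(ord) / block_cfg$anchor_step)
    seg_label <- character(n_seg)
    seg_label[1] <- sample(c("low", "high"), 1)
    for (s in seq_len(n_seg - 1) + 1) {
      seg_label[s] <- if (runif(1) < cfg$persistence) seg_label[s - 1] else
        setdiff(c("low", "high"), seg_label[s - 1])
    }
    # per-node regime: difficulty is a local image property (signal quality),
    # so every node takes the regime of its spatially nearest anchor; nodes
    # on the anchor path effectively keep their own segment's regime
    anchors <- select_anchors(gold, block_cfg$anchor_step)
    apos <- cbind(anchors$z, anchors$y, anchors$x)
    npos <- cbind(gold$nodes$z, gold$nodes$y, gold$nodes$x)
    d2 <- outer(rowSums(npos^2), rowSums(apos^2), "+") - 2 * npos %*% t(apos)
    nearest_anchor <- max.col(-d2, ties.method = "first")
    aseg <- anchors$order_index %/% block_cfg$anchor_step + 1L
    node_diff <- seg_label[aseg[nearest_anchor]]
    node_int <- ifelse(node_diff == "high", cfg$fg_high, cfg$fg_low)
    vol <- render_volume(gold, cfg, node_intensity = node_int)
    auto <- perturb_to_auto(gold, node_diff, cfg)
    blks <- build_blocks(vol, gold, auto, block_cfg, neuron_id = neuron_id)
    for (b in blks) {
      b$label <- seg_label[b$anchor_order_index %/% block_cfg$anchor_step + 1L]
      blocks[[length(blocks) + 1L]] <- b
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = neuron_id, block_index = length(blocks),
        anchor_z = b$anchor[1], anchor_y = b$anchor[2], anchor_x = b$anchor[3],
        anchor_order_index = b$anchor_order_index, label = b$label)
    }
    if (keep_volumes) volumes[[neuron_id]] <- vol
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = character(), block_index = integer(),
               anchor_z = numeric(), anchor_y = numeric(), anchor_x = numeric(),
               anchor_order_index = integer(), label = character())
  out <- list(blocks = blocks, manifest = manifest, config = cfg, seed = seed)
  if (keep_volumes) out$volumes <- volumes
  out
}
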