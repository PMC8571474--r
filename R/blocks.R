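# Partition a neuron volume into overlapped 32x64x64 blocks anchored every
# `anchor_step` nodes along the gold reconstruction, crop gold/auto forests
# into each block, and apply the burr and node-count filters to auto blocks.

#' Wrap a 3D intensity array as an image volume
#'
#' @param data non-negative numeric 3D array, axis order (z, y, x)
#' @return object of class `image_volume`
#' @export
image_volume <- function(data) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < 0)) stop("image_volume: intensities must be non-negative")
  structure(list(data = data, shape = dim(data)), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s (z,y,x), range [%.1f, %.1f]>\n",
              paste(x$shape, collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

#' Default block-construction configuration
#'
#' @param block_size block extents (z, y, x) in voxels
#' @param anchor_step nodes between consecutive anchors along the traversal
#' @param min_branch_nodes terminal branches smaller than this are burrs
#' @param min_fragment_nodes fragments smaller than this are burr candidates
#' @param edge_margin burr fragments must additionally lie within this many
#'   voxels of a block face to be deleted
#' @param min_total_nodes auto blocks with fewer total nodes are filtered out
#' @return named list of parameters
#' @export
block_config <- function(block_size = c(32, 64, 64), anchor_step = 100,
                         min_branch_nodes = 4, min_fragment_nodes = 4,
                         edge_margin = 4, min_total_nodes = 11) {
  list(block_size = as.integer(block_size), anchor_step = as.integer(anchor_step),
       min_branch_nodes = as.integer(min_branch_nodes),
       min_fragment_nodes = as.integer(min_fragment_nodes),
       edge_margin = edge_margin, min_total_nodes = as.integer(min_total_nodes))
}

#' Select anchor nodes along the gold reconstruction
#'
#' Anchors are the nodes at positions 0, step, 2*step, ... of the depth-first
#' preorder from the soma root; the root is always the first anchor.
#'
#' @param gold non-empty [neuron_forest()] with a soma root
#' @param step positive integer node step
#' @return data frame with columns `id` (node id), `order_index` (0-based
#'   position in traversal order), `z`, `y`, `x` (anchor position)
#' @export
select_anchors <- function(gold, step = 100) {
  if (n_nodes(gold) == 0) stop("select_anchors: empty forest")
  stopifnot(step >= 1)
  ord <- traversal_order(gold, soma_root(gold))
  sel <- seq.int(1L, length(ord), by = as.integer(step))
  ids <- ord[sel]
  rows <- match(ids, gold$nodes$id)
  data.frame(id = ids, order_index = sel - 1L,
             z = gold$nodes$z[rows], y = gold$nodes$y[rows],
             x = gold$nodes$x[rows])
}

#' Extract a zero-padded image block around an anchor
#'
#' The anchor voxel lands at index `floor(size/2)` of the block; regions
#' outside the volume are zero-filled so the output always has shape `size`.
#'
#' @param volume an [image_volume()]
#' @param anchor voxel coordinate (z, y, x); must lie inside the volume
#' @param size block extents (z, y, x)
#' @return numeric array of dimension `size`
#' @export
extract_image_block <- function(volume, anchor, size = c(32, 64, 64)) {
  anchor <- floor(as.numeric(anchor))
  shp <- volume$shape
  if (any(anchor < 0) || any(anchor >= shp)) {
    stop("extract_image_block: anchor outside volume")
  }
  ctr <- floor(size / 2)
  lo <- anchor - ctr            # 0-based inclusive start in volume frame
  hi <- lo + size - 1           # 0-based inclusive end
  block <- array(0, dim = size)
  vlo <- pmax(lo, 0); vhi <- pmin(hi, shp - 1)
  if (all(vlo <= vhi)) {
    block[(vlo[1] - lo[1] + 1):(vhi[1] - lo[1] + 1),
          (vlo[2] - lo[2] + 1):(vhi[2] - lo[2] + 1),
          (vlo[3] - lo[3] + 1):(vhi[3] - lo[3] + 1)] <-
      volume$data[(vlo[1] + 1):(vhi[1] + 1),
                  (vlo[2] + 1):(vhi[2] + 1),
                  (vlo[3] + 1):(vhi[3] + 1)]
  }
  block
}

#' Remove burrs from an auto block
#'
#' Two rules, mirroring how spurious structure is cleaned from automatic
#' reconstructions: (a) terminal branches (maximal path from a bifurcation,
#' exclusive, to a tip) with fewer than `min_branch_nodes` nodes are deleted,
#' iteratively until stable; (b) whole fragments with fewer than
#' `min_fragment_nodes` nodes whose minimum distance to any block face is
#' below `edge_margin` voxels are deleted. Unbranched fragments have no
#' terminal branch in the sense of rule (a) and are governed by rule (b)
#' only.
#'
#' @param auto_block [neuron_forest()] in block-local coordinates
#' @param min_branch_nodes,min_fragment_nodes,edge_margin rule parameters
#' @param block_size block extents (z, y, x)
#' @return pruned [neuron_forest()] (possibly empty)
#' @export
prune_burrs <- function(auto_block, min_branch_nodes = 4,
                        min_fragment_nodes = 4, edge_margin = 4,
                        block_size = c(32, 64, 64)) {
  nodes <- auto_block$nodes
  # (a) iteratively delete short terminal branches hanging off bifurcations
  repeat {
    if (nrow(nodes) == 0) break
    n <- nrow(nodes)
    pidx <- match(nodes$parent, nodes$id)
    nkids <- tabulate(pidx[!is.na(pidx)], nbins = n)
    drop <- logical(n)
    for (tip in which(nkids == 0)) {
      path <- tip
      cur <- tip
      repeat {
        p <- pidx[cur]
        if (is.na(p) || nkids[p] >= 2) break
        cur <- p
        path <- c(path, cur)
      }
      # branch exists only if it hangs off a bifurcation
      if (!is.na(pidx[cur]) && nkids[pidx[cur]] >= 2 &&
          length(path) < min_branch_nodes) {
        drop[path] <- TRUE
      }
    }
    if (!any(drop)) break
    nodes <- nodes[!drop, , drop = FALSE]
    nodes$parent[!(nodes$parent %in% nodes$id)] <- -1L
  }
  # (b) delete small fragments hugging a block face
  if (nrow(nodes) > 0) {
    f <- neuron_forest(nodes)
    frag <- fragment_ids(f)
    pos <- cbind(nodes$z, nodes$y, nodes$x)
    face_dist <- pmin(pos[, 1], block_size[1] - pos[, 1],
                      pos[, 2], block_size[2] - pos[, 2],
                      pos[, 3], block_size[3] - pos[, 3])
    keep <- rep(TRUE, nrow(nodes))
    for (g in unique(frag)) {
      m <- frag == g
      if (sum(m) < min_fragment_nodes && min(face_dist[m]) < edge_margin) {
        keep[m] <- FALSE
      }
    }
    nodes <- nodes[keep, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  neuron_forest(nodes)
}

#' Node-count filter for auto blocks
#'
#' @param auto_block burr-pruned [neuron_forest()]
#' @param min_total_nodes retention threshold
#' @return `TRUE` iff the block keeps at least `min_total_nodes` nodes
#' @export
passes_node_filter <- function(auto_block, min_total_nodes = 11) {
  n_nodes(auto_block) >= min_total_nodes
}

#' Build the block corpus for one neuron
#'
#' Walks the gold reconstruction from its soma root, placing one candidate
#' block every `anchor_step` nodes, crops the gold and auto forests into each
#' block, burr-prunes the auto forest, and retains only blocks passing the
#' node-count filter (dropping the paired image and gold data otherwise).
#'
#' @param volume an [image_volume()] (or `NULL` to skip image extraction)
#' @param gold gold-standard [neuron_forest()] in the volume frame
#' @param auto automatic-reconstruction [neuron_forest()] in the same frame
#' @param config a [block_config()]
#' @param neuron_id identifier stored on every block
#' @return list of `block` objects, each a list with `anchor` (z,y,x voxel),
#'   `anchor_order_index`, `image`, `gold`, `auto`, `label` (NA until set),
#'   `neuron_id`
#' @export
build_blocks <- function(volume, gold, auto, config = block_config(),
                         neuron_id = "neuron") {
  anchors <- select_anchors(gold, config$anchor_step)
  size <- config$block_size
  ctr <- floor(size / 2)
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    av <- floor(c(anchors$z[i], anchors$y[i], anchors$x[i]))
    lo <- av - ctr
    box <- bounding_box(lo, lo + size)
    auto_blk <- prune_burrs(crop_to_box(auto, box),
                            min_branch_nodes = config$min_branch_nodes,
                            min_fragment_nodes = config$min_fragment_nodes,
                            edge_margin = config$edge_margin,
                            block_size = size)
    if (!passes_node_filter(auto_blk, config$min_total_nodes)) next
    gold_blk <- crop_to_box(gold, box)
    img <- if (is.null(volume)) NULL else extract_image_block(volume, av, size)
    out[[length(out) + 1L]] <- structure(
      list(anchor = av, anchor_order_index = anchors$order_index[i],
           image = img, gold = gold_blk, auto = auto_blk,
           label = NA_character_, neuron_id = neuron_id),
      class = "tdb_block")
  }
  out
}

#' @export
print.tdb_block <- function(x, ...) {
  cat(sprintf("<block %s@%s ord=%d gold=%d auto=%d label=%s>\n", x$neuron_id,
              paste(x$anchor, collapse = ","), x$anchor_order_index,
              n_nodes(x$gold), n_nodes(x$auto), x$label))
  invisible(x)
}
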