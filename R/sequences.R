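# Block adjacency and fixed-length block sequences for the sequence stage.

#' Are two blocks adjacent in the tracing order?
#'
#' Adjacent means (1) anchor Euclidean distance at most 100 voxels and
#' (2) traversal order indices exactly one anchor step (100 nodes) apart.
#' Blocks from different neurons are never adjacent.
#'
#' @param a,b block objects (from [build_blocks()])
#' @param max_anchor_distance voxel bound on the anchor distance
#' @param node_step required order-index difference
#' @return logical
#' @export
are_adjacent <- function(a, b, max_anchor_distance = 100, node_step = 100) {
  if (!identical(a$neuron_id, b$neuron_id)) return(FALSE)
  d <- sqrt(sum((a$anchor - b$anchor)^2))
  d <= max_anchor_distance &&
    abs(a$anchor_order_index - b$anchor_order_index) == node_step
}

#' Enumerate block sequences of length s
#'
#' Builds the directed adjacency (order index increasing by one step) over
#' the given blocks and enumerates every path of `s` blocks. The prediction
#' target of each sequence is its last block; `s = 1` yields one sequence
#' per block.
#'
#' @param blocks list of block objects
#' @param s sequence length (>= 1)
#' @param max_anchor_distance,node_step adjacency parameters
#' @return list of integer vectors, each of length `s`, indexing `blocks`
#' @export
build_sequences <- function(blocks, s, max_anchor_distance = 100,
                            node_step = 100) {
  if (s < 1) stop("build_sequences: s must be >= 1")
  nb <- length(blocks)
  if (s == 1) return(lapply(seq_len(nb), identity))
  if (nb == 0) return(list())
  # successors: j follows i
  succ <- vector("list", nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (i != j &&
          blocks[[j]]$anchor_order_index ==
            blocks[[i]]$anchor_order_index + node_step &&
          are_adjacent(blocks[[i]], blocks[[j]], max_anchor_distance, node_step)) {
        succ[[i]] <- c(succ[[i]], j)
      }
    }
  }
  out <- list()
  extend <- function(path) {
    if (length(path) == s) {
      out[[length(out) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (j in succ[[path[length(path)]]]) extend(c(path, j))
  }
  for (i in seq_len(nb)) extend(i)
  out
}

#' Fraction of length-2 sequences whose two labels agree
#'
#' @param blocks list of labeled blocks
#' @param sequences list of length-2 index vectors (defaults to all
#'   length-2 sequences of `blocks`)
#' @return fraction in `[0, 1]`
#' @export
same_label_fraction <- function(blocks, sequences = build_sequences(blocks, 2)) {
  if (length(sequences) == 0) return(NA_real_)
  agree <- vapply(sequences, function(p) {
    stopifnot(length(p) == 2)
    la <- blocks[[p[1]]]$label; lb <- blocks[[p[2]]]$label
    if (is.na(la) || is.na(lb)) stop("same_label_fraction: unlabeled block")
    la == lb
  }, logical(1))
  mean(agree)
}
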