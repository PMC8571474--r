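test_that("select_anchors picks every step-th node of the preorder", {
  f <- make_chain(201)
  a <- select_anchors(f, step = 100)
  expect_equal(a$order_index, c(0, 100, 200))
  expect_equal(a$id, c(1, 101, 201))
  expect_equal(nrow(select_anchors(make_chain(99), 100)), 1)
  expect_error(select_anchors(neuron_forest()), "empty")
  # branched tree vs independent preorder walk
  f <- make_random_tree(250, seed = 31)
  a <- select_anchors(f, step = 100)
  ord <- oracle_preorder(f, 1)
  expect_equal(a$id, ord[c(1, 101, 201)])
})

test_that("extract_image_block crops, centers and zero-pads", {
  vol <- image_volume(array(seq_len(40 * 50 * 60), dim = c(40, 50, 60)))
  blk <- extract_image_block(vol, anchor = c(20, 25, 30), size = c(8, 8, 8))
  expect_equal(dim(blk), c(8, 8, 8))
  # center voxel equals the anchor voxel (0-based anchor -> 1-based index)
  expect_equal(blk[5, 5, 5], vol$data[21, 26, 31])
  # direct index oracle on the ramp volume
  expect_equal(blk, vol$data[17:24, 22:29, 27:34])
  # corner anchor: padding zeros, shape kept
  blk <- extract_image_block(vol, anchor = c(0, 0, 0), size = c(8, 8, 8))
  expect_equal(dim(blk), c(8, 8, 8))
  expect_true(all(blk[1:4, , ] == 0))
  expect_equal(blk[5, 5, 5], vol$data[1, 1, 1])
  expect_error(extract_image_block(vol, anchor = c(40, 0, 0)), "outside")
  # intensity conservation: block sum never exceeds volume sum
  expect_lte(sum(blk), sum(vol$data))
})

test_that("prune_burrs implements the branch and fragment rules", {
  bs <- c(32, 64, 64)
  # lone 3-node chain with a node 1 voxel from the z face: fragment rule fires
  near_edge <- make_chain(3, origin = c(30, 30, 1), step = c(0, 0, 1)) # z=1,2,3
  expect_equal(n_nodes(prune_burrs(near_edge, block_size = bs)), 0)
  # same chain centered: kept (no terminal branch off a bifurcation)
  centered <- make_chain(3, origin = c(30, 30, 15))
  expect_equal(n_nodes(prune_burrs(centered, block_size = bs)), 3)
  # Y-tree whose daughters are 2 and 1 nodes: both burr branches removed,
  # the unbranched root-stem remainder survives via the fragment rule
  y <- make_y_tree(2, origin = c(20, 30, 15))
  y$nodes <- y$nodes[y$nodes$id != 6, ]
  y <- neuron_forest(y$nodes)
  pruned <- prune_burrs(y, block_size = bs)
  expect_equal(n_nodes(pruned), 2)
  expect_setequal(pruned$nodes$id, c(1, 2))
})

test_that("prune_burrs boundary cases: 3 vs 4 nodes, edge distance 3 vs 4", {
  bs <- c(32, 64, 64)
  # 4-node branch survives, 3-node branch is deleted
  y4 <- make_y_tree(4, origin = c(20, 30, 15))
  expect_equal(n_nodes(prune_burrs(y4, block_size = bs)), n_nodes(y4))
  y3 <- make_y_tree(3, origin = c(20, 30, 15))
  pr <- prune_burrs(y3, block_size = bs)
  # both 3-node daughters hang off the bifurcation: both deleted, then the
  # remaining 2-node chain has no bifurcation and survives as a fragment
  expect_equal(n_nodes(pr), 2)
  # fragment of 3 nodes at face distance exactly 4: kept (< 4 required)
  at4 <- make_chain(3, origin = c(30, 30, 4), step = c(0, 0, 1))
  expect_equal(n_nodes(prune_burrs(at4, block_size = bs)), 3)
  at3 <- make_chain(3, origin = c(30, 30, 3), step = c(0, 0, 1))
  expect_equal(n_nodes(prune_burrs(at3, block_size = bs)), 0)
  # 4-node fragment near the face: node-count clause saves it
  n4 <- make_chain(4, origin = c(30, 30, 1), step = c(0, 0, 1))
  expect_equal(n_nodes(prune_burrs(n4, block_size = bs)), 4)
})

test_that("passes_node_filter at the 10/11 boundary", {
  expect_false(passes_node_filter(make_chain(10)))
  expect_true(passes_node_filter(make_chain(11)))
  for (n in c(1, 7, 15, 30)) {
    expect_equal(passes_node_filter(make_chain(n)), n >= 11)
  }
})

test_that("build_blocks composes anchors, cropping, pruning and filtering", {
  # straight gold chain of 300 nodes along x at volume center; auto = gold
  vol <- image_volume(array(1, dim = c(32, 64, 320)))
  gold <- make_chain(300, origin = c(5, 32, 16), step = c(1, 0, 0))
  blocks <- build_blocks(vol, gold, gold, block_config(), neuron_id = "n1")
  expect_equal(length(blocks), 3)
  expect_equal(vapply(blocks, function(b) b$anchor_order_index, 0L), c(0L, 100L, 200L))
  for (b in blocks) {
    expect_equal(dim(b$image), c(32, 64, 64))
    expect_equal(n_nodes(b$gold), n_nodes(b$auto)) # auto == gold, nothing pruned
    expect_true(passes_node_filter(b$auto))
    pos <- cbind(b$gold$nodes$z, b$gold$nodes$y, b$gold$nodes$x)
    expect_true(all(pos >= 0 & pos < matrix(c(32, 64, 64), nrow(pos), 3, byrow = TRUE)))
  }
  # empty auto: nothing retained
  expect_length(build_blocks(vol, gold, neuron_forest(), block_config()), 0)
  # determinism
  b2 <- build_blocks(vol, gold, gold, block_config(), neuron_id = "n1")
  expect_identical(blocks, b2)
})
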