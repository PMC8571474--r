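test_that("read_swc parses minimal and chain files, ignores comments", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 1 -1"), p)
  f <- read_swc(p)
  expect_equal(n_nodes(f), 1)
  expect_equal(count_fragments(f), 1)
  expect_equal(forest_roots(f), 1)

  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 1", "3 3 2 0 0 1 2"), p)
  f <- read_swc(p)
  expect_equal(n_nodes(f), 3)
  expect_equal(count_fragments(f), 1)
  expect_equal(count_bifurcations(f), 0)
})

test_that("read_swc rejects malformed lines and broken parent links", {
  p <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 1 0 0 0 1"), p)
  expect_error(read_swc(p), "line 2")
  writeLines(c("1 1 0 0 0 1 -1", "2 1 0 0 0 1 5"), p)
  expect_error(read_swc(p), "integrity")
  writeLines("1 1 zero 0 0 1 -1", p)
  expect_error(read_swc(p), "malformed")
  expect_error(read_swc(file.path(tempdir(), "absent.swc")), "not found")
})

test_that("write/read round-trip preserves topology and coordinates", {
  p <- withr::local_tempfile(fileext = ".swc")
  # empty forest: header-only file
  write_swc(neuron_forest(), p)
  expect_equal(n_nodes(read_swc(p)), 0)
  # random 50-node tree: parent map and coordinates to 1e-6
  f <- make_random_tree(50, seed = 11)
  write_swc(f, p)
  g <- read_swc(p)
  expect_equal(g$nodes$id, f$nodes$id)
  expect_equal(g$nodes$parent, f$nodes$parent)
  expect_equal(g$nodes$x, f$nodes$x, tolerance = 1e-6)
  expect_equal(g$nodes$y, f$nodes$y, tolerance = 1e-6)
  expect_equal(g$nodes$z, f$nodes$z, tolerance = 1e-6)
})

test_that("count_bifurcations matches the child-count oracle", {
  expect_equal(count_bifurcations(make_chain(5)), 0)
  expect_equal(count_bifurcations(make_y_tree(2)), 1)
  for (seed in 1:5) {
    f <- make_random_tree(40, seed = seed)
    expect_equal(count_bifurcations(f), oracle_bifurcations(f))
  }
})

test_that("crop_to_box severs edges and matches per-node containment oracle", {
  # fully inside
  f <- make_chain(5, origin = c(2, 2, 2))
  box <- bounding_box(c(0, 0, 0), c(10, 10, 10))
  g <- crop_to_box(f, box)
  expect_equal(n_nodes(g), 5)
  expect_equal(count_fragments(g), 1)
  expect_equal(g$nodes$x, f$nodes$x) # min corner 0: no shift
  # chain crossing one face: x from 6..15 inside [0,10)
  f <- make_chain(10, origin = c(6, 2, 2))
  g <- crop_to_box(f, box)
  inside <- f$nodes$x >= 0 & f$nodes$x < 10
  expect_equal(n_nodes(g), sum(inside))
  expect_equal(count_fragments(g), 1)
  # disjoint box
  expect_equal(n_nodes(crop_to_box(f, bounding_box(c(50, 50, 50), c(60, 60, 60)))), 0)
  # random tree vs containment + component oracle
  for (seed in 1:5) {
    f <- make_random_tree(40, seed = 100 + seed, spread = 20)
    box <- bounding_box(c(5, 5, 5), c(15, 15, 15))
    g <- crop_to_box(f, box)
    ins <- f$nodes$z >= 5 & f$nodes$z < 15 & f$nodes$y >= 5 & f$nodes$y < 15 &
           f$nodes$x >= 5 & f$nodes$x < 15
    expect_equal(n_nodes(g), sum(ins))
    expect_equal(sort(g$nodes$id), sort(f$nodes$id[ins]))
    expect_equal(count_fragments(g), if (sum(ins)) oracle_components(g) else 0L)
    # conservation: in-box + out-of-box = total
    out_ct <- sum(!ins)
    expect_equal(n_nodes(g) + out_ct, n_nodes(f))
  }
})

test_that("crop coordinates are re-expressed relative to the box corner", {
  f <- make_chain(3, origin = c(7, 8, 9)) # SWC (x, y, z)
  g <- crop_to_box(f, bounding_box(c(5, 5, 5), c(20, 20, 20))) # (z, y, x)
  expect_equal(g$nodes$x, c(2, 3, 4))
  expect_equal(g$nodes$y, rep(3, 3))
  expect_equal(g$nodes$z, rep(4, 3))
})

test_that("traversal_order is preorder with ascending-id children", {
  f <- make_chain(3)
  expect_equal(traversal_order(f, 1), c(1, 2, 3))
  y <- make_y_tree(2)
  ord <- traversal_order(y, 1)
  expect_equal(ord[1:2], c(1, 2))
  # smaller-id daughter first
  expect_lt(match(3, ord), match(5, ord))
  expect_error(traversal_order(f, 99), "not in forest")
  for (seed in 1:5) {
    f <- make_random_tree(30, seed = 200 + seed)
    ord <- traversal_order(f, 1)
    expect_setequal(ord, f$nodes$id)
    expect_equal(ord, oracle_preorder(f, 1))
    # every parent precedes its descendants
    pos <- match(f$nodes$id, ord)
    par <- f$nodes$parent
    has <- par != -1
    expect_true(all(pos[match(par[has], f$nodes$id)] < pos[has]))
    # determinism
    expect_identical(ord, traversal_order(f, 1))
  }
})

test_that("forest invariants are enforced", {
  bad <- data.frame(id = c(1, 1), type = 1, x = 0, y = 0, z = 0, radius = 1,
                    parent = c(-1, -1))
  expect_error(neuron_forest(bad), "duplicate")
  cyc <- data.frame(id = 1:2, type = 1, x = 0, y = 0, z = 0, radius = 1,
                    parent = c(2L, 1L))
  expect_error(neuron_forest(cyc), "cycle")
  expect_error(bounding_box(c(0, 0, 0), c(0, 1, 1)), "min_corner")
})
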