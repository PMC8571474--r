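# the generator tests run on deliberately small configurations: the science
# is in the mechanisms (determinism, regime separation, Markov continuity),
# not in corpus scale

small_cfg <- function(...) {
  base <- synth_config(n_neurons = 1, nodes_per_neuron = 450,
                       volume_shape = c(48, 160, 160), max_radius = 60,
                       segment_length_range = c(80, 150), n_distractors = 2)
  utils::modifyList(base, list(...))
}

test_that("simulate_neuron_tree: determinism, branch control, containment", {
  cfg <- small_cfg()
  set.seed(1); t1 <- simulate_neuron_tree(cfg)
  set.seed(1); t2 <- simulate_neuron_tree(cfg)
  expect_identical(t1, t2)
  expect_equal(n_nodes(t1), 450)
  expect_equal(count_fragments(t1), 1)
  pos <- cbind(t1$nodes$z, t1$nodes$y, t1$nodes$x)
  expect_true(all(pos >= 0 & pos < matrix(cfg$volume_shape, 450, 3, byrow = TRUE)))
  # branch probability 0: an unbranched chain
  set.seed(2)
  t0 <- simulate_neuron_tree(small_cfg(branch_prob = 0))
  expect_equal(count_bifurcations(t0), 0)
  expect_error(simulate_neuron_tree(small_cfg(nodes_per_neuron = 0)), "degenerate")
})

test_that("empirical bifurcation rate tracks the configured branch rate", {
  cfg <- small_cfg(branch_prob = 0.03, nodes_per_neuron = 400)
  set.seed(3)
  rates <- replicate(40, {
    tr <- simulate_neuron_tree(cfg)
    count_bifurcations(tr) / n_nodes(tr)
  })
  # binomial check: mean rate within 3 standard errors (branch seeds at the
  # leash boundary or at the node budget can be cut short, so compare to the
  # configured rate with that slack)
  se <- sqrt(0.03 * 0.97 / (400 * 40))
  expect_lt(abs(mean(rates) - 0.03), 3 * se + 0.005)
})

test_that("render_volume stamps tubes over background, reproducibly", {
  cfg <- small_cfg(noise_sd = 0, n_distractors = 0)
  # one straight horizontal edge in the middle
  tree <- make_chain(20, origin = c(60, 80, 24)) # SWC (x,y,z)
  vol <- render_volume(tree, cfg)
  # on-tube voxel has foreground, far voxel has background
  expect_equal(vol$data[25, 81, 70], cfg$fg_low)
  expect_equal(vol$data[10, 10, 10], cfg$bg_mean)
  # same seed -> identical volume (with noise on)
  cfgn <- small_cfg(noise_sd = 8)
  set.seed(5); v1 <- render_volume(tree, cfgn)
  set.seed(5); v2 <- render_volume(tree, cfgn)
  expect_identical(v1$data, v2$data)
  expect_error(render_volume(make_chain(3, origin = c(500, 0, 0)), cfg), "outside")
})

test_that("rendered contrast matches the configured levels", {
  cfg <- small_cfg(noise_sd = 6, n_distractors = 0)
  tree <- make_chain(40, origin = c(40, 80, 24))
  set.seed(8)
  fg <- bg <- numeric(10)
  for (i in 1:10) {
    vol <- render_volume(tree, cfg)$data
    fg[i] <- mean(vol[25, 81, 41:79])   # along the tube
    bg[i] <- mean(vol[10, 10:40, 10])   # far background
  }
  expect_lt(abs(mean(fg) - cfg$fg_low) / cfg$fg_low, 0.1)
  expect_lt(abs(mean(bg) - cfg$bg_mean) / cfg$bg_mean, 0.1)
})

test_that("perturb_to_auto: identity at zero jitter, losses under high", {
  cfg <- small_cfg(jitter_low = 0)
  set.seed(4)
  gold <- simulate_neuron_tree(small_cfg())
  auto <- perturb_to_auto(gold, "low", cfg)
  expect_identical(auto$nodes[, c("x", "y", "z")], gold$nodes[, c("x", "y", "z")])
  expect_equal(unname(neuron_distance_features(gold, auto)[1:7]),
               rep(0, 7), tolerance = 1e-12)
  # high with certain branch loss on a branched tree: nodes disappear
  cfg_hi <- small_cfg(branch_drop_high = 1, branch_prob = 0.05)
  set.seed(6)
  gold_b <- simulate_neuron_tree(cfg_hi)
  set.seed(7)
  auto_hi <- perturb_to_auto(gold_b, "high", cfg_hi)
  expect_lt(n_nodes(auto_hi), n_nodes(gold_b))
})

test_that("high-regime perturbation separates esa from low-regime", {
  cfg <- small_cfg()
  set.seed(9)
  esa_lo <- esa_hi <- numeric(30)
  for (i in 1:30) {
    gold <- simulate_neuron_tree(small_cfg(nodes_per_neuron = 150))
    esa_lo[i] <- neuron_distance_features(gold, perturb_to_auto(gold, "low", cfg))["esa"]
    esa_hi[i] <- neuron_distance_features(gold, perturb_to_auto(gold, "high", cfg))["esa"]
  }
  expect_gt(mean(esa_hi), mean(esa_lo))
  expect_gt(mean(esa_hi) - mean(esa_lo), 0.5)
})

test_that("generate_labeled_corpus is a pure function of (config, seed)", {
  cfg <- small_cfg()
  c1 <- generate_labeled_corpus(cfg, seed = 12)
  c2 <- generate_labeled_corpus(cfg, seed = 12)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$blocks, c2$blocks)
  c3 <- generate_labeled_corpus(cfg, seed = 13)
  expect_false(identical(c1$manifest, c3$manifest))
})

test_that("label continuity follows the persistence parameter", {
  # persistence 1: every neuron is single-label, agreement 1
  cfg <- small_cfg(persistence = 1, nodes_per_neuron = 900)
  c1 <- generate_labeled_corpus(cfg, seed = 21)
  if (length(build_sequences(c1$blocks, 2)) > 0) {
    expect_equal(same_label_fraction(c1$blocks), 1.0)
  }
  expect_true(all(tapply(c1$manifest$label, c1$manifest$neuron_id,
                         function(x) length(unique(x)) == 1)))
  # the Markov agreement at the default persistence: pooled over corpora
  agree <- n <- 0
  for (seed in 31:34) {
    cc <- generate_labeled_corpus(small_cfg(n_neurons = 2, nodes_per_neuron = 1200),
                                  seed = seed)
    man <- cc$manifest
    for (nid in unique(man$neuron_id)) {
      lab <- man$label[man$neuron_id == nid][order(man$anchor_order_index[man$neuron_id == nid])]
      oi <- sort(man$anchor_order_index[man$neuron_id == nid])
      adj <- diff(oi) == 100
      agree <- agree + sum((lab[-1] == lab[-length(lab)])[adj])
      n <- n + sum(adj)
    }
  }
  expect_gt(n, 40)
  # binomial tolerance around the configured persistence
  expect_lt(abs(agree / n - 0.6), 3 * sqrt(0.6 * 0.4 / n) + 0.02)
})

test_that("every generated block satisfies the construction invariants", {
  cc <- generate_labeled_corpus(small_cfg(nodes_per_neuron = 900), seed = 41)
  expect_gt(length(cc$blocks), 2)
  for (b in cc$blocks) {
    expect_equal(dim(b$image), c(32, 64, 64))
    expect_gte(n_nodes(b$auto), 11)
    expect_true(b$label %in% c("low", "high"))
    ft <- c(similarity_features(b$gold, b$auto), lmeasure_features(b$auto))
    expect_true(all(is.finite(ft)))
  }
})
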