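tb <- asNamespace("traceblocks")

test_that("image branch stage shapes follow the printed architecture", {
  chain <- sfe_image_shape_chain()
  expect_equal(chain$output_size,
               c("32x32x32", "16x16x16", "16x16x16", "8x8x8", "4x4x4",
                 "2x2x2", "1x1x1", "2"))
})

test_that("sfe forwards: shapes, softmax normalization, eval determinism", {
  set.seed(1)
  net <- sfe_image_new(input_shape = c(8, 16, 16), channels = c(4, 4, 8, 8))
  img <- array(runif(8 * 16 * 16), dim = c(8, 16, 16))
  z <- sfe_image_forward(net, img)
  expect_length(z, 2)
  p <- exp(z - max(z)); p <- p / sum(p)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(z, sfe_image_forward(net, img)) # dropout off at eval
  expect_error(sfe_image_forward(net, array(0, c(4, 4, 4))), "shape")

  anet <- sfe_auto_new(32)
  z <- sfe_auto_forward(anet, rnorm(32))
  expect_length(z, 2)
  expect_true(all(is.finite(sfe_auto_forward(anet, rep(0, 32)))))
  expect_error(sfe_auto_forward(anet, rnorm(31)), "width")
  # injectivity probe: different inputs give different outputs
  z2 <- sfe_auto_forward(anet, rnorm(32))
  expect_false(isTRUE(all.equal(z, z2)))
})

test_that("sie_forward consumes label context + branch outputs", {
  set.seed(2)
  net <- lstm_new(4, 10, 2, 2)
  o <- sie_forward(net, list(c(0.7, 0.3)), list(c(0, 0)))
  expect_length(o, 2)
  expect_true(all(is.finite(o)))
  expect_identical(o, sie_forward(net, list(c(0.7, 0.3)), list(c(0, 0))))
  o3 <- sie_forward(net, list(c(.9, .1), c(.2, .8), c(.5, .5)),
                    list(c(1, 0), c(0, 1), c(0, 0)))
  expect_length(o3, 2)
  expect_error(sie_forward(net, list(c(1, 2, 3)), list(c(0, 0))), "2 \\+ 2")
})

test_that("mf_forward fuses and normalizes; order of inputs matters", {
  set.seed(3)
  net <- tb$mlp_new(c(4, 30, 2))
  p <- mf_forward(net, c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  q <- mf_forward(net, c(0.2, 0.8), c(0.9, 0.1))
  expect_false(isTRUE(all.equal(p, q)))
  expect_error(mf_forward(net, c(1, 2, 3), c(0, 1)), "length 2")
})

test_that("augment_rotations: 3 copies, label preservation, 4x90 identity", {
  set.seed(4)
  blocks <- lapply(1:5, function(i) {
    structure(list(anchor = c(16, 32, 32), anchor_order_index = 0L,
                   image = array(runif(32 * 64 * 64), c(32, 64, 64)),
                   gold = make_chain(3), auto = make_chain(12),
                   label = sample(c("low", "high"), 1), neuron_id = "n1"),
              class = "tdb_block")
  })
  aug <- augment_rotations(blocks)
  expect_length(aug, 15)
  expect_equal(vapply(aug, function(b) b$label, ""),
               rep(vapply(blocks, function(b) b$label, ""), each = 3))
  # shape preserved by every rotation
  for (b in aug) expect_equal(dim(b$image), c(32, 64, 64))
  # the 270-degree copy rotated once more recovers the original
  r4 <- tb$.rot90_depth(aug[[3]]$image)
  expect_identical(r4, blocks[[1]]$image)
  # index-map oracle on a ramp: out[z,y,x] == in[z, x, X+1-y]
  ramp <- array(seq_len(4 * 6 * 6), c(4, 6, 6))
  r1 <- tb$.rot90_depth(ramp)
  for (z in 1:4) for (y in 1:6) for (x in 1:6) {
    expect_equal(r1[z, y, x], ramp[z, x, 6 + 1 - y])
  }
})

test_that("rotation count matches the published augmentation arithmetic", {
  # 3 new samples per training block: at n = 100, 300 new samples, and at
  # the published scale 12372 inputs would give 37116
  blocks <- lapply(1:100, function(i) {
    structure(list(anchor = c(0, 0, 0), anchor_order_index = 0L,
                   image = array(0, c(2, 4, 4)), gold = NULL, auto = NULL,
                   label = "low", neuron_id = "n"), class = "tdb_block")
  })
  expect_length(augment_rotations(blocks), 300)
  expect_identical(12372L * 3L, 37116L)
})

test_that("evaluate metrics: worked confusion example and leakage guard", {
  cm <- classification_metrics(
    truth = c(rep("high", 4), rep("low", 6)),
    pred = c("high", "high", "high", "low", "high", rep("low", 5)))
  expect_equal(unname(cm["f1"]), 0.75)
  blocks <- lapply(1:4, function(i) {
    structure(list(anchor = c(0, 0, 0), anchor_order_index = (i - 1) * 100L,
                   image = array(0, c(2, 4, 4)), gold = NULL, auto = NULL,
                   label = "low", neuron_id = "shared"), class = "tdb_block")
  })
  expect_error(run_experiment(blocks, blocks, s = 1), "leakage")
})

test_that("staged training learns a tiny separable corpus end to end", {
  # miniature world: 8x16x16 blocks whose image mean and morphometrics both
  # carry the label; exercises all three stages + evaluation wiring
  set.seed(10)
  mk_block <- function(i, neuron, ord) {
    lab <- sample(c("low", "high"), 1)
    base <- if (lab == "high") 0.2 else 0.8
    img <- array(pmax(rnorm(8 * 16 * 16, base, 0.1), 0), c(8, 16, 16))
    auto <- make_chain(12 + if (lab == "high") 10 else 0,
                       origin = c(2, 8, 4), step = c(0.5, 0, 0))
    structure(list(anchor = c(4, 8, ord), anchor_order_index = ord,
                   image = img, gold = auto, auto = auto, label = lab,
                   neuron_id = neuron), class = "tdb_block")
  }
  blocks <- c(lapply(1:12, function(i) mk_block(i, "a", (i - 1) * 100L)),
              lapply(1:6, function(i) mk_block(i, "b", (i - 1) * 100L)))
  cfg <- train_config(epochs_sfe_image = 4, epochs_sfe_auto = 60,
                      epochs_sie = 40, epochs_joint = 2, seed = 3,
                      batch_size = 10)
  # blocks are tiny, so retarget the image branch input shape via training
  model <- train_stagewise(blocks[1:12], s = 2, cfg = cfg)
  expect_s3_class(model, "ssm_model")
  # checkpoints exist for every stage and joint training moved every group
  expect_named(model$checkpoints, c("stage1", "stage2", "stage3"))
  moved <- abs(model$checkpoints$stage3 - model$checkpoints$stage2) > 1e-10
  expect_true(all(moved))
  # loss decreased over stage-1 image epochs (allow noise: compare ends)
  expect_lt(tail(model$losses$sfe_image, 1), model$losses$sfe_image[1])
  # evaluation on the held-out neuron returns all five predictors
  ev <- evaluate_ssm(model, blocks[13:18], train_neurons = "a")
  expect_named(ev, c("mf", "sie_image", "sie_auto", "sfe_image", "sfe_auto"))
  for (m in ev) expect_true(is.finite(m["accuracy"]))
  # determinism: same seed, same data -> identical metrics
  model2 <- train_stagewise(blocks[1:12], s = 2, cfg = cfg)
  ev2 <- evaluate_ssm(model2, blocks[13:18], train_neurons = "a")
  expect_identical(ev, ev2)
  # label-dependent image/morphometrics: the cheap branch should learn it
  expect_gte(ev$sfe_auto["accuracy"], 0.5)
})

test_that("sequence context helps when the previous label determines the next", {
  # constructed Markov corpus: the SFE features are pure noise, but labels
  # alternate deterministically along each chain; with teacher forcing the
  # label-context input fully determines the target, so a trained SIE must
  # beat the 50% marginal
  set.seed(11)
  mk <- function(neuron, n) {
    labs <- rep(c("low", "high"), length.out = n)
    lapply(seq_len(n), function(i) {
      structure(list(anchor = c(4, 8, (i - 1) * 50), anchor_order_index = (i - 1) * 100L,
                     image = NULL, gold = NULL, auto = NULL,
                     label = labs[i], neuron_id = neuron), class = "tdb_block")
    })
  }
  blocks <- c(mk("a", 16), mk("b", 16))
  windows <- build_sequences(blocks, 2)
  Y <- label_one_hot(vapply(blocks, function(b) b$label, ""))
  P <- matrix(0.5, 2, length(blocks)) # uninformative branch outputs
  net <- lstm_new(4, 10, 2, 2)
  fit <- tb$.train_sie(net, windows, P, Y, Y, epochs = 150,
                       cfg = train_config(batch_size = 16, seed = 1))
  # teacher-forced prediction of every window's last label
  xs <- tb$.lstm_inputs(windows, P, Y)
  pred <- apply(tb$lstm_fw(fit$net, xs)$Z, 2, which.max)
  truth <- vapply(windows, function(w) which.max(Y[, w[length(w)]]), 0L)
  expect_gte(mean(pred == truth), 0.9)
})
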