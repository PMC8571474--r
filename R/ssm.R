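# The three-module tracing-difficulty classifier:
#   SFE - structure feature extraction: a volumetric residual network over
#         image blocks and a 3-layer dense network (100, 50, 2) over the 32
#         morphometric features, each emitting a 2-vector.
#   SIE - sequence information extraction: two 2-layer x 10-hidden LSTMs
#         whose per-step input is the one-hot label context concatenated
#         with the SFE output of that step (4-wide); the label context of
#         the prediction step is a zero vector (the label is the answer),
#         earlier steps use teacher forcing in training and previously
#         predicted labels at inference.
#   MF  - model fusion: softmax(W_M * cat(O_Is, O_As)) via a 2-layer dense
#         network (30, 2).
# Training is staged: (1) both SFE nets with cross-entropy against one-hot
# labels; (2) both LSTMs with SFE frozen; (3) everything jointly through MF.

.sfe_chunk <- 8L # micro-batch for the volumetric net (memory ceiling)

#' Build the morphometrics branch of SFE
#' @param input_width number of morphometric features
#' @return `tdb_mlp` with widths (input, 100, 50, 2)
#' @export
sfe_auto_new <- function(input_width = 32) {
  mlp_new(c(input_width, 100, 50, 2))
}

#' Forward one image block through the SFE image branch
#'
#' @param net a [sfe_image_new()] network
#' @param block_image 32 x 64 x 64 array (or already-flattened column)
#' @return length-2 numeric logit vector
#' @export
sfe_image_forward <- function(net, block_image) {
  if (is.array(block_image) && length(dim(block_image)) == 3) {
    if (!all(dim(block_image) == net$input_shape)) {
      stop("sfe_image_forward: input shape must be ",
           paste(net$input_shape, collapse = "x"))
    }
    block_image <- flatten_block(block_image)
  }
  if (length(block_image) != prod(net$input_shape)) {
    stop("sfe_image_forward: input shape must be ",
         paste(net$input_shape, collapse = "x"))
  }
  fw <- resnet_fw(net, matrix(block_image, ncol = 1), training = FALSE)
  as.vector(fw$Z)
}

#' Forward a morphometric vector through the SFE auto branch
#'
#' @param net a [sfe_auto_new()] network
#' @param morphometrics standardized feature vector (width must match)
#' @return length-2 numeric logit vector
#' @export
sfe_auto_forward <- function(net, morphometrics) {
  if (length(morphometrics) != net$widths[1]) {
    stop("sfe_auto_forward: expected width ", net$widths[1])
  }
  as.vector(mlp_fw(net, matrix(morphometrics, ncol = 1))$Z)
}

#' Forward a sequence through one SIE network
#'
#' @param net a [lstm_new()] network
#' @param sfe_outputs list of length-2 vectors (one per step, softmax scale)
#' @param label_context list of length-2 vectors; one-hot for steps
#'   1..s-1, the zero vector for the prediction step
#' @return length-2 logit vector (the projection of the final hidden state)
#' @export
sie_forward <- function(net, sfe_outputs, label_context) {
  s <- length(sfe_outputs)
  stopifnot(length(label_context) == s)
  xs <- lapply(seq_len(s), function(t) {
    if (length(label_context[[t]]) != 2 || length(sfe_outputs[[t]]) != 2) {
      stop("sie_forward: per-step inputs must be 2 + 2 wide")
    }
    matrix(c(label_context[[t]], sfe_outputs[[t]]), 4, 1)
  })
  as.vector(lstm_fw(net, xs)$Z)
}

#' Fuse the two sequence outputs
#'
#' @param net the fusion `tdb_mlp` (widths 4, 30, 2)
#' @param o_is,o_as length-2 outputs of the image / auto sequence networks
#' @return length-2 softmax vector
#' @export
mf_forward <- function(net, o_is, o_as) {
  if (length(o_is) != 2 || length(o_as) != 2) {
    stop("mf_forward: inputs must be length 2")
  }
  as.vector(softmax_cols(mlp_fw(net, matrix(c(o_is, o_as), 4, 1))$Z))
}

# ---- augmentation -----------------------------------------------------------

# 90-degree rotation of the (y, x) plane (about the depth axis, the only
# rotation preserving the 32x64x64 shape); out[z,y,x] = in[z, x, X+1-y]
.rot90_depth <- function(img) {
  aperm(img[, , dim(img)[3]:1, drop = FALSE], c(1, 3, 2))
}

#' Rotation augmentation of training blocks
#'
#' Produces three new blocks per input with the image rotated by 90, 180 and
#' 270 degrees about the depth axis; labels and reconstructions are copied
#' (the morphometric features of a rotated block are those of the original).
#'
#' @param blocks list of training blocks
#' @return list of 3 * length(blocks) new blocks
#' @export
augment_rotations <- function(blocks) {
  out <- vector("list", 3L * length(blocks))
  k <- 0L
  for (b in blocks) {
    img <- b$image
    for (r in 1:3) {
      img <- .rot90_depth(img)
      nb <- b
      nb$image <- img
      nb$augmented <- TRUE
      k <- k + 1L
      out[[k]] <- nb
    }
  }
  out
}

# ---- dataset preparation ----------------------------------------------------

# turn labeled blocks into training tensors; images are scaled by a fixed
# global constant (absolute intensity is a real cue -- weak signal IS what
# makes a block hard -- so per-block normalization would erase it)
.image_scale <- 255

ssm_dataset <- function(blocks) {
  n <- length(blocks)
  stopifnot(n > 0)
  npix <- prod(dim(blocks[[1]]$image))
  images <- matrix(0, npix, n)
  morpho <- matrix(0, 32, n)
  for (i in seq_len(n)) {
    images[, i] <- flatten_block(blocks[[i]]$image) / .image_scale
    morpho[, i] <- lmeasure_features(blocks[[i]]$auto)
  }
  list(images = images, morpho = morpho,
       labels = vapply(blocks, function(b) b$label, ""),
       neuron = vapply(blocks, function(b) b$neuron_id, ""),
       ord = vapply(blocks, function(b) as.numeric(b$anchor_order_index), 0),
       n = n)
}

# ---- staged training --------------------------------------------------------

.train_image_net <- function(net, X, Y, epochs, cfg) {
  opt <- adam_new(net$params, lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2,
                  weight_decay = cfg$weight_decay)
  n <- ncol(X)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      grads <- NULL
      bl <- 0
      for (cs in seq(1, length(idx), by = .sfe_chunk)) {
        ci <- idx[cs:min(cs + .sfe_chunk - 1, length(idx))]
        fw <- resnet_fw(net, X[, ci, drop = FALSE], training = TRUE)
        net$state <- fw$net$state
        ce <- softmax_ce(fw$Z, Y[, ci, drop = FALSE])
        g <- resnet_bw(net, fw$cache, ce$dZ * length(ci) / length(idx),
                       training = TRUE)
        rm(fw)
        grads <- grads_add_inplace(grads, g)
        rm(g)
        bl <- bl + ce$loss * length(ci)
      }
      opt <- adam_step_inplace(opt, net$params, grads,
                               no_decay = c("b", "gamma", "beta"))
      rm(grads)
      tot <- tot + bl
    }
    losses[ep] <- tot / n
    gc(FALSE)
  }
  net <- resnet_refresh_stats(net, X)
  list(net = net, losses = losses)
}

# eval-mode SFE image outputs for all columns of X (softmax scale)
.image_probs <- function(net, X) {
  n <- ncol(X)
  P <- matrix(0, 2, n)
  for (cs in seq(1, n, by = .sfe_chunk)) {
    ci <- cs:min(cs + .sfe_chunk - 1, n)
    fw <- resnet_fw(net, X[, ci, drop = FALSE], training = FALSE)
    P[, ci] <- softmax_cols(fw$Z)
  }
  P
}

# assemble LSTM step inputs for a batch of windows
# windows: list of index vectors (length s); P: 2 x n SFE probs;
# ctx_true: 2 x n one-hot truth; ctx_pred: 2 x n one-hot predicted labels.
# With forcing < 1, each context step independently uses the true label with
# probability `forcing` and the predicted label otherwise (scheduled
# sampling): inference supplies predicted contexts, so training only on
# truth would leave the networks brittle to context errors.
.lstm_inputs <- function(windows, P, ctx_true, ctx_pred = NULL, forcing = 1) {
  s <- length(windows[[1]])
  B <- length(windows)
  lapply(seq_len(s), function(t) {
    idx <- vapply(windows, `[`, 0L, t)
    ctx <- if (t < s) {
      cc <- ctx_true[, idx, drop = FALSE]
      if (!is.null(ctx_pred) && forcing < 1) {
        use_pred <- runif(B) >= forcing
        if (any(use_pred)) cc[, use_pred] <- ctx_pred[, idx[use_pred], drop = FALSE]
      }
      cc
    } else matrix(0, 2, B)
    rbind(ctx, P[, idx, drop = FALSE])
  })
}

# hard one-hot predictions from branch probabilities
.hard_onehot <- function(P) {
  H <- matrix(0, 2, ncol(P))
  H[cbind(max.col(t(P), ties.method = "first"), seq_len(ncol(P)))] <- 1
  H
}

# minibatches of equal window length (the LSTM batches time steps)
.length_batches <- function(windows, batch_size) {
  lens <- lengths(windows)
  batches <- list()
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    perm <- idx[sample.int(length(idx))]
    for (start in seq(1, length(perm), by = batch_size)) {
      batches[[length(batches) + 1L]] <-
        perm[start:min(start + batch_size - 1, length(perm))]
    }
  }
  if (length(batches) > 1) batches <- batches[sample.int(length(batches))]
  batches
}

.train_sie <- function(lnet, windows, P, ctx_onehot, Ylast, epochs, cfg,
                       ctx_pred = NULL, forcing = 0.5) {
  opt <- adam_new(lnet$params, lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2,
                  weight_decay = cfg$weight_decay)
  nw <- length(windows)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (wi in .length_batches(windows, cfg$batch_size)) {
      xs <- .lstm_inputs(windows[wi], P, ctx_onehot, ctx_pred, forcing)
      fw <- lstm_fw(lnet, xs)
      last <- vapply(windows[wi], function(w) w[length(w)], 0L)
      ce <- softmax_ce(fw$Z, Ylast[, last, drop = FALSE])
      bw <- lstm_bw(lnet, fw, ce$dZ)
      st <- adam_step(opt, lnet$params, bw$grads, no_decay = c("b"))
      opt <- st$opt; lnet$params <- st$params
      tot <- tot + ce$loss * length(wi)
    }
    losses[ep] <- tot / nw
  }
  list(net = lnet, losses = losses)
}

# SIE outputs for a set of windows (2 x n_windows), under given contexts
.sie_outputs <- function(lnet, windows, P, ctx_onehot) {
  O <- matrix(0, 2, length(windows))
  lens <- lengths(windows)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    xs <- .lstm_inputs(windows[idx], P, ctx_onehot)
    O[, idx] <- lstm_fw(lnet, xs)$Z
  }
  O
}

# summarize parameter groups (L2 norms) for checkpoint bookkeeping
.param_summary <- function(model) {
  f <- function(p) sqrt(sum(unlist(rapply(p, function(x) sum(x^2), how = "unlist"))))
  c(sfe_image = f(model$img_net$params),
    sfe_auto = f(model$auto_net$layers),
    sie_image = f(model$lstm_img$params),
    sie_auto = f(model$lstm_auto$params),
    mf = f(model$mf_net$layers))
}

#' Stage-wise training of the full classifier
#'
#' Stage 1 trains the two SFE networks independently (cross-entropy against
#' one-hot labels). Stage 2 freezes SFE, computes its outputs once, and
#' trains the two label-conditioned LSTMs. Stage 3 trains everything jointly
#' through the fusion head; within each minibatch the volumetric network
#' runs once per distinct block and gradients from all windows touching a
#' block are accumulated (an exact reformulation, not an approximation).
#'
#' @param blocks labeled training blocks
#' @param s sequence length for the LSTMs
#' @param cfg a [train_config()]
#' @param verbose print per-stage progress
#' @return object of class `ssm_model` (networks, morphometrics scaler,
#'   per-stage losses, per-stage parameter-norm checkpoints)
#' @export
train_stagewise <- function(blocks, s = 3, cfg = train_config(),
                            verbose = FALSE) {
  labs <- vapply(blocks, function(b) b$label, "")
  if (anyNA(labs) || any(labs == "NA")) stop("train_stagewise: missing labels")
  set.seed(cfg$seed)
  ds <- ssm_dataset(blocks)
  scaler <- scaler_fit(ds$morpho)
  M <- scaler_apply(scaler, ds$morpho)
  Y <- label_one_hot(ds$labels)
  say <- function(...) if (verbose) message(sprintf(...))

  # ---- stage 1: SFE ----
  say("stage 1: image branch (%d blocks, %d epochs)", ds$n, cfg$epochs_sfe_image)
  img_net <- sfe_image_new(input_shape = dim(blocks[[1]]$image))
  img_fit <- .train_image_net(img_net, ds$images, Y, cfg$epochs_sfe_image, cfg)
  img_net <- img_fit$net
  say("stage 1: auto branch (%d epochs)", cfg$epochs_sfe_auto)
  train_auto <- function(sub) { # sub: column indices to train on
    net <- sfe_auto_new(32)
    opt <- adam_new(net$layers, lr = cfg$lr, beta1 = cfg$beta1,
                    beta2 = cfg$beta2, weight_decay = cfg$weight_decay)
    losses <- numeric(cfg$epochs_sfe_auto)
    for (ep in seq_len(cfg$epochs_sfe_auto)) {
      perm <- sub[sample.int(length(sub))]
      tot <- 0
      for (start in seq(1, length(perm), by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
        fw <- mlp_fw(net, M[, idx, drop = FALSE])
        ce <- softmax_ce(fw$Z, Y[, idx, drop = FALSE])
        bw <- mlp_bw(net, fw, ce$dZ)
        st <- adam_step(opt, net$layers, bw$grads, no_decay = c("b"))
        opt <- st$opt; net$layers <- st$params
        tot <- tot + ce$loss * length(idx)
      }
      losses[ep] <- tot / length(sub)
    }
    list(net = net, losses = losses)
  }
  auto_fit <- train_auto(seq_len(ds$n))
  auto_net <- auto_fit$net
  auto_losses <- auto_fit$losses
  model <- structure(list(img_net = img_net, auto_net = auto_net,
                          lstm_img = lstm_new(4, 10, 2, 2),
                          lstm_auto = lstm_new(4, 10, 2, 2),
                          mf_net = mlp_new(c(4, 30, 2)),
                          scaler = scaler, s = s, cfg = cfg),
                     class = "ssm_model")
  checkpoints <- list(stage1 = .param_summary(model))

  # ---- stage 2: SIE with SFE frozen ----
  # training windows include every length 1..s: at inference a block is
  # classified from however long an adjacent run it has, so the LSTMs must
  # also learn the short-context regimes
  windows <- unlist(lapply(seq_len(s), function(L) build_sequences(blocks, L)),
                    recursive = FALSE)
  if (length(build_sequences(blocks, s)) == 0 && s > 1) {
    stop("train_stagewise: empty sequence set for s = ", s)
  }
  P_img <- .image_probs(img_net, ds$images)
  # the sequence and fusion stages consume CROSS-FITTED auto-branch outputs
  # (leave-one-neuron-out): the dense branch memorizes its training neurons,
  # and a fusion head fitted on overfit outputs learns to over-trust it on
  # unseen neurons. The image branch trains for very few epochs and is used
  # as-is. The full-data auto_net remains the inference network (stacking).
  neurons <- unique(ds$neuron)
  P_auto <- softmax_cols(mlp_fw(auto_net, M)$Z)
  if (length(neurons) >= 2) {
    for (nid in neurons) {
      hold <- which(ds$neuron == nid)
      cv <- train_auto(which(ds$neuron != nid))
      P_auto[, hold] <- softmax_cols(mlp_fw(cv$net, M[, hold, drop = FALSE])$Z)
    }
  }
  say("stage 2: %d windows of lengths 1..%d, %d epochs",
      length(windows), s, cfg$epochs_sie)
  C_img <- .hard_onehot(P_img)
  C_auto <- .hard_onehot(P_auto)
  fit_i <- .train_sie(model$lstm_img, windows, P_img, Y, Y, cfg$epochs_sie, cfg,
                      ctx_pred = C_img)
  fit_a <- .train_sie(model$lstm_auto, windows, P_auto, Y, Y, cfg$epochs_sie, cfg,
                      ctx_pred = C_auto)
  model$lstm_img <- fit_i$net
  model$lstm_auto <- fit_a$net
  checkpoints$stage2 <- .param_summary(model)

  # ---- warm-start the fusion head on cached sequence outputs ----
  # the joint stage below is budget-capped at very few epochs; the tiny
  # fusion network is first fitted on the frozen O_Is/O_As so joint training
  # fine-tunes rather than trains from scratch. Contexts here are the branch
  # predictions -- the distribution the head will see at inference.
  OI <- .sie_outputs(model$lstm_img, windows, P_img, C_img)
  OA <- .sie_outputs(model$lstm_auto, windows, P_auto, C_auto)
  last_all <- vapply(windows, function(w) w[length(w)], 0L)
  mf_opt <- adam_new(model$mf_net$layers, lr = cfg$lr, beta1 = cfg$beta1,
                     beta2 = cfg$beta2, weight_decay = cfg$weight_decay)
  nw <- length(windows)
  for (ep in seq_len(cfg$epochs_mf)) {
    perm <- sample.int(nw)
    for (start in seq(1, nw, by = cfg$batch_size)) {
      wi <- perm[start:min(start + cfg$batch_size - 1, nw)]
      fw <- mlp_fw(model$mf_net, rbind(OI[, wi, drop = FALSE], OA[, wi, drop = FALSE]))
      ce <- softmax_ce(fw$Z, Y[, last_all[wi], drop = FALSE])
      bw <- mlp_bw(model$mf_net, fw, ce$dZ)
      st <- adam_step(mf_opt, model$mf_net$layers, bw$grads, no_decay = c("b"))
      mf_opt <- st$opt; model$mf_net$layers <- st$params
    }
  }

  # ---- stage 3: joint training through MF ----
  say("stage 3: joint (%d epochs)", cfg$epochs_joint)
  params <- list(img = model$img_net$params, auto = model$auto_net$layers,
                 li = model$lstm_img$params, la = model$lstm_auto$params,
                 mf = model$mf_net$layers)
  # fine-tuning rate: a fresh Adam takes first steps of size ~lr regardless
  # of gradient magnitude, and at desk scale the joint stage is only a few
  # minibatches -- full-rate steps would jolt the converged branches
  opt <- adam_new(params, lr = cfg$lr * 0.1, beta1 = cfg$beta1,
                  beta2 = cfg$beta2, weight_decay = cfg$weight_decay)
  joint_losses <- numeric(cfg$epochs_joint)
  # joint fine-tuning uses the operating-length windows only, in chain order:
  # consecutive windows share blocks, so each minibatch's distinct-block set
  # (the unit of volumetric-network cost) stays close to the batch size
  windows_joint <- if (s > 1) build_sequences(blocks, s) else windows
  nw <- length(windows_joint)
  joint_batches <- split(seq_len(nw),
                         ceiling(seq_len(nw) / cfg$batch_size))
  for (ep in seq_len(cfg$epochs_joint)) {
    tot <- 0
    for (wi in joint_batches) {
      wb <- windows_joint[wi]
      s_b <- length(wb[[1]])                    # equal within a batch
      ub <- sort(unique(unlist(wb)))            # distinct blocks in the batch
      pos <- match(unlist(wb), ub)
      wpos <- split(pos, rep(seq_along(wb), lengths(wb))) # windows in ub positions
      B <- length(wb)
      # SFE forward (train mode) once per distinct block; caches are NOT
      # retained (memory): the backward pass below re-runs each chunk's
      # forward under the same RNG state so dropout masks agree
      rng_before <- .Random.seed
      Zi <- matrix(0, 2, length(ub))
      for (cs in seq(1, length(ub), by = .sfe_chunk)) {
        ci <- cs:min(cs + .sfe_chunk - 1, length(ub))
        fw <- resnet_fw(model$img_net, ds$images[, ub[ci], drop = FALSE],
                        training = TRUE)
        model$img_net$state <- fw$net$state
        Zi[, ci] <- fw$Z
        rm(fw)
      }
      Pi <- softmax_cols(Zi)
      afw <- mlp_fw(model$auto_net, M[, ub, drop = FALSE])
      Pa <- softmax_cols(afw$Z)
      # LSTMs over windows (inputs indexed by position within ub)
      mk_inputs <- function(P) {
        Chard <- .hard_onehot(P)
        lapply(seq_len(s_b), function(t) {
          idx <- vapply(wpos, `[`, 0L, t)
          ctx <- if (t < s_b) {
            cc <- Y[, ub[idx], drop = FALSE]
            use_pred <- runif(B) >= 0.5 # scheduled sampling, as in stage 2
            if (any(use_pred)) cc[, use_pred] <- Chard[, idx[use_pred], drop = FALSE]
            cc
          } else matrix(0, 2, B)
          rbind(ctx, P[, idx, drop = FALSE])
        })
      }
      lfw_i <- lstm_fw(model$lstm_img, mk_inputs(Pi))
      lfw_a <- lstm_fw(model$lstm_auto, mk_inputs(Pa))
      mfw <- mlp_fw(model$mf_net, rbind(lfw_i$Z, lfw_a$Z))
      last <- vapply(wb, function(w) w[length(w)], 0L)
      ce <- softmax_ce(mfw$Z, Y[, last, drop = FALSE])
      tot <- tot + ce$loss * B
      # backward
      mbw <- mlp_bw(model$mf_net, mfw, ce$dZ)
      lbw_i <- lstm_bw(model$lstm_img, lfw_i, mbw$dX[1:2, , drop = FALSE])
      lbw_a <- lstm_bw(model$lstm_auto, lfw_a, mbw$dX[3:4, , drop = FALSE])
      scatter_dP <- function(lbw) {
        dP <- matrix(0, 2, length(ub))
        for (t in seq_len(s_b)) {
          idx <- vapply(wpos, `[`, 0L, t)
          dstep <- lbw$dXs[[t]][3:4, , drop = FALSE]
          for (bb in seq_len(B)) dP[, idx[bb]] <- dP[, idx[bb]] + dstep[, bb]
        }
        dP
      }
      dZi <- softmax_bw(Pi, scatter_dP(lbw_i))
      dZa <- softmax_bw(Pa, scatter_dP(lbw_a))
      img_grads <- NULL
      rng_after <- .Random.seed
      assign(".Random.seed", rng_before, envir = globalenv())
      for (cs in seq(1, length(ub), by = .sfe_chunk)) {
        ci <- cs:min(cs + .sfe_chunk - 1, length(ub))
        fw <- resnet_fw(model$img_net, ds$images[, ub[ci], drop = FALSE],
                        training = TRUE) # state deliberately not re-saved
        g <- resnet_bw(model$img_net, fw$cache, dZi[, ci, drop = FALSE],
                       training = TRUE)
        rm(fw)
        img_grads <- grads_add_inplace(img_grads, g)
        rm(g)
      }
      assign(".Random.seed", rng_after, envir = globalenv())
      abw <- mlp_bw(model$auto_net, afw, dZa)
      grads <- list(img = img_grads, auto = abw$grads,
                    li = lbw_i$grads, la = lbw_a$grads, mf = mbw$grads)
      # in-place: the model's parameter arrays are updated directly
      opt <- adam_step_inplace(opt, params, grads,
                               no_decay = c("b", "gamma", "beta"))
      rm(grads, img_grads)
      gc(FALSE)
    }
    joint_losses[ep] <- tot / nw
  }
  model$img_net <- resnet_refresh_stats(model$img_net, ds$images)
  checkpoints$stage3 <- .param_summary(model)
  model$checkpoints <- checkpoints
  model$losses <- list(sfe_image = img_fit$losses, sfe_auto = auto_losses,
                       sie_image = fit_i$losses, sie_auto = fit_a$losses,
                       joint = joint_losses)
  model
}

# ---- prediction and evaluation ----------------------------------------------

#' Predict difficulty labels for a set of blocks
#'
#' Blocks are processed per neuron in ascending traversal order; each block
#' is classified from the longest available adjacent run ending at it (up to
#' the model's sequence length), with earlier steps' label context taken
#' from the predictions already made along the run (never from true labels).
#'
#' @param model a trained [train_stagewise()] model
#' @param blocks list of blocks to classify
#' @return list with per-block predictions: `mf`, `sie_image`, `sie_auto`,
#'   `sfe_image`, `sfe_auto` (character vectors) and `prob_mf` (2 x n)
#' @export
predict_ssm <- function(model, blocks) {
  ds <- ssm_dataset(blocks)
  M <- scaler_apply(model$scaler, ds$morpho)
  P_img <- .image_probs(model$img_net, ds$images)
  P_auto <- softmax_cols(mlp_fw(model$auto_net, M)$Z)
  s <- model$s
  lv <- .label_levels
  sfe_img <- lv[apply(P_img, 2, which.max)]
  sfe_auto <- lv[apply(P_auto, 2, which.max)]

  # predecessor of each block along the tracing order (smallest index wins)
  pred_of <- integer(ds$n)
  for (i in seq_len(ds$n)) {
    cand <- which(ds$neuron == ds$neuron[i] &
                  ds$ord == ds$ord[i] - 100L)
    cand <- cand[vapply(cand, function(j)
      are_adjacent(blocks[[j]], blocks[[i]]), logical(1))]
    pred_of[i] <- if (length(cand)) min(cand) else 0L
  }
  order_idx <- order(ds$neuron, ds$ord)
  pred_mf <- character(ds$n)
  sie_img <- character(ds$n)
  sie_auto <- character(ds$n)
  prob_mf <- matrix(0, 2, ds$n)
  onehot <- function(lab) if (lab == "low") c(1, 0) else c(0, 1)
  for (i in order_idx) {
    # walk back up to s-1 predecessors
    path <- i
    while (length(path) < s && pred_of[path[1]] > 0L) path <- c(pred_of[path[1]], path)
    L <- length(path)
    ctx <- lapply(seq_len(L), function(t) {
      if (t < L) onehot(pred_mf[path[t]]) else c(0, 0)
    })
    o_is <- sie_forward(model$lstm_img,
                        lapply(path, function(j) P_img[, j]), ctx)
    o_as <- sie_forward(model$lstm_auto,
                        lapply(path, function(j) P_auto[, j]), ctx)
    pm <- mf_forward(model$mf_net, o_is, o_as)
    prob_mf[, i] <- pm
    pred_mf[i] <- lv[which.max(pm)]
    sie_img[i] <- lv[which.max(o_is)]
    sie_auto[i] <- lv[which.max(o_as)]
  }
  list(mf = pred_mf, sie_image = sie_img, sie_auto = sie_auto,
       sfe_image = sfe_img, sfe_auto = sfe_auto, prob_mf = prob_mf)
}

#' Evaluate a trained model on labeled blocks
#'
#' @param model a trained `ssm_model`
#' @param blocks labeled evaluation blocks
#' @param train_neurons neuron ids seen in training; evaluation refuses to
#'   proceed if any evaluation block shares one (split leakage)
#' @return list of [classification_metrics()] per predictor
#' @export
evaluate_ssm <- function(model, blocks, train_neurons = NULL) {
  if (!is.null(train_neurons)) {
    ev <- unique(vapply(blocks, function(b) b$neuron_id, ""))
    if (length(intersect(ev, train_neurons))) {
      stop("evaluate_ssm: train/test split leakage (shared neuron ids)")
    }
  }
  truth <- vapply(blocks, function(b) b$label, "")
  pr <- predict_ssm(model, blocks)
  lapply(pr[c("mf", "sie_image", "sie_auto", "sfe_image", "sfe_auto")],
         function(p) classification_metrics(truth, p))
}

#' Split blocks into train and test sets by neuron
#'
#' @param blocks list of blocks
#' @param test_fraction fraction of neurons assigned to the test set
#' @param seed RNG seed
#' @return list with `train`, `test` (block lists) and the neuron id sets
#' @export
split_by_neuron <- function(blocks, test_fraction = 0.3, seed = 1) {
  ids <- vapply(blocks, function(b) b$neuron_id, "")
  neurons <- sort(unique(ids))
  set.seed(seed)
  ntest <- max(1, round(test_fraction * length(neurons)))
  test_ids <- sort(sample(neurons, ntest))
  list(train = blocks[!(ids %in% test_ids)], test = blocks[ids %in% test_ids],
       train_neurons = setdiff(neurons, test_ids), test_neurons = test_ids)
}

#' Train and evaluate over repeated runs
#'
#' Repeats the full staged training `runs` times (run r uses seed
#' `cfg$seed + r - 1`) and reports the mean and standard deviation of
#' accuracy and F1 for every predictor.
#'
#' @param train_blocks,test_blocks labeled block lists with disjoint neurons
#' @param s sequence length
#' @param cfg a [train_config()]
#' @param runs number of repeats (defaults to `cfg$runs`)
#' @param verbose print progress
#' @return list with `runs` (per-run metric lists), `summary` (data frame of
#'   mean/sd accuracy and F1 per predictor), `models` last trained model
#' @export
run_experiment <- function(train_blocks, test_blocks, s = 3,
                           cfg = train_config(), runs = cfg$runs,
                           verbose = FALSE) {
  tr_ids <- unique(vapply(train_blocks, function(b) b$neuron_id, ""))
  te_ids <- unique(vapply(test_blocks, function(b) b$neuron_id, ""))
  if (length(intersect(tr_ids, te_ids))) {
    stop("run_experiment: train/test split leakage (shared neuron ids)")
  }
  per_run <- list()
  model <- NULL
  for (r in seq_len(runs)) {
    rcfg <- cfg
    rcfg$seed <- cfg$seed + r - 1L
    model <- train_stagewise(train_blocks, s = s, cfg = rcfg, verbose = verbose)
    per_run[[r]] <- evaluate_ssm(model, test_blocks, train_neurons = tr_ids)
  }
  preds <- names(per_run[[1]])
  summary <- do.call(rbind, lapply(preds, function(p) {
    acc <- vapply(per_run, function(m) m[[p]]["accuracy"], 0)
    f1 <- vapply(per_run, function(m) m[[p]]["f1"], 0)
    data.frame(predictor = p, accuracy_mean = mean(acc),
               accuracy_sd = if (runs > 1) sd(acc) else 0,
               f1_mean = mean(f1), f1_sd = if (runs > 1) sd(f1) else 0)
  }))
  list(runs = per_run, summary = summary, model = model)
}
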