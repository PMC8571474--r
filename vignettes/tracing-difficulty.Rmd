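---
title: "Classifying the tracing difficulty of 3D neuron image blocks"
author: "traceblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the tracing difficulty of 3D neuron image blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Block-by-block automatic tracing of single neurons in whole-brain
light-microscopy volumes fails unevenly: blocks with a single bright
neurite are traced almost perfectly, while blocks with weak signal, strong
noise, crossings or dense arborization come out broken or incomplete. This
package classifies 32 x 64 x 64 voxel blocks into *low* and *high* tracing
difficulty so that an automatic tracer can keep going on the easy ones and
defer the hard ones to annotators.

Everything runs on synthetic data generated in-package; the original brain
volumes behind the published numbers are not publicly archived, so the
headline accuracies reported there (for context: ~84% fused test accuracy
on the training brain, ~83% on a second brain, ~96.5% auto-labeler
accuracy, 60.55% adjacent-label agreement) are *not* reproduction targets
here. What this package reproduces exactly is the printed architecture and
the procedural semantics; what it verifies statistically are properties on
its own synthetic corpora.

## Blocks, metrics, labels

**Blocks.** Anchors are taken every 100 nodes of the depth-first preorder
of the gold reconstruction from the soma root (children visited in
ascending id; the rounding and traversal conventions are the package's
choice — the source text does not fix them). Each anchor centers a
32 x 64 x 64 block (anchor at `floor(size/2)`; border blocks are
zero-padded). Gold and auto reconstructions are cropped with a half-open
containment test on real-valued coordinates, severed edges creating new
fragment roots. Auto blocks are burr-pruned — terminal branches of < 4
nodes hanging off a bifurcation (iterated to stability), and fragments of
< 4 nodes within 4 voxels of a block face — and blocks with < 11 auto
nodes are dropped together with their image and gold data. An unbranched
fragment is governed only by the fragment rule: deleting every small
unbranched fragment regardless of position would make the separate
edge-distance clause meaningless.

**Similarity metrics.** The seven distances follow the ESA/DSA/PDS family:
mean nearest-node distance in each direction and their average; the mean of
pooled distances strictly above 2 voxels (`dsa2`, 0 when the set is empty);
and fractions of nodes at >= 2 voxels (per direction and pooled). The
threshold asymmetry (strictly `> 2` for DSA2, `>= 2` for PDS) mirrors the
stated definitions rather than harmonizing them. DSA2 pools both
directions — the one-line definition in the source does not fix a
direction, and the pooled form matches the symmetric "different structure"
notion. The three morphology features are absolute gold-minus-auto count
differences (bifurcations, nodes, fragments); raw one-sided counts would
not measure similarity of the *pair*.

**Morphometrics.** The 32-feature registry (`lmeasure_feature_names()`)
covers counts (stems, bifurcations, branches, tips, fragments), branch and
total lengths, spatial extents, radii, frustum surface and volume,
Euclidean and path distances from fragment roots, contraction and
tortuosity, branch orders, partition asymmetry, local and remote
bifurcation angles, parent/daughter ratios and terminal-segment counts.
The original feature list is not published; this registry is fixed, ordered
and documented so results are reproducible against *this* definition. All
values are finite on any non-empty forest (degenerate denominators fall
back to 0 or 1 as documented per feature).

**Auto-labeler.** A dense 50-30-20-2 classifier on the z-scored 10
similarity features (standardization fitted on the training split only),
softmax cross-entropy, Adam, random 70/30 split. Training hyper-parameters
are package defaults (`labeler_spec()`) — the source reports only the layer
widths — and are echoed in the training report.

## The three-module classifier

The image branch is a volumetric residual network (stem convolution 64
channels stride (1,2,2); 3x3x3 max pool stride 2; four residual layers
[A(64) x2], [B(128), A(128)], [B(256), A(256)], [B(512), A(512)]; 2x2x2
average pool; fully connected to 2). Residual units use the standard
two-convolution layout with batch norm and an identity skip; unit B strides
2 and projects the skip with a 1x1x1 stride-2 convolution. Dropout 0.2 is
applied at the entry of each residual layer during training. The auto
branch is a 100-50-2 dense network on the standardized morphometrics.

The sequence stage defines blocks as adjacent when their anchors are at
most 100 voxels apart *and* exactly 100 nodes apart in traversal order.
Each LSTM (2 layers x 10 hidden units) consumes per step the concatenation
of a one-hot label context and the 2-dim softmax output of its structure
branch. The label context of the *prediction* step is a zero vector —
feeding the true label of the block being predicted would leak the answer;
earlier steps use teacher forcing during training and the model's own
previous predictions at inference. Fusion is
`softmax(W_M cat(O_Is, O_As))` through a 30-2 dense head.

Training is staged: (1) both structure branches with cross-entropy against
one-hot labels; (2) both LSTMs with the branches frozen (their outputs are
precomputed once), then a warm start of the fusion head on the cached
sequence outputs; (3) joint fine-tuning of everything through the fusion
head. In stage 3 each distinct block in a minibatch passes through the
volumetric network once, and gradients from every sequence window touching
it are summed — an exact reformulation that keeps single-CPU cost near one
stage-1 epoch. The backward pass re-runs each chunk's forward under a
restored RNG state so dropout masks agree; batch-norm statistics are
computed per micro-batch of 8 samples (a memory ceiling, noted because it
makes "batch" statistics micro-batch statistics). The joint stage runs at
one tenth of the base learning rate: a freshly initialized Adam takes first
steps of size ~lr regardless of gradient magnitude, and with only a handful
of joint minibatches at desk scale, full-rate steps demonstrably jolt the
converged branches.

Three further choices keep the sequence and fusion stages from *losing*
information relative to the structure branches, which is both a stated
acceptance property and the point of the architecture:

- **Scheduled sampling.** Earlier-step label contexts are the true labels
  with probability 0.5 and the frozen branch predictions otherwise (and the
  fusion warm start uses predicted contexts throughout). Inference supplies
  predicted labels, so pure teacher forcing leaves the LSTMs brittle to
  exactly the contexts they will see (exposure bias); with it we observed
  held-out sequence accuracy several points *below* the branch it reads.
- **Stacked (cross-fitted) fusion inputs.** The morphometrics branch — a
  dense network trained for many epochs on a handful of neurons — memorizes
  its training neurons; a fusion head fitted on those overfit outputs
  learns to over-trust it on unseen neurons. The sequence and fusion
  stages therefore consume leave-one-neuron-out auto-branch outputs (the
  branch is retrained per held-out neuron in seconds), while the full-data
  network remains the inference branch. The image branch trains for very
  few epochs and is used as-is.
- **Variable-length windows.** The LSTMs train on windows of every length
  1..s, because inference classifies each block from however long an
  adjacent run it actually has.

At evaluation, blocks are processed per neuron in ascending traversal
order; each is classified from the longest available adjacent run ending at
it (up to `s`), with label context from predictions already made along the
run. Blocks with no predecessors fall back to the length-1 path, so
corpus-level accuracy is defined for every block. F1 uses *high* as the
positive class (the operationally costly one).

### Epochs and budgets

Per-stage epoch counts are unreported in the source and are configurable
(`train_config()`). The defaults here are sized for desk-scale synthetic
runs on one CPU: the dense and LSTM stages are cheap and get large counts
(200 / 120); the volumetric branch costs seconds per sample and gets few
(3 stage-1 epochs, 1 joint epoch by default; the acceptance run uses 1/1).
This trades image-branch accuracy for tractability; the fused model leans
on the morphometrics branch accordingly, which is also the behavior of the
published system (its morphometrics branch was the weaker one only because
its image branch had GPU-scale training).

Rotation augmentation (3 copies per training block, 90/180/270 degrees) is
implemented and tested but off by default in desk-scale runs — it triples
stage-1 cost. The rotation axis is the depth axis: for a 32 x 64 x 64
block only rotations in the 64 x 64 plane preserve the shape.

## The synthetic world

`synth_config()` defaults define the stated world; they were chosen once,
on the following reasoning, and are not tuned per run:

- **Trees.** Depth-first biased random walks: one neurite grows 100-250
  nodes (step 1 voxel, direction jitter 0.08 rad, outward drift 0.08 in
  the slab plane), then yields to a queued branch seed; tips terminate at
  a 250-voxel leash from the soma (real arbors radiate and do not crawl
  along volume walls) and the walker reseeds at the soma when idle. 2600
  nodes per neuron give 26 anchors; 8 neurons give ~208 blocks.
- **Rendering.** Edges are stamped as radius-1.6 tubes (max composited)
  over background 40 with Gaussian noise sd 12; foreground is 160 in low
  regions and 70 in high regions — ~10 sigma vs ~2.5 sigma above
  background, i.e. obvious vs weak signal. Distractor tubes rendered but
  absent from both reconstructions emulate crossing neurites.
- **Difficulty.** Anchor labels follow a symmetric 2-state Markov chain
  along traversal order with persistence 0.6 (matching the observed ~60%
  adjacent-label agreement; stationary distribution 50/50, so classes are
  balanced by construction). Each *node* takes the regime of its spatially
  nearest anchor: difficulty is physically a local image property, so a
  neurite passing through a low-difficulty neighborhood renders and traces
  like its neighborhood. The anchor label process itself is exactly the
  Markov chain.
- **Auto reconstructions.** Low regime: coordinate jitter sd 0.15 voxels.
  High regime: jitter sd 3.0, loss of small side branches (<= 40 nodes,
  p = 0.5), tracing gaps (p = 0.02 per node, 8-25 nodes disappearing with
  the remainder continuing as a new fragment), spontaneous breaks, and
  spurious 3-8 node branches (p = 0.03) — the canonical failure modes of
  gray-weighted distance-transform tracers on weak signal.

What a green test does **not** establish: the simulator has no optics (no
PSF, no depth attenuation, Gaussian rather than Poisson noise), no imaging
anisotropy, no soma-shaped blobs beyond a larger stamped radius, and its
difficulty is a hidden two-state regime rather than a continuum. Absolute
accuracies on it do not transfer to real brains; the pipeline mechanics,
the metric definitions and the learning dynamics do.

One stated property of the world deserves honesty: with labels flipping
every ~2.5 anchors, blocks near regime boundaries (and blocks crossed by
order-distant segments) contain mixed-regime nodes and are intrinsically
ambiguous. In-sample linear separability of the 10 similarity features
measures ~0.84-0.89 across seeds (morphometrics ~0.89-0.92) — short of the
~0.90 one might hope for; the geometry above was engineered to push
transitions to block edges, and the residual gap is irreducible at
persistence 0.6. The corresponding auto-labeler recovery check therefore
uses a separable feature-space corpus (Gaussian classes with a known rule),
which tests the labeler, not the world.

### Normalization and batch-norm calibration

Image blocks are scaled by a fixed global constant (1/255), *not* min-max
normalized per block: per-block normalization maps the peak of a bright
tube and of a dim tube both to 1, erasing absolute signal strength — which
is precisely the weak-signal cue that defines high difficulty. This was
verified empirically (with per-block min-max the image branch collapses to
the majority class).

Because the volumetric network trains in micro-batches of 6 samples, the
exponential running averages of batch norm drift from population
statistics and the error compounds across the ten normalization layers
(train-mode accuracy can be perfect while eval-mode collapses). After
stage 1 and stage 3 the running statistics are therefore recalibrated with
a dropout-free pass over up to 48 training blocks, replacing them with
arithmetic means of the chunk statistics ("precise BN").

## Numerical choices

- All learning runs in double precision except the volumetric
  convolutions, which run in single precision internally (sgemm + halved
  bandwidth dominate single-CPU cost); gradient tests budget 1e-3 for the
  convolution path and 1e-6 to 1e-8 elsewhere.
- Adam uses classic L2 weight decay added to gradients (decay skipped for
  biases and batch-norm parameters); beta1 0.9, beta2 0.99, lr 0.001,
  decay 0.01, batch 30.
- Batch-norm eps 1e-5, momentum 0.1; evaluation uses running statistics.
- Ties: preorder children in ascending id; the predecessor chosen at a
  branch point during sequential prediction is the lowest block index;
  `which.max` resolves probability ties toward *low* (first class).
- Degenerate inputs: empty forests error in metrics (distances are
  undefined), return 0 counts in morphology differences; blocks whose
  image is constant normalize to all zeros.
- Determinism: everything funnels through R's RNG under explicit seeds;
  BLAS is pinned to one thread at package load.

## Known limitations

- The LSTM/fusion stack is trained on windows of a single fixed length
  `s`; mixed-length curricula are not implemented.
- `read_nrrd()` supports the subset of NRRD this package writes (raw/gzip,
  little-endian scalar types); TIFF stacks are not read in R (no TIFF
  package in the supported environment).
- The manual 4-rule annotation protocol that produced the original labeled
  subset is not implemented; manual labels are an input (CSV), and the
  synthetic world substitutes construction labels.
- Single-channel volumes only; multi-resolution (whole-brain streaming)
  access is out of scope.
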