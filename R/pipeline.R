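# End-to-end orchestration: simulate -> build blocks -> features -> label ->
# sequences -> staged training -> evaluation, as one reproducible run.

#' Full-run configuration
#'
#' @param synth a [synth_config()]
#' @param block a [block_config()]
#' @param labeler a [labeler_spec()]
#' @param train a [train_config()]
#' @param s_values sequence lengths to train/evaluate
#' @param seed master seed (sub-stage seeds derive from it)
#' @param test_fraction fraction of neurons held out by neuron id
#' @param manual_fraction fraction of blocks treated as manually labeled
#'   (their construction labels are given to the labeler as "manual" truth)
#' @param use_auto_labeler label the remaining blocks with the trained
#'   labeler (otherwise construction labels are used directly)
#' @param runs repeat runs for mean/sd reporting
#' @param output_dir optional directory for reports and artifacts
#' @return named list
#' @export
run_config <- function(synth = synth_config(), block = block_config(),
                       labeler = labeler_spec(), train = train_config(),
                       s_values = c(1, 3), seed = 1, test_fraction = 0.3,
                       manual_fraction = 0.3, use_auto_labeler = TRUE,
                       runs = 1, output_dir = NULL) {
  stopifnot(all(s_values >= 1), seed == floor(seed))
  as.list(environment())
}

#' Run the whole pipeline
#'
#' Stages, in order: (1) synthetic corpus generation; (2) similarity +
#' morphometric feature extraction; (3) difficulty labeling — a labeler is
#' trained on the "manual" fraction and labels the rest; (4) neuron-level
#' train/test split; (5) staged model training and evaluation for each
#' requested sequence length. Any stage failure aborts with the stage name.
#'
#' @param cfg a [run_config()]
#' @param verbose print progress
#' @return run report (list): per-stage counts, label distribution,
#'   adjacent-label agreement, labeler report, per-`s` metric summaries,
#'   seeds and config hash
#' @export
run_end_to_end <- function(cfg = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  report <- list(package_version = as.character(utils::packageVersion("traceblocks")),
                 config_hash = config_hash(cfg[setdiff(names(cfg), "output_dir")]),
                 seed = cfg$seed)

  say("stage: simulate")
  corpus <- stage("simulate", generate_labeled_corpus(cfg$synth, seed = cfg$seed,
                                                      block_cfg = cfg$block))
  if (length(corpus$blocks) == 0) {
    stop("pipeline stage 'simulate' failed: empty corpus (no blocks survived filtering)")
  }
  report$n_blocks <- length(corpus$blocks)
  report$n_neurons <- length(unique(corpus$manifest$neuron_id))
  report$label_distribution <- table(corpus$manifest$label)
  report$same_label_fraction <- same_label_fraction(corpus$blocks)

  say("stage: features (%d blocks)", length(corpus$blocks))
  feats <- stage("features", feature_table(corpus$blocks))

  say("stage: label")
  blocks <- corpus$blocks
  if (cfg$use_auto_labeler) {
    lab <- stage("label", {
      set.seed(cfg$seed + 1000L)
      n <- length(blocks)
      manual_idx <- sort(sample.int(n, max(2, round(cfg$manual_fraction * n))))
      fx <- t(as.matrix(feats[, names(similarity_features(
        blocks[[1]]$gold, blocks[[1]]$auto))]))
      spec <- cfg$labeler
      spec$seed <- cfg$seed + 1001L
      labeler <- train_auto_labeler(fx[, manual_idx, drop = FALSE],
                                    feats$label[manual_idx], spec)
      applied <- predict(labeler, fx)
      final <- feats$label
      final[-manual_idx] <- applied[-manual_idx]
      list(labeler = labeler, final = final, manual_idx = manual_idx,
           agreement = mean(applied == feats$label))
    })
    for (i in seq_along(blocks)) blocks[[i]]$label <- lab$final[i]
    report$labeler <- lab$labeler$report[c("train", "test", "n_train", "n_test")]
    report$labeler_agreement_with_truth <- lab$agreement
    report$n_manual <- length(lab$manual_idx)
  }

  say("stage: split")
  sp <- stage("split", split_by_neuron(blocks, cfg$test_fraction,
                                       seed = cfg$seed + 2000L))
  if (length(sp$train) == 0 || length(sp$test) == 0) {
    stop("pipeline stage 'split' failed: empty train or test set")
  }
  report$n_train <- length(sp$train)
  report$n_test <- length(sp$test)
  report$train_neurons <- sp$train_neurons
  report$test_neurons <- sp$test_neurons

  report$metrics <- list()
  for (s in cfg$s_values) {
    say("stage: train+evaluate (s = %d)", s)
    ex <- stage(sprintf("train s=%d", s),
                run_experiment(sp$train, sp$test, s = s, cfg = cfg$train,
                               runs = cfg$runs, verbose = verbose))
    report$metrics[[paste0("s", s)]] <- ex$summary
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(corpus$manifest, file.path(cfg$output_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(feats, file.path(cfg$output_dir, "features.csv"), row.names = FALSE)
    rj <- report
    rj$label_distribution <- as.list(report$label_distribution)
    rj$metrics <- lapply(report$metrics, function(m) m)
    jsonlite::write_json(rj, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
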