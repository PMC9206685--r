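#' Epoch segmentation configuration
#'
#' @param window_s Window length in seconds (default 8, the duration used
#'   for long music-listening recordings).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @param taper `"rectangular"` (samples unmodified) or `"hamming"`.
#' @param balance_classes When segmenting several labelled recordings,
#'   increase the minority class's overlap until per-class epoch counts
#'   match exactly.
#' @export
epoching_config <- function(window_s = 8, overlap_fraction = 0,
                            taper = c("rectangular", "hamming"),
                            balance_classes = TRUE) {
  taper <- match.arg(taper)
  stopifnot(window_s > 0, overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 taper = taper, balance_classes = isTRUE(balance_classes)),
            class = "epoching_config")
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Half-open windows `[start, start + len)` over 0-based sample indices,
#' stepped by `len * (1 - overlap_fraction)`; the number of epochs is
#' `floor((T - len)/step) + 1`.  An optional Hamming taper multiplies each
#' window.
#'
#' @param recording A `sensor_recording`.
#' @param cfg An [epoching_config()].
#' @param label Optional class label attached to every epoch.
#' @param overlap_override Internal: replaces `cfg$overlap_fraction`.
#' @return An `epoch_set`.
#' @export
segment_epochs <- function(recording, cfg = epoching_config(), label = NA,
                           overlap_override = NULL) {
  len <- round(cfg$window_s * recording$fs)
  T_len <- ncol(recording$y_t)
  if (T_len < len)
    stop("recording shorter than one window", call. = FALSE)
  ov <- overlap_override %||% cfg$overlap_fraction
  step <- max(1L, round(len * (1 - ov)))
  starts <- seq.int(0L, T_len - len, by = step)
  tap <- if (cfg$taper == "hamming") hamming_window(len) else rep(1, len)
  epochs <- lapply(starts, function(s0) {
    y <- recording$y_t[, (s0 + 1L):(s0 + len), drop = FALSE]
    y <- sweep(y, 2L, tap, "*")
    structure(list(y_t = y, fs = recording$fs, sigma2_n = recording$sigma2_n,
                   subject_id = recording$subject_id,
                   trial_id = recording$trial_id),
              class = "sensor_recording")
  })
  structure(list(epochs = epochs,
                 labels = factor(rep(as.character(label), length(epochs)),
                                 levels = c("negative", "positive")),
                 subject_ids = rep(recording$subject_id %||% NA_integer_,
                                   length(epochs)),
                 trial_ids = seq_along(epochs)),
            class = "epoch_set")
}

#' Segment several labelled recordings with class balancing
#'
#' Each recording is segmented at the configured overlap; if
#' `cfg$balance_classes` is on and class counts differ, the minority class
#' is re-segmented with the smallest overlap increase that yields equal
#' counts.
#'
#' @param recordings List of `sensor_recording`s (one long recording per
#'   class, as produced by concatenating same-emotion segments).
#' @param labels Character class per recording.
#' @param cfg An [epoching_config()].
#' @return A combined `epoch_set` with equal per-class counts when
#'   balancing is on.
#' @export
segment_labeled_recordings <- function(recordings, labels,
                                       cfg = epoching_config()) {
  stopifnot(length(recordings) == length(labels))
  sets <- Map(function(r, l) segment_epochs(r, cfg, label = l),
              recordings, labels)
  counts <- vapply(sets, function(s) length(s$epochs), integer(1))
  by_class <- tapply(counts, labels, sum)
  if (cfg$balance_classes && length(unique(by_class)) > 1L) {
    target <- max(by_class)
    for (cl in names(by_class)[by_class < target]) {
      idx <- which(labels == cl)
      need <- target  # epochs wanted for this class in total
      # distribute across this class's recordings proportionally
      per <- diff(round(seq(0, need, length.out = length(idx) + 1L)))
      sets[idx] <- Map(function(r, n_want) {
        len <- round(cfg$window_s * r$fs)
        T_len <- ncol(r$y_t)
        # largest step giving n_want windows: floor((T-len)/(n_want-1))
        step <- if (n_want <= 1L) T_len else
          max(1L, (T_len - len) %/% (n_want - 1L))
        segment_epochs(r, cfg, label = cl,
                       overlap_override = 1 - step / len)
      }, recordings[idx], as.list(per))
    }
  }
  combine_epoch_sets(sets)
}

combine_epoch_sets <- function(sets) {
  structure(list(epochs = do.call(c, lapply(sets, `[[`, "epochs")),
                 labels = factor(unlist(lapply(sets, function(s)
                   as.character(s$labels))), c("negative", "positive")),
                 subject_ids = unlist(lapply(sets, `[[`, "subject_ids")),
                 trial_ids = unlist(lapply(sets, `[[`, "trial_ids"))),
            class = "epoch_set")
}

#' Train/test(/validation) split plans
#'
#' Two evaluation protocols:
#' \describe{
#'   \item{subject_dependent}{within every subject, 40% of trials
#'     (stratified by class) are drawn at random for training and the
#'     remaining 60% for testing — the 4-train / 6-test pattern for ten
#'     trials.}
#'   \item{subject_independent}{subjects themselves are partitioned
#'     40% / 40% / 20% into train / test / validation; no subject appears
#'     in two partitions.}
#' }
#'
#' @param epoch_set An `epoch_set`.
#' @param mode `"subject_dependent"` or `"subject_independent"`.
#' @param seed Seed for the shuffles.
#' @return Object of class `split_plan` with integer epoch-index vectors
#'   `train`, `test`, `validation` and, for the independent mode, the
#'   subject partition.
#' @export
make_split <- function(epoch_set,
                       mode = c("subject_dependent", "subject_independent"),
                       seed = 1L) {
  mode <- match.arg(mode)
  subj <- epoch_set$subject_ids
  labs <- epoch_set$labels
  withr_seed(seed, {
    if (mode == "subject_dependent") {
      train <- integer(0)
      for (s in unique(subj)) {
        for (cl in levels(labs)) {
          idx <- which(subj == s & labs == cl)
          if (length(idx))
            train <- c(train, sample(idx, round(0.4 * length(idx))))
        }
      }
      train <- sort(train)
      test <- setdiff(seq_along(subj), train)
      plan <- list(mode = mode, train = train, test = test,
                   validation = integer(0), seed = seed)
    } else {
      su <- unique(subj)
      if (length(su) < 3L)
        stop("subject_independent mode needs at least 3 subjects",
             call. = FALSE)
      su <- sample(su)
      n_tr <- round(0.4 * length(su)); n_te <- round(0.4 * length(su))
      tr_s <- su[seq_len(n_tr)]
      te_s <- su[n_tr + seq_len(n_te)]
      va_s <- setdiff(su, c(tr_s, te_s))
      stopifnot(length(intersect(tr_s, te_s)) == 0L,
                length(intersect(tr_s, va_s)) == 0L)
      plan <- list(mode = mode,
                   train = which(subj %in% tr_s),
                   test = which(subj %in% te_s),
                   validation = which(subj %in% va_s),
                   train_subjects = tr_s, test_subjects = te_s,
                   validation_subjects = va_s, seed = seed)
    }
  })
  structure(plan, class = "split_plan")
}

#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by [run_pipeline()], with
#' every stage's defaults filled in.  Values given in `...` (or loaded from
#' YAML) override defaults by name.
#'
#' @param ... Named overrides, e.g. `split = list(mode =
#'   "subject_independent")`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    dataset = list(),                 # emotion_dataset_spec() overrides
    split = list(mode = "subject_dependent"),
    gibbs = list(n_iter = 600L, burn_in = 200L, inclusion_threshold = 0.5,
                 n_snapshots = 4L),
    graph = list(power_fraction = 0.5, beta = 0.3,
                 absolute_correlation = TRUE),
    model = list(K = 3L, n_filters = 16L, n_conv = 32L),
    train = list(rho = 1e-3, lr = 3e-3, epochs = 200L, batch_size = 16L,
                 adjacency_updates = TRUE, weight_decay = 1e-2,
                 augment_shift = TRUE),
    max_nodes = 16L,
    out_dir = NULL)
  modifyList(base, list(...))
}

#' Run the full decoding pipeline on synthetic data
#'
#' simulate -> localize training epochs (Gibbs) -> merge supports -> extract
#' node signals for every epoch by support-restricted least squares -> build
#' the correlation graph from the training epochs -> train the DGCNN ->
#' evaluate on the held-out split.  Deterministic for a fixed config.
#'
#' @param config A [pipeline_config()] list, or a path to a YAML file with
#'   the same structure.
#' @return Object of class `run_report`: accuracies per split, confusion
#'   matrix on the test set, merged support, loss history and a config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  cfg <- config
  spec <- do.call(emotion_dataset_spec,
                  c(cfg$dataset, list(seed = cfg$seed)))
  ds <- generate_dataset(spec)
  lf <- ds$lead_field
  es <- ds$epochs
  split <- make_split(es, cfg$split$mode, seed = cfg$seed)

  gcfg0 <- gibbs_config(n_iter = cfg$gibbs$n_iter, burn_in = cfg$gibbs$burn_in,
                        inclusion_threshold = cfg$gibbs$inclusion_threshold,
                        seed = cfg$seed)
  supports <- vector("list", length(split$train))
  for (j in seq_along(split$train)) {
    k <- split$train[j]
    gcfg <- gcfg0
    gcfg$seed <- cfg$seed + 7919L * k
    supports[[j]] <- estimate_epoch_sources(es$epochs[[k]], lf, gcfg,
                                            n_snapshots =
                                              cfg$gibbs$n_snapshots)$support
  }
  nodes <- merge_supports(supports, max_nodes = min(cfg$max_nodes,
                                                    nrow(lf$H) - 1L))

  feats <- lapply(es$epochs, function(ep)
    estimate_epoch_sources(ep, lf, gcfg0, support = nodes)$signals)

  gbc <- graph_build_config(power_fraction = cfg$graph$power_fraction,
                            beta = cfg$graph$beta,
                            absolute_correlation =
                              cfg$graph$absolute_correlation)
  Ws <- lapply(split$train, function(k) correlation_adjacency(feats[[k]], gbc))
  W <- apply_edge_threshold(Reduce(`+`, Ws) / length(Ws), gbc$beta)
  if (max(rowSums(W)) == 0)
    stop("graph stage: thresholding removed every edge; lower beta",
         call. = FALSE)

  labels_int <- as.integer(es$labels)  # 1 = negative, 2 = positive
  model <- dgcnn_model(W, input_dim = ncol(feats[[1L]]), K = cfg$model$K,
                       n_filters = cfg$model$n_filters,
                       n_conv = cfg$model$n_conv, seed = cfg$seed)
  tr <- train_dgcnn(model, feats[split$train], labels_int[split$train],
                    train_config(rho = cfg$train$rho, lr = cfg$train$lr,
                                 epochs = cfg$train$epochs,
                                 batch_size = cfg$train$batch_size,
                                 seed = cfg$seed,
                                 adjacency_updates =
                                   cfg$train$adjacency_updates,
                                 weight_decay =
                                   cfg$train$weight_decay %||% 0,
                                 augment_shift =
                                   cfg$train$augment_shift %||% FALSE))
  model <- tr$model

  acc <- list(train = evaluate_accuracy(model, feats[split$train],
                                        labels_int[split$train]),
              test = evaluate_accuracy(model, feats[split$test],
                                       labels_int[split$test]))
  if (length(split$validation))
    acc$validation <- evaluate_accuracy(model, feats[split$validation],
                                        labels_int[split$validation])
  pred <- vapply(feats[split$test], function(X) predict(model, X), integer(1))
  conf <- table(truth = es$labels[split$test],
                predicted = levels(es$labels)[pred])

  report <- structure(list(accuracy = acc, confusion = conf,
                           support = nodes, split = split,
                           loss_history = tr$loss_history,
                           config = cfg),
                      class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  mode:", x$split$mode, "\n")
  for (nm in names(x$accuracy))
    cat(sprintf("  %s accuracy: %.3f\n", nm, x$accuracy[[nm]]))
  cat("  merged support:", paste(x$support, collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(mode = report$split$mode, accuracy = report$accuracy,
         support = report$support, seed = report$config$seed,
         config = report$config,
         package_version = as.character(utils::packageVersion("emosource"))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  write.table(as.matrix(report$confusion), file.path(dir, "confusion.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
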