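#' Training harness: random sub-sampling, hidden-size sweep, and
#' criterion-specific checkpoint selection
#'
#' Datasets are split repeatedly into train/test partitions with the
#' positives divided 4:1 and negatives sampled at a fixed ratio per
#' positive (1:5 by default).  For each split the hidden-layer size is
#' swept (2..20 in steps of 2 by default); during every training run the
#' weights achieving the best value of the selection criterion (AUC,
#' recall or precision) on the held-out test split are retained.  Three
#' networks per PTM type result, one per criterion, whose consensus can
#' be queried at prediction time.
#'
#' @name training
NULL

#' Specification of the random sub-sampling scheme
#'
#' @param train_pos_fraction Fraction of positives assigned to training
#'   (default 4/5, i.e. a 4:1 train:test split).
#' @param neg_per_pos Negatives sampled per positive in each partition
#'   (default 5, i.e. a 1:5 positive:negative ratio).
#' @param n_splits Number of independent random splits (default 3).
#' @param seed Integer seed; split `i` uses `seed + i - 1`.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_pos_fraction = 4 / 5, neg_per_pos = 5L,
                       n_splits = 3L, seed = 1L) {
  stopifnot(train_pos_fraction > 0, train_pos_fraction < 1,
            neg_per_pos >= 1, n_splits >= 1)
  structure(list(train_pos_fraction = train_pos_fraction,
                 neg_per_pos = as.integer(neg_per_pos),
                 n_splits = as.integer(n_splits),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Random sub-sampling splits of a labeled dataset
#'
#' Positives are partitioned 4:1 (test count floored, remainder to
#' training); negatives are drawn without replacement at `neg_per_pos`
#' per positive in each partition.  Negatives are re-sampled
#' independently for every split.
#'
#' @param dataset A [labeled_dataset()].
#' @param spec A [split_spec()].
#' @return List of `n_splits` elements, each a list with `train` and
#'   `test` [labeled_dataset()]s.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "split_spec"))
  n_pos <- nrow(dataset$positives)
  n_neg <- nrow(dataset$negatives)
  if (n_pos < 2L) stop("need at least 2 positives to split")
  # round before flooring: 1 - 4/5 is not exact in binary
  test_pos_n <- floor(round(n_pos * (1 - spec$train_pos_fraction), 9))
  if (test_pos_n < 1L) test_pos_n <- 1L
  train_pos_n <- n_pos - test_pos_n
  need_neg <- (train_pos_n + test_pos_n) * spec$neg_per_pos
  if (n_neg < need_neg)
    stop("insufficient negatives: need ", need_neg, " (", spec$neg_per_pos,
         " per positive), have ", n_neg)
  lapply(seq_len(spec$n_splits), function(i) {
    set.seed(spec$seed + i - 1L)
    pos_ord <- sample.int(n_pos)
    train_pos <- dataset$positives[pos_ord[seq_len(train_pos_n)], ,
                                   drop = FALSE]
    test_pos <- dataset$positives[pos_ord[train_pos_n + seq_len(test_pos_n)], ,
                                  drop = FALSE]
    neg_ord <- sample.int(n_neg, need_neg)
    train_neg <- dataset$negatives[
      neg_ord[seq_len(train_pos_n * spec$neg_per_pos)], , drop = FALSE]
    test_neg <- dataset$negatives[
      neg_ord[train_pos_n * spec$neg_per_pos +
                seq_len(test_pos_n * spec$neg_per_pos)], , drop = FALSE]
    list(train = labeled_dataset(train_pos, train_neg, dataset$ptm_type),
         test = labeled_dataset(test_pos, test_neg, dataset$ptm_type))
  })
}

# Criterion value from batched predictions on the test split.
criterion_value <- function(pred, labels, criterion) {
  switch(criterion,
    auc = auc_score(pred$score, labels),
    recall = {
      cc <- confusion_counts(pred$decision, labels)
      safe_div(cc[["TP"]], cc[["TP"]] + cc[["FN"]])
    },
    precision = {
      cc <- confusion_counts(pred$decision, labels)
      safe_div(cc[["TP"]], cc[["TP"]] + cc[["FP"]])
    },
    stop("unknown criterion '", criterion, "'"))
}

encoder_metadata <- function(encoder) {
  list(accessions = encoder$accessions,
       normalization = encoder$normalization,
       unknown_residue = encoder$unknown_residue)
}

#' Rebuild the feature encoder recorded in a model's metadata
#'
#' @param model An `mlp` whose metadata carries an `encoder` block.
#' @return A [feature_encoder()].
#' @export
encoder_from_model <- function(model) {
  meta <- model$metadata$encoder
  if (is.null(meta))
    stop("model metadata does not record encoder settings")
  feature_encoder(lapply(unlist(meta$accessions), load_scale),
                  normalization = meta$normalization,
                  unknown_residue = meta$unknown_residue)
}

#' Hidden-layer size sweep with test-set checkpointing
#'
#' Trains one network per hidden size.  After every epoch the selection
#' criterion is evaluated on the test split and the best-so-far weights
#' are retained (checkpoint selection, the overfitting control).  The
#' best checkpoint across hidden sizes is returned; ties go to the
#' smaller hidden layer.
#'
#' @param train,test [labeled_dataset()]s (one train/test split).
#' @param encoder A [feature_encoder()]; its settings are stored in the
#'   returned model's metadata.
#' @param h_values Hidden-layer sizes to try (default `seq(2, 20, 2)`).
#' @param config A [train_config()].
#' @param criterion `"auc"`, `"recall"` or `"precision"`.
#' @return List with `model` (best checkpoint, metadata records
#'   criterion/hidden/epoch), `value` (its criterion value), `report`
#'   (one row per hidden size: `hidden`, `value`, `best_epoch`) and
#'   `history` (per-hidden-size numeric vector of the per-epoch
#'   criterion values, for audit).
#' @export
sweep_hidden <- function(train, test, encoder = feature_encoder(),
                         h_values = seq(2L, 20L, 2L),
                         config = train_config(),
                         criterion = c("auc", "recall", "precision")) {
  criterion <- match.arg(criterion)
  stopifnot(length(h_values) >= 1L)
  tr <- dataset_segments(train)
  te <- dataset_segments(test)
  x_tr <- encode_segments(tr$segments, encoder)
  x_te <- encode_segments(te$segments, encoder)
  y_tr <- class_targets(tr$labels)

  runs <- lapply(h_values, function(h) {
    ck <- new.env(parent = emptyenv())
    ck$best <- -Inf; ck$model <- NULL; ck$epoch <- NA_integer_
    ck$trace <- numeric(config$epochs)
    net <- mlp_init(c(ncol(x_tr), h, 2L), seed = config$seed,
                    init_range = config$init_range,
                    metadata = list(ptm_type = train$ptm_type,
                                    criterion = criterion,
                                    hidden = h,
                                    seed = config$seed,
                                    encoder = encoder_metadata(encoder)))
    fit <- tryCatch(
      mlp_train(net, x_tr, y_tr, config, on_epoch = function(ep, m, sse) {
        v <- criterion_value(mlp_scores(m, x_te), te$labels, criterion)
        ck$trace[ep] <- if (is.na(v)) NA_real_ else v
        if (!is.na(v) && v > ck$best) {
          ck$best <- v; ck$model <- m; ck$epoch <- ep
        }
      }),
      error = function(e) stop("training failed at hidden size ", h, ": ",
                               conditionMessage(e)))
    if (is.null(ck$model)) {   # criterion undefined at every epoch
      ck$model <- fit$model; ck$best <- NA_real_
    }
    ck$model$metadata$checkpoint_epoch <- ck$epoch
    list(hidden = h, value = ck$best, epoch = ck$epoch,
         model = ck$model, trace = ck$trace)
  })

  report <- data.frame(hidden = vapply(runs, `[[`, numeric(1), "hidden"),
                       value = vapply(runs, `[[`, numeric(1), "value"),
                       best_epoch = vapply(runs, `[[`, numeric(1), "epoch"))
  vals <- report$value
  if (all(is.na(vals))) {
    best_i <- 1L
    warning("criterion '", criterion, "' undefined for every checkpoint")
  } else {
    best_i <- order(-vals, report$hidden, na.last = TRUE)[1L]
  }
  history <- setNames(lapply(runs, `[[`, "trace"),
                      paste0("h", report$hidden))
  list(model = runs[[best_i]]$model, value = report$value[best_i],
       report = report, history = history, criterion = criterion)
}

#' Train the per-PTM-type model triplet
#'
#' For every random split, three hidden-size sweeps are run, one per
#' selection criterion (AUC, recall, precision), and each selected model
#' is evaluated on that split's test set.  Test metrics are averaged
#' across splits.
#'
#' @param dataset A [labeled_dataset()].
#' @param spec A [split_spec()].
#' @param config A [train_config()].
#' @param encoder A [feature_encoder()].
#' @param h_values Hidden sizes for [sweep_hidden()].
#' @return An `mlp_triplet` object: `splits` (per split: `models`, a
#'   list of the three checkpointed networks keyed by criterion; `eval`,
#'   their `eval_result`s; `sweeps`, the sweep reports) and `summary`, a
#'   data frame of test metrics averaged across splits per criterion.
#' @export
train_triplet <- function(dataset, spec = split_spec(),
                          config = train_config(),
                          encoder = feature_encoder(),
                          h_values = seq(2L, 20L, 2L)) {
  splits <- split_dataset(dataset, spec)
  criteria <- c("auc", "recall", "precision")
  fits <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    te <- dataset_segments(sp$test)
    x_te <- encode_segments(te$segments, encoder)
    models <- list(); evals <- list(); sweeps <- list()
    for (cr in criteria) {
      sw <- sweep_hidden(sp$train, sp$test, encoder, h_values, config, cr)
      sw$model$metadata$split <- i
      models[[cr]] <- sw$model
      pred <- mlp_scores(sw$model, x_te)
      evals[[cr]] <- evaluate_predictions(pred$score, te$labels,
                                          pred$decision)
      sweeps[[cr]] <- sw$report
    }
    list(models = models, eval = evals, sweeps = sweeps)
  })
  rows <- do.call(rbind, lapply(criteria, function(cr) {
    per_split <- do.call(rbind, lapply(fits, function(f)
      eval_row(f$eval[[cr]])))
    cbind(criterion = cr,
          as.data.frame(t(colMeans(per_split))))
  }))
  structure(list(ptm_type = dataset$ptm_type, splits = fits,
                 summary = rows, spec = spec),
            class = "mlp_triplet")
}

#' @export
print.mlp_triplet <- function(x, ...) {
  cat("<mlp_triplet>", x$ptm_type, "-", length(x$splits),
      "split(s), criteria auc/recall/precision\n")
  print(x$summary[, c("criterion", "error", "recall", "precision", "auc")],
        row.names = FALSE)
  invisible(x)
}

#' Consensus prediction from a criterion triplet
#'
#' @param models List of the three networks (AUC-, recall- and
#'   precision-optimized), e.g. `triplet$splits[[1]]$models`.
#' @param x Input feature vector.
#' @param scheme `"report_all"` (default) returns each model's decision
#'   and confidence; `"majority"` votes 1 iff at least two models do;
#'   `"mean_confidence"` averages the positive-class confidences and
#'   decides at 0.5 (ties negative).
#' @return Depends on `scheme`: a data frame (`report_all`) or a list
#'   with `decision` (and `confidence` for `mean_confidence`).
#' @export
consensus_predict <- function(models, x,
                              scheme = c("report_all", "majority",
                                         "mean_confidence")) {
  scheme <- match.arg(scheme)
  stopifnot(length(models) == 3L)
  preds <- lapply(models, mlp_predict, x = x)
  crits <- if (!is.null(names(models))) names(models)
           else paste0("model", 1:3)
  if (scheme == "report_all")
    return(data.frame(criterion = crits,
                      decision = vapply(preds, `[[`, integer(1), "decision"),
                      confidence = vapply(preds, `[[`, numeric(1),
                                          "confidence")))
  if (scheme == "majority") {
    votes <- vapply(preds, `[[`, integer(1), "decision")
    return(list(decision = as.integer(sum(votes) >= 2L), votes = votes))
  }
  mean_pos <- mean(vapply(preds, `[[`, numeric(1), "score"))
  list(decision = as.integer(mean_pos > 0.5), confidence = mean_pos)
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a network trained on the remaining n - 1
#' for a fixed epoch budget (no checkpointing: there is no held-out
#' split inside a fold).  Folds whose training part lacks one class are
#' skipped and counted in the `skipped_folds` attribute.
#'
#' @param dataset A [labeled_dataset()] with at least 2 samples.
#' @param config A [train_config()].
#' @param encoder A [feature_encoder()].
#' @param hidden Hidden-layer size of the per-fold networks.
#' @return An `eval_result` aggregating the out-of-fold confusion
#'   counts and scores.
#' @export
loocv <- function(dataset, config = train_config(),
                  encoder = feature_encoder(), hidden = 4L) {
  ds <- dataset_segments(dataset)
  n <- length(ds$labels)
  if (n < 2L) stop("LOOCV needs at least 2 samples")
  x <- encode_segments(ds$segments, encoder)
  y <- class_targets(ds$labels)
  decisions <- integer(0); scores <- numeric(0); labels <- integer(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    if (length(unique(ds$labels[keep])) < 2L) { skipped <- skipped + 1L; next }
    net <- mlp_init(c(ncol(x), hidden, 2L), seed = config$seed,
                    init_range = config$init_range)
    fit <- mlp_train(net, x[keep, , drop = FALSE],
                     y[keep, , drop = FALSE], config)
    p <- mlp_predict(fit$model, x[i, ])
    decisions <- c(decisions, p$decision)
    scores <- c(scores, p$score)
    labels <- c(labels, ds$labels[i])
  }
  if (length(labels) == 0L) stop("every LOOCV fold was degenerate")
  if (length(unique(labels)) == 2L) {
    res <- evaluate_predictions(scores, labels, decisions)
  } else {
    # ROC/AUC undefined when only one class was evaluable
    counts <- confusion_counts(decisions, labels)
    res <- structure(c(list(counts = counts),
                       classification_rates(counts),
                       list(roc = NULL, auc = NA_real_,
                            n = length(labels))),
                     class = "eval_result")
  }
  attr(res, "skipped_folds") <- skipped
  res
}
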