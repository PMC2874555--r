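make_motif_data <- function(n_pos = 30, neg_per_pos = 5, strength = 0.9,
                            seed = 17) {
  generate_dataset(motif_spec(consensus = "KRRASFAAA",
                              consensus_strength = strength),
                   n_pos, neg_per_pos, seed = seed)
}

test_that("splits respect the 4:1 and 1:5 ratios and are disjoint", {
  ds <- make_motif_data(100, 6)
  spl <- split_dataset(ds, split_spec(seed = 5))
  expect_length(spl, 3L)
  for (sp in spl) {
    expect_identical(nrow(sp$train$positives), 80L)
    expect_identical(nrow(sp$test$positives), 20L)
    expect_identical(nrow(sp$train$negatives), 400L)
    expect_identical(nrow(sp$test$negatives), 100L)
    # instance-level partition: train and test positives together are
    # exactly the sampled positives (duplicate 9-mer strings can occur
    # in a generated dataset, so compare as multisets)
    expect_identical(sort(c(sp$train$positives$segment,
                            sp$test$positives$segment)),
                     sort(ds$positives$segment))
  }
  spl2 <- split_dataset(ds, split_spec(seed = 5))
  expect_identical(spl, spl2)
  spl3 <- split_dataset(ds, split_spec(seed = 6))
  expect_false(identical(spl, spl3))
})

test_that("insufficient negatives fail with the shortfall named", {
  ds <- make_motif_data(10, 2)
  expect_error(split_dataset(ds, split_spec()), "need 50")
})

test_that("hidden sweep reports every size and returns the argmax checkpoint", {
  ds <- make_motif_data(30)
  sp <- split_dataset(ds, split_spec(n_splits = 1, seed = 2))[[1]]
  enc <- feature_encoder()
  cfg <- train_config(epochs = 60, seed = 3)
  for (crit in c("auc", "recall", "precision")) {
    sw <- sweep_hidden(sp$train, sp$test, enc, h_values = c(2, 4),
                       config = cfg, criterion = crit)
    expect_identical(nrow(sw$report), 2L)
    # per-H: reported value is the max of the recorded per-epoch trace
    # (NA when the criterion was undefined at every epoch)
    for (i in seq_len(nrow(sw$report))) {
      trace <- sw$history[[paste0("h", sw$report$hidden[i])]]
      if (all(is.na(trace))) expect_true(is.na(sw$report$value[i]))
      else expect_equal(sw$report$value[i], max(trace, na.rm = TRUE))
    }
    # across H: returned model attains the report maximum
    expect_equal(sw$value, max(sw$report$value, na.rm = TRUE))
    # and re-evaluating the checkpoint on the test split reproduces it
    te <- ptmscan:::dataset_segments(sp$test)
    pred <- ptmscan:::mlp_scores(sw$model, encode_segments(te$segments, enc))
    expect_equal(ptmscan:::criterion_value(pred, te$labels, crit),
                 sw$value, tolerance = 1e-12)
    expect_identical(sw$model$metadata$criterion, crit)
  }
})

test_that("sweep defaults cover hidden sizes 2..20 in steps of 2", {
  expect_identical(eval(formals(sweep_hidden)$h_values),
                   seq(2L, 20L, 2L))
})

test_that("single-size sweep and tie-breaking to smaller H", {
  ds <- make_motif_data(20)
  sp <- split_dataset(ds, split_spec(n_splits = 1, seed = 9))[[1]]
  cfg <- train_config(epochs = 10, seed = 9)
  sw <- sweep_hidden(sp$train, sp$test, feature_encoder(),
                     h_values = 4, config = cfg)
  expect_identical(nrow(sw$report), 1L)
  expect_identical(sw$model$metadata$hidden, 4)
})

test_that("triplet: recall-optimized recall dominates, summary averages", {
  ds <- make_motif_data(30)
  tri <- train_triplet(ds, split_spec(n_splits = 1, seed = 4),
                       train_config(epochs = 60, seed = 4),
                       h_values = c(2, 4))
  s1 <- tri$splits[[1]]
  # all checkpoints come from the same training trajectories, so the
  # recall-selected model's test recall bounds the others
  expect_gte(s1$eval$recall$recall, s1$eval$auc$recall)
  expect_gte(s1$eval$recall$recall, s1$eval$precision$recall)
  if (!is.na(s1$eval$precision$precision) && !is.na(s1$eval$auc$precision))
    expect_gte(s1$eval$precision$precision, s1$eval$auc$precision)

  # with a single split the summary is that split's metrics
  for (cr in c("auc", "recall", "precision")) {
    row <- tri$summary[tri$summary$criterion == cr, ]
    expect_equal(row$auc, s1$eval[[cr]]$auc)
    expect_equal(row$recall, s1$eval[[cr]]$recall)
  }

  # models persist with criterion metadata intact
  dir <- withr::local_tempdir()
  save_model_set(s1$models, dir, ds$ptm_type)
  avail <- list_models(dir)
  expect_setequal(avail$criterion, c("auc", "recall", "precision"))
  m <- load_mlp(avail$path[avail$criterion == "recall"])
  expect_identical(m$metadata$criterion, "recall")
  expect_identical(m$layer_sizes, s1$models$recall$layer_sizes)
})

test_that("consensus schemes", {
  ds <- separable_dataset(12, 24, seed = 31)
  enc <- feature_encoder()
  seg <- ptmscan:::dataset_segments(ds)
  x <- encode_segments(seg$segments, enc)
  y <- class_targets(seg$labels)
  models <- lapply(c(auc = 1, recall = 2, precision = 3), function(s) {
    mlp_train(mlp_init(c(90, 3, 2), seed = s,
                       metadata = list(encoder =
                                         ptmscan:::encoder_metadata(enc))),
              x, y, train_config(epochs = 40, seed = s))$model
  })
  xq <- x[1, ]
  rep_all <- consensus_predict(models, xq, "report_all")
  expect_identical(nrow(rep_all), 3L)
  maj <- consensus_predict(models, xq, "majority")
  expect_identical(maj$decision,
                   as.integer(sum(rep_all$decision) >= 2))
  mc <- consensus_predict(models, xq, "mean_confidence")
  scores <- vapply(models, function(m) mlp_predict(m, xq)$score,
                   numeric(1))
  expect_equal(mc$confidence, mean(scores))
  expect_identical(mc$decision, as.integer(mean(scores) > 0.5))
  # unanimity: all schemes agree when all models agree
  if (length(unique(rep_all$decision)) == 1L)
    expect_identical(maj$decision, rep_all$decision[1])
})

test_that("LOOCV on a trivially separable toy", {
  ds <- labeled_dataset(c("RRRRSRRRR", "RRRKSRRRR"),
                        c("DDDDSDDDD", "DDDESDDDD"))
  res <- loocv(ds, train_config(epochs = 400, seed = 6), hidden = 2)
  expect_identical(sum(res$counts), 4L)
  expect_equal(res$error, 0)
  expect_identical(attr(res, "skipped_folds"), 0L)
})

test_that("LOOCV skips degenerate folds", {
  ds <- labeled_dataset("RRRRSRRRR", c("DDDDSDDDD", "DDDESDDDD"))
  res <- loocv(ds, train_config(epochs = 50, seed = 6), hidden = 2)
  expect_identical(attr(res, "skipped_folds"), 1L)
  expect_identical(sum(res$counts), 2L)
})
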