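test_that("initialization: shapes, determinism, validation", {
  m <- mlp_init(c(90, 10, 2), seed = 1)
  expect_identical(dim(m$weights[[1]]), c(90L, 10L))
  expect_identical(dim(m$weights[[2]]), c(10L, 2L))
  expect_length(m$biases[[1]], 10L)
  expect_identical(mlp_init(c(90, 10, 2), seed = 1), m)
  expect_false(identical(mlp_init(c(90, 10, 2), seed = 2), m))
  expect_error(mlp_init(c(90)), "at least")
  expect_error(mlp_init(c(90, 0, 2)), ">= 1")
  expect_true(all(abs(unlist(m$weights)) <= 0.5))
})

test_that("forward pass matches hand computation and the sigmoid(0) case", {
  zero <- mlp_init(c(4, 3, 2), seed = 1)
  zero$weights <- lapply(zero$weights, function(w) array(0, dim(w)))
  zero$biases <- lapply(zero$biases, function(b) numeric(length(b)))
  expect_equal(mlp_forward(zero, runif(4)), c(0.5, 0.5))

  # single-hidden-unit toy, evaluated independently with plogis
  m <- mlp_init(c(2, 1, 2), seed = 1)
  m$weights <- list(matrix(c(0.5, -0.25), nrow = 2),
                    matrix(c(0.3, -0.2), nrow = 1))
  m$biases <- list(0.1, c(0.05, -0.1))
  x <- c(0.7, -1.2)
  h <- plogis(0.5 * 0.7 - 0.25 * (-1.2) + 0.1)
  expect_equal(mlp_forward(m, x),
               plogis(c(0.3 * h + 0.05, -0.2 * h - 0.1)),
               tolerance = 1e-12)

  # increasing a positive output weight increases that response
  m2 <- m
  m2$weights[[2]][1, 1] <- m2$weights[[2]][1, 1] + 0.1
  expect_gt(mlp_forward(m2, x)[1], mlp_forward(m, x)[1])

  expect_error(mlp_forward(m, c(1, 2, 3)), "expects")
})

test_that("forward agrees with the naive reference on random nets", {
  set.seed(9)
  for (i in 1:20) {
    sizes <- c(sample(2:10, 1), sample(2:8, 1), 2)
    m <- mlp_init(sizes)
    x <- runif(sizes[1], -1, 1)
    expect_equal(mlp_forward(m, x), ref_forward(m$weights, m$biases, x),
                 tolerance = 1e-12)
  }
})

test_that("confidence normalizes responses", {
  expect_equal(mlp_confidence(c(0.8, 0.2)), c(0.8, 0.2))
  expect_equal(mlp_confidence(c(0.6, 0.6)), c(0.5, 0.5))
  expect_equal(mlp_confidence(c(0.3, 0.1)), c(0.75, 0.25))
  expect_error(mlp_confidence(c(0.5, NaN)), "finite")
  set.seed(4)
  for (i in 1:50) {
    r <- runif(2, 1e-6, 1)
    expect_equal(sum(mlp_confidence(r)), 1, tolerance = 1e-15)
  }
})

test_that("decision takes the larger response, ties go negative", {
  m <- mlp_init(c(2, 2, 2), seed = 1)
  fake <- function(responses) {
    # craft biases on a zero-weight net so outputs hit the responses
    m$weights <- lapply(m$weights, function(w) array(0, dim(w)))
    m$biases <- list(c(0, 0), qlogis(responses))
    m
  }
  p <- mlp_predict(fake(c(0.9, 0.1)), c(0, 0))
  expect_identical(p$decision, 1L)
  expect_equal(p$confidence, 0.9)
  tie <- mlp_predict(fake(c(0.5, 0.5)), c(0, 0))
  expect_identical(tie$decision, 0L)
  expect_equal(tie$confidence, 0.5)
})

test_that("zero learning rate leaves weights unchanged", {
  m <- mlp_init(c(3, 2, 2), seed = 2)
  x <- matrix(runif(12), 4)
  y <- class_targets(c(1L, 0L, 1L, 0L))
  expect_error(train_config(learning_rate = 0), "learning_rate")
  # eta -> 0 limit: use a tiny but legal eta and momentum 0
  fit <- mlp_train(m, x, y, train_config(learning_rate = 1e-300,
                                         momentum = 0, epochs = 3))
  expect_equal(fit$model$weights, m$weights, tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(11)
  for (i in 1:10) {
    sizes <- c(sample(2:10, 1), sample(2:8, 1), 2)
    m <- mlp_init(sizes)
    x <- runif(sizes[1], -1, 1)
    target <- as.numeric(sample(c(TRUE, FALSE), 1))
    target <- c(target, 1 - target)
    g <- mlp_gradient(m, x, target)
    fd <- ref_fd_gradient(m$weights, m$biases, x, target)
    dev <- max(abs(unlist(g$weights) - unlist(fd$weights)),
               abs(unlist(g$biases) - unlist(fd$biases)))
    expect_lt(dev, 1e-6)
  }
})

test_that("momentum 0 reduces exactly to plain per-sample SGD", {
  set.seed(21)
  m <- mlp_init(c(5, 4, 2), seed = 3)
  x <- matrix(runif(40, -1, 1), 8)
  y <- class_targets(rep(c(1L, 0L), 4))
  fit <- mlp_train(m, x, y, train_config(learning_rate = 0.8, momentum = 0,
                                         epochs = 4, shuffle = FALSE))
  W <- m$weights; b <- m$biases
  for (ep in 1:4) {
    r <- ref_sgd_epoch(W, b, x, y, 0.8)
    W <- r$W; b <- r$b
  }
  expect_equal(fit$model$weights, W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$model$biases, b, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a single sample is memorized to tiny error", {
  m <- mlp_init(c(4, 3, 2), seed = 5)
  x <- matrix(runif(4), 1)
  y <- matrix(c(1, 0), 1)
  fit <- mlp_train(m, x, y, train_config(epochs = 5000, seed = 5))
  expect_lt(tail(fit$sse, 1), 1e-3)
})

test_that("training learns a separable motif to < 5% error", {
  ds <- separable_dataset(30, 60, seed = 8)
  enc <- feature_encoder()
  seg <- c(ds$positives$segment, ds$negatives$segment)
  lab <- rep(c(1L, 0L), c(30, 60))
  x <- encode_segments(seg, enc)
  m <- mlp_init(c(90, 4, 2), seed = 8)
  fit <- mlp_train(m, x, class_targets(lab),
                   train_config(epochs = 80, seed = 8))
  pred <- predict_windows(seg, fit$model, enc)
  expect_lt(mean(pred$decision != lab), 0.05)
})

test_that("model JSON round trip is exact and tampering is caught", {
  enc <- feature_encoder()
  m <- mlp_init(c(90, 6, 2), seed = 13,
                metadata = list(ptm_type = "demo", criterion = "auc",
                                seed = 13,
                                encoder = ptmscan:::encoder_metadata(enc)))
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(m, path)
  m2 <- load_mlp(path)
  x <- encode_segment("LCLYTHIGR", enc)
  expect_identical(mlp_forward(m2, x), mlp_forward(m, x))
  expect_identical(m2$metadata$ptm_type, "demo")
  expect_identical(m2$metadata$criterion, "auc")
  expect_identical(unlist(m2$metadata$encoder$accessions),
                   enc$accessions)

  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$layer_sizes[[2]] <- 7
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_mlp(bad), "corrupt")
})
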