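#' Multilayer perceptron with back-propagation and momentum
#'
#' The classifier is a feed-forward network of sigmoid units.  Input
#' neurons are dummy (pass-through); every subsequent layer computes
#' `sigmoid(W'a + b)`.  The canonical site predictor has 90 input
#' neurons (one per feature dimension), one hidden layer and two output
#' neurons, one per class (positive = modified, negative = background).
#' Training minimizes the sum of squared output errors by per-sample
#' gradient descent with a momentum ("acceleration") term.
#'
#' @name mlp
NULL

#' Training hyper-parameters
#'
#' @param learning_rate Gradient step size (eta), default 0.8.
#' @param momentum Fraction of the previous weight update added to the
#'   current one (delta), default 0.8; must lie in \[0, 1).
#' @param epochs Number of passes over the training set (default 500).
#' @param seed Integer seed controlling weight initialization and the
#'   per-epoch sample shuffle.
#' @param init_range Weights start uniform in
#'   \[-`init_range`, `init_range`\].
#' @param shuffle Whether to reshuffle the sample order every epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.8, momentum = 0.8,
                         epochs = 500L, seed = 1L, init_range = 0.5,
                         shuffle = TRUE) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1,
            init_range > 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 init_range = init_range, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Initialize a network
#'
#' @param layer_sizes Integer vector of layer widths, input first (e.g.
#'   `c(90, 10, 2)`); at least two layers.
#' @param seed Integer seed for the uniform weight draw (`NULL` uses the
#'   current RNG state).
#' @param init_range Half-width of the uniform initialization interval.
#' @param metadata Named list stored with the model (encoder settings,
#'   PTM type, optimization criterion, training seed).
#' @return An `mlp` object with weight matrices of dimension
#'   `layer_sizes[l] x layer_sizes[l+1]`.
#' @export
mlp_init <- function(layer_sizes, seed = NULL, init_range = 0.5,
                     metadata = list()) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L)
    stop("a network needs at least an input and an output layer")
  if (any(layer_sizes < 1L)) stop("all layer sizes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- length(layer_sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(runif(layer_sizes[l] * layer_sizes[l + 1L],
                                 -init_range, init_range),
                           nrow = layer_sizes[l])
    biases[[l]] <- runif(layer_sizes[l + 1L], -init_range, init_range)
  }
  structure(list(layer_sizes = layer_sizes, weights = weights,
                 biases = biases, activation = "sigmoid",
                 metadata = metadata),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("<mlp>", paste(x$layer_sizes, collapse = "-"),
      "sigmoid network\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Forward pass: output-neuron responses
#'
#' @param model An [mlp_init()] model.
#' @param x Numeric input vector, or a matrix with one sample per row.
#' @return For a vector input, the vector of output responses (each in
#'   (0, 1)); for a matrix, a matrix of responses with one row per
#'   sample.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp"))
  if (is.matrix(x)) {
    if (ncol(x) != model$layer_sizes[1])
      stop("input has ", ncol(x), " columns, network expects ",
           model$layer_sizes[1])
    return(cpp_mlp_forward(model$weights, model$biases, x))
  }
  if (length(x) != model$layer_sizes[1])
    stop("input has length ", length(x), ", network expects ",
         model$layer_sizes[1])
  drop(cpp_mlp_forward(model$weights, model$biases, matrix(x, nrow = 1)))
}

#' Normalized-response confidence
#'
#' Each output response is divided by the sum of responses, so the two
#' class confidences are non-negative and sum to one.
#'
#' @param responses Numeric vector of output responses (both > 0).
#' @return Vector of confidences of the same length.
#' @export
mlp_confidence <- function(responses) {
  if (any(!is.finite(responses)) || any(responses <= 0))
    stop("responses must be finite and positive")
  responses / sum(responses)
}

#' Binary decision and confidence for one input
#'
#' Output neuron 1 carries the positive (modified) class, neuron 2 the
#' negative class.  The decision is the class with the larger response,
#' ties resolved to negative; the reported confidence is the normalized
#' response of the winning class.
#'
#' @param model An `mlp` with two output neurons.
#' @param x Input feature vector.
#' @return List with `decision` (0/1), `confidence` and `score` (the
#'   positive-class confidence, used for ranking/ROC).
#' @export
mlp_predict <- function(model, x) {
  r <- mlp_forward(model, x)
  if (length(r) != 2L) stop("prediction requires a 2-output network")
  conf <- mlp_confidence(r)
  decision <- if (r[1] > r[2]) 1L else 0L
  list(decision = decision,
       confidence = unname(if (decision == 1L) conf[1] else conf[2]),
       score = unname(conf[1]))
}

# Batched decisions/confidences; X is n x d.
mlp_scores <- function(model, x) {
  r <- mlp_forward(model, if (is.matrix(x)) x else matrix(x, nrow = 1))
  conf <- r / rowSums(r)
  decision <- as.integer(r[, 1] > r[, 2])
  data.frame(decision = decision,
             confidence = ifelse(decision == 1L, conf[, 1], conf[, 2]),
             score = conf[, 1])
}

#' One-hot targets from 0/1 class labels
#'
#' @param labels Integer vector of 0/1 labels.
#' @return Matrix with columns (positive, negative): label 1 maps to
#'   (1, 0), label 0 to (0, 1).
#' @export
class_targets <- function(labels) {
  stopifnot(all(labels %in% c(0L, 1L)))
  cbind(pos = as.numeric(labels == 1L), neg = as.numeric(labels == 0L))
}

#' Train a network by back-propagation with momentum
#'
#' Per-sample (stochastic) updates
#' `dw(t) = -eta * dSSE/dw + delta * dw(t-1)`, with the visiting order
#' reshuffled each epoch under the configuration seed.
#'
#' @param model An [mlp_init()] model.
#' @param x Training inputs, one sample per row.
#' @param targets Target matrix, one row per sample (see
#'   [class_targets()]).
#' @param config A [train_config()].
#' @param on_epoch Optional callback `function(epoch, model, sse)`
#'   invoked after every epoch, e.g. for checkpoint selection.
#' @return List with the trained `model` and `sse`, the per-epoch sum of
#'   squared errors.
#' @export
mlp_train <- function(model, x, targets, config = train_config(),
                      on_epoch = NULL) {
  stopifnot(inherits(model, "mlp"), is.matrix(x))
  targets <- as.matrix(targets)
  n <- nrow(x)
  if (n == 0L) stop("no training samples")
  if (nrow(targets) != n) stop("x and targets disagree on sample count")
  if (ncol(x) != model$layer_sizes[1])
    stop("input has ", ncol(x), " columns, network expects ",
         model$layer_sizes[1])
  if (ncol(targets) != model$layer_sizes[length(model$layer_sizes)])
    stop("target width does not match the output layer")
  vW <- lapply(model$weights, function(w) array(0, dim(w)))
  vb <- lapply(model$biases, function(b) numeric(length(b)))
  sse <- numeric(config$epochs)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    res <- cpp_mlp_epoch(model$weights, model$biases, vW, vb, x, targets,
                         config$learning_rate, config$momentum, ord)
    model$weights <- res$weights
    model$biases <- res$biases
    vW <- res$vel_weights
    vb <- res$vel_biases
    sse[epoch] <- res$sse
    if (!is.finite(res$sse) ||
        !all(vapply(model$weights, function(w) all(is.finite(w)), logical(1))))
      stop("training diverged at epoch ", epoch,
           " (non-finite weights or error); reduce the learning rate")
    if (!is.null(on_epoch)) on_epoch(epoch, model, res$sse)
  }
  list(model = model, sse = sse)
}

#' Analytic gradient of the squared error for one sample
#'
#' Returns `d(1/2 * sum((R - t)^2)) / d(parameters)` via
#' back-propagation; used for gradient verification and available for
#' custom optimizers.
#'
#' @param model An `mlp`.
#' @param x Input vector.
#' @param target Target vector (one-hot for classification).
#' @return List with `weights` and `biases` gradients, shaped like the
#'   model parameters.
#' @export
mlp_gradient <- function(model, x, target) {
  stopifnot(inherits(model, "mlp"),
            length(x) == model$layer_sizes[1],
            length(target) == model$layer_sizes[length(model$layer_sizes)])
  cpp_mlp_gradient(model$weights, model$biases, as.numeric(x),
                   as.numeric(target))
}

MODEL_SCHEMA_VERSION <- 1L

#' Save / load a trained network as JSON
#'
#' The JSON schema stores layer sizes, weight matrices (row-major),
#' biases and the metadata block (encoder settings, PTM type,
#' optimization criterion, seeds) at full floating-point precision, so a
#' reloaded model reproduces forward outputs exactly.
#'
#' @param model An `mlp`.
#' @param path Output / input path.
#' @return `load_mlp` returns the restored `mlp`.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "mlp"))
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              layer_sizes = model$layer_sizes,
              weights = lapply(model$weights, function(w)
                list(nrow = nrow(w), ncol = ncol(w),
                     data = as.vector(t(w)))),
              biases = model$biases,
              activation = model$activation,
              metadata = model$metadata)
  # 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  # parse without vector simplification so layer shapes never collapse
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    stop("unsupported model schema in '", path, "'")
  sizes <- as.integer(unlist(obj$layer_sizes))
  L <- length(sizes) - 1L
  if (length(obj$weights) != L || length(obj$biases) != L)
    stop("model file '", path, "' is corrupt: layer count mismatch")
  rebuild <- function(l) {
    w <- obj$weights[[l]]
    nr <- as.integer(w$nrow); nc <- as.integer(w$ncol)
    dat <- as.numeric(unlist(w$data))
    if (length(dat) != nr * nc || nr != sizes[l] || nc != sizes[l + 1L])
      stop("model file '", path, "' is corrupt: weight matrix ", l,
           " does not match the declared layer sizes")
    matrix(dat, nrow = nr, byrow = TRUE)
  }
  weights <- lapply(seq_len(L), rebuild)
  biases <- lapply(obj$biases, function(b) as.numeric(unlist(b)))
  if (any(vapply(biases, length, integer(1)) != sizes[-1]))
    stop("model file '", path, "' is corrupt: bias lengths do not match")
  meta <- if (is.null(obj$metadata)) list() else obj$metadata
  # scalar metadata fields arrive as length-1 lists; flatten one level
  meta <- lapply(meta, function(f)
    if (is.list(f) && length(f) == 1L && !is.list(f[[1]])) f[[1]] else f)
  structure(list(layer_sizes = sizes, weights = weights, biases = biases,
                 activation = as.character(obj$activation),
                 metadata = meta),
            class = "mlp")
}
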