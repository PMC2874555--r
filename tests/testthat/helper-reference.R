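# Independent reference implementations used as oracles.  These are
# deliberately naive and share no code with the package internals.

# Plain sigmoid forward pass for one input vector.
ref_forward <- function(W, b, x) {
  a <- x
  for (l in seq_along(W)) a <- plogis(drop(t(W[[l]]) %*% a) + b[[l]])
  a
}

ref_sse <- function(W, b, x, target) {
  y <- ref_forward(W, b, x)
  0.5 * sum((y - target)^2)
}

# Central finite-difference gradient of ref_sse w.r.t. all parameters.
ref_fd_gradient <- function(W, b, x, target, h = 1e-5) {
  gW <- lapply(W, function(w) array(0, dim(w)))
  gb <- lapply(b, function(v) numeric(length(v)))
  for (l in seq_along(W)) {
    for (i in seq_along(W[[l]])) {
      Wp <- W; Wm <- W
      Wp[[l]][i] <- Wp[[l]][i] + h
      Wm[[l]][i] <- Wm[[l]][i] - h
      gW[[l]][i] <- (ref_sse(Wp, b, x, target) -
                       ref_sse(Wm, b, x, target)) / (2 * h)
    }
    for (i in seq_along(b[[l]])) {
      bp <- b; bm <- b
      bp[[l]][i] <- bp[[l]][i] + h
      bm[[l]][i] <- bm[[l]][i] - h
      gb[[l]][i] <- (ref_sse(W, bp, x, target) -
                       ref_sse(W, bm, x, target)) / (2 * h)
    }
  }
  list(weights = gW, biases = gb)
}

# One epoch of plain per-sample gradient descent (no momentum), samples
# visited in row order.
ref_sgd_epoch <- function(W, b, X, Y, eta) {
  L <- length(W)
  for (i in seq_len(nrow(X))) {
    a <- vector("list", L + 1L)
    a[[1]] <- X[i, ]
    for (l in seq_len(L))
      a[[l + 1]] <- plogis(drop(t(W[[l]]) %*% a[[l]]) + b[[l]])
    delta <- vector("list", L)
    out <- a[[L + 1]]
    delta[[L]] <- (out - Y[i, ]) * out * (1 - out)
    if (L > 1)
      for (l in (L - 1):1)
        delta[[l]] <- drop(W[[l + 1]] %*% delta[[l + 1]]) *
          a[[l + 1]] * (1 - a[[l + 1]])
    for (l in seq_len(L)) {
      W[[l]] <- W[[l]] - eta * outer(a[[l]], delta[[l]])
      b[[l]] <- b[[l]] - eta * delta[[l]]
    }
  }
  list(W = W, b = b)
}

# Brute-force ROC: every distinct score as threshold (score >= t calls
# positive), plus the two sentinel corners.
ref_roc <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(fpr = 0, tpr = 0)
  for (t in ts) {
    pred <- as.integer(scores >= t)
    pts <- rbind(pts, data.frame(
      fpr = sum(pred == 1 & labels == 0) / sum(labels == 0),
      tpr = sum(pred == 1 & labels == 1) / sum(labels == 1)))
  }
  pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  unique(pts[order(pts$fpr, pts$tpr), ])
}

# Pairwise Mann-Whitney AUC by explicit enumeration, ties counted 1/2.
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# Rates written straight from their textbook definitions.
ref_rates <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(error = (fp + fn) / n,
       recall = div(tp, tp + fn),
       precision = div(tp, tp + fp),
       fpr = div(fp, fp + tn),
       specificity = div(tn, tn + fp),
       accuracy = (tp + tn) / n,
       mcc = {
         d <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
           sqrt((tn + fn))
         if (d == 0) NA_real_ else (tp * tn - fp * fn) / d
       })
}

# A tiny strongly-separable dataset: positives carry an arginine-rich
# PKA-like context, negatives an acidic context, shared central serine.
separable_dataset <- function(n_pos = 20, n_neg = 40, seed = 1,
                              strength = 0.95) {
  pos <- generate_dataset(
    motif_spec(consensus = "RRRKSFRRK", consensus_strength = strength),
    n_pos, 1, seed = seed)
  neg <- generate_dataset(
    motif_spec(consensus = "DDEDSEDDE", consensus_strength = strength),
    n_neg, 1, seed = seed + 1)
  labeled_dataset(pos$positives, neg$positives, ptm_type = "separable")
}
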