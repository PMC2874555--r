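#' Amino-acid property scales and the 90-dimensional segment encoding
#'
#' Each residue of a 9-mer segment is described by a set of numeric
#' property scales taken from the AAindex database; with the default ten
#' scales a segment becomes a point in a 90-dimensional feature space.
#' The functions here load the bundled scales, build encoders and turn
#' segments into feature vectors.
#'
#' @name scales
NULL

aaindex_dir <- function() {
  dir <- system.file("extdata", "aaindex", package = "ptmscan")
  if (!nzchar(dir)) stop("bundled AAindex data not found")
  dir
}

#' Read the manifest of bundled amino-acid scales
#'
#' The manifest mirrors the candidate table used during feature
#' selection: 15 rows (one accession, BLAS910101, is listed twice there,
#' once accepted and once rejected) of which 10 carry status
#' `"selected"`.
#'
#' @return A data frame with columns `accession`, `description`,
#'   `status`.
#' @export
scale_manifest <- function() {
  path <- file.path(aaindex_dir(), "manifest.tsv")
  if (!file.exists(path)) stop("AAindex manifest missing: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load one bundled amino-acid scale
#'
#' @param accession AAindex accession, e.g. `"BIOV880101"`.
#' @return An `aa_scale` object: a list with `accession`, `description`
#'   and `values`, a named numeric vector over the 20 standard residues.
#' @export
load_scale <- function(accession) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  path <- file.path(aaindex_dir(), paste0(accession, ".tsv"))
  if (!file.exists(path))
    stop("no bundled scale table for accession '", accession, "'")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab)))
    stop("corrupt scale table for accession '", accession, "'")
  values <- setNames(as.numeric(tab$value), tab$residue)
  mf <- scale_manifest()
  desc <- mf$description[match(accession, mf$accession)]
  new_aa_scale(accession, if (is.na(desc)) "" else desc, values)
}

new_aa_scale <- function(accession, description, values) {
  if (!setequal(names(values), AA_RESIDUES) || length(values) != 20L)
    stop("scale '", accession,
         "' must assign exactly one value to each of the 20 residues")
  if (!all(is.finite(values)))
    stop("scale '", accession, "' contains non-finite values")
  structure(list(accession = accession, description = description,
                 values = values[AA_RESIDUES]),
            class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat("<aa_scale>", x$accession, "-", x$description, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Load the bundled AAindex scales
#'
#' The ten scales retained after feature selection (in manifest order,
#' `BIOV880101` first, `OOBM850105` last) form the default encoder;
#' `which = "all"` additionally returns the rejected candidates.
#'
#' @param which `"selected"` (default), `"rejected"` or `"all"`.
#' @return A list of [load_scale()] objects, one per unique accession.
#' @export
load_bundled_scales <- function(which = c("selected", "rejected", "all")) {
  which <- match.arg(which)
  mf <- scale_manifest()
  if (which != "all") mf <- mf[mf$status == which, , drop = FALSE]
  acc <- unique(mf$accession)
  lapply(acc, load_scale)
}

#' Build a feature encoder from amino-acid scales
#'
#' @param scales List of `aa_scale` objects; defaults to the ten
#'   selected scales. Scale order is fixed and persisted with any
#'   trained model.
#' @param normalization How raw per-residue values are rescaled before
#'   entering a network: `"minmax"` (default) maps each scale's 20
#'   values onto \[0, 1\], `"zscore"` standardizes over the 20 residues,
#'   `"raw"` leaves them untouched.
#' @param unknown_residue Policy for residues outside the standard
#'   20-letter alphabet: `"error"` (default) or `"impute_mean"`, which
#'   substitutes each scale's mean normalized value.
#' @return A `feature_encoder` object.
#' @export
feature_encoder <- function(scales = load_bundled_scales(),
                            normalization = c("minmax", "zscore", "raw"),
                            unknown_residue = c("error", "impute_mean")) {
  normalization <- match.arg(normalization)
  unknown_residue <- match.arg(unknown_residue)
  stopifnot(length(scales) >= 1L)
  lookup <- vapply(scales, function(sc) {
    if (!inherits(sc, "aa_scale")) stop("scales must be aa_scale objects")
    v <- sc$values
    switch(normalization,
      minmax = {
        rng <- range(v)
        if (diff(rng) == 0) stop("degenerate scale ", sc$accession)
        (v - rng[1]) / diff(rng)
      },
      zscore = (v - mean(v)) / stats::sd(v),
      raw = v)
  }, numeric(20))
  accessions <- vapply(scales, `[[`, character(1), "accession")
  colnames(lookup) <- accessions
  structure(list(accessions = accessions, lookup = lookup,
                 impute = colMeans(lookup),
                 normalization = normalization,
                 unknown_residue = unknown_residue,
                 n_scales = length(scales)),
            class = "feature_encoder")
}

#' @export
print.feature_encoder <- function(x, ...) {
  cat("<feature_encoder>", x$n_scales, "scales,",
      9L * x$n_scales, "dimensions per 9-mer\n")
  cat("  scales:", paste(x$accessions, collapse = " "), "\n")
  cat("  normalization:", x$normalization,
      " unknown residues:", x$unknown_residue, "\n")
  invisible(x)
}

#' Number of feature dimensions produced per segment
#' @param encoder A [feature_encoder()].
#' @export
encoding_dim <- function(encoder) 9L * encoder$n_scales

#' Encode a 9-residue segment as a feature vector
#'
#' Layout is position-major: positions 1..9 each contribute one block of
#' values, in the encoder's scale order, so the default encoder yields a
#' 90-dimensional vector.
#'
#' @param segment A 9-character string of residues.
#' @param encoder A [feature_encoder()].
#' @return Numeric vector of length `9 * n_scales`.
#' @export
encode_segment <- function(segment, encoder = feature_encoder()) {
  stopifnot(is.character(segment), length(segment) == 1L)
  if (nchar(segment) != 9L)
    stop("segment must be exactly 9 residues, got ", nchar(segment))
  chars <- strsplit(toupper(segment), "")[[1]]
  idx <- match(chars, AA_RESIDUES)
  F <- encoder$n_scales
  out <- numeric(9L * F)
  for (p in seq_len(9L)) {
    block <- if (is.na(idx[p])) {
      if (encoder$unknown_residue == "error")
        stop("unknown residue '", chars[p], "' at position ", p,
             " of segment '", segment, "'")
      encoder$impute
    } else {
      encoder$lookup[idx[p], ]
    }
    out[((p - 1L) * F + 1L):(p * F)] <- block
  }
  names(out) <- paste0("p", rep(seq_len(9L), each = F), ".",
                       rep(encoder$accessions, 9L))
  out
}

#' Encode many segments into a feature matrix
#'
#' @param segments Character vector of 9-mers.
#' @inheritParams encode_segment
#' @return Numeric matrix, one row per segment.
#' @export
encode_segments <- function(segments, encoder = feature_encoder()) {
  stopifnot(length(segments) >= 1L)
  t(vapply(segments, encode_segment, numeric(encoding_dim(encoder)),
           encoder = encoder, USE.NAMES = FALSE))
}

#' Re-run feature subset selection on a labeled dataset
#'
#' Evaluates subsets of candidate scales by encoding the dataset with
#' each subset, training a small network on a stratified 4:1 split and
#' scoring the held-out AUC, then returns the subset maximizing that
#' AUC.  `greedy_forward` grows the subset one scale at a time while the
#' held-out AUC improves; `exhaustive_upto_k` scores every non-empty
#' subset of size at most `max_k`.
#'
#' @param candidates List of `aa_scale` objects (at least 2 unless a
#'   single candidate is supplied, which is returned as-is).
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param config A [train_config()]; its seed fixes the split, the
#'   weight initialization and the sample order.
#' @param strategy `"greedy_forward"` or `"exhaustive_upto_k"`.
#' @param hidden Hidden-layer size of the evaluation network.
#' @param max_k Largest subset size for `"exhaustive_upto_k"`.
#' @return List with `accepted` (accessions in acceptance order) and
#'   `report`, a data frame with one row per evaluated subset and its
#'   held-out AUC.
#' @export
select_feature_subset <- function(candidates, dataset,
                                  config = train_config(epochs = 60),
                                  strategy = c("greedy_forward",
                                               "exhaustive_upto_k"),
                                  hidden = 4L, max_k = 3L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (nrow(dataset$positives) == 0L || nrow(dataset$negatives) == 0L)
    stop("feature selection needs both classes in the dataset")
  acc <- vapply(candidates, `[[`, character(1), "accession")
  names(candidates) <- acc
  if (length(candidates) == 1L)
    return(list(accepted = acc,
                report = data.frame(subset = acc, auc = NA_real_)))

  segs <- c(dataset$positives$segment, dataset$negatives$segment)
  labels <- rep(c(1L, 0L), c(nrow(dataset$positives),
                             nrow(dataset$negatives)))
  set.seed(config$seed)
  test_idx <- c(sample(which(labels == 1L),
                       max(1L, floor(sum(labels == 1L) / 5))),
                sample(which(labels == 0L),
                       max(1L, floor(sum(labels == 0L) / 5))))
  is_test <- seq_along(labels) %in% test_idx

  eval_subset <- function(subset_acc) {
    enc <- feature_encoder(candidates[subset_acc])
    x <- encode_segments(segs, enc)
    net <- mlp_init(c(ncol(x), hidden, 2L), seed = config$seed)
    fit <- mlp_train(net, x[!is_test, , drop = FALSE],
                     class_targets(labels[!is_test]), config)
    scores <- mlp_scores(fit$model, x[is_test, , drop = FALSE])$score
    auc_score(scores, labels[is_test])
  }

  report <- data.frame(subset = character(), auc = numeric())
  note <- function(subset_acc, auc) {
    report[nrow(report) + 1L, ] <<-
      list(paste(subset_acc, collapse = "+"), auc)
  }

  if (strategy == "exhaustive_upto_k") {
    best <- NULL; best_auc <- -Inf
    for (k in seq_len(min(max_k, length(acc)))) {
      combs <- utils::combn(acc, k, simplify = FALSE)
      for (s in combs) {
        a <- eval_subset(s)
        note(s, a)
        if (!is.na(a) && a > best_auc) { best <- s; best_auc <- a }
      }
    }
    return(list(accepted = best, report = report))
  }

  current <- character(0); current_auc <- -Inf
  remaining <- acc
  while (length(remaining) > 0L) {
    trial_auc <- vapply(remaining, function(a) {
      v <- eval_subset(c(current, a)); note(c(current, a), v); v
    }, numeric(1))
    best_i <- which.max(trial_auc)
    if (trial_auc[best_i] > current_auc) {
      current <- c(current, remaining[best_i])
      current_auc <- trial_auc[best_i]
      remaining <- remaining[-best_i]
    } else break
  }
  list(accepted = current, report = report)
}
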