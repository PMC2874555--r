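#' Synthetic motif datasets
#'
#' Generators emulating kinase-like recognition motifs: positives are
#' drawn from a position weight matrix (PWM) mixed with a background
#' distribution at a controllable consensus strength, negatives from the
#' background alone.  Both classes share the same central residue
#' constraint (e.g. the phospho-acceptor S), so a classifier must learn
#' the sequence context rather than the center letter.
#'
#' @name synthetic
NULL

uniform_background <- function() setNames(rep(1 / 20, 20L), AA_RESIDUES)

#' Specify a sequence motif
#'
#' Either give a `consensus` 9-mer (its PWM puts probability 1 on the
#' consensus residue at each position) or a full 20 x 9 `pwm` with
#' residues as rows.  The sampling distribution at each position is
#' `consensus_strength * pwm + (1 - consensus_strength) * background`:
#' strength 1 reproduces the motif exactly, strength 0 is a signal-free
#' null in which positives and negatives are identically distributed.
#'
#' @param consensus Optional 9-residue consensus string (e.g. a PKA-like
#'   `"KRRASFAAA"` context, phospho-acceptor S at position 5); its
#'   center residue must be one of `center_residues`.
#' @param pwm Optional 20 x 9 column-stochastic matrix with `rownames`
#'   equal to the 20 residues.
#' @param center_residues Residues allowed at the central position 5 for
#'   both classes (default `"S"`).
#' @param consensus_strength Mixing weight in \[0, 1\] (default 0.9).
#' @param background Named length-20 residue probability vector
#'   (uniform by default).
#' @return A `motif_spec` object; `$mixed` holds the strength-mixed
#'   per-position probability tables.
#' @export
motif_spec <- function(consensus = NULL, pwm = NULL,
                       center_residues = "S", consensus_strength = 0.9,
                       background = uniform_background()) {
  stopifnot(consensus_strength >= 0, consensus_strength <= 1,
            length(center_residues) >= 1L,
            all(center_residues %in% AA_RESIDUES))
  if (is.null(pwm)) {
    if (is.null(consensus)) stop("give either a consensus or a pwm")
    consensus <- toupper(consensus)
    if (nchar(consensus) != 9L ||
        !all(strsplit(consensus, "")[[1]] %in% AA_RESIDUES))
      stop("consensus must be a 9-mer over the 20 standard residues")
    cc <- strsplit(consensus, "")[[1]]
    if (!(cc[5] %in% center_residues))
      stop("consensus center residue '", cc[5],
           "' is not among center_residues {",
           paste(center_residues, collapse = ","), "}")
    pwm <- matrix(0, 20L, 9L, dimnames = list(AA_RESIDUES, NULL))
    for (p in 1:9) pwm[cc[p], p] <- 1
  }
  stopifnot(is.matrix(pwm), nrow(pwm) == 20L, ncol(pwm) == 9L,
            setequal(rownames(pwm), AA_RESIDUES))
  pwm <- pwm[AA_RESIDUES, , drop = FALSE]
  if (any(pwm < 0) || any(abs(colSums(pwm) - 1) > 1e-8))
    stop("pwm columns must be probability distributions")
  background <- background[AA_RESIDUES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-8)
    stop("background must be a probability distribution over the ",
         "20 residues")
  mixed <- consensus_strength * pwm +
    (1 - consensus_strength) * matrix(background, 20L, 9L)
  structure(list(consensus = consensus, pwm = pwm,
                 center_residues = center_residues,
                 consensus_strength = consensus_strength,
                 background = background, mixed = mixed,
                 name = if (is.null(consensus)) "pwm_motif" else consensus),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("<motif_spec>", x$name, "- center {",
      paste(x$center_residues, collapse = ","), "}, strength",
      x$consensus_strength, "\n")
  invisible(x)
}

# Draw one 9-mer: per-position distribution `probs` (20 x 9), center
# position restricted to `center_residues` (renormalized).
sample_segment <- function(probs, center_residues) {
  seg <- character(9L)
  for (p in 1:9) {
    pr <- probs[, p]
    if (p == 5L) {
      pr <- pr[center_residues]
      if (sum(pr) == 0) pr <- rep(1, length(center_residues))
      seg[p] <- sample(center_residues, 1L, prob = pr / sum(pr))
    } else {
      seg[p] <- sample(AA_RESIDUES, 1L, prob = pr)
    }
  }
  paste(seg, collapse = "")
}

#' Generate a labeled motif dataset
#'
#' Positives are sampled from the strength-mixed PWM, negatives from the
#' background, both with the central residue restricted to
#' `center_residues`.  Negatives exactly duplicating a positive segment
#' are rejected and resampled, mirroring the rule that background
#' windows must not contain known modified sites.
#'
#' @param motif A [motif_spec()].
#' @param n_pos Number of positive segments (>= 1).
#' @param neg_per_pos Negatives per positive (default 5).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   byte-identically.
#' @param ptm_type Label attached to the dataset.
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(motif, n_pos, neg_per_pos = 5L, seed = 1L,
                             ptm_type = "synthetic") {
  stopifnot(inherits(motif, "motif_spec"), n_pos >= 1L)
  set.seed(seed)
  positives <- vapply(seq_len(n_pos), function(i)
    sample_segment(motif$mixed, motif$center_residues), character(1))
  bg <- matrix(motif$background, 20L, 9L,
               dimnames = list(AA_RESIDUES, NULL))
  n_neg <- n_pos * neg_per_pos
  pos_set <- unique(positives)
  negatives <- character(n_neg)
  for (i in seq_len(n_neg)) {
    for (try in seq_len(1000L)) {
      s <- sample_segment(bg, motif$center_residues)
      if (!(s %in% pos_set)) break
      if (try == 1000L)
        stop("cannot generate negatives distinct from the positives; ",
             "the motif constraints leave too few segments")
    }
    negatives[i] <- s
  }
  labeled_dataset(positives, negatives, ptm_type = ptm_type)
}

#' Generate a synthetic proteome with planted motif sites
#'
#' Background sequences of uniform residue composition with motif
#' instances planted at recorded positions; window spans of planted
#' sites do not overlap.
#'
#' @param n_seqs Number of sequences.
#' @param length_range Length bounds `c(min, max)`, both >= 9.
#' @param planted_motifs List of `list(motif = motif_spec, rate = k)`:
#'   `k` instances of each motif are planted per sequence.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector, ids
#'   `seq1..seqN`) and `truth`, a data frame of planted sites
#'   (`parent_id`, `position` 1-based center, `motif`, `segment`).
#' @export
generate_proteome <- function(n_seqs, length_range = c(50L, 150L),
                              planted_motifs = list(), seed = 1L) {
  stopifnot(n_seqs >= 1L, length(length_range) == 2L,
            all(length_range >= 9L),
            length_range[1] <= length_range[2])
  set.seed(seed)
  sequences <- character(n_seqs)
  truth <- data.frame(parent_id = character(0), position = integer(0),
                      motif = character(0), segment = character(0))
  for (i in seq_len(n_seqs)) {
    L <- sample(length_range[1]:length_range[2], 1L)
    chars <- sample(AA_RESIDUES, L, replace = TRUE)
    used <- integer(0)   # occupied center positions
    for (pm in planted_motifs) {
      motif <- pm$motif; rate <- pm$rate
      stopifnot(inherits(motif, "motif_spec"), rate >= 0L)
      for (k in seq_len(rate)) {
        free <- setdiff(5:(L - 4L),
                        unlist(lapply(used, function(u) (u - 8L):(u + 8L))))
        if (length(free) == 0L)
          stop("cannot plant ", rate, " non-overlapping site(s) of '",
               motif$name, "' in a sequence of length ", L,
               "; lower the rate or lengthen the sequences")
        center <- if (length(free) == 1L) free else sample(free, 1L)
        seg <- sample_segment(motif$mixed, motif$center_residues)
        chars[(center - 4L):(center + 4L)] <- strsplit(seg, "")[[1]]
        used <- c(used, center)
        truth[nrow(truth) + 1L, ] <-
          list(paste0("seq", i), center, motif$name, seg)
      }
    }
    sequences[i] <- paste(chars, collapse = "")
  }
  names(sequences) <- paste0("seq", seq_len(n_seqs))
  list(sequences = sequences, truth = truth)
}
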