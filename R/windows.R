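#' Sequence I/O and 9-mer window extraction
#'
#' Prediction operates on overlapping 9-residue windows of a query
#' protein; training operates on 9-mers centered on annotated
#' modification sites.  Coordinates are 1-based and windows are closed
#' intervals, matching the usual site-annotation convention.
#'
#' @name windows
NULL

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (possibly multi-record, line-wrapped) FASTA
#'   file.
#' @return Named character vector of upper-cased sequences in file
#'   order; names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '",
                                           path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("FASTA record with empty sequence in '", path, "'")
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Generate all overlapping k-mer windows of a sequence
#'
#' Stride-1 sliding windows in sequence order; a sequence shorter than
#' `k` yields zero windows.
#'
#' @param sequence Protein sequence string.
#' @param k Odd window length (default 9).
#' @return Data frame with columns `segment` and `center_pos` (1-based
#'   position of the central residue in the parent sequence).
#' @export
generate_windows <- function(sequence, k = 9L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("window length k must be odd and >= 1")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k)
    return(data.frame(segment = character(0), center_pos = integer(0)))
  starts <- seq_len(L - k + 1L)
  data.frame(segment = substring(sequence, starts, starts + k - 1L),
             center_pos = starts + (k - 1L) %/% 2L)
}

#' Extract the k-mer centered on a candidate modification site
#'
#' @param sequence Protein sequence string.
#' @param site_pos 1-based position of the (candidate) modified residue.
#' @param k Odd window length (default 9).
#' @param edge_policy What to do when the site lies within `(k-1)/2`
#'   residues of a terminus: `"skip"` (default) returns `NULL`;
#'   `"pad_X"` pads with `'X'` (requiring an encoder with the
#'   `impute_mean` policy downstream).
#' @return List with `segment` and `center_pos`, or `NULL` when skipped.
#' @export
extract_site_segment <- function(sequence, site_pos, k = 9L,
                                 edge_policy = c("skip", "pad_X")) {
  edge_policy <- match.arg(edge_policy)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("window length k must be odd and >= 1")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  site_pos <- as.integer(site_pos)
  if (site_pos < 1L || site_pos > L)
    stop("site_pos ", site_pos, " outside sequence of length ", L)
  flank <- (k - 1L) %/% 2L
  lo <- site_pos - flank
  hi <- site_pos + flank
  if (lo < 1L || hi > L) {
    if (edge_policy == "skip") return(NULL)
    seg <- paste0(strrep("X", max(0L, 1L - lo)),
                  substr(sequence, max(1L, lo), min(L, hi)),
                  strrep("X", max(0L, hi - L)))
  } else {
    seg <- substr(sequence, lo, hi)
  }
  list(segment = seg, center_pos = site_pos)
}

as_window_frame <- function(x) {
  if (is.character(x))
    return(data.frame(segment = toupper(x),
                      parent_id = rep(NA_character_, length(x)),
                      center_pos = rep(NA_integer_, length(x)),
                      stringsAsFactors = FALSE))
  stopifnot(is.data.frame(x), "segment" %in% names(x))
  n <- nrow(x)
  data.frame(segment = toupper(x$segment),
             parent_id = if ("parent_id" %in% names(x))
               as.character(x$parent_id) else rep(NA_character_, n),
             center_pos = if ("center_pos" %in% names(x))
               as.integer(x$center_pos) else rep(NA_integer_, n),
             stringsAsFactors = FALSE)
}

#' Construct a labeled 9-mer dataset for one PTM type
#'
#' @param positives,negatives Character vectors of 9-mer segments, or
#'   data frames with columns `segment` and optionally `parent_id`,
#'   `center_pos`.
#' @param ptm_type Label for the modification type (e.g.
#'   `"Phosphoserine/PKA"`).
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(positives, negatives,
                            ptm_type = "unspecified") {
  pos <- as_window_frame(positives)
  neg <- as_window_frame(negatives)
  segs <- c(pos$segment, neg$segment)
  if (length(segs) > 0L && any(nchar(segs) != 9L))
    stop("all segments must be exactly 9 residues long")
  both <- intersect(pos$segment, neg$segment)
  if (length(both) > 0L)
    stop("segment(s) present in both classes: ",
         paste(head(both, 3L), collapse = ", "))
  structure(list(ptm_type = ptm_type, positives = pos, negatives = neg),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", x$ptm_type, "-",
      nrow(x$positives), "positives,", nrow(x$negatives), "negatives\n")
  invisible(x)
}

#' Read a labeled-segment TSV file
#'
#' The file format is tab-separated with columns `segment`, `label`
#' (1 = modified site, 0 = background) and optionally `parent_id`,
#' `center_pos`; no header.
#'
#' @param path Path to the TSV file.
#' @param ptm_type PTM-type label to attach.
#' @return A [labeled_dataset()].
#' @export
read_labeled_segments <- function(path, ptm_type = "unspecified") {
  if (!file.exists(path)) stop("segment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("segment file '", path, "' is empty")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(i) {
    f <- rows[[i]]
    if (length(f) < 2L || !(f[2] %in% c("0", "1")) || nchar(f[1]) != 9L)
      stop("malformed segment row at line ", i, " of '", path,
           "': expected 'SEGMENT<TAB>0|1[<TAB>parent_id<TAB>center_pos]'")
    data.frame(segment = toupper(f[1]), label = as.integer(f[2]),
               parent_id = if (length(f) >= 3L) f[3] else NA_character_,
               center_pos = if (length(f) >= 4L) as.integer(f[4])
                            else NA_integer_,
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(seq_along(rows), parse_row))
  labeled_dataset(tab[tab$label == 1L, , drop = FALSE],
                  tab[tab$label == 0L, , drop = FALSE],
                  ptm_type = ptm_type)
}

#' Write a labeled dataset as a segment TSV file
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @export
write_labeled_segments <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  tab <- rbind(cbind(dataset$positives, label = 1L),
               cbind(dataset$negatives, label = 0L))
  keep_prov <- !all(is.na(tab$parent_id)) || !all(is.na(tab$center_pos))
  cols <- if (keep_prov) c("segment", "label", "parent_id", "center_pos")
          else c("segment", "label")
  write.table(tab[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

# Stack a labeled dataset into (segments, labels) in positive-first order.
dataset_segments <- function(dataset) {
  list(segments = c(dataset$positives$segment, dataset$negatives$segment),
       labels = rep(c(1L, 0L), c(nrow(dataset$positives),
                                 nrow(dataset$negatives))))
}
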