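#' The two-phase prediction pipeline
#'
#' Phase one (the sequence generator) dissects FASTA proteins into
#' overlapping 9-mers, one per line.  Phase two (the predictor) encodes
#' each 9-mer, queries a trained network for the requested PTM type and
#' optimization criterion, and emits one line per window in the format
#' `SEGMENT DECISION CONFIDENCE`, e.g. `LCLYTHIGR 0 0.9853`, where 0/1
#' signify predicted negative/positive and the confidence (4 decimals)
#' is the normalized response of the winning output neuron.
#'
#' @name predictor
NULL

#' Sequence generator: FASTA to overlapping 9-mer windows
#'
#' @param fasta_path Input FASTA file.
#' @param out_path Optional output file; one 9-mer per line, all records
#'   in file order.  Records shorter than 9 residues are skipped with a
#'   message on stderr.
#' @return Invisibly, a data frame with `parent_id`, `segment`,
#'   `center_pos` for every window.
#' @export
sequence_generator <- function(fasta_path, out_path = NULL) {
  seqs <- read_fasta(fasta_path)
  per_rec <- lapply(seq_along(seqs), function(i) {
    w <- generate_windows(seqs[[i]])
    if (nrow(w) == 0L) {
      message("skipping record '", names(seqs)[i],
              "': shorter than 9 residues")
      return(NULL)
    }
    cbind(parent_id = names(seqs)[i], w)
  })
  windows <- do.call(rbind, per_rec)
  if (is.null(windows))
    windows <- data.frame(parent_id = character(0), segment = character(0),
                          center_pos = integer(0))
  if (!is.null(out_path)) writeLines(windows$segment, out_path)
  invisible(windows)
}

#' Predict PTM status for a set of 9-mer windows
#'
#' @param windows Character vector of 9-mers.
#' @param model A trained `mlp`; its metadata supplies the encoder
#'   settings unless `encoder` is given.
#' @param encoder Optional [feature_encoder()] override.
#' @return Data frame with `segment`, `decision` (0/1), `confidence`
#'   (winning class) and `score` (positive-class confidence).
#' @export
predict_windows <- function(windows, model, encoder = NULL) {
  stopifnot(inherits(model, "mlp"))
  if (length(windows) == 0L)
    return(data.frame(segment = character(0), decision = integer(0),
                      confidence = numeric(0), score = numeric(0)))
  if (is.null(encoder)) encoder <- encoder_from_model(model)
  x <- encode_segments(windows, encoder)
  cbind(data.frame(segment = windows), mlp_scores(model, x))
}

#' Render predictions in the standard output format
#'
#' @param predictions Data frame from [predict_windows()].
#' @return Character vector of lines `SEGMENT DECISION CONF4DP`.
#' @export
format_predictions <- function(predictions) {
  sprintf("%s %d %.4f", predictions$segment, predictions$decision,
          predictions$confidence)
}

model_filename <- function(ptm_type, criterion) {
  paste0(gsub("[^A-Za-z0-9._-]", "_", ptm_type), ".", criterion, ".json")
}

#' Save a model triplet into a model directory
#'
#' Files are named `<ptm_type>.<criterion>.json` with non-portable
#' characters in the PTM type replaced by `_`.
#'
#' @param models Named list of `mlp` models keyed by criterion
#'   (`auc`, `recall`, `precision`), e.g. `triplet$splits[[1]]$models`.
#' @param model_dir Directory (created if missing).
#' @param ptm_type PTM-type name used in the file names.
#' @return Invisibly, the written paths.
#' @export
save_model_set <- function(models, model_dir, ptm_type) {
  dir.create(model_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(models), function(cr) {
    m <- models[[cr]]
    m$metadata$ptm_type <- ptm_type
    m$metadata$criterion <- cr
    p <- file.path(model_dir, model_filename(ptm_type, cr))
    save_mlp(m, p)
    p
  }, character(1))
  invisible(paths)
}

#' List the (ptm_type, criterion) models available in a directory
#'
#' @param model_dir Directory of model JSON files.
#' @return Data frame with `ptm_type`, `criterion`, `path`.
#' @export
list_models <- function(model_dir) {
  files <- list.files(model_dir, pattern = "\\.json$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    m <- tryCatch(load_mlp(f), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    data.frame(ptm_type = as.character(m$metadata$ptm_type %||% NA),
               criterion = as.character(m$metadata$criterion %||% NA),
               path = f)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ptm_type = character(0), criterion = character(0),
                      path = character(0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_model_for <- function(model_dir, ptm_type, optimization) {
  avail <- list_models(model_dir)
  hit <- which(avail$ptm_type == ptm_type & avail$criterion == optimization)
  if (length(hit) == 0L) {
    listing <- if (nrow(avail) == 0L) "none"
               else paste(sprintf("(%s, %s)", avail$ptm_type,
                                  avail$criterion), collapse = ", ")
    stop("no model for PTM type '", ptm_type, "' with optimization '",
         optimization, "' in '", model_dir, "'; available: ", listing)
  }
  load_mlp(avail$path[hit[1L]])
}

#' Predictor: windows file to decisions and confidences
#'
#' @param windows_path File with one 9-mer per line (the sequence
#'   generator's output).
#' @param model_dir Directory holding trained model JSONs.
#' @param ptm_type PTM type to predict.
#' @param optimization `"auc"`, `"recall"` or `"precision"` — which of
#'   the triplet networks to use.
#' @param out_path Optional output file; one line per window,
#'   `SEGMENT DECISION CONF4DP`.
#' @return Invisibly, the prediction data frame.
#' @export
run_predictor <- function(windows_path, model_dir, ptm_type,
                          optimization = c("auc", "recall", "precision"),
                          out_path = NULL) {
  optimization <- match.arg(optimization)
  if (!file.exists(windows_path))
    stop("windows file not found: ", windows_path)
  lines <- readLines(windows_path)
  lines <- toupper(trimws(lines))
  lines <- lines[nzchar(lines)]
  bad <- which(nchar(lines) != 9L)
  if (length(bad) > 0L)
    stop("malformed window at line ", bad[1L], ": '", lines[bad[1L]],
         "' is not a 9-mer")
  model <- load_model_for(model_dir, ptm_type, optimization)
  pred <- predict_windows(lines, model)
  out_lines <- format_predictions(pred)
  if (!is.null(out_path)) writeLines(out_lines, out_path)
  else cat(out_lines, sep = "\n")
  invisible(pred)
}
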