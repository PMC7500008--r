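# Reading, validation and writing of count matrices, sample annotations and
# result tables. The count matrix is the unit of analysis: its column order
# defines the canonical sample order everywhere downstream.

#' Validate a miRNA count matrix
#'
#' Checks the structural invariants every downstream step relies on:
#' an integer-valued, non-negative matrix with unique miRNA row names and
#' unique sample column names, at least one miRNA and at least two samples.
#' Raw read counts are required; normalized (fractional) inputs are rejected
#' because the negative-binomial test models counts.
#'
#' @param counts numeric matrix, rows = miRNAs, columns = samples.
#' @return the validated matrix, invisibly coerced to storage mode double
#'   with integral values.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    lm_abort("malformed_count_error", "counts must be a numeric matrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    lm_abort("empty_input_error", "count matrix is empty")
  if (ncol(counts) < 2L)
    lm_abort("malformed_count_error", "count matrix needs at least 2 samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    lm_abort("malformed_count_error", "counts must have miRNA row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    lm_abort("duplicate_id_error", "duplicate miRNA ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    lm_abort("duplicate_id_error", "duplicate sample ids in count matrix")
  if (anyNA(counts) || any(counts < 0))
    lm_abort("malformed_count_error", "counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    lm_abort("malformed_count_error",
             "counts must be integers (raw reads); normalized values are not accepted")
  storage.mode(counts) <- "double"
  counts
}

.sep_for <- function(path, format) {
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  format
}

#' Read a miRNA count matrix
#'
#' TSV/CSV layout: first column holds miRNA ids, header row holds sample ids.
#' MatrixMarket triplet (`format = "mtx"`) expects sidecar id files holding
#' one id per line (defaults: `<path>.rows`, `<path>.cols`).
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"tsv"`, `"csv"`, `"mtx"`.
#' @param row_ids,col_ids sidecar id files for `format = "mtx"`.
#' @return validated count matrix (see [validate_counts()]).
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        row_ids = paste0(path, ".rows"),
                        col_ids = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (!file.exists(path))
    lm_abort("empty_input_error", sprintf("file not found: %s", path))
  format <- .sep_for(path, format)

  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_ids)
    cn <- readLines(col_ids)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      lm_abort("malformed_count_error", "sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(validate_counts(m))
  }

  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          strip.white = TRUE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    lm_abort("empty_input_error", sprintf("no count data in %s", path))
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    lm_abort("malformed_count_error",
             sprintf("non-numeric count column(s): %s",
                     paste(names(vals)[bad], collapse = ", ")))
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_counts(m)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; integer counts round-trip exactly.
#'
#' @inheritParams read_counts
#' @param counts validated count matrix.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "csv", "mtx"),
                         row_ids = paste0(path, ".rows"),
                         col_ids = paste0(path, ".cols")) {
  counts <- validate_counts(counts)
  format <- .sep_for(path, match.arg(format))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), row_ids)
    writeLines(colnames(counts), col_ids)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV/CSV with required columns `sample_id` and `node_status` (N0/N1,
#' case-insensitive) and an optional `gleason` column (integers 6-10).
#' Any further columns are carried along as covariates.
#'
#' @param path file path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return data.frame with columns `sample_id` (character), `node_status`
#'   (factor with levels N0, N1), `gleason` (integer, `NA` when absent) and
#'   any extra covariate columns.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "csv")) {
  format <- .sep_for(path, match.arg(format))
  if (!file.exists(path))
    lm_abort("empty_input_error", sprintf("file not found: %s", path))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "")
  if (nrow(df) == 0L)
    lm_abort("empty_input_error", sprintf("no annotation rows in %s", path))
  if (!all(c("sample_id", "node_status") %in% names(df)))
    lm_abort("annotation_parse_error",
             "annotation file must have columns sample_id and node_status")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    lm_abort("duplicate_id_error", "duplicate sample ids in annotation file")
  ns <- toupper(trimws(as.character(df$node_status)))
  bad <- !ns %in% c("N0", "N1")
  if (any(bad))
    lm_abort("annotation_parse_error",
             sprintf("unknown node_status value(s): %s",
                     paste(unique(df$node_status[bad]), collapse = ", ")))
  df$node_status <- factor(ns, levels = c("N0", "N1"))
  if ("gleason" %in% names(df)) {
    g <- suppressWarnings(as.numeric(df$gleason))
    has <- !is.na(g)
    if (any(has & (g < 6 | g > 10 | g != round(g))))
      lm_abort("annotation_parse_error", "gleason values must be integers in [6, 10]")
    df$gleason <- as.integer(g)
  } else {
    df$gleason <- NA_integer_
  }
  df
}

#' Bind counts and annotations into a validated dataset
#'
#' Annotations are re-ordered to the count-matrix column order, which is the
#' canonical sample order for the whole analysis. Every count column must be
#' annotated; annotation rows without a matching count column are dropped
#' with a warning.
#'
#' @param counts validated count matrix.
#' @param annotations data.frame as returned by [read_annotations()].
#' @return object of class `mir_dataset`: a list with elements `counts` and
#'   `annotations` (row-aligned to `colnames(counts)`).
#' @export
bind_dataset <- function(counts, annotations) {
  counts <- validate_counts(counts)
  if (!is.data.frame(annotations) || !all(c("sample_id", "node_status") %in% names(annotations)))
    lm_abort("annotation_parse_error", "annotations must have sample_id and node_status columns")
  samples <- colnames(counts)
  missing <- setdiff(samples, annotations$sample_id)
  if (length(missing) > 0L)
    lm_abort("missing_annotation_error",
             sprintf("samples without annotation: %s", paste(missing, collapse = ", ")))
  extra <- setdiff(annotations$sample_id, samples)
  if (length(extra) > 0L)
    lm_warn(sprintf("dropping %d annotation row(s) without count data: %s",
                    length(extra), paste(extra, collapse = ", ")))
  ann <- annotations[match(samples, annotations$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(counts = counts, annotations = ann), class = "mir_dataset")
}

#' @export
print.mir_dataset <- function(x, ...) {
  tab <- table(x$annotations$node_status)
  cat(sprintf("mir_dataset: %d miRNAs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Node-status factor of a dataset
#'
#' @param dataset a `mir_dataset`.
#' @return factor with levels N0, N1 aligned to the count-matrix columns.
#' @export
node_groups <- function(dataset) {
  stopifnot(inherits(dataset, "mir_dataset"))
  dataset$annotations$node_status
}

#' Write a result table as TSV
#'
#' Deterministic column order (as supplied); numeric columns serialized with
#' 10 significant digits so values round-trip at well above 6 significant
#' digits.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    lm_abort("empty_input_error", "no records to write")
  out <- records
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 10, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
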