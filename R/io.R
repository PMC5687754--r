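detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a delimited samples-by-features matrix
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers; TSV or CSV is detected from the header line. Empty cells or
#' `NA` are read as missing. Ragged rows, duplicate identifiers and
#' non-numeric cells raise errors naming the offending line.
#'
#' @param path File path.
#' @param allow_missing Permit `NA` cells (only NIPALS PCA consumes them).
#' @return An `omics_block`.
#' @export
read_matrix <- function(path, allow_missing = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  sep <- detect_sep(lines[1L])
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  p <- length(header) - 1L
  if (p < 1L) stop("header has no feature columns: ", path)
  feature_ids <- header[-1L]
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, n, p)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != p + 1L) {
      stop(sprintf("line %d of %s has %d fields, expected %d",
                   i + 1L, path, length(row), p + 1L))
    }
    sample_ids[i] <- row[1L]
    raw <- row[-1L]
    empty <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !empty)
    if (length(bad)) {
      stop(sprintf("line %d of %s: non-numeric cell '%s' (column %s)",
                   i + 1L, path, raw[bad[1L]], feature_ids[bad[1L]]))
    }
    vals[i, ] <- num
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s) in ", path)
  }
  omics_block(vals, sample_ids = sample_ids, feature_ids = feature_ids,
              allow_missing = allow_missing)
}

#' Write a matrix (or omics block) to a delimited file
#'
#' @param x `omics_block` or matrix.
#' @param path Output path; `.csv` extension selects CSV, otherwise TSV.
#' @export
write_matrix <- function(x, path) {
  blk <- as_omics_block(x, allow_missing = TRUE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  M <- blk$values
  header <- paste(c("sample_id", blk$feature_ids), collapse = sep)
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(blk$sample_ids[i], ifelse(is.na(M[i, ]), "NA",
                                      format(M[i, ], digits = 15, trim = TRUE,
                                             scientific = FALSE))),
          collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an outcome table (sample id, label, optional study)
#'
#' @param path TSV/CSV with header; columns: sample id, outcome label, and
#'   optionally a study column.
#' @return data.frame with `sample_id`, `label`, and `study` when present.
#' @export
read_outcome <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- detect_sep(first)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("outcome file needs at least 2 columns")
  names(df)[1:2] <- c("sample_id", "label")
  if (ncol(df) >= 3L) names(df)[3L] <- "study"
  df
}

#' Serialise a fitted model to JSON
#'
#' Full-precision JSON serialisation; [load_model()] restores an object
#' whose predictions match the original exactly.
#'
#' @param model A `latent_model` or `latent_pca`.
#' @param path Output file path.
#' @export
save_model <- function(model, path) {
  json <- jsonlite::serializeJSON(model, digits = 17)
  writeLines(json, path)
  invisible(path)
}

#' Restore a model saved with [save_model()]
#'
#' @param path File path.
#' @return The model object.
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

#' Export a performance report (or any list of results) as JSON
#'
#' @param report A `perf_report`, `tune_result`, or plain list.
#' @param path Output path.
#' @export
export_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (inherits(x, "hclust") || is.function(x)) return(NULL)
  if (is.factor(x)) return(as.character(x))
  if (is.array(x) && length(dim(x)) > 2L) {
    # JSON has no native >2-d arrays; flatten to per-slice matrices
    dn <- dimnames(x)
    slices <- lapply(seq_len(dim(x)[3L]), function(h) {
      m <- x[, , h, drop = FALSE]
      dim(m) <- dim(x)[1:2]
      dimnames(m) <- dn[1:2]
      m
    })
    names(slices) <- if (!is.null(dn[[3L]])) dn[[3L]] else paste0("slice", seq_along(slices))
    return(slices)
  }
  if (is.list(x)) {
    out <- lapply(x, unclass_deep)
    attributes(out) <- list(names = names(out))
    return(out)
  }
  x
}
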