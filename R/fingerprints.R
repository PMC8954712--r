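#' Validate a binary fingerprint matrix
#'
#' A fingerprint matrix holds compounds in rows and named binary bits in
#' columns; entries are strictly 0/1, row names (compound ids) and column
#' names (bit names) are unique.
#'
#' @param fp matrix to validate.
#' @return `fp`, invisibly, if valid; otherwise an error.
#' @export
validate_fingerprint_matrix <- function(fp) {
  if (!is.matrix(fp) || !is.numeric(fp))
    stop("fingerprint matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(fp)) || is.null(colnames(fp)))
    stop("fingerprint matrix needs compound row names and bit column names",
         call. = FALSE)
  if (anyDuplicated(rownames(fp)))
    stop("duplicate compound ids in fingerprint matrix", call. = FALSE)
  if (anyDuplicated(colnames(fp)))
    stop("duplicate bit names in fingerprint matrix", call. = FALSE)
  bad <- which(!(fp == 0 | fp == 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary fingerprint value %s at row '%s', column '%s'",
                 format(fp[bad[1, 1], bad[1, 2]]),
                 rownames(fp)[bad[1, 1]], colnames(fp)[bad[1, 2]]),
         call. = FALSE)
  invisible(fp)
}

#' Read a fingerprint matrix from CSV
#'
#' Reads the dialect emitted by common fingerprint calculators: a header
#' row of bit names, first column of compound ids (conventionally headed
#' `Name`), cells 0/1. A semicolon-separated variant is accepted via `sep`.
#'
#' @param path CSV file path.
#' @param sep field separator, `","` (default) or `";"`.
#' @return numeric matrix with compound ids as row names and bit names as
#'   column names.
#' @export
load_fingerprint_table <- function(path, sep = ",") {
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2)
    stop("fingerprint CSV needs an id column plus at least one bit", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) | !(col == 0 | col == 1))
    if (length(bad) > 0)
      stop(sprintf(
        "non-binary value '%s' at row %d (compound '%s'), column '%s' of %s",
        as.character(vals[[j]][bad[1]]), bad[1], ids[bad[1]],
        names(vals)[j], path), call. = FALSE)
    vals[[j]] <- col
  }
  fp <- as.matrix(vals)
  rownames(fp) <- ids
  validate_fingerprint_matrix(fp)
  fp
}

#' Write a fingerprint matrix to CSV
#'
#' Inverse of [load_fingerprint_table()]: first column `Name`, one column
#' per bit.
#'
#' @param fp validated fingerprint matrix.
#' @param path output CSV path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fp, path, sep = ",") {
  validate_fingerprint_matrix(fp)
  out <- data.frame(Name = rownames(fp), fp, check.names = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
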