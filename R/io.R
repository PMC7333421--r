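# Delimited-matrix readers/writers. All on-disk index files are 0-based;
# in-memory indices follow R's 1-based convention.

#' Read a numeric matrix from a delimited text file
#'
#' Accepts TSV or CSV (the separator is sniffed from the first line), with or
#' without a header row. Every cell must parse as a decimal number; a
#' non-numeric cell is reported with its row and column coordinates, and
#' ragged rows are a format error.
#'
#' @param path file path.
#' @param expect_rows,expect_cols optional dimension checks.
#' @return A numeric matrix (column names kept when a header is present).
#' @export
read_matrix <- function(path, expect_rows = NULL, expect_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(unique(widths), collapse = ", ")))
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- anyNA(first)
  header <- if (has_header) cells[[1]]
  if (has_header) cells <- cells[-1]
  if (length(cells) == 0L) stop("no data rows in ", path)
  m <- matrix(NA_real_, length(cells), widths[[1]])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell '%s' at data row %d, column %d of %s",
                   cells[[i]][j], i, j, path))
    }
    m[i, ] <- v
  }
  if (has_header) colnames(m) <- header
  if (!is.null(expect_rows) && nrow(m) != expect_rows)
    stop(sprintf("%s: expected %d rows, found %d", path, expect_rows, nrow(m)))
  if (!is.null(expect_cols) && ncol(m) != expect_cols)
    stop(sprintf("%s: expected %d columns, found %d", path, expect_cols,
                 ncol(m)))
  m
}

#' Write a numeric matrix as TSV
#'
#' Header row of column labels; values at 17 significant digits so a
#' write/read round trip preserves doubles exactly.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(m)))
  chr <- matrix(formatC(m, digits = 17, format = "g"), nrow(m), ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  writeLines(apply(chr, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
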