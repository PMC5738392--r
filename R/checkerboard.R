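#' Checkerboard combination-assay data
#'
#' Long-format container for a two-compound checkerboard experiment: one row
#' per well, with the dose of each compound, the measured readout and an
#' optional replicate id. Rows with exactly one zero dose are mono-therapy
#' points, the all-zero row is the untreated control, and rows with both
#' doses positive are off-axis combination points.
#'
#' Duplicated `(d1, d2)` rows without a `replicate` column are assigned
#' replicate ids `1..n` in file order.
#'
#' @param x A data.frame with numeric columns `d1`, `d2`, `effect` and
#'   optionally `replicate`.
#' @return An object of class `checkerboard` (a data.frame).
#' @seealso [read_board()], [board_view()]
#' @export
checkerboard <- function(x) {
  if (inherits(x, "checkerboard")) return(x)
  if (!is.data.frame(x)) stop_invalid("checkerboard input must be a data.frame")
  need <- c("d1", "d2", "effect")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop_invalid("missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  for (col in need) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop_invalid("column '", col, "' is not numeric (first bad row: ",
                   if (is.na(bad)) 1L else bad, ")")
    }
    if (anyNA(v) || any(!is.finite(v)))
      stop_invalid("column '", col, "' contains missing or non-finite values (row ",
                   which(!is.finite(v))[1], ")")
  }
  for (col in c("d1", "d2")) {
    if (any(x[[col]] < 0))
      stop_invalid("negative dose in column '", col, "' (row ",
                   which(x[[col]] < 0)[1], ")")
  }
  if (is.null(x$replicate)) {
    key <- interaction(x$d1, x$d2, drop = TRUE)
    x$replicate <- stats::ave(seq_len(nrow(x)), key, FUN = seq_along)
  }
  x <- x[, c("d1", "d2", "effect", "replicate")]
  class(x) <- c("checkerboard", "data.frame")
  x
}

#' Extract a view of a checkerboard
#'
#' @param board A [checkerboard()].
#' @param which One of `"mono1"` (d2 = 0, d1 > 0), `"mono2"` (d1 = 0,
#'   d2 > 0), `"untreated"` (both zero) or `"off_axis"` (both positive).
#' @return The matching rows as a data.frame.
#' @export
board_view <- function(board,
                       which = c("mono1", "mono2", "untreated", "off_axis")) {
  board <- checkerboard(board)
  which <- match.arg(which)
  keep <- switch(which,
    mono1     = board$d2 == 0 & board$d1 > 0,
    mono2     = board$d1 == 0 & board$d2 > 0,
    untreated = board$d1 == 0 & board$d2 == 0,
    off_axis  = board$d1 > 0 & board$d2 > 0)
  out <- board[keep, , drop = FALSE]
  class(out) <- "data.frame"
  out
}

#' Read a checkerboard from a long-format CSV file
#'
#' Expects a comma-separated UTF-8 file with a header naming at least
#' `d1`, `d2` and `effect` (a `replicate` column is optional). Scientific
#' notation is accepted; row order is preserved.
#'
#' @param path Path to the CSV file.
#' @return A [checkerboard()].
#' @export
read_board <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  checkerboard(raw)
}

#' Write a checkerboard to CSV
#'
#' Full-precision long-format CSV that [read_board()] round-trips exactly.
#'
#' @param board A [checkerboard()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_board <- function(board, path) {
  board <- checkerboard(board)
  df <- as.data.frame(board)
  for (col in c("d1", "d2", "effect"))
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.checkerboard <- function(x, ...) {
  k <- vapply(c("mono1", "mono2", "untreated", "off_axis"),
              function(v) nrow(board_view(x, v)), integer(1))
  cat(sprintf(paste0(
    "Checkerboard: %d wells (%d + %d mono-therapy, %d untreated, ",
    "%d off-axis)\n"), nrow(x), k[1], k[2], k[3], k[4]))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}
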