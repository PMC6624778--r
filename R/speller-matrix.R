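#' The 6x6 speller matrix
#'
#' A speller matrix is the 6x6 character grid whose rows and columns flash
#' during stimulation. Flash locations are numbered 1-6 for rows (top to
#' bottom) and 7-12 for columns (left to right); a letter is identified by the
#' intersection of its row and column locations.
#'
#' @param grid A 6x6 character matrix (36 unique single characters), or `NULL`
#'   for the default A-Z, 1-9, 0 layout used by common open-source spellers.
#' @return An object of class `speller_matrix`.
#' @examples
#' m <- speller_matrix()
#' matrix_letter(m, row = 1, col = 7)   # "A"
#' letter_locations(m, "T")
#' @export
speller_matrix <- function(grid = NULL) {
  if (is.null(grid)) {
    grid <- matrix(strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ1234567890", "")[[1]],
                   nrow = 6, byrow = TRUE)
  }
  if (!is.matrix(grid) || !identical(dim(grid), c(6L, 6L))) {
    abort("speller matrix must be 6x6")
  }
  grid[] <- as.character(grid)
  if (anyDuplicated(grid)) abort("speller matrix characters must be unique")
  if (any(nchar(grid) != 1L)) abort("speller matrix entries must be single characters")
  structure(list(grid = grid), class = "speller_matrix")
}

#' @export
print.speller_matrix <- function(x, ...) {
  cat("<speller_matrix>\n")
  apply(x$grid, 1, function(r) cat(" ", paste(r, collapse = " "), "\n"))
  invisible(x)
}

#' @rdname speller_matrix
#' @param matrix A `speller_matrix`.
#' @param row Row location in 1..6.
#' @param col Column location in 7..12.
#' @export
matrix_letter <- function(matrix, row, col) {
  stopifnot(inherits(matrix, "speller_matrix"), row %in% 1:6, col %in% 7:12)
  matrix$grid[row, col - 6L]
}

#' @rdname speller_matrix
#' @param letter A single character present in the grid.
#' @return `letter_locations()` returns a named integer vector
#'   `c(row = , col = )` with the row location (1-6) and column location
#'   (7-12) of `letter`.
#' @export
letter_locations <- function(matrix, letter) {
  stopifnot(inherits(matrix, "speller_matrix"))
  idx <- which(matrix$grid == letter, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort(paste0("letter not in speller matrix: ", letter))
  c(row = as.integer(idx[1, "row"]), col = as.integer(idx[1, "col"]) + 6L)
}

#' Read or write a speller matrix as a 6-line text file
#'
#' Each line holds the 6 characters of one row, optionally space-separated.
#'
#' @param path File path.
#' @return `read_speller_matrix()` returns a [speller_matrix()].
#' @export
read_speller_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 6L) abort("speller matrix file must have 6 non-empty lines")
  rows <- lapply(lines, function(l) strsplit(gsub("[[:space:]]", "", l), "")[[1]])
  if (any(lengths(rows) != 6L)) abort("each speller matrix row must have 6 characters")
  speller_matrix(do.call(rbind, rows))
}

#' @rdname read_speller_matrix
#' @param matrix A [speller_matrix()].
#' @export
write_speller_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "speller_matrix"))
  writeLines(apply(matrix$grid, 1, paste, collapse = ""), path)
  invisible(path)
}
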