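#' Write a periodic grid as gnuplot-ready matrix text
#'
#' Emits one data block per grid row (blank-line separated), each line
#' `x y value`, preceded by comment headers carrying the axis names and
#' cell-center coordinates.  Masked cells (`NA`/`Inf` values) are written
#' as the sentinel token `NA` (gnuplot: `set datafile missing "NA"`).
#'
#' @param grid a [count_grid], [fes_grid], or any list with elements
#'   `values` (matrix), `x`, `y` (cell-center vectors) and `axes`
#'   (two axis names).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_matrix <- function(grid, path) {
  g <- as_grid_list(grid)
  vals <- g$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axes: %s %s", g$axes[1], g$axes[2]),
               paste("# x:", paste(sprintf("%.10g", g$x), collapse = " ")),
               paste("# y:", paste(sprintf("%.10g", g$y), collapse = " "))),
             con)
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.10g", v), "NA")
  for (i in seq_along(g$x)) {
    writeLines(sprintf("%.10g %.10g %s", g$x[i], g$y, fmt(vals[i, ])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a grid written by [write_grid_matrix]
#'
#' @param path file produced by [write_grid_matrix].
#' @return list with `values` matrix (masked cells `NA`), `x`, `y`, `axes`.
#' @export
read_grid_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  axes <- strsplit(sub("^# axes: ", "", lines[1]), " ")[[1]]
  x <- as.numeric(strsplit(sub("^# x: ", "", lines[2]), " ")[[1]])
  y <- as.numeric(strsplit(sub("^# y: ", "", lines[3]), " ")[[1]])
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, " ")
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  values <- matrix(vals, nrow = length(x), ncol = length(y), byrow = TRUE)
  list(values = values, x = x, y = y, axes = axes)
}

as_grid_list <- function(grid) {
  if (inherits(grid, "count_grid"))
    return(list(values = grid$counts, x = grid$x, y = grid$y, axes = grid$axes))
  if (inherits(grid, "fes_grid")) {
    v <- grid$free_energy
    v[grid$mask] <- NA_real_
    return(list(values = v, x = grid$x, y = grid$y, axes = grid$axes))
  }
  stopifnot(is.list(grid), !is.null(grid$values))
  if (is.null(grid$axes)) grid$axes <- c("x", "y")
  grid
}
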