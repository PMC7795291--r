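#' Construct a dihedral time series
#'
#' A `dihedral_series` holds per-frame backbone torsions (phi, psi) and
#' optionally the side-chain orientation torsion theta, for one or both
#' monomers of a capped X-X tripeptide (monomer 1 = N-terminal residue,
#' monomer 2 = C-terminal residue).  Angles are wrapped to `[-180, 180)`
#' degrees on construction.
#'
#' @param monomer integer vector of monomer ids (1 or 2).
#' @param phi,psi numeric vectors of torsions in degrees.
#' @param theta optional numeric vector of theta torsions in degrees.
#' @param frame optional integer frame indices; defaults to running order
#'   within each monomer.
#' @param frame_interval sampling interval between frames, ps.
#' @return a data frame of class `dihedral_series` with columns
#'   `frame`, `monomer`, `phi`, `psi` and (if given) `theta`.
#' @export
dihedral_series <- function(monomer, phi, psi, theta = NULL, frame = NULL,
                            frame_interval = 10) {
  monomer <- as.integer(monomer)
  if (!all(monomer %in% c(1L, 2L)))
    stop("monomer_id must be 1 (N-terminal) or 2 (C-terminal)")
  n <- length(phi)
  if (length(psi) != n || length(monomer) != n)
    stop("monomer, phi and psi must have equal length")
  if (is.null(frame)) {
    frame <- integer(n)
    for (m in unique(monomer)) frame[monomer == m] <- seq_len(sum(monomer == m))
  }
  x <- data.frame(frame = as.integer(frame), monomer = monomer,
                  phi = wrap_angle(phi), psi = wrap_angle(psi))
  if (!is.null(theta)) {
    if (length(theta) != n) stop("theta must match phi/psi length")
    x$theta <- wrap_angle(theta)
  }
  tab <- table(monomer)
  if (length(tab) == 2L && tab[[1]] != tab[[2]])
    stop("both monomers must have equal frame counts")
  structure(x, frame_interval = frame_interval,
            class = c("dihedral_series", "data.frame"))
}

#' @export
print.dihedral_series <- function(x, ...) {
  mons <- sort(unique(x$monomer))
  cat(sprintf("dihedral_series: %d frames x %d monomer(s) [%s]%s, interval %g ps\n",
              sum(x$monomer == mons[1]), length(mons),
              paste(mons, collapse = ","),
              if ("theta" %in% names(x)) " with theta" else "",
              attr(x, "frame_interval")))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a dihedral time series from a delimited table
#'
#' Accepts the package CSV dialect (header `frame,monomer,phi,psi[,theta]`)
#' or whitespace-separated tables of the kind trajectory-analysis tools
#' emit (`dialect = "whitespace"`).  Alternative column names can be mapped
#' with `col_map`, e.g. `c(monomer = "set")`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"whitespace"`.
#' @param col_map optional named character vector mapping canonical names
#'   to the file's column names.
#' @param frame_interval sampling interval, ps.
#' @return a [dihedral_series].
#' @export
read_dihedral_series <- function(path, dialect = c("csv", "whitespace"),
                                 col_map = NULL, frame_interval = 10) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    if (dialect == "csv")
      utils::read.csv(path, header = TRUE, colClasses = NA)
    else
      utils::read.table(path, header = TRUE),
    warning = function(w) stop("parse error in ", path, ": ",
                               conditionMessage(w)))
  for (canon in names(col_map)) {
    if (col_map[[canon]] %in% names(df))
      names(df)[names(df) == col_map[[canon]]] <- canon
  }
  need <- c("monomer", "phi", "psi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path)
  for (col in intersect(c("phi", "psi", "theta"), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("parse error: non-numeric value in column '%s' at data line %d",
                   col, bad))
    }
  }
  dihedral_series(df$monomer, df$phi, df$psi,
                  theta = if ("theta" %in% names(df)) df$theta,
                  frame = if ("frame" %in% names(df)) df$frame,
                  frame_interval = frame_interval)
}

#' Write a dihedral series as CSV
#'
#' @param x a [dihedral_series].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dihedral_series <- function(x, path) {
  stopifnot(inherits(x, "dihedral_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# extract one monomer's angle pair as a two-column matrix
series_axes <- function(series, axis_pair = c("phi", "psi"), monomer = NULL) {
  stopifnot(inherits(series, "dihedral_series"))
  if (!is.null(monomer)) series <- series[series$monomer == monomer, , drop = FALSE]
  if (nrow(series) == 0) stop("series is empty for the requested monomer")
  missing_ax <- setdiff(axis_pair, names(series))
  if (length(missing_ax))
    stop("axis not present in series: ", paste(missing_ax, collapse = ", "))
  cbind(series[[axis_pair[1]]], series[[axis_pair[2]]])
}
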