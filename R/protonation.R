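#' Construct a protonation-state time series
#'
#' Per-frame discrete protonation-state indices for one or more titratable
#' residues, with a label per observed state index (e.g. `syn-O1`,
#' `anti-O2`, `delta`, `epsilon`, `prot`, `deprot`).  Optional metadata
#' carries the solvent pH and intrinsic pKa of the scenario.
#'
#' @param frames data frame with columns `frame`, `residue`, `state`
#'   (integer state indices).
#' @param state_labels named character vector mapping state index (as
#'   name) to label.
#' @param metadata optional list (e.g. `solvent_pH`, `intrinsic_pKa`).
#' @return object of class `state_series`.
#' @export
state_series <- function(frames, state_labels, metadata = list()) {
  stopifnot(all(c("frame", "residue", "state") %in% names(frames)))
  seen <- unique(frames$state)
  unlabelled <- setdiff(as.character(seen), names(state_labels))
  if (length(unlabelled))
    stop("validation error: state index without label: ",
         paste(unlabelled, collapse = ", "))
  structure(list(frames = frames, state_labels = state_labels,
                 metadata = metadata),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state_series: %d frames x %d residue(s); states: %s\n",
              length(unique(x$frames$frame)),
              length(unique(x$frames$residue)),
              paste(x$state_labels, collapse = ", ")))
  invisible(x)
}

#' Read a protonation-state series from CSV
#'
#' Expects columns `frame,residue,state`; labels are supplied separately
#' (or as a JSON sidecar written by [write_state_series]).
#'
#' @param path CSV file.
#' @param state_labels named character vector (index -> label); if `NULL`,
#'   read from `<path>.labels.json`.
#' @param metadata optional list.
#' @return a [state_series].
#' @export
read_state_series <- function(path, state_labels = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (is.null(state_labels)) {
    side <- paste0(path, ".labels.json")
    if (!file.exists(side))
      stop("state labels required: pass state_labels or provide ", side)
    state_labels <- unlist(jsonlite::fromJSON(side))
  }
  state_series(df, state_labels, metadata)
}

#' Write a protonation-state series as CSV (+ label sidecar)
#'
#' @param x a [state_series].
#' @param path output CSV; labels go to `<path>.labels.json`.
#' @return `path`, invisibly.
#' @export
write_state_series <- function(x, path) {
  stopifnot(inherits(x, "state_series"))
  utils::write.csv(x$frames, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(x$state_labels), paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Protonation-state populations
#'
#' Empirical per-residue fractions of each labelled state, plus aggregate
#' fractions over user-defined groups (e.g. `syn` = syn-O1 + syn-O2, or
#' `protonated` over all protonated states).  When several residues (or
#' replicate series) are present, across-residue averages are reported
#' both unweighted and frame-weighted; they coincide for equal frame
#' counts.
#'
#' @param x a [state_series], or a list of them (replicates).
#' @param aggregation named list: group label -> character vector of
#'   member state labels.  Must cover every observed label if given.
#' @return object of class `state_populations`: `per_residue` (matrix
#'   label x residue), `aggregates` (matrix group x residue),
#'   `average`, `average_frame_weighted` (named lists of vectors).
#' @export
state_populations <- function(x, aggregation = NULL) {
  if (inherits(x, "state_series")) x <- list(x)
  frames <- do.call(rbind, lapply(seq_along(x), function(i) {
    f <- x[[i]]$frames
    f$residue <- paste0(if (length(x) > 1) sprintf("rep%d:", i) else "",
                        f$residue)
    lab_i <- x[[i]]$state_labels
    f$label <- unname(lab_i[as.character(f$state)])
    f
  }))
  labels <- unique(unlist(lapply(x, `[[`, "state_labels")))
  res <- unique(frames$residue)
  per <- vapply(res, function(r) {
    sub <- frames[frames$residue == r, ]
    as.numeric(table(factor(sub$label, levels = labels))) / nrow(sub)
  }, numeric(length(labels)))
  per <- matrix(per, nrow = length(labels), dimnames = list(labels, res))
  nfr <- vapply(res, function(r) sum(frames$residue == r), 0)
  agg <- NULL
  if (!is.null(aggregation)) {
    uncovered <- setdiff(labels, unlist(aggregation))
    if (length(uncovered))
      stop("validation error: aggregation map does not cover label(s): ",
           paste(uncovered, collapse = ", "))
    agg <- t(vapply(aggregation, function(members)
      colSums(per[intersect(labels, members), , drop = FALSE]),
      numeric(ncol(per))))
    agg <- matrix(agg, nrow = length(aggregation), ncol = ncol(per),
                  dimnames = list(names(aggregation), colnames(per)))
  }
  avg <- function(m, w) if (is.null(m)) NULL else
    drop(m %*% (w / sum(w)))
  structure(list(per_residue = per, aggregates = agg,
                 n_frames = nfr,
                 average = avg(rbind(per, agg), rep(1, length(nfr))),
                 average_frame_weighted = avg(rbind(per, agg), nfr)),
            class = "state_populations")
}

#' @export
print.state_populations <- function(x, digits = 3, ...) {
  cat("state_populations per residue:\n")
  print(round(x$per_residue, digits))
  if (!is.null(x$aggregates)) {
    cat("aggregates:\n"); print(round(x$aggregates, digits))
  }
  cat("average (unweighted):\n"); print(round(x$average, digits))
  invisible(x)
}

#' State-to-state transition counts
#'
#' `counts[a, b]` is the number of frame pairs where state `a` is followed
#' by state `b` within the same residue; the total count is
#' `n_frames - 1` per residue.
#'
#' @param x a [state_series].
#' @return integer matrix labelled by state labels.
#' @export
transition_counts <- function(x) {
  stopifnot(inherits(x, "state_series"))
  labels <- x$state_labels
  k <- length(labels)
  counts <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (r in unique(x$frames$residue)) {
    s <- x$frames$state[x$frames$residue == r]
    if (length(s) < 2) stop("series length must be >= 2")
    a <- s[-length(s)]; b <- s[-1]
    t2 <- table(factor(a, levels = names(labels)),
                factor(b, levels = names(labels)))
    counts <- counts + matrix(as.integer(t2), k, k)
  }
  counts
}

#' Split a dihedral series by concurrent protonation state
#'
#' Routes each frame of the dihedral series to the protonation state
#' active at that frame, enabling state-conditioned Ramachandran maps.
#' The concatenation of the outputs reconstitutes the input up to order.
#'
#' @param dihedrals a [dihedral_series].
#' @param states a [state_series] for one residue, with one state per
#'   dihedral frame (per monomer).
#' @return named list (state label -> [dihedral_series]).
#' @export
conditional_series_split <- function(dihedrals, states) {
  stopifnot(inherits(dihedrals, "dihedral_series"),
            inherits(states, "state_series"))
  sf <- states$frames
  if (length(unique(sf$residue)) != 1)
    stop("validation error: pass a single-residue state series")
  per_mon <- sum(dihedrals$monomer == dihedrals$monomer[1])
  if (nrow(sf) != per_mon)
    stop(sprintf("validation error: %d state frames for %d dihedral frames",
                 nrow(sf), per_mon))
  lab <- unname(states$state_labels[as.character(sf$state)])
  out <- list()
  for (L in unique(lab)) {
    keep <- dihedrals$frame %in% sf$frame[lab == L]
    sub <- dihedrals[keep, , drop = FALSE]
    attr(sub, "frame_interval") <- attr(dihedrals, "frame_interval")
    class(sub) <- c("dihedral_series", "data.frame")
    out[[L]] <- sub
  }
  out
}
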