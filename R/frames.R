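#' Coordinate frame stack
#'
#' Frames are stored as a numeric array of dimension
#' `(n_atoms, 3, n_frames)` in Angstrom, with atom names carried in the
#' dimnames when known.
#'
#' @param xyz numeric array `(n_atoms, 3, n_frames)`, or an `n_atoms x 3`
#'   matrix for a single frame.
#' @param atom_names optional character vector of atom names.
#' @return object of class `coord_frames`.
#' @export
coord_frames <- function(xyz, atom_names = NULL) {
  if (is.matrix(xyz)) xyz <- array(xyz, c(nrow(xyz), 3, 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (!is.null(atom_names)) {
    stopifnot(length(atom_names) == dim(xyz)[1])
    dimnames(xyz) <- list(atom_names, c("x", "y", "z"), NULL)
  }
  structure(xyz, class = "coord_frames")
}

#' @export
print.coord_frames <- function(x, ...) {
  cat(sprintf("coord_frames: %d frame(s) x %d atoms\n", dim(x)[3], dim(x)[1]))
  invisible(x)
}

n_frames <- function(frames) dim(frames)[3]

frame_matrix <- function(frames, i) {
  m <- frames[, , i, drop = FALSE]
  dim(m) <- dim(frames)[1:2]
  m
}

#' Read coordinate frames from a multi-model PDB
#'
#' Every model must contain the same atoms in the same order; a model with
#' a differing atom count raises a structure error naming the model.
#'
#' @param path PDB file (single- or multi-model).
#' @return a [coord_frames] stack; atom names from the PDB are kept.
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  counts <- pdb_model_atom_counts(path)
  if (length(counts) > 1 && length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("structure error: model %d has %d atoms, expected %d",
                 bad, counts[bad], counts[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # n_models x 3N
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  arr <- array(0, c(nat, 3, nrow(xyz)))
  for (i in seq_len(nrow(xyz)))
    arr[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  coord_frames(arr, atom_names = pdb$atom$elety[seq_len(nat)])
}

# atom counts per MODEL block straight from the text (bio3d pads/recycles,
# so the error contract needs a raw scan)
pdb_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!length(model_starts)) return(sum(is_atom))
  ends <- which(rec == "ENDMDL")
  if (length(ends) < length(model_starts))
    stop(sprintf("structure error: model %d is truncated (missing ENDMDL)",
                 length(model_starts)))
  vapply(seq_along(model_starts), function(i)
    sum(is_atom[model_starts[i]:ends[i]]), 0L)
}

#' Write coordinate frames as a multi-model PDB
#'
#' @param frames a [coord_frames] stack.
#' @param topology optional [topology] supplying atom/residue names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, topology = NULL) {
  stopifnot(inherits(frames, "coord_frames"))
  nat <- dim(frames)[1]
  if (!is.null(topology)) {
    elety <- topology$atoms$name
    resid <- topology$atoms$residue_name
    resno <- topology$atoms$residue_index
  } else {
    elety <- if (!is.null(dimnames(frames)[[1]])) dimnames(frames)[[1]]
             else rep("C", nat)
    resid <- rep("UNK", nat); resno <- rep(1, nat)
  }
  xyz <- t(vapply(seq_len(n_frames(frames)),
                  function(i) as.numeric(t(frame_matrix(frames, i))),
                  numeric(3 * nat)))
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resid = resid,
                   resno = resno, chain = rep("A", nat))
  invisible(path)
}
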