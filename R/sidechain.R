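#' Backbone and side-chain-orientation torsions from coordinates
#'
#' Computes phi (C'-N-CA-C), psi (N-CA-C-N') for both monomers and the
#' side-chain orientation torsion theta (atom1-CA1-CA2-atom2, with atom1
#' and atom2 selected side-chain atoms) for every frame, returning a
#' [dihedral_series] with the theta column filled.  theta is shared by
#' the two monomers, so pairing it with phi/psi of either monomer yields
#' the four orientation-map axes (phi1/theta, theta/psi1, phi2/theta,
#' theta/psi2).
#'
#' @param frames a [coord_frames] stack.
#' @param topology the matching [topology].
#' @param selection list with `atom1`, `atom2` side-chain atom names (e.g.
#'   one entry of [read_theta_selection]); defaults to the shipped
#'   selection for the topology's residue type.
#' @param frame_interval ps.
#' @return a [dihedral_series] with columns phi, psi, theta for monomers
#'   1 and 2.
#' @export
theta_series <- function(frames, topology, selection = NULL,
                         frame_interval = 10) {
  resname <- topology$atoms$residue_name[topology$atoms$residue_index == 2][1]
  if (is.null(selection)) {
    sel_table <- read_theta_selection()
    if (!resname %in% names(sel_table))
      stop("selection error: no default theta selection for residue ", resname)
    selection <- sel_table[[resname]]
  }
  ai <- function(name, res) {
    hit <- which(topology$atoms$name == name &
                   topology$atoms$residue_index == res)
    if (!length(hit))
      stop("selection error: atom '", name, "' not found in residue ", res)
    hit[1]
  }
  i_s1 <- ai(selection$atom1, 2); i_ca1 <- ai("CA", 2)
  i_ca2 <- ai("CA", 3);           i_s2 <- ai(selection$atom2, 3)
  stack <- function(i) t(frames[i, , ])   # n_frames x 3
  theta <- torsion_rows(stack(i_s1), stack(i_ca1), stack(i_ca2), stack(i_s2))

  bb <- lapply(c(2, 3), function(res) {
    prevC <- ai("C", res - 1); nextN <- ai("N", res + 1)
    iN <- ai("N", res); iCA <- ai("CA", res); iC <- ai("C", res)
    data.frame(
      phi = torsion_rows(stack(prevC), stack(iN), stack(iCA), stack(iC)),
      psi = torsion_rows(stack(iN), stack(iCA), stack(iC), stack(nextN)))
  })
  nf <- n_frames(frames)
  dihedral_series(monomer = rep(c(1, 2), each = nf),
                  phi = c(bb[[1]]$phi, bb[[2]]$phi),
                  psi = c(bb[[1]]$psi, bb[[2]]$psi),
                  theta = rep(theta, 2),
                  frame = rep(seq_len(nf), 2),
                  frame_interval = frame_interval)
}

#' Orientation-space free-energy maps
#'
#' Builds the four theta-map count grids (phi1/theta, theta/psi1,
#' phi2/theta, theta/psi2) from a theta-filled series and inverts them to
#' free energies.
#'
#' @param series a [dihedral_series] with a theta column.
#' @param spacing grid spacing, degrees.
#' @param temperature K.
#' @return named list of four [boltzmann_invert] grids.
#' @export
theta_maps <- function(series, spacing = 1, temperature = 300) {
  specs <- list(phi1_theta = list(c("phi", "theta"), 1),
                theta_psi1 = list(c("theta", "psi"), 1),
                phi2_theta = list(c("phi", "theta"), 2),
                theta_psi2 = list(c("theta", "psi"), 2))
  lapply(specs, function(s)
    boltzmann_invert(bin_angles(series, s[[1]], spacing, monomer = s[[2]]),
                     temperature))
}

#' Interatomic distance distribution over frames
#'
#' Euclidean distance between two selected atoms per frame, as a
#' unit-area histogram (default bin width 0.1 A, which resolves the
#' sub-Angstrom shifts of interest).
#'
#' @param frames a [coord_frames] stack.
#' @param topology the matching [topology].
#' @param atomA,atomB atom selectors: `"name"` or `"name:residue_index"`.
#' @param bin_width A.
#' @return an `energy_histogram`-style density histogram plus attribute
#'   `distances` with the raw per-frame distances.
#' @export
distance_distribution <- function(frames, topology, atomA, atomB,
                                  bin_width = 0.1) {
  stopifnot(bin_width > 0)
  find <- function(sel) {
    parts <- strsplit(sel, ":")[[1]]
    hit <- which(topology$atoms$name == parts[1] &
                   (length(parts) == 1 |
                      topology$atoms$residue_index == as.integer(parts[2])))
    if (!length(hit)) stop("selection error: atom '", sel, "' not found")
    hit[1]
  }
  ia <- find(atomA); ib <- find(atomB)
  if (ia == ib) stop("selection error: the same atom was selected twice")
  d <- sqrt(colSums((frames[ia, , ] - frames[ib, , ])^2))
  h <- density_histogram(d, bin_width)
  attr(h, "distances") <- d
  h
}
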