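# Single-point AMBER-style energies on coordinate frames.
#
# Conventions (AMBER defaults, fixed package-wide):
#   Coulomb constant 332.0636 kcal A / (mol e^2); 1-4 electrostatics
#   divided by SCEE = 1.2; 1-4 Lennard-Jones divided by SCNB = 2.0;
#   LJ combination Rmin_ij = Ri + Rj, eps_ij = sqrt(ei ej).
# GB flavour: OBC-I (alpha = 0.8, beta = 0, gamma = 2.909125), eps_in = 1,
# eps_out = 78.5, with Debye-Hueckel salt screening exp(-kappa fGB) on the
# pairwise dielectric term.  gb_radius is the offset-corrected intrinsic
# radius: an isolated atom's effective Born radius equals it exactly.

SCEE <- 1.2
SCNB <- 2.0
EPS_OUT <- 78.5
OBC_ALPHA <- 0.8
OBC_BETA <- 0.0
OBC_GAMMA <- 2.909125

#' Debye screening constant for a 1:1 electrolyte
#'
#' \eqn{\kappa = \sqrt{8 \pi \lambda_B n}} in 1/Angstrom, with Bjerrum
#' length \eqn{\lambda_B = 332.0636 / (\epsilon k_B T)} and ion number
#' density n from the molar ionic strength.
#'
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param eps_out solvent dielectric constant.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength, temperature = 300,
                        eps_out = EPS_OUT) {
  if (ionic_strength <= 0) return(0)
  lambda_b <- pepconf_constants[["coulomb"]] /
    (eps_out * pepconf_constants[["kB"]] * temperature)
  n_dens <- ionic_strength * 6.02214076e23 / 1e27   # ions / A^3
  sqrt(8 * pi * lambda_b * n_dens)
}

# nonbonded pair bookkeeping, cached on the topology object
pair_tables <- function(topology) {
  n <- nrow(topology$atoms)
  all_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pk <- function(ai, aj) pmin(ai, aj) * (n + 1) + pmax(ai, aj)
  key_all <- pk(all_ij[, 1], all_ij[, 2])
  key_ex <- pk(topology$exclusions$ai, topology$exclusions$aj)
  key_14 <- pk(topology$pairs14$ai, topology$pairs14$aj)
  list(nb = all_ij[!(key_all %in% c(key_ex, key_14)), , drop = FALSE],
       p14 = all_ij[key_all %in% key_14, , drop = FALSE])
}

pair_dist <- function(xyz, ij) {
  d <- xyz[ij[, 1], , drop = FALSE] - xyz[ij[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Effective Born radii (OBC model)
#'
#' Pairwise descreening (HCT integrals with screened radii) followed by
#' the OBC tanh rescaling.  With no neighbours the effective radius equals
#' the atom's `gb_radius`.
#'
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param topology a [topology].
#' @return numeric vector of effective radii, Angstrom.
#' @export
born_radii <- function(xyz, topology) {
  rho <- topology$atoms$gb_radius
  scr <- topology$atoms$gb_screen
  n <- nrow(xyz)
  I <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    r <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    sr <- scr[j] * rho[j]
    keep <- (r + sr) > rho[i]
    if (!any(keep)) next
    r <- r[keep]; sr <- sr[keep]
    U <- r + sr
    L <- pmax(rho[i], abs(r - sr))
    h <- 0.5 * (1 / L - 1 / U + 0.25 * (r - sr^2 / r) * (1 / U^2 - 1 / L^2) +
                  0.5 * log(L / U) / r)
    engulf <- sr > (r + rho[i])
    h[engulf] <- h[engulf] + (1 / rho[i] - 1 / L[engulf])
    I[i] <- sum(h)
  }
  psi <- I * rho
  1 / (1 / rho - tanh(OBC_ALPHA * psi - OBC_BETA * psi^2 +
                        OBC_GAMMA * psi^3) / rho)
}

gb_energy_terms <- function(xyz, charges, topology, kappa) {
  R <- born_radii(xyz, topology)
  n <- nrow(xyz)
  kc <- pepconf_constants[["coulomb"]]
  diel <- function(f) (1 - exp(-kappa * f) / EPS_OUT)
  self <- -0.5 * kc * charges^2 * diel(R) / R
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  r <- pair_dist(xyz, ij)
  RiRj <- R[ij[, 1]] * R[ij[, 2]]
  f <- sqrt(r^2 + RiRj * exp(-r^2 / (4 * RiRj)))
  pairw <- -kc * charges[ij[, 1]] * charges[ij[, 2]] * diel(f) / f
  list(total = sum(self) + sum(pairw), self = self, pair_ij = ij,
       pair_e = pairw)
}

#' Single-point energy of one coordinate frame
#'
#' Evaluates the force-field energy terms on a frame: harmonic bonds and
#' angles, cosine torsions, 12-6 Lennard-Jones and Coulomb electrostatics
#' over non-excluded pairs (1-4 pairs scaled by the AMBER factors), and
#' the OBC Generalized Born solvation energy with Debye-Hueckel salt
#' screening.
#'
#' @param frame single-frame [coord_frames] or n x 3 matrix, atom order
#'   matching the topology.
#' @param topology a [topology].
#' @param charge_set name of the charge set to use.
#' @param ionic_strength mol/L (salt screening of the GB term).
#' @param temperature K (enters the Debye constant only).
#' @return object of class `energy_breakdown`: named list with `bond`,
#'   `angle`, `dihedral_t`, `vdw`, `vdw14`, `eel`, `eel14`, `egb` and
#'   their sum `potential`, kcal/mol.
#' @export
single_point <- function(frame, topology, charge_set = "protonated",
                         ionic_strength = 0.1, temperature = 300) {
  xyz <- as_xyz(frame)
  if (nrow(xyz) != nrow(topology$atoms))
    stop("coordinates and topology atom counts differ")
  q <- charge_vector(topology, charge_set)
  pt <- pair_tables(topology)
  check_overlaps(xyz, rbind(pt$nb, pt$p14))

  b <- topology$bonds
  e_bond <- sum(b$k * (pair_dist(xyz, cbind(b$ai, b$aj)) - b$r0)^2)
  a <- topology$angles
  v1 <- xyz[a$ai, , drop = FALSE] - xyz[a$aj, , drop = FALSE]
  v2 <- xyz[a$ak, , drop = FALSE] - xyz[a$aj, , drop = FALSE]
  th <- acos(pmax(-1, pmin(1, rowSums(v1 * v2) /
                             sqrt(rowSums(v1^2) * rowSums(v2^2))))) * 180 / pi
  e_angle <- sum(a$k * ((th - a$theta0) * pi / 180)^2)
  tt <- topology$torsions
  e_tor <- 0
  if (nrow(tt)) {
    phi <- torsion_rows(xyz[tt$ai, , drop = FALSE], xyz[tt$aj, , drop = FALSE],
                        xyz[tt$ak, , drop = FALSE], xyz[tt$al, , drop = FALSE])
    e_tor <- sum(tt$vn / 2 * (1 + cos((tt$n * phi - tt$gamma) * pi / 180)))
  }

  lj <- function(ij, scale) {
    if (!nrow(ij)) return(0)
    r <- pair_dist(xyz, ij)
    rmin <- topology$atoms$lj_radius[ij[, 1]] + topology$atoms$lj_radius[ij[, 2]]
    eps <- sqrt(topology$atoms$lj_epsilon[ij[, 1]] *
                  topology$atoms$lj_epsilon[ij[, 2]])
    s6 <- (rmin / r)^6
    sum(eps * (s6^2 - 2 * s6)) / scale
  }
  coul <- function(ij, scale) {
    if (!nrow(ij)) return(0)
    r <- pair_dist(xyz, ij)
    sum(pepconf_constants[["coulomb"]] * q[ij[, 1]] * q[ij[, 2]] / r) / scale
  }
  kappa <- debye_kappa(ionic_strength, temperature)
  egb <- gb_energy_terms(xyz, q, topology, kappa)$total

  out <- list(bond = e_bond, angle = e_angle, dihedral_t = e_tor,
              vdw = lj(pt$nb, 1), vdw14 = lj(pt$p14, SCNB),
              eel = coul(pt$nb, 1), eel14 = coul(pt$p14, SCEE), egb = egb)
  out$potential <- sum(unlist(out))
  structure(out, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy_breakdown (kcal/mol):\n")
  print(round(unlist(unclass(x)), 4))
  invisible(x)
}

as_xyz <- function(frame) {
  if (inherits(frame, "coord_frames")) {
    if (n_frames(frame) != 1)
      stop("pass a single frame (use single_point_series for stacks)")
    return(frame_matrix(frame, 1))
  }
  stopifnot(is.matrix(frame), ncol(frame) == 3)
  frame
}

charge_vector <- function(topology, charge_set) {
  if (!charge_set %in% names(topology$charge_sets))
    stop("unknown charge set '", charge_set, "'; available: ",
         paste(names(topology$charge_sets), collapse = ", "))
  topology$charge_sets[[charge_set]]$charges
}

check_overlaps <- function(xyz, ij) {
  if (!nrow(ij)) return(invisible())
  r <- pair_dist(xyz, ij)
  if (any(r < 1e-6)) {
    k <- which(r < 1e-6)[1]
    stop(sprintf("singularity error: atoms %d and %d overlap (r = %g A)",
                 ij[k, 1], ij[k, 2], r[k]))
  }
}

#' Single-point energies over a frame stack
#'
#' @param frames a [coord_frames] stack.
#' @inheritParams single_point
#' @param frame_interval ps, recorded on the output.
#' @return an `energy_series` data frame (one row per frame) with the
#'   [single_point] terms and `potential`.
#' @export
single_point_series <- function(frames, topology, charge_set = "protonated",
                                ionic_strength = 0.1, temperature = 300,
                                frame_interval = 2) {
  rows <- lapply(seq_len(n_frames(frames)), function(i)
    unlist(unclass(single_point(frame_matrix(frames, i), topology,
                                charge_set, ionic_strength, temperature))))
  out <- as.data.frame(do.call(rbind, rows))
  energy_series(out, frame_interval = frame_interval)
}

#' Construct / validate an energy time series
#'
#' A data frame of named per-frame energy terms (kcal/mol).  When both
#' `potential` and its component terms are present, their consistency is
#' verified to 1e-4 kcal/mol.
#'
#' @param df data frame of energy columns.
#' @param frame_interval sampling interval, ps.
#' @return `energy_series` data frame.
#' @export
energy_series <- function(df, frame_interval = 2) {
  comp <- intersect(c("bond", "angle", "dihedral_t", "vdw", "vdw14",
                      "eel", "eel14", "egb"), names(df))
  if ("potential" %in% names(df) && length(comp) == 8) {
    resid <- df$potential - rowSums(df[comp])
    if (any(abs(resid) > 1e-4))
      stop(sprintf(
        "energy series validation: potential differs from term sum by %g",
        max(abs(resid))))
  }
  structure(df, frame_interval = frame_interval,
            class = c("energy_series", "data.frame"))
}

#' Read / write energy series CSV
#'
#' @param path CSV file with one column per energy term.
#' @param frame_interval ps.
#' @return an [energy_series].
#' @export
read_energy_series <- function(path, frame_interval = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  energy_series(utils::read.csv(path), frame_interval)
}

#' @rdname read_energy_series
#' @param x an [energy_series].
#' @export
write_energy_series <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decompose electrostatics into backbone and side-chain contributions
#'
#' Splits the 1-4 and long-range Coulomb terms by atom group; cap atoms
#' count as backbone.  Two assignment rules for backbone/side-chain cross
#' pairs are available:
#'
#' * `"half"` (default): each pair energy is split half to each atom's
#'   group, so `eel_bb + eel_sc` equals the total exactly;
#' * `"separate"`: `eel_bb`/`eel_sc` sum only pairs internal to the
#'   group (the semantics of a masked trajectory analysis - backbone
#'   values then depend on backbone charges alone) and the cross terms
#'   are reported as `eel_cross`/`eel14_cross`.
#'
#' @param frame single frame (or [coord_frames] stack: one row per frame).
#' @param topology a [topology]; every atom must carry a group label.
#' @param charge_set charge-set name.
#' @param cross cross-pair assignment rule.
#' @return data frame with columns `eel14_bb`, `eel14_sc`, `eel_bb`,
#'   `eel_sc` (plus `eel14_cross`, `eel_cross` for `"separate"`), one row
#'   per frame.
#' @export
decompose_electrostatics <- function(frame, topology,
                                     charge_set = "protonated",
                                     cross = c("half", "separate")) {
  cross <- match.arg(cross)
  if (anyNA(topology$atoms$group))
    stop("validation error: unlabeled atom group")
  q <- charge_vector(topology, charge_set)
  grp <- ifelse(topology$atoms$group == "sidechain", "sc", "bb")
  pt <- pair_tables(topology)
  frames <- if (inherits(frame, "coord_frames")) frame
            else coord_frames(as_xyz(frame))
  kc <- pepconf_constants[["coulomb"]]
  one <- function(xyz, ij, scale) {
    if (!nrow(ij)) return(c(bb = 0, sc = 0, cross = 0))
    e <- kc * q[ij[, 1]] * q[ij[, 2]] / pair_dist(xyz, ij) / scale
    g1 <- grp[ij[, 1]]; g2 <- grp[ij[, 2]]
    if (cross == "half")
      c(bb = sum(e * ((g1 == "bb") + (g2 == "bb")) / 2),
        sc = sum(e * ((g1 == "sc") + (g2 == "sc")) / 2), cross = 0)
    else
      c(bb = sum(e[g1 == "bb" & g2 == "bb"]),
        sc = sum(e[g1 == "sc" & g2 == "sc"]),
        cross = sum(e[g1 != g2]))
  }
  rows <- lapply(seq_len(n_frames(frames)), function(i) {
    xyz <- frame_matrix(frames, i)
    e14 <- one(xyz, pt$p14, SCEE)
    enb <- one(xyz, pt$nb, 1)
    r <- c(eel14_bb = e14[["bb"]], eel14_sc = e14[["sc"]],
           eel_bb = enb[["bb"]], eel_sc = enb[["sc"]])
    if (cross == "separate")
      r <- c(r, eel14_cross = e14[["cross"]], eel_cross = enb[["cross"]])
    r
  })
  as.data.frame(do.call(rbind, rows))
}

#' Normalized energy histograms
#'
#' Per-term density histograms (unit area) over an energy series, on a
#' common bin width.
#'
#' @param energy_series an [energy_series] (>= 2 frames).
#' @param bin_width kcal/mol.
#' @param terms which columns to histogram; default all numeric columns.
#' @return named list of `energy_histogram` objects (`breaks`, `density`,
#'   `bin_width`).
#' @export
energy_distributions <- function(energy_series, bin_width = 1,
                                 terms = NULL) {
  stopifnot(nrow(energy_series) >= 2)
  if (is.null(terms))
    terms <- names(energy_series)[vapply(energy_series, is.numeric, TRUE)]
  out <- lapply(terms, function(tm)
    density_histogram(energy_series[[tm]], bin_width))
  stats::setNames(out, terms)
}

#' Build a unit-area histogram on a fixed bin width
#'
#' Bins are anchored at multiples of `bin_width` so histograms of
#' different samples share a binning and can be compared with
#' [distribution_overlap].
#'
#' @param x numeric sample.
#' @param bin_width bin width (same units as `x`).
#' @return object of class `energy_histogram`.
#' @export
density_histogram <- function(x, bin_width) {
  stopifnot(bin_width > 0)
  lo <- floor(min(x) / bin_width)
  hi <- floor(max(x) / bin_width) + 1
  breaks <- seq(lo, hi) * bin_width
  cnt <- tabulate(pmin(floor(x / bin_width) - lo + 1, length(breaks) - 1),
                  nbins = length(breaks) - 1)
  structure(list(breaks = breaks, density = cnt / (sum(cnt) * bin_width),
                 bin_width = bin_width),
            class = "energy_histogram")
}

#' @export
print.energy_histogram <- function(x, ...) {
  cat(sprintf("energy_histogram: %d bins of %g on [%g, %g], area %g\n",
              length(x$density), x$bin_width, min(x$breaks), max(x$breaks),
              sum(x$density) * x$bin_width))
  invisible(x)
}

#' @export
plot.energy_histogram <- function(x, ...) {
  mid <- x$breaks[-length(x$breaks)] + x$bin_width / 2
  graphics::plot(mid, x$density, type = "s", xlab = "energy (kcal/mol)",
                 ylab = "density", ...)
  invisible(x)
}

#' Overlap coefficient of two normalized histograms
#'
#' \eqn{\sum_b \min(f_A(b), f_B(b)) \Delta} over a common binning grid:
#' 1 for identical distributions, 0 for disjoint supports.  Histograms
#' built by [density_histogram] with the same bin width are automatically
#' aligned (bins are anchored at multiples of the width).
#'
#' @param histA,histB `energy_histogram` objects with equal bin width.
#' @return overlap coefficient in `[0, 1]`.
#' @export
distribution_overlap <- function(histA, histB) {
  if (abs(histA$bin_width - histB$bin_width) > 1e-12)
    stop("validation error: histograms use different bin widths")
  w <- histA$bin_width
  lo <- min(histA$breaks[1], histB$breaks[1])
  at <- function(h) round((h$breaks[1] - lo) / w)
  if (max(abs(c(histA$breaks[1], histB$breaks[1]) / w -
                round(c(histA$breaks[1], histB$breaks[1]) / w))) > 1e-8)
    stop("validation error: histogram binning grids are not aligned")
  n <- max(at(histA) + length(histA$density), at(histB) + length(histB$density))
  dens <- function(h) {
    d <- numeric(n); d[at(h) + seq_along(h$density)] <- h$density; d
  }
  sum(pmin(dens(histA), dens(histB))) * w
}
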