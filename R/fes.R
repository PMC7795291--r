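#' Bin an angle pair onto a periodic grid
#'
#' Assigns each sample to exactly one cell of a `(360/spacing)^2` grid over
#' the torus, by the half-open rule: the bin index of angle `a` (after
#' wrapping) is `floor((a + 180)/spacing)`, so a cell owns its lower edge.
#' The paper-scale default is a 1 degree grid.
#'
#' @param series a [dihedral_series] (or a two-column matrix of angles in
#'   degrees).
#' @param axis_pair character vector of two angle names, e.g.
#'   `c("phi","psi")` or `c("theta","psi")`.
#' @param spacing grid spacing in degrees; must divide 360.
#' @param monomer restrict to one monomer (1 or 2); `NULL` uses all rows.
#' @return object of class `count_grid`: integer `counts` matrix indexed
#'   `[x, y]`, cell-center vectors `x`, `y`, `axes`, `spacing`, `n_total`.
#' @export
bin_angles <- function(series, axis_pair = c("phi", "psi"), spacing = 1,
                       monomer = NULL) {
  if (360 %% spacing != 0)
    stop("configuration error: spacing must divide 360 (got ", spacing, ")")
  ang <- if (is.matrix(series)) series
         else series_axes(series, axis_pair, monomer)
  if (nrow(ang) == 0) stop("series is empty")
  nb <- as.integer(360 / spacing)
  ix <- floor((wrap_angle(ang[, 1]) + 180) / spacing)
  iy <- floor((wrap_angle(ang[, 2]) + 180) / spacing)
  counts <- matrix(tabulate(ix * nb + iy + 1L, nbins = nb * nb),
                   nrow = nb, ncol = nb, byrow = TRUE)
  centers <- -180 + (seq_len(nb) - 0.5) * spacing
  structure(list(counts = counts, x = centers, y = centers, axes = axis_pair,
                 spacing = spacing, n_total = nrow(ang)),
            class = "count_grid")
}

#' @export
print.count_grid <- function(x, ...) {
  cat(sprintf("count_grid: %dx%d cells (%g deg) over %s/%s, n = %d\n",
              nrow(x$counts), ncol(x$counts), x$spacing,
              x$axes[1], x$axes[2], x$n_total))
  invisible(x)
}

#' Boltzmann inversion of a population grid
#'
#' Converts cell populations to relative Gibbs free energies,
#' \deqn{\Delta G_i = -k_B T \ln(n_i / n_{max}),}
#' with kB = 0.0019872041 kcal/(mol K).  The most populated cell defines
#' the zero; empty cells are masked (infinite free energy), never
#' interpolated.
#'
#' @param count_grid a [count_grid].
#' @param temperature simulation temperature, K.
#' @return object of class `fes_grid` with `free_energy` matrix (kcal/mol,
#'   `Inf` where masked), logical `mask`, grid geometry, `temperature`.
#' @export
boltzmann_invert <- function(count_grid, temperature = 300) {
  stopifnot(inherits(count_grid, "count_grid"))
  if (temperature <= 0) stop("temperature must be positive")
  n <- count_grid$counts
  nmax <- max(n)
  if (nmax < 1) stop("degenerate input: all cells are empty")
  kB <- pepconf_constants[["kB"]]
  fe <- matrix(Inf, nrow(n), ncol(n))
  occ <- n > 0
  fe[occ] <- -kB * temperature * log(n[occ] / nmax)
  fe[n == nmax] <- 0   # exact zero at the reference cell
  structure(list(free_energy = fe, mask = !occ, x = count_grid$x,
                 y = count_grid$y, axes = count_grid$axes,
                 spacing = count_grid$spacing, temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf(
    "fes_grid: %dx%d cells (%g deg) over %s/%s at %g K; max %.3f kcal/mol, %d masked\n",
    nrow(x$free_energy), ncol(x$free_energy), x$spacing, x$axes[1], x$axes[2],
    x$temperature, max(x$free_energy[!x$mask]), sum(x$mask)))
  invisible(x)
}

#' Plot a free-energy surface
#'
#' Filled image of the surface with contour lines at [contour_levels]
#' spacing (default 0.6 kcal/mol, the conventional Ramachandran contour
#' increment).  Masked cells are left white.
#'
#' @param x a [fes_grid].
#' @param increment contour increment, kcal/mol.
#' @param ... passed to [graphics::image].
#' @return `x`, invisibly.
#' @export
plot.fes_grid <- function(x, increment = 0.6, ...) {
  z <- x$free_energy
  z[x$mask] <- NA
  pal <- grDevices::hcl.colors(64, "viridis", rev = TRUE)
  graphics::image(x$x, x$y, z, col = pal, useRaster = TRUE,
                  xlab = x$axes[1], ylab = x$axes[2], ...)
  graphics::contour(x$x, x$y, z, levels = contour_levels(x, increment),
                    add = TRUE, drawlabels = FALSE)
  invisible(x)
}

#' Contour levels for a free-energy surface
#'
#' Levels `0, inc, 2*inc, ...` up to the largest unmasked free energy.
#'
#' @param fes_grid a [fes_grid].
#' @param increment level increment, kcal/mol (> 0).
#' @return numeric vector of levels.
#' @export
contour_levels <- function(fes_grid, increment = 0.6) {
  stopifnot(inherits(fes_grid, "fes_grid"))
  if (increment <= 0) stop("increment must be positive")
  mx <- max(fes_grid$free_energy[!fes_grid$mask])
  seq(0, mx, by = increment)
}

#' Locate free-energy minima on a coarsened grid
#'
#' Rebins the series at a wider spacing (default 2 degrees, which damps
#' spurious minima from counting noise), Boltzmann-inverts, and returns
#' every unmasked cell strictly lower than all 8 toroidal neighbours
#' (periodic wrap across the +-180 seam; ties produce no minimum).
#'
#' @param series a [dihedral_series] or two-column angle matrix.
#' @param axis_pair,monomer as in [bin_angles].
#' @param temperature K.
#' @param spacing minima-search grid spacing, degrees.
#' @param min_separation degrees; when positive, minima are merged to
#'   basin level: scanning in depth order, any minimum within this
#'   toroidal distance of an already-kept (deeper) one is dropped.  At
#'   fine grid spacings counting noise produces clusters of shallow local
#'   minima inside a single basin; a separation of the order of the basin
#'   width reduces the list to one entry per basin.
#' @return data frame of class `fes_minima`, rows sorted by free energy:
#'   cell centers (named by axes), `free_energy`, `rank`.
#' @export
locate_minima <- function(series, axis_pair = c("phi", "psi"),
                          temperature = 300, spacing = 2, monomer = NULL,
                          min_separation = 0) {
  cg <- bin_angles(series, axis_pair, spacing, monomer)
  fes <- boltzmann_invert(cg, temperature)
  is_min <- local_minima_mask(fes$free_energy)
  idx <- which(is_min, arr.ind = TRUE)
  out <- data.frame(a1 = fes$x[idx[, 1]], a2 = fes$y[idx[, 2]],
                    free_energy = fes$free_energy[idx])
  out <- out[order(out$free_energy, out$a1, out$a2), , drop = FALSE]
  if (min_separation > 0 && nrow(out) > 1) {
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      kept <- which(keep)
      d <- pmax(abs(wrap_angle(out$a1[kept] - out$a1[i])),
                abs(wrap_angle(out$a2[kept] - out$a2[i])))
      keep[i] <- !length(kept) || all(d >= min_separation)
    }
    out <- out[keep, , drop = FALSE]
  }
  names(out)[1:2] <- fes$axes
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("fes_minima", "data.frame")
  out
}

# strict 8-neighbour dominance on a torus.  A minimum must be unmasked,
# strictly below all 8 neighbours, and have no masked neighbour: isolated
# occupied cells on the sparse fringe of a basin would otherwise register
# as spurious minima, the artifact the coarser search grid is meant to
# suppress.
local_minima_mask <- function(fe) {
  nb <- nrow(fe)
  sh <- function(m, di, dj) {
    i <- ((seq_len(nb) - 1 + di) %% nb) + 1
    j <- ((seq_len(nb) - 1 + dj) %% nb) + 1
    m[i, j, drop = FALSE]
  }
  res <- is.finite(fe)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbv <- sh(fe, di, dj)
    res <- res & is.finite(nbv) & (fe < nbv)
  }
  res
}
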