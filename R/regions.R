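#' Load a nine-region Ramachandran table
#'
#' A region table partitions the phi/psi torus into the nine classical
#' conformational regions (C5, PII, alphaD, beta2, C7axial, alphaL,
#' alpha-prime, alphaR, C7eq).  Regions are polygons in an unwrapped
#' chart (vertices may lie outside `[-180, 180)` so that seam-crossing
#' regions stay contiguous), listed in priority order: a point on a
#' shared boundary belongs to the earlier region.
#'
#' The shipped default table (`system.file("extdata",
#' "regions_default.json", package = "pepconf")`) is a documented
#' rectangular-partition convention placing the canonical centers of each
#' region (e.g. PII near (-75, 150), alphaR near (-57, -47)); any
#' user-supplied table with full coverage may be used instead.
#'
#' @param path JSON file; default is the shipped table.
#' @param validate check full coverage of the torus by rasterizing at
#'   `4` degree resolution (a gap raises a validation error at load time).
#' @return object of class `region_table`.
#' @export
read_region_table <- function(path = NULL, validate = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "regions_default.json", package = "pepconf")
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  regions <- lapply(j$regions, function(r) {
    v <- r$vertices
    if (!is.matrix(v)) v <- do.call(rbind, lapply(v, as.numeric))
    list(label = r$label, vertices = v)
  })
  labels <- vapply(regions, `[[`, "", "label")
  expected <- c("C5", "PII", "alphaD", "beta2", "C7axial", "alphaL",
                "alphaPrime", "alphaR", "C7eq")
  if (!setequal(labels, expected))
    stop("region table validation: labels must be exactly the nine names; got ",
         paste(labels, collapse = ", "))
  x <- structure(list(regions = regions, labels = labels),
                 class = "region_table")
  if (validate) {
    g <- seq(-178, 180, by = 4)
    pts <- expand.grid(phi = g, psi = g)
    lab <- classify_conformers(pts$phi, pts$psi, x, .check = TRUE)
    if (anyNA(lab))
      stop("region table validation: coverage gap at e.g. (",
           pts$phi[which(is.na(lab))[1]], ", ", pts$psi[which(is.na(lab))[1]], ")")
  }
  x
}

#' @export
print.region_table <- function(x, ...) {
  cat("region_table with priority order:",
      paste(x$labels, collapse = " > "), "\n")
  invisible(x)
}

#' Classify backbone torsions into the nine conformational regions
#'
#' Wraps the angles and tests region polygons in priority order with a
#' toroidal, boundary-inclusive point-in-polygon test; each point receives
#' exactly one label.
#'
#' @param phi,psi numeric vectors, degrees.
#' @param table a [region_table] (default: shipped table).
#' @param .check internal; return `NA` instead of erroring on a gap.
#' @return factor of region labels, levels in the table's priority order.
#' @export
classify_conformers <- function(phi, psi, table = read_region_table(),
                                .check = FALSE) {
  stopifnot(all(is.finite(phi)), all(is.finite(psi)),
            length(phi) == length(psi))
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  lab <- rep(NA_character_, length(phi))
  for (r in table$regions) {
    un <- which(is.na(lab))
    if (!length(un)) break
    hit <- point_in_polygon_torus(phi[un], psi[un], r$vertices)
    lab[un[hit]] <- r$label
  }
  if (anyNA(lab) && !.check)
    stop("region table validation: point not covered by any region")
  factor(lab, levels = table$labels)
}

# boundary-inclusive even-odd test, replicated over the 9 torus images
point_in_polygon_torus <- function(px, py, verts) {
  inside <- logical(length(px))
  rx <- range(verts[, 1]); ry <- range(verts[, 2])
  for (dx in c(-360, 0, 360)) for (dy in c(-360, 0, 360)) {
    if (rx[1] + dx > 180 || rx[2] + dx < -180) next
    if (ry[1] + dy > 180 || ry[2] + dy < -180) next
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- point_in_polygon(px[todo] - dx, py[todo] - dy, verts)
  }
  inside
}

point_in_polygon <- function(px, py, verts) {
  nv <- nrow(verts)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # boundary test: point within segment bbox and cross-product ~ 0
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg <- abs(cr) < 1e-9 &
      px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Per-monomer populations of the nine conformational regions
#'
#' Classifies every frame and reports, per monomer, the fraction of frames
#' in each region, plus the aggregated view used in stacked-bar population
#' comparisons: the four dominant regions (PII, alphaR, C7eq, C5) reported
#' individually and beta2, alphaPrime, alphaD, alphaL, C7axial grouped as
#' `others`.
#'
#' @param series a [dihedral_series].
#' @param table a [region_table].
#' @return object of class `region_populations`: list with `fractions`
#'   (matrix label x monomer), `aggregated` (matrix with rows PII, alphaR,
#'   C7eq, C5, others), `n_samples` per monomer.
#' @export
region_populations <- function(series, table = read_region_table()) {
  stopifnot(inherits(series, "dihedral_series"))
  if (nrow(series) == 0) stop("series is empty")
  mons <- sort(unique(series$monomer))
  frac <- sapply(mons, function(m) {
    s <- series[series$monomer == m, ]
    tab <- table(classify_conformers(s$phi, s$psi, table))
    as.numeric(tab) / nrow(s)
  })
  frac <- matrix(frac, ncol = length(mons),
                 dimnames = list(table$labels, paste0("monomer", mons)))
  main <- c("PII", "alphaR", "C7eq", "C5")
  agg <- rbind(frac[main, , drop = FALSE],
               others = colSums(frac[setdiff(table$labels, main), ,
                                     drop = FALSE]))
  structure(list(fractions = frac, aggregated = agg,
                 n_samples = as.integer(table(series$monomer))),
            class = "region_populations")
}

#' @export
print.region_populations <- function(x, digits = 3, ...) {
  cat("region_populations (n =", paste(x$n_samples, collapse = ", "), ")\n")
  print(round(x$aggregated, digits))
  invisible(x)
}

#' Plot region populations as stacked bars
#'
#' @param x a [region_populations].
#' @param ... passed to [graphics::barplot].
#' @export
plot.region_populations <- function(x, ...) {
  graphics::barplot(x$aggregated, legend.text = rownames(x$aggregated),
                    ylab = "population fraction", ...)
  invisible(x)
}

#' Compare two region-population vectors
#'
#' Reports per-label absolute differences and the total variation
#' distance, `TV = 0.5 * sum |pA - pB|`, a `[0, 1]` summary of how far two
#' conformational profiles are (0 = identical sampling, 1 = disjoint).
#'
#' @param popA,popB named numeric fraction vectors over the same label
#'   set, or single-monomer [region_populations] columns.
#' @return list with `per_label` (named absolute differences) and `tv`.
#' @export
compare_populations <- function(popA, popB) {
  a <- as_pop_vector(popA); b <- as_pop_vector(popB)
  if (!setequal(names(a), names(b)))
    stop("validation error: population label sets differ")
  b <- b[names(a)]
  d <- abs(a - b)
  list(per_label = d, tv = 0.5 * sum(d))
}

as_pop_vector <- function(p) {
  if (inherits(p, "region_populations")) {
    if (ncol(p$fractions) != 1)
      stop("pass a single-monomer population (subset the fractions matrix)")
    return(stats::setNames(p$fractions[, 1], rownames(p$fractions)))
  }
  if (is.null(names(p))) stop("population vectors must be named")
  p
}
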