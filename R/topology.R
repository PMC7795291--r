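#' Construct a peptide topology
#'
#' A `topology` bundles everything the energetics stage needs besides
#' coordinates: atoms with group labels (backbone / sidechain / cap),
#' Lennard-Jones and Generalized Born parameters, one partial-charge set
#' per protonation state, bonded terms, and the 1-2/1-3 exclusion and 1-4
#' pair lists.  Charges are in elementary-charge units, distances in
#' Angstrom, energies in kcal/mol.
#'
#' `gb_radius` is the offset-corrected intrinsic Born radius used directly
#' by the OBC model (an isolated atom's effective radius equals it).
#'
#' @param atoms data frame with columns `name`, `residue_index`,
#'   `residue_name`, `group` (one of backbone/sidechain/cap), `lj_radius`
#'   (Rmin/2, A), `lj_epsilon` (kcal/mol), `gb_radius` (A), `gb_screen`.
#' @param charge_sets named list; each element a list with `charges`
#'   (numeric, one per atom) and `net_charge` (declared total, e).
#' @param bonds data frame `ai, aj, k, r0` (k in kcal/mol/A^2).
#' @param angles data frame `ai, aj, ak, k, theta0` (theta0 degrees).
#' @param torsions data frame `ai, aj, ak, al, vn, n, gamma` (gamma degrees).
#' @param exclusions data frame `ai, aj` of 1-2 and 1-3 pairs.
#' @param pairs14 data frame `ai, aj` of 1-4 pairs.
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, charge_sets, bonds, angles, torsions,
                     exclusions, pairs14) {
  x <- structure(list(atoms = atoms, charge_sets = charge_sets,
                      bonds = bonds, angles = angles, torsions = torsions,
                      exclusions = exclusions, pairs14 = pairs14),
                 class = "topology")
  validate_topology(x)
  x
}

#' Validate topology invariants
#'
#' Checks index bounds of all bonded terms and pair lists, one charge per
#' atom per set, disjointness of exclusion and 1-4 lists, and that each
#' charge set sums to its declared net charge within 1e-6 e.
#'
#' @param x a [topology].
#' @return `x`, invisibly; stops with a validation error otherwise.
#' @export
validate_topology <- function(x) {
  n <- nrow(x$atoms)
  need_atom_cols <- c("name", "residue_index", "residue_name", "group",
                      "lj_radius", "lj_epsilon", "gb_radius", "gb_screen")
  missing_cols <- setdiff(need_atom_cols, names(x$atoms))
  if (length(missing_cols))
    stop("topology validation: atoms table lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!all(x$atoms$group %in% c("backbone", "sidechain", "cap")))
    stop("topology validation: atom group labels must be backbone/sidechain/cap")
  idx <- c(x$bonds$ai, x$bonds$aj, x$angles$ai, x$angles$aj, x$angles$ak,
           x$torsions$ai, x$torsions$aj, x$torsions$ak, x$torsions$al,
           x$exclusions$ai, x$exclusions$aj, x$pairs14$ai, x$pairs14$aj)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop(sprintf("topology validation: bonded term references atom %d of %d",
                 max(idx), n))
  pk <- function(p) paste(pmin(p$ai, p$aj), pmax(p$ai, p$aj))
  overlap <- intersect(pk(x$exclusions), pk(x$pairs14))
  if (length(overlap))
    stop("topology validation: pair(s) in both exclusions and pairs14: ",
         paste(overlap, collapse = "; "))
  for (lbl in names(x$charge_sets)) {
    cs <- x$charge_sets[[lbl]]
    if (length(cs$charges) != n)
      stop(sprintf("topology validation: charge set '%s' has %d charges for %d atoms",
                   lbl, length(cs$charges), n))
    dq <- sum(cs$charges) - cs$net_charge
    if (abs(dq) > 1e-6)
      stop(sprintf(
        "topology validation: charge set '%s' sums to %.6f, declared net %.6f (discrepancy %.2e e)",
        lbl, sum(cs$charges), cs$net_charge, dq))
  }
  invisible(x)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms (%s), %d bonds, %d angles, %d torsions\n",
              nrow(x$atoms),
              paste(sprintf("%d %s", table(x$atoms$group),
                            names(table(x$atoms$group))), collapse = ", "),
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  cat("charge sets:", paste(sprintf("%s (net %+g)", names(x$charge_sets),
        vapply(x$charge_sets, function(cs) cs$net_charge, 0)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a topology from its JSON transport document
#'
#' The schema mirrors the [topology] constructor: objects `atoms` (array of
#' records), `charge_sets` (map label -> {charges, net_charge}), `bonds`,
#' `angles`, `torsions`, `exclusions`, `pairs14`.  All invariants are
#' verified on load.
#'
#' @param path JSON file.
#' @return a [topology].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cs <- lapply(j$charge_sets, function(s)
    list(charges = as.numeric(s$charges), net_charge = as.numeric(s$net_charge)))
  as_pairs <- function(d) {
    if (is.null(d) || length(d) == 0) return(data.frame(ai = integer(), aj = integer()))
    as.data.frame(d)
  }
  topology(atoms = as.data.frame(j$atoms), charge_sets = cs,
           bonds = as.data.frame(j$bonds), angles = as.data.frame(j$angles),
           torsions = as.data.frame(j$torsions),
           exclusions = as_pairs(j$exclusions), pairs14 = as_pairs(j$pairs14))
}

#' Write a topology as JSON
#'
#' @param x a [topology].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(x, path) {
  stopifnot(inherits(x, "topology"))
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
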