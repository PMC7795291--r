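# Idealized ACE-X-X-NME builder.  Geometry comes from an internal-coordinate
# template (ideal bond lengths/angles, PII-like backbone); bonded force-field
# parameters are taken from the built geometry (r0/theta0 at the template),
# so the template sits at the bonded-energy minimum.  Charge sets are
# schematic stand-ins with exact net charges, never a claim of force-field
# fidelity.

# place atom D bonded to c: |cD| = bond, angle(b,c,D) = angle,
# torsion(a,b,c,D) = torsion (degrees, IUPAC sign)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- -torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c + bond * (-cos(ang) * bc + sin(ang) * cos(tor) * m +
                sin(ang) * sin(tor) * n)
}

# side-chain templates: z-matrix rows (name, parent, ref2, ref3, bond,
# angle, torsion) and schematic charges for the protonated / matched
# deprotonated states.  "@" prefixes resolve within the residue; "CPREV"
# is the preceding carbonyl carbon.
sidechain_templates <- list(
  ASP = list(
    zmat = list(
      list("CG",  "@CB", "@CA", "@N",   1.522, 114.0, 65),
      list("OD1", "@CG", "@CB", "@CA",  1.250, 117.0, 0),
      list("OD2", "@CG", "@CB", "@CA",  1.250, 117.0, 180),
      list("HD2", "@OD2", "@CG", "@OD1", 0.960, 113.0, 0)),  # syn-O2 proton
    elements = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O", HD2 = "H"),
    q_prot   = c(CG = 0.6462, OD1 = -0.5554, OD2 = -0.6376, HD2 = 0.4747),
    q_deprot = c(CG = 0.7990, OD1 = -0.8010, OD2 = -0.8010, HD2 = 0.0),
    net_prot = 0, net_deprot = -1, theta_atom = "CG"),
  LYS = list(
    zmat = list(
      list("CG", "@CB", "@CA", "@N",  1.526, 110.5, 65),
      list("CD", "@CG", "@CB", "@CA", 1.526, 110.5, 180),
      list("CE", "@CD", "@CG", "@CB", 1.526, 110.5, 180),
      list("NZ", "@CE", "@CD", "@CG", 1.470, 110.0, 180),
      list("HZ", "@NZ", "@CE", "@CD", 1.010, 109.0, 180)),
    elements = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N", HZ = "H"),
    q_prot   = c(CG = -0.05, CD = -0.05, CE = 0.20, NZ = -0.40, HZ = 0.90),
    q_deprot = c(CG = -0.048, CD = -0.06, CE = 0.30, NZ = -0.90, HZ = 0.60),
    net_prot = 1, net_deprot = 0, theta_atom = "NZ"),
  HIS = list(
    zmat = list(
      list("CG",  "@CB",  "@CA", "@N",  1.500, 113.0, 65),
      list("ND1", "@CG",  "@CB", "@CA", 1.380, 122.0, 0),
      list("CD2", "@CG",  "@CB", "@CA", 1.360, 122.0, 180),
      list("CE1", "@ND1", "@CG", "@CB", 1.320, 108.0, 180),
      list("NE2", "@CD2", "@CG", "@CB", 1.370, 108.0, 180),
      list("HD1", "@ND1", "@CG", "@CB", 1.010, 125.0, 0),
      list("HE2", "@NE2", "@CD2", "@CG", 1.010, 125.0, 180)),
    elements = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C", CE1 = "C",
                 NE2 = "N", HD1 = "H", HE2 = "H"),
    q_prot   = c(CG = 0.00, ND1 = -0.15, CD2 = -0.11, CE1 = 0.16,
                 NE2 = -0.15, HD1 = 0.39, HE2 = 0.39),
    q_deprot = c(CG = -0.02, ND1 = -0.38, CD2 = 0.13, CE1 = 0.19,
                 NE2 = -0.57, HD1 = 0.36, HE2 = 0.0),  # delta tautomer
    net_prot = 1, net_deprot = 0, theta_atom = "CE1",
    extra_bonds = list(c("CE1", "NE2"))),   # imidazole ring closure
  CYS = list(
    zmat = list(
      list("SG", "@CB", "@CA", "@N",  1.810, 114.0, 65),
      list("HG", "@SG", "@CB", "@CA", 1.340,  96.0, 180)),
    elements = c(CB = "C", SG = "S", HG = "H"),
    q_prot   = c(SG = -0.31, HG = 0.19),
    q_deprot = c(SG = -0.88, HG = 0.0),
    net_prot = 0, net_deprot = -1, theta_atom = "SG")
)

# per-element nonbonded / GB parameters (Rmin/2 A, eps kcal/mol,
# intrinsic Born radius A, HCT screening factor)
element_params <- data.frame(
  element = c("C", "N", "O", "H", "S"),
  lj_radius = c(1.9080, 1.8240, 1.6612, 0.6000, 2.0000),
  lj_epsilon = c(0.0860, 0.1700, 0.2100, 0.0157, 0.2500),
  gb_radius = c(1.70, 1.55, 1.50, 1.20, 1.80),
  gb_screen = c(0.72, 0.79, 0.85, 0.85, 0.96))

# schematic backbone charges; the matched deprotonated state shifts them
# slightly, as real residue libraries do
backbone_charges <- list(
  prot   = c(N = -0.4157, H = 0.2719, CA = 0.0337, C = 0.5973, O = -0.5679),
  deprot = c(N = -0.4500, H = 0.2900, CA = 0.0500, C = 0.5500, O = -0.5800))
cap_charges <- c("ACE:CH3" = -0.0293, "ACE:C" = 0.5972, "ACE:O" = -0.5679,
                 "NME:N" = -0.4157, "NME:H" = 0.2719, "NME:CH3" = 0.1438)

#' Build an idealized blocked tripeptide (ACE-X-X-NME)
#'
#' Constructs a toy capped di-amino-acid tripeptide of a titratable
#' residue type, with idealized internal-coordinate geometry (PII-like
#' backbone, extended side chains; the acidic proton sits in the syn
#' position) and three schematic partial-charge sets:
#'
#' * `protonated` - the reference state;
#' * `deprotonated` - a matched (conventional-MD style) deprotonated
#'   residue whose side-chain, C-beta and (slightly) backbone charges all
#'   differ from the protonated set;
#' * `deprotonated_cphmd` - a constant-pH-MD style set that keeps the
#'   protonated backbone and cap charges unchanged and absorbs the net
#'   charge difference into C-beta, reproducing the charge-assignment
#'   behaviour of AMBER's discrete constant-pH residues.
#'
#' In every set the C-beta charge is adjusted so each residue's total
#' charge is exact; titratable protons are retained with zero charge in
#' deprotonated states (ghost atoms).
#'
#' @param residue one of `"ASP"`, `"LYS"`, `"HIS"`, `"CYS"` (-like).
#' @param phi,psi backbone template torsions, degrees.
#' @return list with elements `topology` (a [topology]) and `frame`
#'   (single-frame [coord_frames] of the template geometry).
#' @export
build_toy_tripeptide <- function(residue = c("ASP", "LYS", "HIS", "CYS"),
                                 phi = -75, psi = 150) {
  residue <- match.arg(residue)
  tpl <- sidechain_templates[[residue]]

  atoms <- list()   # each: name, res, resname, group, element, parent idx
  coords <- list()
  key <- function(res, name) paste0(res, ":", name)
  index <- new.env()
  add <- function(name, res, resname, group, element, parent = NA,
                  refs = NULL, bond = NULL, angle = NULL, torsion = NULL,
                  xyz = NULL) {
    i <- length(atoms) + 1L
    if (is.null(xyz)) {
      r <- vapply(refs, function(k) coords[[get(k, envir = index)]],
                  numeric(3))
      xyz <- place_atom(r[, 3], r[, 2], r[, 1], bond, angle, torsion)
    }
    atoms[[i]] <<- list(name = name, res = res, resname = resname,
                        group = group, element = element, parent = parent)
    coords[[i]] <<- xyz
    assign(key(res, name), i, envir = index)
    i
  }
  ref <- function(res, name) key(res, name)

  # ACE cap
  add("CH3", 1, "ACE", "cap", "C", xyz = c(0, 0, 0))
  add("C", 1, "ACE", "cap", "C", parent = 1, xyz = c(1.522, 0, 0))
  add("O", 1, "ACE", "cap", "O", parent = 2,
      xyz = c(1.522 + 1.229 * cos(pi * (180 - 120.5) / 180),
              1.229 * sin(pi * (180 - 120.5) / 180), 0))

  prev <- list(C = ref(1, "C"), CA = ref(1, "CH3"), O = ref(1, "O"))
  for (ri in 2:3) {
    add("N", ri, residue, "backbone", "N",
        parent = get(prev$C, envir = index),
        refs = c(prev$C, prev$CA, prev$O), bond = 1.335, angle = 116.6,
        torsion = 180)
    add("CA", ri, residue, "backbone", "C",
        parent = get(key(ri, "N"), envir = index),
        refs = c(ref(ri, "N"), prev$C, prev$CA), bond = 1.449,
        angle = 121.9, torsion = 180)                      # omega trans
    add("H", ri, residue, "backbone", "H",
        parent = get(key(ri, "N"), envir = index),
        refs = c(ref(ri, "N"), prev$C, ref(ri, "CA")), bond = 1.010,
        angle = 119.0, torsion = 180)
    add("CB", ri, residue, "sidechain", tpl$elements[["CB"]],
        parent = get(key(ri, "CA"), envir = index),
        refs = c(ref(ri, "CA"), ref(ri, "N"), prev$C), bond = 1.526,
        angle = 110.5, torsion = phi + 122)
    for (z in tpl$zmat) {
      rr <- function(nm) if (nm == "CPREV") prev$C
                         else ref(ri, sub("^@", "", nm))
      add(z[[1]], ri, residue, "sidechain", tpl$elements[[z[[1]]]],
          parent = get(rr(z[[2]]), envir = index),
          refs = c(rr(z[[2]]), rr(z[[3]]), rr(z[[4]])),
          bond = z[[5]], angle = z[[6]], torsion = z[[7]])
    }
    add("C", ri, residue, "backbone", "C",
        parent = get(key(ri, "CA"), envir = index),
        refs = c(ref(ri, "CA"), ref(ri, "N"), prev$C), bond = 1.522,
        angle = 111.1, torsion = phi)
    add("O", ri, residue, "backbone", "O",
        parent = get(key(ri, "C"), envir = index),
        refs = c(ref(ri, "C"), ref(ri, "CA"), ref(ri, "N")), bond = 1.229,
        angle = 120.5, torsion = wrap_angle(psi + 180))
    prev <- list(C = ref(ri, "C"), CA = ref(ri, "CA"), O = ref(ri, "O"))
  }
  # NME cap
  add("N", 4, "NME", "cap", "N", parent = get(prev$C, envir = index),
      refs = c(prev$C, prev$CA, prev$O), bond = 1.335, angle = 116.6,
      torsion = 180)
  add("CH3", 4, "NME", "cap", "C", parent = get(key(4, "N"), envir = index),
      refs = c(ref(4, "N"), prev$C, prev$CA), bond = 1.449, angle = 121.9,
      torsion = 180)
  add("H", 4, "NME", "cap", "H", parent = get(key(4, "N"), envir = index),
      refs = c(ref(4, "N"), prev$C, ref(4, "CH3")), bond = 1.010,
      angle = 119.0, torsion = 180)

  xyz <- do.call(rbind, coords)
  at <- do.call(rbind, lapply(atoms, function(a)
    data.frame(name = a$name, residue_index = a$res, residue_name = a$resname,
               group = a$group, element = a$element)))
  ep <- element_params[match(at$element, element_params$element), ]
  atoms_df <- cbind(at[c("name", "residue_index", "residue_name", "group")],
                    lj_radius = ep$lj_radius, lj_epsilon = ep$lj_epsilon,
                    gb_radius = ep$gb_radius, gb_screen = ep$gb_screen)

  parents <- vapply(atoms, function(a)
    if (is.na(a$parent[1])) NA_integer_ else as.integer(a$parent), 0L)
  bonds_idx <- cbind(which(!is.na(parents)), parents[!is.na(parents)])
  for (eb in tpl$extra_bonds) for (ri in 2:3)
    bonds_idx <- rbind(bonds_idx,
                       c(get(key(ri, eb[1]), envir = index),
                         get(key(ri, eb[2]), envir = index)))
  topo <- topology_from_geometry(atoms_df, bonds_idx, xyz,
                                 charge_sets_for(at, tpl))
  list(topology = topo, frame = coord_frames(xyz, atom_names = at$name))
}

charge_sets_for <- function(at, tpl) {
  n <- nrow(at)
  q_of <- function(state) {
    q <- numeric(n)
    bbq <- backbone_charges[[state]]
    scq <- if (state == "prot") tpl$q_prot else tpl$q_deprot
    net_res <- if (state == "prot") tpl$net_prot else tpl$net_deprot
    for (i in seq_len(n)) {
      if (at$group[i] == "cap")
        q[i] <- cap_charges[[paste0(at$residue_name[i], ":", at$name[i])]]
      else if (at$group[i] == "backbone") q[i] <- bbq[[at$name[i]]]
      else if (at$name[i] != "CB") q[i] <- scq[[at$name[i]]]
    }
    for (ri in 2:3) {   # CB absorbs the residual so residue nets are exact
      res <- at$residue_index == ri
      cb <- which(res & at$name == "CB")
      q[cb] <- net_res - sum(q[res & at$name != "CB"])
    }
    q
  }
  qp <- q_of("prot"); qd <- q_of("deprot")
  # CPHMD-style: protonated backbone/cap charges, deprotonated side chain,
  # CB readjusted so the deprotonated net charge is still exact
  qm <- qd
  bbcap <- at$group %in% c("backbone", "cap")
  qm[bbcap] <- qp[bbcap]
  for (ri in 2:3) {
    res <- at$residue_index == ri
    cb <- which(res & at$name == "CB")
    qm[cb] <- tpl$net_deprot - sum(qm[res][at$name[res] != "CB"])
  }
  list(protonated = list(charges = qp, net_charge = 2 * tpl$net_prot),
       deprotonated = list(charges = qd, net_charge = 2 * tpl$net_deprot),
       deprotonated_cphmd = list(charges = qm,
                                 net_charge = 2 * tpl$net_deprot))
}

# derive bonded terms and pair lists from the bond graph; equilibrium
# values are read off the template geometry
topology_from_geometry <- function(atoms_df, bonds_idx, xyz, charge_sets) {
  n <- nrow(atoms_df)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds_idx))) {
    i <- bonds_idx[r, 1]; j <- bonds_idx[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist3 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  bonds <- data.frame(ai = pmin(bonds_idx[, 1], bonds_idx[, 2]),
                      aj = pmax(bonds_idx[, 1], bonds_idx[, 2]))
  bonds$k <- ifelse(atoms_df$gb_radius[bonds$ai] < 1.3 |
                      atoms_df$gb_radius[bonds$aj] < 1.3, 400, 300)
  bonds$r0 <- mapply(dist3, bonds$ai, bonds$aj)

  ang <- list(); tor <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2)
      for (a in seq_along(nb)) for (b in seq_along(nb))
        if (a < b) ang[[length(ang) + 1]] <- c(nb[a], j, nb[b])
  }
  for (r in seq_len(nrow(bonds))) {
    j <- bonds$ai[r]; k <- bonds$aj[r]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      if (i != l) tor[[length(tor) + 1]] <- c(i, j, k, l)
  }
  angles <- as.data.frame(do.call(rbind, ang))
  names(angles) <- c("ai", "aj", "ak")
  angles$k <- 50
  angles$theta0 <- vapply(seq_len(nrow(angles)), function(r) {
    v1 <- xyz[angles$ai[r], ] - xyz[angles$aj[r], ]
    v2 <- xyz[angles$ak[r], ] - xyz[angles$aj[r], ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }, 0)
  torsions <- as.data.frame(do.call(rbind, tor))
  names(torsions) <- c("ai", "aj", "ak", "al")
  torsions$vn <- 0.5; torsions$n <- 3; torsions$gamma <- 0

  # graph distances 1-2/1-3 -> exclusions, 1-4 -> scaled pairs
  excl <- unique(rbind(
    bonds[c("ai", "aj")],
    stats::setNames(data.frame(ai = pmin(angles$ai, angles$ak),
                               aj = pmax(angles$ai, angles$ak)),
                    c("ai", "aj"))))
  p14 <- unique(data.frame(ai = pmin(torsions$ai, torsions$al),
                           aj = pmax(torsions$ai, torsions$al)))
  pk <- function(p) paste(p$ai, p$aj)
  p14 <- p14[!(pk(p14) %in% pk(excl)), ]   # exclusion takes precedence
  rownames(p14) <- NULL

  topology(atoms = atoms_df, charge_sets = charge_sets, bonds = bonds,
           angles = angles, torsions = torsions, exclusions = excl,
           pairs14 = p14)
}

#' Default theta-angle atom selection for the toy residues
#'
#' The theta torsion is (side-chain atom of monomer 1) - CA1 - CA2 -
#' (side-chain atom of monomer 2).  The shipped JSON table
#' (`extdata/theta_default.json`) picks CG for Asp/His-like (CE1 for the
#' His imidazole), SG for Cys-like and NZ for Lys-like residues and can
#' be replaced by the user.
#'
#' @param path JSON file; default is the shipped table.
#' @return named list: residue -> list(atom1, atom2).
#' @export
read_theta_selection <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "theta_default.json", package = "pepconf")
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}
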