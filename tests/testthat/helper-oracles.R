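# Independent reference implementations used as oracles.  These are
# deliberately naive (plain loops, re-derived formulas) and share no code
# with the package internals they check.

# --- naive single-point energy: O(N^2) double loops ---------------------
naive_single_point <- function(xyz, topo, charge_set,
                               ionic_strength = 0.1, temperature = 300) {
  q <- topo$charge_sets[[charge_set]]$charges
  n <- nrow(xyz)
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  e_bond <- 0
  for (r in seq_len(nrow(topo$bonds)))
    e_bond <- e_bond + topo$bonds$k[r] *
      (d(topo$bonds$ai[r], topo$bonds$aj[r]) - topo$bonds$r0[r])^2
  e_angle <- 0
  for (r in seq_len(nrow(topo$angles))) {
    v1 <- xyz[topo$angles$ai[r], ] - xyz[topo$angles$aj[r], ]
    v2 <- xyz[topo$angles$ak[r], ] - xyz[topo$angles$aj[r], ]
    th <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
    e_angle <- e_angle + topo$angles$k[r] *
      (th - topo$angles$theta0[r] * pi / 180)^2
  }
  e_tor <- 0
  for (r in seq_len(nrow(topo$torsions))) {
    tt <- topo$torsions[r, ]
    phi <- oracle_torsion(xyz[tt$ai, ], xyz[tt$aj, ], xyz[tt$ak, ], xyz[tt$al, ])
    e_tor <- e_tor + tt$vn / 2 * (1 + cos((tt$n * phi - tt$gamma) * pi / 180))
  }

  pair_set <- function(df) {
    if (!nrow(df)) return(character())
    paste(pmin(df$ai, df$aj), pmax(df$ai, df$aj))
  }
  excl <- pair_set(topo$exclusions); p14 <- pair_set(topo$pairs14)
  e_vdw <- e_vdw14 <- e_eel <- e_eel14 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- paste(i, j)
    if (key %in% excl) next
    r <- d(i, j)
    rmin <- topo$atoms$lj_radius[i] + topo$atoms$lj_radius[j]
    eps <- sqrt(topo$atoms$lj_epsilon[i] * topo$atoms$lj_epsilon[j])
    elj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    ec <- 332.0636 * q[i] * q[j] / r
    if (key %in% p14) {
      e_vdw14 <- e_vdw14 + elj / 2.0
      e_eel14 <- e_eel14 + ec / 1.2
    } else {
      e_vdw <- e_vdw + elj
      e_eel <- e_eel + ec
    }
  }

  egb <- naive_gb(xyz, q, topo, ionic_strength, temperature)
  pot <- e_bond + e_angle + e_tor + e_vdw + e_vdw14 + e_eel + e_eel14 + egb
  list(bond = e_bond, angle = e_angle, dihedral_t = e_tor, vdw = e_vdw,
       vdw14 = e_vdw14, eel = e_eel, eel14 = e_eel14, egb = egb,
       potential = pot)
}

naive_gb <- function(xyz, q, topo, ionic_strength, temperature) {
  n <- nrow(xyz)
  rho <- topo$atoms$gb_radius; scr <- topo$atoms$gb_screen
  R <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sr <- scr[j] * rho[j]
      if (r + sr <= rho[i]) next
      U <- r + sr
      L <- max(rho[i], abs(r - sr))
      h <- 0.5 * (1 / L - 1 / U + 0.25 * (r - sr^2 / r) * (1 / U^2 - 1 / L^2) +
                    0.5 * log(L / U) / r)
      if (sr > r + rho[i]) h <- h + (1 / rho[i] - 1 / L)
      I <- I + h
    }
    psi <- I * rho[i]
    R[i] <- 1 / (1 / rho[i] -
                   tanh(0.8 * psi + 2.909125 * psi^3) / rho[i])
  }
  # Debye constant re-derived: kappa^2 = 8 pi lB n_ion
  kappa <- 0
  if (ionic_strength > 0) {
    lB <- 332.0636 / (78.5 * 0.0019872041 * temperature)
    kappa <- sqrt(8 * pi * lB * ionic_strength * 6.02214076e23 / 1e27)
  }
  e <- 0
  for (i in seq_len(n)) for (j in i:n) {
    r2 <- sum((xyz[i, ] - xyz[j, ])^2)
    f <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    pref <- if (i == j) 0.5 else 1
    e <- e - pref * 332.0636 * q[i] * q[j] * (1 - exp(-kappa * f) / 78.5) / f
  }
  e
}

# torsion via an independent construction: angle between plane normals,
# signed by the triple product of (b1, b2, b3)
oracle_torsion <- function(p1, p2, p3, p4) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  p3 <- as.numeric(p3); p4 <- as.numeric(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(max(-1, min(1, cosphi))) * 180 / pi
  if (sum(cr(n1, n2) * b2) > 0) phi <- -phi   # IUPAC: clockwise positive
  phi <- phi - 360 * floor((phi + 180) / 360)
  if (phi >= 180) phi <- phi - 360 else phi
}

# --- exhaustive toroidal minima scan ------------------------------------
oracle_scan_minima <- function(fe) {
  nb <- nrow(fe)
  hits <- NULL
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    v <- fe[i, j]
    if (!is.finite(v)) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- ((i - 1 + di) %% nb) + 1
      jj <- ((j - 1 + dj) %% nb) + 1
      if (!is.finite(fe[ii, jj]) || !(v < fe[ii, jj])) ok <- FALSE
    }
    if (ok) hits <- rbind(hits, c(i, j))
  }
  hits
}

# --- circular mean in degrees -------------------------------------------
oracle_circ_mean <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

# --- independent interval-logic classifier for the shipped region table --
oracle_region_default <- function(phi, psi) {
  phi <- phi - 360 * floor((phi + 180) / 360)
  psi <- psi - 360 * floor((psi + 180) / 360)
  mapply(function(f, s) {
    if (f < 0) {
      if (s >= 100 || s < -140) {
        if (f < -110) "C5" else "PII"
      } else if (s >= 30) "C7eq"
      else if (s >= -100) "alphaR"
      else "alphaPrime"
    } else {
      if (s >= 100) "alphaD"
      else if (s >= 0) "alphaL"
      else if (s >= -100) "C7axial"
      else "beta2"
    }
  }, phi, psi)
}

# tiny deterministic two-atom topology for Coulomb / Born checks
two_atom_topology <- function(q1, q2, gb_r = c(1.5, 1.5)) {
  topology(
    atoms = data.frame(
      name = c("A1", "A2"), residue_index = c(1, 1),
      residue_name = c("TST", "TST"), group = c("backbone", "sidechain"),
      lj_radius = c(0, 0), lj_epsilon = c(0, 0),
      gb_radius = gb_r, gb_screen = c(0.8, 0.8)),
    charge_sets = list(test = list(charges = c(q1, q2),
                                   net_charge = q1 + q2)),
    bonds = data.frame(ai = integer(), aj = integer(), k = numeric(),
                       r0 = numeric()),
    angles = data.frame(ai = integer(), aj = integer(), ak = integer(),
                        k = numeric(), theta0 = numeric()),
    torsions = data.frame(ai = integer(), aj = integer(), ak = integer(),
                          al = integer(), vn = numeric(), n = numeric(),
                          gamma = numeric()),
    exclusions = data.frame(ai = integer(), aj = integer()),
    pairs14 = data.frame(ai = integer(), aj = integer()))
}

randomized_toy_system <- function(seed) {
  set.seed(seed)
  res <- sample(c("ASP", "LYS", "HIS", "CYS"), 1)
  toy <- build_toy_tripeptide(res)
  xyz <- toy$frame[, , 1] + matrix(rnorm(length(toy$frame[, , 1]), sd = 0.1),
                                   ncol = 3)
  topo <- toy$topology
  # randomize one charge set (zero-sum perturbation keeps the invariant)
  pert <- rnorm(nrow(topo$atoms), sd = 0.1)
  pert <- pert - mean(pert)
  topo$charge_sets$test <- list(
    charges = topo$charge_sets$protonated$charges + pert,
    net_charge = topo$charge_sets$protonated$net_charge)
  list(xyz = xyz, topology = topo)
}
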