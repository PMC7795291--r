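test_that("Coulomb term reproduces the hand-evaluated two-charge case", {
  topo <- two_atom_topology(1, -1)
  xyz <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  e <- single_point(xyz, topo, "test", ionic_strength = 0)
  expect_equal(e$eel, -100.0, tolerance = 1e-9)
  expect_equal(e$eel14, 0)
  zero <- two_atom_topology(0, 0)
  e0 <- single_point(xyz, zero, "test")
  expect_equal(e0$eel + e0$eel14 + e0$egb, 0)
  expect_error(single_point(rbind(c(0, 0, 0), c(0, 0, 1e-8)), topo, "test"),
               "singularity")
})

test_that("isolated-ion GB energy matches the analytic Born expression", {
  for (R in c(1.2, 1.7, 2.5)) for (q in c(-1, 0.5)) {
    topo <- topology(
      atoms = data.frame(name = "ION", residue_index = 1,
                         residue_name = "ION", group = "sidechain",
                         lj_radius = 1, lj_epsilon = 0.1,
                         gb_radius = R, gb_screen = 0.8),
      charge_sets = list(test = list(charges = q, net_charge = q)),
      bonds = data.frame(ai = integer(), aj = integer(), k = numeric(),
                         r0 = numeric()),
      angles = data.frame(ai = integer(), aj = integer(), ak = integer(),
                          k = numeric(), theta0 = numeric()),
      torsions = data.frame(ai = integer(), aj = integer(), ak = integer(),
                            al = integer(), vn = numeric(), n = numeric(),
                            gamma = numeric()),
      exclusions = data.frame(ai = integer(), aj = integer()),
      pairs14 = data.frame(ai = integer(), aj = integer()))
    xyz <- rbind(c(0, 0, 0))
    expect_equal(born_radii(xyz, topo), R)
    e <- single_point(xyz, topo, "test", ionic_strength = 0)
    born <- -0.5 * 332.0636 * q^2 * (1 / 1 - 1 / 78.5) / R
    expect_equal(e$egb, born, tolerance = 1e-6)
  }
})

test_that("vectorized evaluator equals the naive double-loop reference", {
  for (seed in 1:10) {
    sys <- randomized_toy_system(seed)
    got <- single_point(sys$xyz, sys$topology, "test")
    ref <- naive_single_point(sys$xyz, sys$topology, "test")
    for (term in names(ref))
      expect_equal(got[[term]], ref[[term]], tolerance = 1e-8,
                   label = paste(term, "seed", seed))
  }
})

test_that("energy terms are invariant under rigid-body motion", {
  sys <- randomized_toy_system(99)
  ref <- single_point(sys$xyz, sys$topology, "test")
  th <- c(0.3, -1.2)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  moved <- sys$xyz %*% t(Rx %*% Ry) +
    matrix(c(5, -3, 11), nrow(sys$xyz), 3, byrow = TRUE)
  got <- single_point(moved, sys$topology, "test")
  for (term in names(unclass(ref)))
    expect_equal(got[[term]], ref[[term]], tolerance = 1e-8, label = term)
})

test_that("potential equals the sum of its terms and the series validator sees it", {
  toy <- build_toy_tripeptide("LYS")
  ens <- perturb_frames(toy$frame, 5, amplitude = 0.05, seed = 61)
  es <- single_point_series(ens, toy$topology, "protonated")
  comps <- c("bond", "angle", "dihedral_t", "vdw", "vdw14", "eel", "eel14",
             "egb")
  expect_true(all(abs(es$potential - rowSums(es[comps])) < 1e-6))
  bad <- as.data.frame(es)
  bad$potential[2] <- bad$potential[2] + 1
  expect_error(energy_series(bad), "differs from term sum")
  f <- withr::local_tempfile(fileext = ".csv")
  write_energy_series(es, f)
  expect_equal(read_energy_series(f)$potential, es$potential,
               tolerance = 1e-10)
})

test_that("electrostatic decomposition conserves the totals", {
  toy <- build_toy_tripeptide("ASP")
  ens <- perturb_frames(toy$frame, 10, amplitude = 0.05, seed = 62)
  for (cs in c("protonated", "deprotonated", "deprotonated_cphmd")) {
    es <- single_point_series(ens, toy$topology, cs)
    dh <- decompose_electrostatics(ens, toy$topology, cs, cross = "half")
    expect_equal(dh$eel_bb + dh$eel_sc, es$eel, tolerance = 1e-8)
    expect_equal(dh$eel14_bb + dh$eel14_sc, es$eel14, tolerance = 1e-8)
    ds <- decompose_electrostatics(ens, toy$topology, cs, cross = "separate")
    expect_equal(ds$eel_bb + ds$eel_sc + ds$eel_cross, es$eel,
                 tolerance = 1e-8)
    expect_equal(ds$eel14_bb + ds$eel14_sc + ds$eel14_cross, es$eel14,
                 tolerance = 1e-8)
  }
})

test_that("group assignment rules behave on labelled edge cases", {
  # two atoms, one backbone + one sidechain: half-splitting gives each half
  topo <- two_atom_topology(1, -1)
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  d <- decompose_electrostatics(xyz, topo, "test", cross = "half")
  pair_e <- 332.0636 * 1 * -1 / 2
  expect_equal(d$eel_bb, pair_e / 2, tolerance = 1e-10)
  expect_equal(d$eel_sc, pair_e / 2, tolerance = 1e-10)
  # in separate mode the cross pair goes to neither group
  ds <- decompose_electrostatics(xyz, topo, "test", cross = "separate")
  expect_equal(ds$eel_bb, 0)
  expect_equal(ds$eel_sc, 0)
  expect_equal(ds$eel_cross, pair_e, tolerance = 1e-10)
  # all atoms backbone: side-chain terms exactly zero, bb equals total
  topo_bb <- topo
  topo_bb$atoms$group <- "backbone"
  db <- decompose_electrostatics(xyz, topo_bb, "test", cross = "half")
  expect_identical(db$eel_sc, 0)
  expect_equal(db$eel_bb, pair_e, tolerance = 1e-10)
})

test_that("CPHMD-style backbone charges leave backbone electrostatics unchanged", {
  toy <- build_toy_tripeptide("ASP")
  ens <- perturb_frames(toy$frame, 20, amplitude = 0.05, seed = 63)
  prot <- decompose_electrostatics(ens, toy$topology, "protonated",
                                   cross = "separate")
  mism <- decompose_electrostatics(ens, toy$topology, "deprotonated_cphmd",
                                   cross = "separate")
  matc <- decompose_electrostatics(ens, toy$topology, "deprotonated",
                                   cross = "separate")
  expect_identical(mism$eel_bb, prot$eel_bb)
  expect_identical(mism$eel14_bb, prot$eel14_bb)
  expect_false(any(matc$eel_bb == prot$eel_bb))
})

test_that("energy histograms are unit-area and recover sample statistics", {
  const <- energy_series(data.frame(eel = rep(-50, 10)))
  h <- energy_distributions(const, bin_width = 0.5)$eel
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(max(h$density), 1 / 0.5)

  set.seed(64)
  x <- rnorm(1e5, mean = -50, sd = 2)
  hg <- density_histogram(x, 0.25)
  mids <- hg$breaks[-length(hg$breaks)] + 0.125
  expect_equal(sum(hg$density) * 0.25, 1, tolerance = 1e-9)
  expect_lt(abs(sum(mids * hg$density) * 0.25 - mean(x)), 0.05)
})

test_that("distribution overlap is a proper [0,1] coefficient", {
  a <- density_histogram(rep(c(0.25, 0.75), 50), 0.5)
  expect_equal(distribution_overlap(a, a), 1, tolerance = 1e-12)
  b <- density_histogram(rep(c(10.25, 10.75), 50), 0.5)
  expect_equal(distribution_overlap(a, b), 0)
  # shares exactly half its mass: bins {0,0.5} vs {0.5,1}
  c2 <- density_histogram(rep(c(0.75, 1.25), 50), 0.5)
  expect_equal(distribution_overlap(a, c2), 0.5, tolerance = 1e-12)
  expect_error(distribution_overlap(a, density_histogram(1:5, 1)),
               "bin width")
})
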