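test_that("binning conserves counts and owns half-open edges", {
  s <- sample_dihedrals(list(basin_spec("x", c(0, 0), c(5, 5), 1)),
                        1000, seed = 21)
  cg <- bin_angles(s, spacing = 1)
  expect_equal(dim(cg$counts), c(360L, 360L))
  expect_equal(sum(cg$counts), 1000)
  expect_equal(cg$n_total, 1000)

  one <- bin_angles(cbind(-180, -180), spacing = 1)
  expect_equal(one$counts[1, 1], 1L)
  # +180 wraps to -180 before binning
  wrapped <- bin_angles(cbind(180, 20.0), spacing = 1)
  expect_equal(which(rowSums(wrapped$counts) == 1), 1L)
  expect_error(bin_angles(cbind(0, 0), spacing = 7), "divide 360")
})

test_that("Boltzmann inversion follows -kBT ln(n/nmax) with masking", {
  cg <- bin_angles(cbind(c(0, 0, 90.5), c(c(0, 0, 45.5))), spacing = 1)
  fes <- boltzmann_invert(cg, temperature = 300)
  ref_cell <- fes$free_energy[181, 181]
  expect_identical(ref_cell, 0)
  half_cell <- fes$free_energy[271, 226]
  expect_equal(half_cell, 0.0019872041 * 300 * log(2), tolerance = 1e-12)
  expect_true(all(fes$free_energy[!fes$mask] >= 0))
  expect_true(all(is.infinite(fes$free_energy[fes$mask])))
  expect_equal(sum(!fes$mask), 2)

  # invariant under uniform count rescaling
  cg10 <- cg; cg10$counts <- cg$counts * 10L; cg10$n_total <- cg$n_total * 10L
  expect_equal(boltzmann_invert(cg10, 300)$free_energy, fes$free_energy)
  empty <- cg; empty$counts[] <- 0L
  expect_error(boltzmann_invert(empty, 300), "degenerate")
})

test_that("contour levels step by the increment up to the maximum", {
  cg <- bin_angles(cbind(c(rep(0, 29), 10, 20), c(rep(0, 29), 10, 20)),
                   spacing = 1)
  fes <- boltzmann_invert(cg, 300)
  mx <- max(fes$free_energy[!fes$mask])
  lv <- contour_levels(fes, 0.6)
  expect_equal(lv, seq(0, mx, by = 0.6))
  single <- boltzmann_invert(bin_angles(cbind(0, 0), spacing = 1), 300)
  expect_equal(contour_levels(single, 0.6), 0)
  expect_equal(contour_levels(fes, mx + 1), 0)
})

test_that("minima search equals the exhaustive toroidal scan oracle", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    w <- runif(k); w <- w / sum(w)
    basins <- lapply(seq_len(k), function(i)
      basin_spec(paste0("b", i),
                 center = c(runif(1, -170, 170), runif(1, -170, 170)),
                 kappa = c(150, 150), weight = w[i]))
    s <- sample_dihedrals(basins, 2e4, seed = 310 + rep)
    found <- locate_minima(s, temperature = 300, spacing = 2)
    fes <- boltzmann_invert(bin_angles(s, spacing = 2), 300)
    ora <- oracle_scan_minima(fes$free_energy)
    expect_equal(nrow(found), nrow(ora))
    got <- cbind(match(found$phi, fes$x), match(found$psi, fes$y))
    expect_setequal(paste(got[, 1], got[, 2]), paste(ora[, 1], ora[, 2]))
  }
})

test_that("a seam-straddling basin yields one minimum, not two", {
  s <- sample_dihedrals(list(basin_spec("seam", c(179, 0), c(200, 200), 1)),
                        5e4, seed = 33)
  m <- locate_minima(s, spacing = 2)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(wrap_angle(m$phi - 179)), 3)
  expect_lt(abs(wrap_angle(m$psi)), 3)
})

test_that("uniform counts produce no minima (strict dominance)", {
  cg <- bin_angles(cbind(0, 0), spacing = 90)   # 4x4 grid
  cg$counts[] <- 5L
  cg$n_total <- sum(cg$counts)
  fes <- boltzmann_invert(cg, 300)
  expect_equal(sum(pepconf:::local_minima_mask(fes$free_energy)), 0)
})

test_that("basin merging keeps the deepest minimum per neighbourhood", {
  s <- sample_dihedrals(list(basin_spec("x", c(-60, -40), c(30, 30), 0.6),
                             basin_spec("y", c(60, 120), c(30, 30), 0.4)),
                        3e5, seed = 35)
  raw <- locate_minima(s, spacing = 1)               # noisy at 1 degree
  merged <- locate_minima(s, spacing = 1, min_separation = 40)
  expect_lte(nrow(merged), nrow(raw))
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$free_energy[1], raw$free_energy[1])
  expect_lt(abs(wrap_angle(merged$phi[1] - (-60))), 5)
  expect_lt(abs(wrap_angle(merged$phi[2] - 60)), 5)
})

test_that("free-energy gap between basins converges to -kBT ln(w2/w1)", {
  n <- 2e5
  s <- sample_dihedrals(list(
    basin_spec("PII", c(-75, 150), c(100, 100), 0.7),
    basin_spec("aR", c(-57, -47), c(100, 100), 0.3)), n, seed = 34)
  m <- locate_minima(s, spacing = 2)
  expect_equal(nrow(m), 2L)
  gap <- m$free_energy[2] - m$free_energy[1]
  kt <- 0.0019872041 * 300
  cg <- bin_angles(s, spacing = 2)
  n1 <- max(cg$counts)
  n2 <- round(n1 * exp(-m$free_energy[2] / kt))
  se <- kt * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(gap - kt * log(0.7 / 0.3)), 3 * se)
})
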