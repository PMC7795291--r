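test_that("angle wrapping is canonical and idempotent", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(180), -180)
  expect_equal(wrap_angle(-180), -180)
  expect_equal(wrap_angle(725), 5)
  x <- runif(1000, -1e4, 1e4)
  w <- wrap_angle(x)
  expect_true(all(w >= -180 & w < 180))
  expect_equal(wrap_angle(w), w)
})

test_that("dihedral series CSV round-trips and wraps on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,monomer,phi,psi", "1,1,190,10", "2,1,-60,150",
               "3,1,180,-180"), f)
  s <- read_dihedral_series(f)
  expect_equal(s$phi, c(-170, -60, -180))
  expect_equal(s$psi, c(10, 150, -180))

  s2 <- dihedral_series(rep(1:2, each = 5), runif(10, -180, 180),
                        runif(10, -180, 180), theta = runif(10, -180, 180))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dihedral_series(s2, f2)
  expect_identical(readLines(f2), {
    f3 <- withr::local_tempfile()
    write_dihedral_series(read_dihedral_series(f2), f3)
    readLines(f3)
  })
})

test_that("dihedral reader error contracts name the offending column/line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,monomer,psi", "1,1,10"), f)
  expect_error(read_dihedral_series(f), "missing column.*phi")
  writeLines(c("frame,monomer,phi,psi", "1,1,bad,10"), f)
  expect_error(read_dihedral_series(f), "parse error")
  # dialect flag for whitespace tables with mapped column names
  f2 <- withr::local_tempfile()
  writeLines(c("frame set phi psi", "1 1 190 10"), f2)
  s <- read_dihedral_series(f2, dialect = "whitespace",
                            col_map = c(monomer = "set"))
  expect_equal(s$phi, -170)
})

test_that("topology JSON round-trips with invariants verified on load", {
  toy <- build_toy_tripeptide("ASP")
  f <- withr::local_tempfile(fileext = ".json")
  write_topology(toy$topology, f)
  topo2 <- read_topology(f)
  expect_equal(topo2$atoms$name, toy$topology$atoms$name)
  expect_equal(topo2$charge_sets$protonated$charges,
               toy$topology$charge_sets$protonated$charges)
  expect_equal(nrow(topo2$pairs14), nrow(toy$topology$pairs14))
})

test_that("topology validation rejects bad charges and bad indices", {
  toy <- build_toy_tripeptide("ASP")
  bad <- toy$topology
  bad$charge_sets$deprotonated$charges[1] <-
    bad$charge_sets$deprotonated$charges[1] + 0.1
  expect_error(validate_topology(bad), "deprotonated.*discrepancy")
  bad2 <- toy$topology
  bad2$bonds$aj[1] <- 99L
  expect_error(validate_topology(bad2), "references atom 99")
  bad3 <- toy$topology
  bad3$pairs14 <- rbind(bad3$pairs14, bad3$exclusions[1, ])
  expect_error(validate_topology(bad3), "both exclusions and pairs14")
})

test_that("multi-model PDB reading enforces constant atom counts", {
  f <- withr::local_tempfile(fileext = ".pdb")
  atom_line <- function(i, x) sprintf(
    "ATOM  %5d  C%-2d UNK A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, i, x, 0, 0)
  writeLines(c("MODEL     1", sapply(1:10, function(i) atom_line(i, i)),
               "ENDMDL", "MODEL     2",
               sapply(1:10, function(i) atom_line(i, i + 0.5)),
               "ENDMDL", "END"), f)
  fr <- read_frames(f)
  expect_equal(dim(fr), c(10L, 3L, 2L))
  expect_equal(fr[3, 1, 2], 3.5)

  writeLines(c("MODEL     1", sapply(1:10, function(i) atom_line(i, i)),
               "ENDMDL", "MODEL     2",
               sapply(1:7, function(i) atom_line(i, i)), "ENDMDL"), f)
  expect_error(read_frames(f), "model 2 has 7 atoms")
  writeLines(c("MODEL     1", sapply(1:4, function(i) atom_line(i, i))), f)
  expect_error(read_frames(f), "truncated")
})

test_that("PDB write/read preserves coordinates to PDB precision", {
  toy <- build_toy_tripeptide("CYS")
  ens <- perturb_frames(toy$frame, 3, amplitude = 0.3, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_frames(ens, f, topology = toy$topology)
  back <- read_frames(f)
  expect_equal(dim(back), dim(ens))
  expect_true(max(abs(back - ens)) < 5e-4)   # 3-decimal PDB fields
  expect_equal(dimnames(back)[[1]], toy$topology$atoms$name)
})

test_that("grid matrix text round-trips including the mask sentinel", {
  g <- list(values = matrix(0, 3, 3), x = c(-1, 0, 1), y = c(-1, 0, 1),
            axes = c("phi", "psi"))
  f <- withr::local_tempfile()
  write_grid_matrix(g, f)
  lines <- readLines(f)
  blocks <- sum(!nzchar(lines))
  expect_equal(blocks, 3)                 # one blank per row block
  expect_equal(sum(nzchar(lines)) - 3, 9) # 9 data lines after 3 headers

  vals <- matrix(rnorm(12), 3, 4)
  vals[2, 3] <- Inf                       # masked cell
  g2 <- list(values = vals, x = 1:3, y = 1:4, axes = c("a", "b"))
  write_grid_matrix(g2, f)
  expect_match(readLines(f), "NA", all = FALSE)
  back <- read_grid_matrix(f)
  expect_true(is.na(back$values[2, 3]))
  expect_equal(back$values[-8], vals[-8], tolerance = 1e-6)
  expect_equal(back$axes, c("a", "b"))
})
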