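test_that("state populations report per-residue fractions and aggregates", {
  st <- state_series(
    data.frame(frame = 1:10, residue = "ASP1", state = rep(1L, 10)),
    state_labels = c(`1` = "syn-O2", `2` = "anti-O2"))
  sp <- state_populations(st, aggregation = list(syn = "syn-O2",
                                                 anti = "anti-O2"))
  expect_equal(unname(sp$aggregates["syn", 1]), 1)
  expect_equal(unname(sp$aggregates["anti", 1]), 0)
  expect_error(state_populations(st, aggregation = list(syn = "syn-O2")),
               "does not cover")
  expect_error(state_series(data.frame(frame = 1, residue = "r", state = 3L),
                            c(`1` = "a")), "without label")
})

test_that("constructed delta fractions are reported verbatim with their average", {
  # two monomers with delta occupancy 0.77 and 0.81 by construction
  mk <- function(res, fdelta, n = 10000) {
    k <- round(n * fdelta)
    data.frame(frame = 1:n, residue = res,
               state = c(rep(1L, k), rep(2L, n - k)))
  }
  st <- state_series(rbind(mk("HIS1", 0.77), mk("HIS2", 0.81)),
                     state_labels = c(`1` = "delta", `2` = "epsilon"))
  sp <- state_populations(st, aggregation = list(delta = "delta",
                                                 epsilon = "epsilon"))
  expect_equal(unname(sp$per_residue["delta", c("HIS1", "HIS2")]),
               c(0.77, 0.81))
  expect_equal(unname(sp$average[["delta"]]), 0.79)
  expect_equal(unname(sp$average_frame_weighted[["delta"]]), 0.79)
})

test_that("transition counts follow the documented conventions", {
  lab <- c(`1` = "a", `2` = "b")
  const <- state_series(data.frame(frame = 1:7, residue = "r",
                                   state = rep(1L, 7)), lab)
  tc <- transition_counts(const)
  expect_equal(tc["a", "a"], 6L)
  expect_equal(sum(tc), 6L)
  alt <- state_series(data.frame(frame = 1:6, residue = "r",
                                 state = rep(c(1L, 2L), 3)), lab)
  ta <- transition_counts(alt)
  expect_equal(unname(diag(ta)), c(0L, 0L))
  expect_equal(sum(ta), 5L)
})

test_that("conditional splitting routes frames by state and is lossless", {
  s <- sample_dihedrals(list(basin_spec("x", c(-70, 140), c(30, 30), 1)),
                        200, seed = 71)
  lab <- c(`1` = "delta", `2` = "epsilon")
  st <- generate_state_series(list(labels = unname(lab),
                                   fractions = c(0.7, 0.3),
                                   switch_prob = 0.4), 200, seed = 72)
  parts <- conditional_series_split(s, st)
  expect_equal(sum(vapply(parts, nrow, 0L)), nrow(s))
  single <- state_series(data.frame(frame = 1:200, residue = "r",
                                    state = rep(2L, 200)), lab)
  whole <- conditional_series_split(s, single)
  expect_named(whole, "epsilon")
  expect_equal(nrow(whole$epsilon), nrow(s))
  expect_error(conditional_series_split(s, state_series(
    data.frame(frame = 1:3, residue = "r", state = rep(1L, 3)), lab)),
    "state frames")
})

test_that("state-conditioned free-energy maps find the conditioning basin", {
  # frames in the delta state drawn from one basin, epsilon from another
  n <- 4000
  sd1 <- sample_dihedrals(list(basin_spec("aR", c(-57, -47), c(150, 150), 1)),
                          n, seed = 73)
  sd2 <- sample_dihedrals(list(basin_spec("PII", c(-75, 150), c(150, 150), 1)),
                          n, seed = 74)
  set.seed(75)
  is_delta <- runif(n) < 0.6
  mixed <- dihedral_series(rep(1, n),
                           ifelse(is_delta, sd1$phi, sd2$phi),
                           ifelse(is_delta, sd1$psi, sd2$psi))
  st <- state_series(data.frame(frame = 1:n, residue = "r",
                                state = ifelse(is_delta, 1L, 2L)),
                     c(`1` = "delta", `2` = "epsilon"))
  parts <- conditional_series_split(mixed, st)
  m <- locate_minima(parts$delta, spacing = 2)
  expect_lt(abs(wrap_angle(m$phi[1] - (-57))), 3)
  expect_lt(abs(wrap_angle(m$psi[1] - (-47))), 3)
})

test_that("populations survive index relabeling and CSV round-trip", {
  df <- data.frame(frame = rep(1:50, 2),
                   residue = rep(c("r1", "r2"), each = 50),
                   state = rep(c(1L, 2L), 50))
  a <- state_series(df, c(`1` = "syn", `2` = "anti"))
  df2 <- df; df2$state <- ifelse(df$state == 1L, 7L, 3L)
  b <- state_series(df2, c(`7` = "syn", `3` = "anti"))
  expect_equal(state_populations(a)$per_residue,
               state_populations(b)$per_residue)
  f <- withr::local_tempfile(fileext = ".csv")
  write_state_series(a, f)
  back <- read_state_series(f)
  expect_equal(state_populations(back)$per_residue,
               state_populations(a)$per_residue)
})
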