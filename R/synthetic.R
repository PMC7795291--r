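#' Specify a conformational basin
#'
#' A basin is an independent von Mises pair on (phi, psi): mean direction
#' `center`, concentrations `kappa` (dimensionless; 1/sqrt(kappa) radians
#' is roughly the angular spread), and a mixture `weight`.
#'
#' @param label region name the basin emulates.
#' @param center numeric length-2, (phi0, psi0) degrees.
#' @param kappa numeric length-2 (recycled), von Mises concentrations >= 0.
#' @param weight mixture fraction.
#' @return object of class `basin_spec`.
#' @export
basin_spec <- function(label, center, kappa = c(100, 100), weight = 1) {
  kappa <- rep_len(kappa, 2)
  if (any(kappa < 0)) stop("kappa must be >= 0")
  structure(list(label = label, center = wrap_angle(center),
                 kappa = kappa, weight = weight),
            class = "basin_spec")
}

check_basins <- function(basins) {
  if (length(basins) == 0) stop("configuration error: empty basin set")
  stopifnot(all(vapply(basins, inherits, TRUE, "basin_spec")))
  w <- vapply(basins, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("configuration error: basin weights must sum to 1 (got ",
         sum(w), ")")
  w
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean mu and concentration kappa in radians; vectorised batches.
r_von_mises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      theta <- sign(stats::runif(k) - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      out[(got + 1):(got + k)] <- theta
      got <- got + k
    }
  }
  out + mu
}

#' Sample dihedral angles from a von Mises mixture
#'
#' Draws `n_frames` i.i.d. (phi, psi) pairs: a basin is chosen per frame
#' according to the weights, then phi and psi are drawn independently from
#' the basin's von Mises components.  Reproducible for a given seed.
#'
#' @param basins list of [basin_spec]s; weights must sum to 1.
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param monomer monomer id recorded in the output.
#' @param frame_interval ps.
#' @return a [dihedral_series] for one monomer.
#' @export
sample_dihedrals <- function(basins, n_frames, seed = NULL, monomer = 1,
                             frame_interval = 10) {
  w <- check_basins(basins)
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  which_basin <- sample.int(length(basins), n_frames, replace = TRUE, prob = w)
  phi <- numeric(n_frames); psi <- numeric(n_frames)
  for (b in seq_along(basins)) {
    idx <- which(which_basin == b)
    if (!length(idx)) next
    ctr <- basins[[b]]$center * pi / 180
    kap <- basins[[b]]$kappa
    phi[idx] <- r_von_mises(length(idx), ctr[1], kap[1]) * 180 / pi
    psi[idx] <- r_von_mises(length(idx), ctr[2], kap[2]) * 180 / pi
  }
  dihedral_series(rep(monomer, n_frames), phi, psi,
                  frame_interval = frame_interval)
}

#' Generate a discrete protonation-state series
#'
#' First-order Markov switching with an exactly prescribed stationary law:
#' at each step, with probability `switch_prob` a new state is proposed
#' from the stationary fractions (and always accepted), otherwise the
#' state is kept.  This mimics the fixed trial-switch cadence of discrete
#' constant-pH simulations while keeping the stationary fractions exact.
#' `switch_prob = 0` freezes the initial state regardless of fractions.
#'
#' @param state_model list with `labels` (character), `fractions`
#'   (numeric, summing to 1), optional `switch_prob` (default 0.1, the
#'   0.01 / ps trial frequency times a 10 ps frame interval), optional
#'   `initial` state index.
#' @param n_frames series length.
#' @param seed integer RNG seed.
#' @param residue residue identifier recorded in the output.
#' @return a [state_series].
#' @export
generate_state_series <- function(state_model, n_frames, seed = NULL,
                                  residue = "RES1") {
  fr <- state_model$fractions
  labels <- state_model$labels
  stopifnot(length(fr) == length(labels))
  if (abs(sum(fr) - 1) > 1e-9)
    stop("configuration error: stationary fractions must sum to 1")
  p <- if (is.null(state_model$switch_prob)) 0.1 else state_model$switch_prob
  if (p < 0 || p > 1)
    stop("configuration error: switch probability must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  init <- if (!is.null(state_model$initial)) state_model$initial
          else sample.int(length(fr), 1, prob = fr)
  states <- integer(n_frames)
  states[1] <- init
  if (n_frames > 1) {
    switch_at <- stats::runif(n_frames - 1) < p
    proposals <- sample.int(length(fr), n_frames - 1, replace = TRUE, prob = fr)
    for (t in 2:n_frames)
      states[t] <- if (switch_at[t - 1]) proposals[t - 1] else states[t - 1]
  }
  state_series(data.frame(frame = seq_len(n_frames),
                          residue = residue, state = states),
               state_labels = stats::setNames(labels, seq_along(labels)))
}

#' Perturb a coordinate frame into an ensemble
#'
#' Adds i.i.d. Gaussian jitter of standard deviation `amplitude` (A) to
#' every Cartesian coordinate of the template, once per output frame.
#'
#' @param frame a single-frame [coord_frames] (or n x 3 matrix).
#' @param n_frames ensemble size.
#' @param amplitude jitter standard deviation, A (>= 0).
#' @param seed integer RNG seed.
#' @return a [coord_frames] stack of `n_frames` frames.
#' @export
perturb_frames <- function(frame, n_frames, amplitude = 0.05, seed = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (inherits(frame, "coord_frames")) {
    nm <- dimnames(frame)[[1]]
    frame <- frame_matrix(frame, 1)
  } else nm <- rownames(frame)
  if (!is.null(seed)) set.seed(seed)
  nat <- nrow(frame)
  arr <- array(rep(as.numeric(frame), n_frames), c(nat, 3, n_frames))
  arr <- arr + array(stats::rnorm(nat * 3 * n_frames, sd = amplitude),
                     c(nat, 3, n_frames))
  coord_frames(arr, atom_names = nm)
}
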