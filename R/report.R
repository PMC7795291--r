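#' Read a scenario / run configuration
#'
#' A scenario bundles everything [run_report] and the synthetic generator
#' need: residue type, per-monomer basin sets, the protonation state
#' model, charge scenario, grid spacing, temperature and seed.  The
#' shipped default scenario (`extdata/scenario_default.json`) emulates a
#' titratable Asp-Asp tripeptide whose sampling concentrates in the four
#' dominant Ramachandran regions.
#'
#' @param path JSON file; `NULL` loads the shipped default.
#' @return list of class `run_config`.
#' @export
read_scenario <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scenario_default.json", package = "pepconf")
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (is.null(cfg$temperature)) cfg$temperature <- 300
  if (cfg$temperature <= 0)
    stop("validation error: temperature must be positive")
  if (is.null(cfg$spacing)) cfg$spacing <- 1
  if (360 %% cfg$spacing != 0)
    stop("validation error: spacing must divide 360")
  if (is.null(cfg$seed)) cfg$seed <- 1
  if (is.null(cfg$n_frames)) cfg$n_frames <- 50000
  if (is.null(cfg$residue)) cfg$residue <- "ASP"
  if (is.null(cfg$charge_scenario)) cfg$charge_scenario <- "backbone_mismatch"
  w <- vapply(cfg$basins, function(b) b$weight, 0)
  if (abs(sum(w) - 1) > 1e-9)
    stop("validation error: basin weights must sum to 1")
  fr <- cfg$state_model$fractions
  if (abs(sum(fr) - 1) > 1e-9)
    stop("validation error: stationary fractions must sum to 1")
  structure(cfg, class = "run_config")
}

scenario_basins <- function(cfg) {
  lapply(cfg$basins, function(b)
    basin_spec(b$label, as.numeric(b$center),
               as.numeric(b$kappa), b$weight))
}

#' Generate all synthetic inputs for a scenario
#'
#' Writes the artifacts a real study would collect from a trajectory:
#' dihedral CSVs for both monomers, the toy topology JSON, a perturbed
#' multi-model PDB coordinate ensemble, single-point energy CSV, and the
#' protonation-state series CSV.
#'
#' @param cfg a `run_config` (see [read_scenario]).
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
generate_scenario <- function(cfg, out_dir) {
  cfg <- validate_scenario(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  basins <- scenario_basins(cfg)
  f <- character()
  s1 <- sample_dihedrals(basins, cfg$n_frames, seed = cfg$seed, monomer = 1)
  s2 <- sample_dihedrals(basins, cfg$n_frames, seed = cfg$seed + 1000L,
                         monomer = 2)
  both <- dihedral_series(c(s1$monomer, s2$monomer), c(s1$phi, s2$phi),
                          c(s1$psi, s2$psi))
  f["dihedrals"] <- file.path(out_dir, "dihedrals.csv")
  write_dihedral_series(both, f[["dihedrals"]])

  toy <- build_toy_tripeptide(cfg$residue)
  f["topology"] <- file.path(out_dir, "topology.json")
  write_topology(toy$topology, f[["topology"]])
  nens <- min(cfg$n_frames, if (is.null(cfg$n_coord_frames)) 500
              else cfg$n_coord_frames)
  ens <- perturb_frames(toy$frame, nens, amplitude = 0.05,
                        seed = cfg$seed + 2000L)
  f["frames"] <- file.path(out_dir, "frames.pdb")
  write_frames(ens, f[["frames"]], topology = toy$topology)

  cs <- if (identical(cfg$charge_scenario, "backbone_mismatch"))
    "deprotonated_cphmd" else "deprotonated"
  es <- single_point_series(ens, toy$topology, charge_set = cs)
  f["energies"] <- file.path(out_dir, "energies.csv")
  write_energy_series(es, f[["energies"]])

  st <- generate_state_series(cfg$state_model, cfg$n_frames,
                              seed = cfg$seed + 3000L, residue = cfg$residue)
  f["states"] <- file.path(out_dir, "states.csv")
  write_state_series(st, f[["states"]])
  invisible(f)
}

#' Run the full analysis pipeline on a scenario
#'
#' End-to-end driver: generates (or reuses) the synthetic inputs, then
#' computes the two Ramachandran free-energy grids (one per monomer), the
#' free-energy minima, the four theta-orientation grids, the nine-region
#' population table, the normalized energy histograms with their
#' backbone/side-chain electrostatic decomposition, and the
#' protonation-state populations.  Every artifact is listed with its MD5
#' checksum in `manifest.txt`; the run is deterministic for a given
#' scenario seed.
#'
#' @param config a `run_config`, a path to a scenario JSON, or `NULL` for
#'   the shipped default scenario.
#' @param out_dir output directory.
#' @return invisible path of the manifest file.
#' @export
run_report <- function(config = NULL, out_dir) {
  cfg <- if (is.null(config) || is.character(config)) read_scenario(config)
         else validate_scenario(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- generate_scenario(cfg, out_dir)

  series <- read_dihedral_series(files[["dihedrals"]])
  topo <- read_topology(files[["topology"]])
  frames <- read_frames(files[["frames"]])
  energies <- read_energy_series(files[["energies"]])
  states <- read_state_series(files[["states"]])

  arts <- as.character(files)
  put <- function(name) {
    p <- file.path(out_dir, name)
    arts <<- c(arts, p)
    p
  }
  for (m in 1:2) {
    fes <- boltzmann_invert(bin_angles(series, spacing = cfg$spacing,
                                       monomer = m), cfg$temperature)
    write_grid_matrix(fes, put(sprintf("rama_monomer%d.dat", m)))
    minima <- locate_minima(series, temperature = cfg$temperature, monomer = m)
    utils::write.csv(format(as.data.frame(minima), digits = 10),
                     put(sprintf("minima_monomer%d.csv", m)),
                     row.names = FALSE, quote = FALSE)
  }
  th <- theta_series(frames, topo)
  maps <- theta_maps(th, spacing = 2, temperature = cfg$temperature)
  for (nm in names(maps))
    write_grid_matrix(maps[[nm]], put(paste0("theta_", nm, ".dat")))

  pops <- region_populations(series)
  utils::write.csv(format(as.data.frame(pops$fractions), digits = 10),
                   put("region_populations.csv"), quote = FALSE)

  dists <- energy_distributions(energies, bin_width = 1)
  hist_df <- do.call(rbind, lapply(names(dists), function(tm)
    data.frame(term = tm,
               bin_lo = dists[[tm]]$breaks[-length(dists[[tm]]$breaks)],
               density = dists[[tm]]$density)))
  utils::write.csv(format(hist_df, digits = 10),
                   put("energy_histograms.csv"),
                   row.names = FALSE, quote = FALSE)

  agg <- default_aggregation(states)
  sp <- state_populations(states, aggregation = agg)
  pr <- as.data.frame(rbind(sp$per_residue, sp$aggregates))
  utils::write.csv(cbind(state = rownames(pr), format(pr, digits = 10)),
                   put("state_populations.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- file.path(out_dir, "manifest.txt")
  arts <- sort(unique(arts))
  sums <- tools::md5sum(arts)
  writeLines(sprintf("%s  %s", unname(sums), basename(arts)), manifest)
  invisible(manifest)
}

default_aggregation <- function(states) {
  labs <- unname(states$state_labels)
  agg <- list()
  syn <- grep("^syn", labs, value = TRUE)
  anti <- grep("^anti", labs, value = TRUE)
  if (length(syn) || length(anti))
    agg <- c(agg, list(syn = syn, anti = anti))
  if (any(c("delta", "epsilon") %in% labs))
    agg <- c(agg, list(delta = "delta", epsilon = "epsilon"))
  if (!length(agg)) agg <- list(all = labs)
  leftover <- setdiff(labs, unlist(agg))
  if (length(leftover)) agg$other <- leftover
  agg
}
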