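# R-side orchestration of the Monte Carlo photon transport: configuration,
# single instances, and batched runs with per-voxel uncertainty.

.KEV_TO_J <- 1.602176634e-16

#' Transport configuration
#'
#' @param n_histories Photon histories per simulation instance.
#' @param n_instances Number of independent instances combined for the dose
#'   estimate and its per-voxel uncertainty.
#' @param seed Master seed; instance seeds are derived deterministically.
#' @param cutoff_keV Photon cutoff energy; photons below it deposit locally.
#' @param compton,photoelectric,rayleigh Physics toggles.
#' @param primary_only If `TRUE`, every real interaction absorbs the photon
#'   locally (scored dose follows primary attenuation exactly).
#' @param ideal_absorber If `TRUE`, any brass path blocks the ray instead of
#'   attenuating it.
#' @param weight_min Post-collimator weights below this are terminated and
#'   booked as collimator absorption.
#' @return A `transport_config`.
#' @export
transport_config <- function(n_histories = 1e5, n_instances = 10, seed = 1,
                             cutoff_keV = 5, compton = TRUE,
                             photoelectric = TRUE, rayleigh = TRUE,
                             primary_only = FALSE, ideal_absorber = FALSE,
                             weight_min = 1e-7) {
  stopifnot(n_histories >= 0, n_instances >= 1, cutoff_keV >= 1)
  structure(list(n_histories = n_histories, n_instances = n_instances,
                 seed = as.numeric(seed), cutoff_keV = cutoff_keV,
                 compton = compton, photoelectric = photoelectric,
                 rayleigh = rayleigh, primary_only = primary_only,
                 ideal_absorber = ideal_absorber, weight_min = weight_min),
            class = "transport_config")
}

# deterministic instance seed stream derived from the master seed via a
# Lehmer generator (multiplications stay exact in double precision); the
# engine expands each seed into an independent xoshiro256** state
.instance_seeds <- function(master, n) {
  m <- 2147483647
  s <- (as.numeric(master) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    out[i] <- s
  }
  out
}

# assemble C++ inputs shared by all instances
.engine_inputs <- function(spectrum, setup, phantom, config) {
  geom <- setup$collimator
  mats <- phantom$materials
  brass <- default_materials()$brass
  mu <- .build_mu_tables(mats, brass, compton = config$compton,
                         photoelectric = config$photoelectric,
                         rayleigh = config$rayleigh)
  # world frame: collimator entrance z=0; phantom surface (z=0 in the
  # phantom frame) sits at thickness + air_gap
  thickness <- if (is.null(geom)) 0 else geom$thickness
  zshift <- thickness + setup$air_gap
  porig <- phantom$origin + c(0, 0, zshift)
  d <- dim(phantom$material_index)

  if (is.null(geom)) {
    half <- c(d[1] * phantom$voxel_size[1], d[2] * phantom$voxel_size[2]) / 2
    rect <- c(-half[1], half[1], -half[2], half[2])
    cpack <- NULL
  } else {
    ax <- slit_axes(geom)
    tk <- tan(ax$angle_deg * pi / 180)
    ce <- ax$offset_um / 1000 - thickness * tk
    margin <- 0.2
    rect <- c(min(ce) - geom$w1 / 2000 - margin,
              max(ce) + geom$w1 / 2000 + margin,
              -geom$slit_height / 2, geom$slit_height / 2)
    cpack <- .colli_pack(geom, ideal = config$ideal_absorber)
  }
  src_code <- match(setup$source_type,
                    c("pencil", "parallel", "point", "aligned")) - 1L
  list(spec_e = spectrum$bin_energies, spec_cdf = .spectrum_cdf(spectrum),
       source = list(type = src_code, rect = rect,
                     distance = setup$source_distance),
       colli = cpack,
       phantom = list(material = as.integer(phantom$material_index),
                      dim = as.integer(d),
                      voxel_size = phantom$voxel_size, origin = porig),
       mu = mu)
}

# voxel masses in kg
.voxel_mass_kg <- function(phantom) {
  dens <- vapply(phantom$materials, `[[`, 0, "mass_density")
  vol_cm3 <- prod(phantom$voxel_size) / 1000
  array(dens[phantom$material_index + 1L] * vol_cm3 / 1000,
        dim = dim(phantom$material_index))
}

.new_dose_grid <- function(dose, sd, phantom, tallies, config, seeds) {
  structure(list(dose = dose, sd = sd, voxel_size = phantom$voxel_size,
                 origin = phantom$origin, phantom = phantom,
                 tallies = tallies, n_histories = config$n_histories,
                 n_instances = length(seeds), seeds = seeds),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, %d instance(s) x %g histories\n",
    d[1], d[2], d[3], x$n_instances, x$n_histories))
  cat(sprintf("  max dose %.3e Gy/history; energy closure %.2e\n",
              max(x$dose), energy_closure(x)))
  invisible(x)
}

#' Simulate one transport instance
#'
#' Runs `config$n_histories` photon histories through the source ->
#' collimator -> air gap -> phantom chain and scores dose-to-medium
#' (Gy per emitted history) on the phantom grid.
#'
#' @param spectrum An `energy_spectrum`.
#' @param setup An [irradiation_setup()].
#' @param phantom A `voxel_phantom`.
#' @param config A [transport_config()].
#' @param seed Instance seed (defaults to `config$seed`).
#' @return A `dose_grid` (no per-voxel uncertainty for a single instance).
#' @export
simulate_instance <- function(spectrum, setup, phantom, config, seed = NULL) {
  stopifnot(inherits(spectrum, "energy_spectrum"),
            inherits(setup, "irradiation_setup"),
            inherits(phantom, "voxel_phantom"),
            inherits(config, "transport_config"))
  if (is.null(seed)) seed <- config$seed
  inp <- .engine_inputs(spectrum, setup, phantom, config)
  res <- cpp_simulate(inp$spec_e, inp$spec_cdf, inp$source, inp$colli,
                      inp$phantom, inp$mu,
                      list(n_histories = config$n_histories,
                           seed = as.numeric(seed),
                           cutoff_keV = config$cutoff_keV,
                           primary_only = config$primary_only,
                           weight_min = config$weight_min))
  edep <- array(res$edep, dim = dim(phantom$material_index))
  if (any(!is.finite(edep))) stop("non-finite dose scored")
  dose <- if (config$n_histories > 0) {
    edep * .KEV_TO_J / .voxel_mass_kg(phantom) / config$n_histories
  } else {
    edep * 0
  }
  tal <- res[c("emitted", "absorbed_collimator", "deposited", "escaped",
               "n_histories")]
  .new_dose_grid(dose, NULL, phantom, tal, config, seeds = seed)
}

#' Run batched transport instances
#'
#' Combines `config$n_instances` statistically independent instances
#' (distinct deterministic seed sub-streams): the dose is the instance
#' mean and the per-voxel uncertainty the standard deviation over
#' instances.
#'
#' @inheritParams simulate_instance
#' @return A `dose_grid` with `sd` filled in (requires >= 2 instances).
#' @export
run_batches <- function(spectrum, setup, phantom, config) {
  stopifnot(inherits(config, "transport_config"), config$n_instances >= 1)
  seeds <- .instance_seeds(config$seed, config$n_instances)
  sum1 <- sum2 <- 0
  tal <- NULL
  for (s in seeds) {
    g <- simulate_instance(spectrum, setup, phantom, config, seed = s)
    sum1 <- sum1 + g$dose
    sum2 <- sum2 + g$dose^2
    tal <- if (is.null(tal)) g$tallies
           else Map(`+`, tal, g$tallies)
  }
  n <- config$n_instances
  dose <- sum1 / n
  sdv <- if (n >= 2) {
    v <- (sum2 - sum1^2 / n) / (n - 1)
    sqrt(pmax(v, 0))
  } else NULL
  .new_dose_grid(dose, sdv, phantom, tal, config, seeds = seeds)
}

#' Relative energy-conservation residual
#'
#' `|emitted - (deposited + escaped + absorbed_in_collimator)| / emitted`.
#'
#' @param grid A `dose_grid`.
#' @return Non-negative residual (0 for a perfectly closed energy balance).
#' @export
energy_closure <- function(grid) {
  t <- grid$tallies
  if (t$emitted == 0) return(0)
  abs(t$emitted - (t$deposited + t$escaped + t$absorbed_collimator)) /
    t$emitted
}

#' Sample the Compton scattering kinematics
#'
#' Draws (scattered energy, polar cosine) pairs from the Klein-Nishina
#' differential cross section via Kahn's rejection method; each pair
#' satisfies the Compton relation exactly.
#'
#' @param energy_keV Incident photon energy, keV.
#' @param n Number of samples.
#' @param seed RNG seed for the engine's deterministic stream.
#' @return Matrix with columns `energy` (keV) and `cos_theta`.
#' @export
sample_compton <- function(energy_keV, n = 1, seed = 1) {
  cpp_sample_compton(energy_keV, as.integer(n), as.numeric(seed))
}

#' Scattered energy at a given angle (Compton relation)
#'
#' @param energy_keV Incident energy, keV.
#' @param cos_theta Polar scattering cosine.
#' @return Scattered photon energy, keV.
#' @export
compton_energy <- function(energy_keV, cos_theta) {
  energy_keV / (1 + energy_keV / 510.998950 * (1 - cos_theta))
}

#' Klein-Nishina angular density (unnormalized)
#'
#' Differential cross section per unit polar cosine, used as the numeric
#' integration oracle for the sampler.
#'
#' @param cos_theta Polar cosine.
#' @param energy_keV Incident energy, keV.
#' @return Unnormalized density values.
#' @export
klein_nishina_density <- function(cos_theta, energy_keV) {
  k <- energy_keV / 510.998950
  r <- 1 / (1 + k * (1 - cos_theta))   # E'/E
  r^2 * (r + 1 / r - 1 + cos_theta^2)
}

#' Write a dose grid to NIfTI
#'
#' Dose and (when present) per-voxel standard deviation as paired volumes,
#' plus a sidecar YAML with seeds, history counts and energy tallies.
#'
#' @param grid A `dose_grid`.
#' @param dose_path Output path for the dose volume.
#' @param sd_path Optional output path for the uncertainty volume.
#' @param meta_path Optional output path for the sidecar metadata.
#' @return Invisibly, the paths written.
#' @export
write_dose_nifti <- function(grid, dose_path, sd_path = NULL,
                             meta_path = NULL) {
  RNifti::writeNifti(.as_nifti_spaced(grid$dose, grid$voxel_size),
                     dose_path)
  if (!is.null(sd_path) && !is.null(grid$sd))
    RNifti::writeNifti(.as_nifti_spaced(grid$sd, grid$voxel_size), sd_path)
  if (!is.null(meta_path))
    yaml::write_yaml(list(n_histories = grid$n_histories,
                          n_instances = grid$n_instances,
                          seeds = grid$seeds, tallies = grid$tallies),
                     meta_path)
  invisible(c(dose_path, sd_path, meta_path))
}
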