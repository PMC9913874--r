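# Shared fixtures: synthetic profiles, dose grids and small phantom/transport
# setups built in code at test time.

# Gaussian comb profile on a fine lateral grid
gauss_comb <- function(centers, sigma = 0.3, amplitude = 1, baseline = 0.1,
                       dx = 0.05, extent = max(abs(centers)) + 2) {
  pos <- seq(-extent, extent, by = dx)
  dose <- baseline + Reduce(`+`, lapply(seq_along(centers), function(i) {
    a <- if (length(amplitude) > 1) amplitude[i] else amplitude
    a * exp(-(pos - centers[i])^2 / (2 * sigma^2))
  }))
  structure(data.frame(position = pos, dose = dose),
            class = c("lateral_profile", "data.frame"))
}

# Synthetic dose grid over a water phantom, with arbitrary dose/sd arrays
synthetic_grid <- function(dose, sd = NULL, voxel_size = c(0.1, 0.1, 0.5),
                           phantom = NULL) {
  d <- dim(dose)
  if (is.null(phantom)) {
    phantom <- mbrt:::.new_phantom(
      array(0L, dim = d), voxel_size,
      c(-d[1] / 2 * voxel_size[1], -d[2] / 2 * voxel_size[2], 0),
      default_materials()["water"], array(0L, dim = d))
  }
  stopifnot(identical(dim(phantom$material_index), d))
  tal <- list(emitted = sum(dose), absorbed_collimator = 0,
              deposited = sum(dose), escaped = 0, n_histories = 1)
  mbrt:::.new_dose_grid(dose, sd, phantom, tal,
                        transport_config(n_histories = 1, n_instances = 1),
                        seeds = 1)
}

# Analytic minibeam-like dose field over a head phantom: Gaussian comb in x,
# exponential decay in depth, uniform in y. Used for summary-pipeline tests
# that need labelled ROIs without running the Monte Carlo engine.
analytic_head_case <- function(voxel_size = c(0.2, 0.2, 0.5),
                               position = "P1", sigma = 0.35,
                               mu_per_mm = 0.02) {
  cfg <- head_phantom_config(position = position, voxel_size = voxel_size)
  ph <- make_head_phantom(cfg)
  setup <- irradiation_setup(position = position, collimator = "A")
  co <- grid_coords(ph)
  centers <- projected_pattern(setup$collimator, setup$air_gap)$center_mm
  lat <- 0.05 + Reduce(`+`, lapply(centers, function(ce)
    exp(-(co$x - ce)^2 / (2 * sigma^2))))
  depth <- exp(-mu_per_mm * pmax(co$z, 0))
  dose <- outer(outer(lat, rep(1, length(co$y))), depth)
  list(grid = synthetic_grid(array(dose, dim = dim(ph$material_index)),
                             voxel_size = voxel_size, phantom = ph),
       setup = setup, config = cfg)
}

# Table-style printed (peak, valley, PVDR) triples whose printed ratio is
# internally consistent under 1-decimal half-away-from-zero rounding
consistent_pvdr_rows <- function() {
  read.csv(text = "roi,peak,valley,pvdr
target,49.1,11.0,4.5
anterior_chamber,98.2,7.7,12.8
lens,101.4,10.4,9.8
retina,41.4,10.8,3.8
bone,57.8,21.3,2.7
brain,18.2,7.8,2.3
brain,13.2,6.5,2.0
target,68.2,5.4,12.6
brain,24.9,3.2,7.8
brain,18.5,2.9,6.4
target,75.3,3.9,19.3
target,58.9,8.5,6.9
retina,38.8,7.9,4.9
bone,47.2,14.0,3.4
brain,15.1,6.5,2.3
brain,11.7,5.8,2.0
target,52.1,8.7,6.0
lens,107.0,8.1,13.2
retina,46.2,8.5,5.4
bone,66.6,19.3,3.5
brain,18.1,6.6,2.7
brain,14.2,6.0,2.4
target,52.4,8.7,6.0
lens,107.5,7.1,15.1
retina,47.0,9.0,5.2
bone,82.8,20.0,4.1
tissue,26.9,8.3,3.2
tissue,19.8,7.6,2.6")
}

# quick transport setups
water_setup <- function(collimator = "A", source_type = "aligned",
                        air_gap = 30) {
  irradiation_setup(collimator = collimator, source_type = source_type,
                    air_gap = air_gap)
}
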