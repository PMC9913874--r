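test_that("Compton samples satisfy the kinematic relation exactly", {
  sm <- sample_compton(220, 2e4, seed = 5)
  expect_lt(max(abs(sm[, "energy"] -
                      compton_energy(220, sm[, "cos_theta"]))), 1e-9)
  expect_true(all(sm[, "energy"] <= 220))
  expect_true(all(abs(sm[, "cos_theta"]) <= 1))
  # backscatter closed form
  expect_equal(compton_energy(220, -1), 220 / (1 + 2 * 220 / 510.998950),
               tolerance = 1e-12)
  # determinism
  expect_identical(sample_compton(100, 100, seed = 9),
                   sample_compton(100, 100, seed = 9))
})

test_that("low-energy Compton limit approaches the symmetric Thomson law", {
  sm <- sample_compton(0.001, 2e5, seed = 2)
  # Thomson: mean polar cosine 0 by fore/aft symmetry
  se <- stats::sd(sm[, "cos_theta"]) / sqrt(nrow(sm))
  expect_lt(abs(mean(sm[, "cos_theta"])), 3 * se)
  # scattering is near-elastic at vanishing energy
  expect_equal(mean(sm[, "energy"]), 0.001, tolerance = 1e-4)
})

test_that("sampled Klein-Nishina moments match numeric integration", {
  E <- 100
  norm <- stats::integrate(klein_nishina_density, -1, 1, energy_keV = E,
                           rel.tol = 1e-10)$value
  mean_cos <- stats::integrate(function(m)
    m * klein_nishina_density(m, E), -1, 1, rel.tol = 1e-10)$value / norm
  mean_e <- stats::integrate(function(m)
    compton_energy(E, m) * klein_nishina_density(m, E), -1, 1,
    rel.tol = 1e-10)$value / norm
  sm <- sample_compton(E, 2e5, seed = 31)
  expect_lt(abs(mean(sm[, "cos_theta"]) - mean_cos),
            3 * stats::sd(sm[, "cos_theta"]) / sqrt(nrow(sm)))
  expect_lt(abs(mean(sm[, "energy"]) - mean_e),
            3 * stats::sd(sm[, "energy"]) / sqrt(nrow(sm)))
})

test_that("primary-only pencil dose follows exp(-mu x) in water", {
  water <- default_materials()$water
  mu <- linear_attenuation(water, 100) / 10  # per mm
  spec <- energy_spectrum(100, 1)
  ph <- make_water_phantom(lateral_extent = 2, depth = 40,
                           voxel_size = c(0.5, 0.5, 0.5))
  setup <- irradiation_setup(collimator = NULL, source_type = "pencil",
                             air_gap = 0)
  cfg <- transport_config(n_histories = 2e5, n_instances = 5, seed = 1,
                          primary_only = TRUE)
  g <- run_batches(spec, setup, ph, cfg)
  expect_lt(energy_closure(g), 1e-9)
  tot <- apply(g$dose, 1:2, sum)
  ij <- which(tot == max(tot), arr.ind = TRUE)[1, ]
  dz <- g$dose[ij[1], ij[2], ]
  sdz <- g$sd[ij[1], ij[2], ] / sqrt(g$n_instances)
  co <- grid_coords(g)
  ref <- dz[1] * exp(-mu * (co$z - co$z[1]))
  refsd <- sdz[1] * exp(-mu * (co$z - co$z[1]))
  for (iz in c(10, 30, 50, 70)) {
    z <- abs(dz[iz] - ref[iz]) / sqrt(sdz[iz]^2 + refsd[iz]^2)
    expect_lt(z, 3)
  }
})

test_that("point-source fluence falls off with inverse square distance", {
  # primary-only monoenergetic cone into water: on-axis dose follows
  # exp(-mu z) / (S + z)^2
  water <- default_materials()$water
  mu <- linear_attenuation(water, 100) / 10
  spec <- energy_spectrum(100, 1)
  ph <- make_water_phantom(lateral_extent = 3, depth = 40,
                           voxel_size = c(1, 1, 0.5) * 0.5)
  setup <- irradiation_setup(collimator = NULL, source_type = "point",
                             air_gap = 0, source_distance = 100)
  cfg <- transport_config(n_histories = 4e5, n_instances = 5, seed = 3,
                          primary_only = TRUE)
  g <- run_batches(spec, setup, ph, cfg)
  expect_lt(energy_closure(g), 1e-9)
  co <- grid_coords(g)
  # average the 2x2 central columns (the axis sits on a voxel corner)
  ctr <- order(abs(co$x))[1:2]
  dz <- apply(g$dose[ctr, ctr, ], 3, mean)
  vz <- apply(g$sd[ctr, ctr, ]^2, 3, sum) / 16 / g$n_instances
  S <- 100
  ref <- dz[1] * exp(-mu * (co$z - co$z[1])) *
    (S + co$z[1])^2 / (S + co$z)^2
  refv <- vz[1] * (exp(-mu * (co$z - co$z[1])) *
                     (S + co$z[1])^2 / (S + co$z)^2)^2
  for (iz in c(20, 40, 60, 79)) {
    z <- abs(dz[iz] - ref[iz]) / sqrt(vz[iz] + refv[iz])
    expect_lt(z, 3.5)
  }
})

test_that("zero histories give an all-zero grid and zero tallies", {
  spec <- energy_spectrum(100, 1)
  ph <- make_water_phantom(lateral_extent = 1, depth = 5,
                           voxel_size = c(0.5, 0.5, 0.5))
  setup <- irradiation_setup(collimator = NULL, source_type = "pencil",
                             air_gap = 0)
  g <- simulate_instance(spec, setup, ph,
                         transport_config(n_histories = 0, n_instances = 1))
  expect_true(all(g$dose == 0))
  expect_equal(g$tallies$emitted, 0)
  expect_equal(energy_closure(g), 0)
})

test_that("runs are deterministic and instances independent", {
  spec <- default_spectrum_220kv()
  ph <- make_water_phantom(lateral_extent = 4, depth = 20,
                           voxel_size = c(0.2, 0.2, 0.5))
  setup <- water_setup("A3s")
  cfg <- transport_config(n_histories = 2e4, n_instances = 3, seed = 42,
                          ideal_absorber = TRUE)
  g1 <- run_batches(spec, setup, ph, cfg)
  g2 <- run_batches(spec, setup, ph, cfg)
  expect_identical(g1$dose, g2$dose)
  expect_identical(g1$sd, g2$sd)
  expect_lt(energy_closure(g1), 1e-9)
  # identical seeds give identical instances (zero variance across them)
  a <- simulate_instance(spec, setup, ph, cfg, seed = 7)
  b <- simulate_instance(spec, setup, ph, cfg, seed = 7)
  expect_identical(a$dose, b$dose)
  # different seeds differ
  d <- simulate_instance(spec, setup, ph, cfg, seed = 8)
  expect_false(identical(a$dose, d$dose))
})

test_that("the minibeam dose field is laterally symmetric", {
  spec <- default_spectrum_220kv()
  ph <- make_water_phantom(lateral_extent = 5, depth = 30,
                           voxel_size = c(0.1, 0.5, 0.5))
  setup <- water_setup("A")
  cfg <- transport_config(n_histories = 2e5, n_instances = 6, seed = 17,
                          ideal_absorber = TRUE)
  g <- run_batches(spec, setup, ph, cfg)
  sl <- extract_slice(g, thickness = 10)
  pr <- lateral_profile(sl, 10, average_mm = 4)
  n <- nrow(pr)
  fwd <- pr$dose; rev <- pr$dose[n:1]
  sdc <- sqrt(pr$sd^2 + pr$sd[n:1]^2) / sqrt(g$n_instances)
  z <- abs(fwd - rev) / pmax(sdc, 1e-300)
  use <- fwd + rev > 0
  expect_lt(mean(z[use] > 3), 0.02)
})

test_that("valleys are dose-free for primary-only ideal-absorber beams", {
  spec <- energy_spectrum(100, 1)
  ph <- make_water_phantom(lateral_extent = 4, depth = 20,
                           voxel_size = c(0.1, 0.5, 0.5))
  setup <- water_setup("A")
  cfg <- transport_config(n_histories = 1e5, n_instances = 1, seed = 4,
                          primary_only = TRUE, ideal_absorber = TRUE)
  g <- simulate_instance(spec, setup, ph, cfg)
  sl <- extract_slice(g, thickness = 10)
  pr <- lateral_profile(sl, 10, average_mm = 4)
  pp <- projected_pattern(setup$collimator, setup$air_gap + 10)
  pv <- find_peaks_valleys(pr, pp$center_mm, ctc = 1.15)
  expect_true(all(pv$peaks$dose > 0))
  expect_equal(max(pv$valleys$dose), 0)
})
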