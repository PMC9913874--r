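test_that("preset geometries carry the published slit dimensions", {
  a <- build_collimator("A")
  expect_equal(a$n_slits, 5)
  expect_equal(a$slit_height, 10)
  expect_equal(c(a$w1, a$w2, a$w3), c(400, 400, 425))
  expect_equal(c(a$alpha, a$beta), c(0.595, 0.632))
  expect_equal(c(a$ctc1, a$ctc2), c(1150, 1275))
  expect_equal(a$thickness, 30)
  expect_equal(a$wall_material, "brass")

  ah <- build_collimator("Ah")
  expect_equal(ah$slit_height, 5)
  expect_equal(c(ah$w1, ah$w2, ah$w3), c(a$w1, a$w2, a$w3))

  b <- build_collimator("B")
  expect_equal(c(b$w1, b$w2, b$w3), c(400, 409, 500))
  expect_equal(c(b$alpha, b$beta), c(0.611, 0.744))
  expect_equal(c(b$ctc1, b$ctc2), c(1900, 1875))

  cc <- build_collimator("C")
  expect_equal(cc$n_slits, 3)
  expect_equal(c(cc$w1, cc$w2), c(400, 425))
  expect_equal(cc$alpha, 0.632)
  expect_equal(cc$ctc1, 2425)

  expect_error(build_collimator("Z"), "unknown collimator")
})

test_that("geometry invariants are enforced at construction", {
  expect_error(collimator_geometry("x", 4, 10, 400, 400, 425, 0.6, 0.7,
                                   1000, 1000), "odd")
  expect_error(collimator_geometry("x", 5, 10, 500, 400, 425, 0.6, 0.7,
                                   1000, 1000), "widen")
  expect_error(collimator_geometry("x", 5, 10, 400, 400, 425, -0.6, 0.7,
                                   1000, 1000))
  expect_error(collimator_geometry("x", 5, 10, 400, 400, NA, 0.6, 0.7,
                                   1000, 1000), "incomplete")
})

test_that("slit axes place the layout symmetrically about the centre", {
  a3 <- slit_axes(build_collimator("A3s"))
  expect_equal(a3$angle_deg, c(-0.595, 0, 0.595))
  expect_equal(a3$offset_um, c(-1150, 0, 1150))

  b <- slit_axes(build_collimator("B"))
  expect_equal(b$offset_um[c(1, 5)], c(-(1900 + 1875), 1900 + 1875))
  expect_equal(b$angle_deg[c(1, 5)], c(-0.744, 0.744))

  one <- collimator_geometry("single", 1, 10, 400, 425, alpha = 0.5,
                             ctc1 = 1)
  expect_equal(slit_axes(one),
               data.frame(slit = 1L, angle_deg = 0, offset_um = 0))
})

test_that("collimator library file reproduces the presets", {
  lib <- read_collimator_library(system.file("extdata", "collimators.yaml",
                                             package = "mbrt"))
  for (lb in c("A", "Ah", "A3s", "B", "C")) {
    expect_equal(lib[[lb]], build_collimator(lb))
  }
})

test_that("transmit handles on-axis, blocked and tilted rays", {
  g <- build_collimator("A")
  # along the central slit axis: zero brass path
  r0 <- transmit(g, c(0, 0, -5), c(0, 0, 1))
  expect_equal(r0$brass_path, 0)
  expect_true(r0$transmitted)
  # 10 mm lateral offset, axial direction: the full 30 mm of brass
  expect_equal(transmit(g, c(10, 0, 0), c(0, 0, 1))$brass_path, 30)
  # entering the central slit but tilted by 2 deg: partial wall path
  tilt <- transmit(g, c(0, 0, 0), c(sin(2 * pi / 180), 0, cos(2 * pi / 180)))
  expect_gt(tilt$brass_path, 0)
  expect_lt(tilt$brass_path, 30)
  # ideal absorber blocks any wall contact
  expect_false(transmit(g, c(10, 0, 0), c(0, 0, 1), ideal = TRUE)$transmitted)
  # ray parallel to the entrance plane is rejected
  expect_error(transmit(g, c(0, 0, 0), c(1, 0, 0)), "parallel")
})

# dense point-in-aperture sampling along the ray: the independent oracle
.oracle_brass_path <- function(geom, origin, direction, n = 2e4) {
  d <- direction / sqrt(sum(direction^2))
  t0 <- (0 - origin[3]) / d[3]
  t1 <- (geom$thickness - origin[3]) / d[3]
  tt <- t0 + (seq_len(n) - 0.5) / n * (t1 - t0)
  px <- origin[1] + tt * d[1]
  py <- origin[2] + tt * d[2]
  pz <- origin[3] + tt * d[3]
  ax <- slit_axes(geom)
  if (geom$n_slits >= 5) {
    wz <- c(0, geom$thickness / 2, geom$thickness)
    ww <- c(geom$w1, geom$w2, geom$w3) / 1000
  } else {
    wz <- c(0, geom$thickness)
    ww <- c(geom$w1, geom$w2) / 1000
  }
  w_at <- stats::approx(wz, ww, xout = pz)$y
  inside <- rep(FALSE, n)
  for (k in seq_len(nrow(ax))) {
    ck <- ax$offset_um[k] / 1000 -
      (geom$thickness - pz) * tan(ax$angle_deg[k] * pi / 180)
    inside <- inside | (abs(px - ck) <= w_at / 2 &
                          abs(py) <= geom$slit_height / 2)
  }
  mean(!inside) * (t1 - t0)
}

test_that("transmit agrees with the point-sampling oracle on random rays", {
  set.seed(11)
  for (lb in c("A", "B", "C")) {
    g <- build_collimator(lb)
    for (i in 1:34) {
      o <- c(runif(1, -4, 4), runif(1, -6, 6), 0)
      d <- c(sin(runif(1, -0.03, 0.03)), sin(runif(1, -0.03, 0.03)), 1)
      d <- d / sqrt(sum(d^2))
      n <- 2e4
      step <- (30 / d[3]) / n
      expect_lt(abs(transmit(g, o, d)$brass_path -
                      .oracle_brass_path(g, o, d, n)),
                3 * step)
    }
  }
})

test_that("the aperture union is mirror-symmetric for every preset", {
  set.seed(13)
  for (lb in c("A", "Ah", "A3s", "B", "C")) {
    g <- build_collimator(lb)
    o <- cbind(runif(50, -4, 4), runif(50, -6, 6), 0)
    d <- cbind(sin(runif(50, -0.05, 0.05)), sin(runif(50, -0.05, 0.05)), 1)
    mo <- o; mo[, 1] <- -mo[, 1]
    md <- d; md[, 1] <- -md[, 1]
    expect_equal(transmit(g, o, d)$brass_path,
                 transmit(g, mo, md)$brass_path, tolerance = 1e-9)
  }
})

test_that("projected pattern follows the slit axes", {
  a <- build_collimator("A")
  # at the exit plane, centres equal the exit offsets
  p0 <- projected_pattern(a, 0)
  expect_equal(p0$center_mm, slit_axes(a)$offset_um / 1000)
  expect_equal(diff(p0$center_mm[3:4]), 1.150)
  # spacing grows trigonometrically with distance
  p20 <- projected_pattern(a, 20)
  expect_equal(diff(p20$center_mm[3:4]) - diff(p0$center_mm[3:4]),
               20 * tan(0.595 * pi / 180), tolerance = 1e-9)
  # strictly increasing spacing in z for all presets
  for (lb in c("A", "Ah", "A3s", "B", "C")) {
    g <- build_collimator(lb)
    sp <- vapply(seq(0, 60, by = 5), function(z) {
      ce <- projected_pattern(g, z)$center_mm
      min(diff(ce))
    }, 0)
    expect_true(all(diff(sp) > 0))
  }
})
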