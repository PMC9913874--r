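test_that("slice extraction averages the requested slab", {
  # uniform grid -> uniform slice
  g <- synthetic_grid(array(2, dim = c(10, 8, 6)))
  sl <- extract_slice(g, axis = "y", at = 0, thickness = 0.3)
  expect_true(all(sl$dose == 2))
  expect_equal(dim(sl$dose), c(10, 6))

  # linear ramp along z: slice values equal the ramp at the slice centre
  co <- grid_coords(g)
  ramp <- array(rep(co$z, each = 80), dim = c(10, 8, 6))
  gr <- synthetic_grid(ramp)
  slr <- extract_slice(gr, axis = "y", at = 0)
  expect_equal(slr$dose[5, ], co$z, tolerance = 1e-12)

  # one-voxel thickness is an identity extraction
  sl1 <- extract_slice(g, axis = "y", at = co$y[3], thickness = 0.1)
  expect_equal(sl1$dose, g$dose[, 3, ])

  expect_error(extract_slice(g, axis = "y", at = 99), "outside")
})

test_that("peak/valley detection recovers a synthetic Gaussian comb", {
  centers <- seq(-2.6, 2.6, by = 1.3)
  pr <- gauss_comb(centers, sigma = 0.3, amplitude = 1, baseline = 0.1)
  pv <- find_peaks_valleys(pr, centers, ctc = 1.3)
  expect_equal(nrow(pv$peaks), 5)
  expect_equal(nrow(pv$valleys), 4)
  expect_lt(max(abs(pv$peaks$center - centers)), 0.05 + 1e-9)
  mid <- centers[-1] - 0.65
  expect_lt(max(abs(pv$valleys$center - mid)), 0.05 + 1e-9)
  expect_true(all(pv$peaks$dose > max(pv$valleys$dose)))

  # flat profile: no detectable modulation
  flat <- data.frame(position = pr$position, dose = rep(1, nrow(pr)))
  expect_error(find_peaks_valleys(flat, centers, ctc = 1.3), "degenerate")

  # single beamlet: one peak, no valleys
  pv1 <- find_peaks_valleys(gauss_comb(0, sigma = 0.3), 0)
  expect_equal(nrow(pv1$peaks), 1)
  expect_null(pv1$valleys)

  # profile must cover the expected centres
  expect_error(find_peaks_valleys(pr, c(centers, 50)), "cover")
})

test_that("interleaving invariant holds for detected peaks and valleys", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:7, 1)
    ctc <- runif(1, 1, 3)
    centers <- (seq_len(n) - (n + 1) / 2) * ctc
    pr <- gauss_comb(centers, sigma = ctc / 5,
                     amplitude = runif(n, 0.5, 1.5), baseline = 0.05)
    pv <- find_peaks_valleys(pr, centers, ctc = ctc)
    ord <- sort(c(pv$peaks$center, pv$valleys$center))
    expect_equal(ord[seq(1, 2 * n - 1, by = 2)], sort(pv$peaks$center))
    expect_true(all(pv$valleys$dose <
                      pmin(pv$peaks$dose[-1], pv$peaks$dose[-n])))
  }
})

test_that("FWHM measures standard shapes correctly", {
  # Gaussian: 2.3548 sigma
  pr <- gauss_comb(0, sigma = 0.3, baseline = 0, dx = 0.05)
  pv <- find_peaks_valleys(pr, 0)
  expect_equal(fwhm(pr, pv$peaks$index), 2 * sqrt(2 * log(2)) * 0.3,
               tolerance = 0.05 / (2 * sqrt(2 * log(2)) * 0.3))

  # rectangular pulse of width 0.4 (within one sample of the true width)
  pos <- seq(-1, 1, by = 0.01)
  rect <- data.frame(position = pos, dose = as.numeric(abs(pos) <= 0.2))
  expect_lt(abs(fwhm(rect, which.min(abs(pos))) - 0.4), 0.011)

  # triangle of height 2 and base 2: half maximum at half base
  tri <- data.frame(position = pos, dose = pmax(0, 2 * (1 - abs(pos))))
  expect_equal(fwhm(tri, which.min(abs(pos))), 1, tolerance = 1e-9)

  # overlapping beams: no crossing within the window -> flagged
  wide <- gauss_comb(0, sigma = 2, baseline = 0, extent = 3)
  iw <- which.max(wide$dose)
  expect_warning(res <- fwhm(wide, iw, window = 0.5), "unmeasurable")
  expect_true(is.na(res))
})

test_that("PVDR arithmetic reproduces printed worked examples", {
  expect_equal(round_half_away(pvdr(49.1, 11.0), 1), 4.5)
  expect_equal(round_half_away(pvdr(75.3, 3.9), 1), 19.3)
  expect_equal(pvdr(1, 1), 1)
  expect_warning(r <- pvdr(5, 0), "infinite")
  expect_equal(r, Inf)
  expect_error(pvdr(-1, 2))
})

test_that("report rounding is half away from zero at one decimal", {
  expect_equal(round_half_away(9.75, 1), 9.8)
  expect_equal(round_half_away(-9.75, 1), -9.8)
  expect_equal(round_half_away(2.04, 1), 2.0)
  expect_equal(round_half_away(4.46363, 1), 4.5)
})

test_that("ROI statistics summarise uniform and modulated regions", {
  # uniform 2 Gy ROI: Dmean 2, PVDR 1
  g <- synthetic_grid(array(2, dim = c(40, 4, 10)))
  sl <- extract_slice(g, at = 0, thickness = 0.4)
  mask <- matrix(TRUE, 40, 10)
  row <- roi_statistics(sl, mask, depths = 2.5, expected_centers = 0,
                        roi = "target")
  expect_equal(row$Dmean, 2)
  expect_equal(row$PVDR, 1)

  # synthetic rectangular comb with known peak 10 / valley 2
  centers <- c(-1.3, 0, 1.3)
  pos <- seq(-2, 2, by = 0.1)
  nearest <- vapply(pos, function(p) min(abs(p - centers)), 0)
  prof <- data.frame(position = pos, dose = 2 + 8 * (nearest < 0.25))
  nz <- 10
  dose <- array(rep(prof$dose, times = 4 * nz),
                dim = c(nrow(prof), 4, nz))
  gc <- synthetic_grid(dose)
  slc <- extract_slice(gc, at = 0, thickness = 0.4)
  maskc <- matrix(TRUE, nrow(prof), nz)
  rowc <- roi_statistics(slc, maskc, depths = 2.5,
                         expected_centers = centers, roi = "target",
                         ctc = 1.3)
  expect_equal(rowc$Dpeak, 10, tolerance = 1e-3)
  expect_equal(rowc$Dvalley, 2, tolerance = 0.01)
  expect_equal(rowc$PVDR, 5, tolerance = 0.01)

  # two-depth ROI rows equal the corresponding single-depth results
  rows2 <- roi_statistics(slc, maskc, depths = c(1, 4),
                          expected_centers = centers, roi = "brain",
                          ctc = 1.3)
  r1 <- roi_statistics(slc, maskc, depths = 1, expected_centers = centers,
                       ctc = 1.3)
  r4 <- roi_statistics(slc, maskc, depths = 4, expected_centers = centers,
                       ctc = 1.3)
  expect_equal(rows2$Dpeak, c(r1$Dpeak, r4$Dpeak))
  expect_equal(rows2$PVDR, c(r1$PVDR, r4$PVDR))

  expect_error(roi_statistics(sl, mask & FALSE, 1, 0), "empty ROI")
})

test_that("prescription scaling reproduces verified relative->absolute cells", {
  rel <- data.frame(roi = c("target", "anterior_chamber", "lens", "bone"),
                    depth = c(20, 1, 5, 29),
                    Dmean = c(100, 157, 180, 108),
                    Dpeak = c(164, 468, 533, 265),
                    Dvalley = c(37, 16, 18, 33),
                    PVDR = c(4.5, 30.2, 29.0, 7.9))
  class(rel) <- c("dose_summary", "data.frame")
  abs30 <- scale_to_prescription(rel, 30)
  expect_equal(abs30$Dmean, c(30.0, 47.1, 54.0, 32.4))
  expect_equal(abs30$PVDR, rel$PVDR)  # PVDR invariant under scaling
  expect_equal(attr(abs30, "units"), "Gy")
  # a non-relative summary is rejected
  expect_error(scale_to_prescription(abs30, 30), "relative")
})

test_that("relative summaries are invariant under global dose rescaling", {
  case <- analytic_head_case()
  s1 <- build_summary(case$grid, case$setup, slice_thickness = 0.2)
  g2 <- case$grid
  g2$dose <- g2$dose * 3.7
  s2 <- build_summary(g2, case$setup, slice_thickness = 0.2)
  expect_equal(s1$Dmean, s2$Dmean, tolerance = 1e-12)
  expect_equal(s1$Dpeak, s2$Dpeak, tolerance = 1e-12)
  expect_equal(s1$PVDR, s2$PVDR, tolerance = 1e-12)
  expect_equal(s1$Dmean[s1$roi == "target"], 100)
  # brain rows are probed at two depths, shallow first
  br <- s1[s1$roi == "brain", ]
  expect_equal(nrow(br), 2)
  expect_lt(br$depth[1], br$depth[2])
})

test_that("global uncertainty averages relative std over the mask", {
  dose <- array(10, dim = c(6, 6, 6))
  gu <- global_uncertainty(synthetic_grid(dose, sd = dose * 0.02),
                           array(TRUE, dim = dim(dose)))
  expect_equal(as.numeric(gu), 0.02)

  # two-voxel mask with 1% and 3% relative uncertainty -> 2%
  sd2 <- dose * 0.01
  sd2[2, 1, 1] <- 10 * 0.03
  mask2 <- array(FALSE, dim = dim(dose)); mask2[1:2, 1, 1] <- TRUE
  expect_equal(as.numeric(global_uncertainty(synthetic_grid(dose, sd2),
                                             mask2)), 0.02)

  # restriction to the analysed region excludes a noisy low-dose halo
  dose3 <- array(0.01, dim = c(20, 4, 10))
  dose3[8:12, , ] <- 10
  sd3 <- dose3 * 0.02
  sd3[dose3 < 1] <- 0.01           # 100% relative noise in the halo
  g3 <- synthetic_grid(dose3, sd3)
  full <- array(TRUE, dim = dim(dose3))
  core <- full; core[c(1:7, 13:20), , ] <- FALSE
  expect_lt(as.numeric(global_uncertainty(g3, core)),
            as.numeric(global_uncertainty(g3, full)))

  # zero-dose voxels are excluded and counted
  dose4 <- dose; dose4[1, 1, 1] <- 0
  gu4 <- global_uncertainty(synthetic_grid(dose4, dose4 * 0.02),
                            array(TRUE, dim = dim(dose)))
  expect_equal(attr(gu4, "n_zero_dose"), 1)
  expect_error(global_uncertainty(synthetic_grid(dose * 0, dose * 0),
                                  array(TRUE, dim = dim(dose))),
               "all-zero")
})

test_that("comb detectors recover generator parameters within one voxel", {
  dx <- 0.1
  sigma <- 0.3
  centers <- seq(-2.6, 2.6, by = 1.3)
  pr <- gauss_comb(centers, sigma = sigma, amplitude = 1, baseline = 0.1,
                   dx = dx)
  pv <- find_peaks_valleys(pr, centers, ctc = 1.3)
  expect_lt(max(abs(pv$peaks$center - centers)), dx + 1e-9)
  expect_lt(max(abs(diff(pv$peaks$center) - 1.3)), dx + 1e-9)
  f <- vapply(pv$peaks$index, function(i) fwhm(pr, i), 0)
  expect_lt(max(abs(f - 2 * sqrt(2 * log(2)) * sigma)), dx)
  expect_lt(max(abs(pv$peaks$dose - (1 + 0.1))), 0.02)
})
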