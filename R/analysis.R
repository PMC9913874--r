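# Spatial-fractionation dose analysis: slice extraction, lateral profiles,
# peak/valley detection anchored to the geometric minibeam pattern, FWHM and
# centre-to-centre metrics, PVDR, per-ROI dose summaries with prescription
# scaling, and region-restricted global uncertainty.

#' Round half away from zero
#'
#' Report rounding policy for dose tables (one decimal by default).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Extract a thin slice from a dose grid
#'
#' Averages the dose (and combines the per-voxel uncertainty) across a slab
#' of the given thickness centred at `at` along the chosen axis. The default
#' is the central 0.1 mm slice perpendicular to the slit-height direction.
#'
#' @param grid A `dose_grid`.
#' @param axis Axis normal to the slice ("y" by default).
#' @param at Slice centre coordinate in mm (grid frame).
#' @param thickness Slice thickness in mm (defaults to one voxel).
#' @return A `dose_slice`: list with `dose` and `sd` matrices (remaining
#'   two axes), coordinate vectors, and the slab definition.
#' @export
extract_slice <- function(grid, axis = "y", at = 0, thickness = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  ai <- match(axis, c("x", "y", "z"))
  if (is.na(ai)) stop("axis must be x, y or z")
  if (is.null(thickness)) thickness <- grid$voxel_size[ai]
  co <- grid_coords(grid)
  sel <- which(abs(co[[ai]] - at) <= thickness / 2 + 1e-9)
  if (length(sel) == 0) stop("slice plane outside the dose grid")
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[ai]] <- sel
  sub <- do.call(`[`, c(list(grid$dose), idx, list(drop = FALSE)))
  dose <- apply(sub, setdiff(1:3, ai), mean)
  sdm <- NULL
  if (!is.null(grid$sd)) {
    subv <- do.call(`[`, c(list(grid$sd^2), idx, list(drop = FALSE)))
    sdm <- sqrt(apply(subv, setdiff(1:3, ai), mean)) / sqrt(length(sel))
  }
  keep <- setdiff(c("x", "y", "z"), c("x", "y", "z")[ai])
  structure(list(dose = dose, sd = sdm,
                 coords = co[keep], axis = axis, at = at,
                 thickness = thickness),
            class = "dose_slice")
}

#' Lateral dose profile at a depth
#'
#' Extracts dose vs lateral position from an x-z dose slice at the stated
#' depth (averaging over `average_mm` of depth around it).
#'
#' @param slice A `dose_slice` with axes x (lateral) and z (depth).
#' @param depth Depth in mm (grid frame z).
#' @param average_mm Longitudinal averaging window, mm (0 = single row).
#' @return A data frame (`lateral_profile`) with `position`, `dose`, `sd`
#'   and the depth as an attribute.
#' @export
lateral_profile <- function(slice, depth, average_mm = 0) {
  stopifnot(inherits(slice, "dose_slice"))
  z <- slice$coords$z
  sel <- which(abs(z - depth) <= max(average_mm / 2, 1e-9) |
                 abs(z - depth) == min(abs(z - depth)))
  prof <- data.frame(position = slice$coords$x,
                     dose = rowMeans(slice$dose[, sel, drop = FALSE]),
                     sd = if (is.null(slice$sd)) NA_real_ else
                       sqrt(rowMeans(slice$sd[, sel, drop = FALSE]^2)) /
                         sqrt(length(sel)))
  attr(prof, "depth") <- depth
  class(prof) <- c("lateral_profile", "data.frame")
  prof
}

#' Detect minibeam peaks and valleys on a lateral profile
#'
#' Each peak is the profile maximum within a window of +/- ctc/4 around its
#' geometric expected centre (from [projected_pattern()]); each valley is
#' the minimum over the open interval between adjacent detected peak
#' centres. Ties break toward the window centre.
#'
#' @param profile A `lateral_profile` or data frame with `position`, `dose`.
#' @param expected_centers Geometric beamlet centres, mm.
#' @param ctc Nominal centre-to-centre spacing used for the search window,
#'   mm (defaults to the minimum spacing of `expected_centers`).
#' @return List with data frames `peaks` (`center` = argmax position,
#'   `centroid` = dose-weighted position within the window, `dose`,
#'   `index`) and `valleys` (`center`, `dose`, `index`).
#' @export
find_peaks_valleys <- function(profile, expected_centers, ctc = NULL) {
  pos <- profile$position
  val <- profile$dose
  expected_centers <- sort(expected_centers)
  if (min(expected_centers) < min(pos) - 1e-9 ||
      max(expected_centers) > max(pos) + 1e-9)
    stop("profile does not cover all expected centers")
  if (is.null(ctc)) {
    ctc <- if (length(expected_centers) > 1) min(diff(expected_centers))
           else (max(pos) - min(pos)) / 2
  }
  peaks <- lapply(expected_centers, function(ce) {
    w <- which(abs(pos - ce) <= ctc / 4)
    if (length(w) == 0) return(NULL)
    m <- max(val[w])
    cand <- w[val[w] >= m]
    i <- cand[which.min(abs(pos[cand] - ce))]  # ties toward window centre
    # dose-weighted centroid: robust position for flat-topped beamlets
    cen <- if (sum(val[w]) > 0) sum(pos[w] * val[w]) / sum(val[w]) else pos[i]
    data.frame(center = pos[i], centroid = cen, dose = val[i], index = i)
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks) || nrow(peaks) < length(expected_centers))
    stop("peak detection failed: fewer maxima than expected beamlets")
  valleys <- NULL
  if (nrow(peaks) > 1) {
    valleys <- do.call(rbind, lapply(seq_len(nrow(peaks) - 1), function(j) {
      w <- which(pos > peaks$center[j] & pos < peaks$center[j + 1])
      if (length(w) == 0)
        stop("no samples between adjacent peaks")
      i <- w[which.min(val[w])]
      data.frame(center = pos[i], dose = val[i], index = i)
    }))
    bad <- which(peaks$dose[-nrow(peaks)] <= valleys$dose |
                   peaks$dose[-1] <= valleys$dose)
    if (length(bad) > 0)
      stop("degenerate profile: missing peaks at expected centers ",
           paste(signif(expected_centers[bad], 4), collapse = ", "),
           " mm (no modulation above adjoining valleys)")
  }
  list(peaks = peaks, valleys = valleys)
}

#' Full width at half maximum of a detected peak
#'
#' Width between the two half-maximum crossings nearest the peak, located by
#' linear interpolation between samples. The half-maximum is measured from
#' zero dose, not from the valley baseline.
#'
#' @param profile A `lateral_profile` or data frame (`position`, `dose`).
#' @param peak_index Sample index of the peak (from [find_peaks_valleys()]).
#' @param window Optional half-window in mm limiting the crossing search
#'   (e.g. ctc/2 for merged arrays); `NA` crossings outside it flag the
#'   peak unmeasurable.
#' @return Width in mm, or `NA` with a warning when a crossing is missing.
#' @export
fwhm <- function(profile, peak_index, window = Inf) {
  pos <- profile$position
  val <- profile$dose
  half <- val[peak_index] / 2
  cross <- function(side) {
    ii <- if (side < 0) seq(peak_index, 1) else seq(peak_index, length(val))
    below <- which(val[ii] < half)
    if (length(below) == 0) return(NA_real_)
    b <- ii[below[1]]; a <- b - side  # a above half, b below
    x <- pos[a] + (half - val[a]) * (pos[b] - pos[a]) / (val[b] - val[a])
    if (abs(x - pos[peak_index]) > window) NA_real_ else x
  }
  left <- cross(-1); right <- cross(+1)
  if (is.na(left) || is.na(right)) {
    warning("peak flagged unmeasurable: no half-maximum crossing in window")
    return(NA_real_)
  }
  right - left
}

#' Peak-to-valley dose ratio
#'
#' @param peak_dose,valley_dose Dose values (any consistent unit).
#' @return `peak_dose / valley_dose`; zero valleys give `Inf` with a
#'   diagnostic warning. Report tables round to one decimal
#'   ([round_half_away()]); full precision is retained internally.
#' @export
pvdr <- function(peak_dose, valley_dose) {
  if (any(valley_dose < 0) || any(peak_dose < 0))
    stop("doses must be non-negative")
  if (any(valley_dose == 0))
    warning("zero valley dose: PVDR reported as infinite")
  peak_dose / valley_dose
}

#' Per-ROI dose statistics
#'
#' Computes the ROI mean dose over the analysed slice region and, at each
#' stated profile depth, the peak/valley doses and PVDR from
#' [find_peaks_valleys()] restricted to the ROI's lateral extent. ROIs
#' probed at two depths report both rows ordered shallow to deep.
#'
#' @param slice A `dose_slice` (x-z).
#' @param roi_mask Logical matrix on the slice (TRUE inside the ROI).
#' @param depths Profile depth(s) in mm, grid frame.
#' @param expected_centers Geometric beamlet centres at each depth: a
#'   function of depth, or a vector reused for all depths.
#' @param roi Name recorded in the output row.
#' @param ctc Nominal spacing for detection windows (see
#'   [find_peaks_valleys()]).
#' @return Data frame with one row per depth: `roi`, `depth`, `Dmean`,
#'   `Dpeak`, `Dvalley`, `PVDR` (Dpeak = max over peaks, Dvalley = min over
#'   inter-peak valleys; unmodulated or single-beamlet profiles fall back
#'   to the profile extrema, so a uniform ROI reports PVDR 1).
#' @export
roi_statistics <- function(slice, roi_mask, depths, expected_centers,
                           roi = "roi", ctc = NULL) {
  stopifnot(inherits(slice, "dose_slice"))
  if (!any(roi_mask)) stop("empty ROI mask")
  dmean <- mean(slice$dose[roi_mask])
  rows <- lapply(sort(depths), function(dz) {
    centers <- if (is.function(expected_centers)) expected_centers(dz)
               else expected_centers
    zcols <- which(apply(roi_mask, 2, any))
    zi <- zcols[which.min(abs(slice$coords$z[zcols] - dz))]
    xrows <- which(roi_mask[, zi])
    prof <- data.frame(position = slice$coords$x[xrows],
                       dose = slice$dose[xrows, zi])
    centers <- centers[centers >= min(prof$position) &
                         centers <= max(prof$position)]
    if (length(centers) == 0)
      stop("no expected beamlet centers inside ROI at depth ", dz)
    # an unmodulated (near-uniform) profile has no detectable beamlet
    # structure: report the profile extrema instead (PVDR -> 1)
    pv <- tryCatch(find_peaks_valleys(prof, centers, ctc = ctc),
                   error = function(e) NULL)
    if (is.null(pv)) {
      dpk <- max(prof$dose)
      dvl <- min(prof$dose)
    } else {
      dpk <- max(pv$peaks$dose)
      # single-beamlet profiles have no inter-peak valley: report the
      # profile minimum inside the ROI instead
      dvl <- if (is.null(pv$valleys)) min(prof$dose)
             else min(pv$valleys$dose)
    }
    data.frame(roi = roi, depth = slice$coords$z[zi], Dmean = dmean,
               Dpeak = dpk, Dvalley = dvl,
               PVDR = if (is.na(dvl)) NA_real_ else pvdr(dpk, dvl))
  })
  do.call(rbind, rows)
}

#' ROI dose summary for a simulated case
#'
#' Builds the relative dose table (mean target dose = 100) for every ROI
#' labelled in the phantom: Dmean over the ROI within the analysed central
#' slice, peak/valley/PVDR along lateral profiles at the default sampling
#' depths (mid-ROI; for brain/tissue ROIs two depths at 1/4 and 3/4 of the
#' ROI's longitudinal extent).
#'
#' @param grid A `dose_grid` from a phantom with ROI labels.
#' @param setup The [irradiation_setup()] used (for the geometric pattern).
#' @param slice_thickness Analysis slice thickness, mm (`NULL`: 0.1 mm or
#'   one voxel, whichever is larger).
#' @param depths Optional named list overriding profile depths per ROI (mm,
#'   depth-below-surface).
#' @return A `dose_summary`: data frame with one row per ROI and depth,
#'   relative doses in percent of the target mean, plus attributes
#'   recording the slice and depths used.
#' @export
build_summary <- function(grid, setup, slice_thickness = NULL,
                          depths = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.null(slice_thickness))
    slice_thickness <- max(0.1, grid$voxel_size[2])
  phantom <- grid$phantom
  lab <- phantom$roi_label_map
  L <- roi_labels()
  slice <- extract_slice(grid, axis = "y", at = 0,
                         thickness = slice_thickness)
  co <- grid_coords(grid)
  ysel <- which(abs(co$y - 0) <= slice_thickness / 2 + 1e-9)
  geom <- setup$collimator
  centers_at <- function(dz)
    projected_pattern(geom, setup$air_gap + max(dz, 0))$center_mm
  ctc_nom <- geom$ctc1 / 1000

  present <- sort(setdiff(unique(as.integer(lab)), L[["none"]]))
  rows <- lapply(present, function(code) {
    roi_name <- names(L)[match(code, L)]
    sub <- lab[, ysel, , drop = FALSE] == code
    mask <- apply(sub, c(1, 3), any)
    zext <- range(co$z[apply(mask, 2, any)])
    dd <- if (!is.null(depths) && !is.null(depths[[roi_name]])) {
      depths[[roi_name]]
    } else if (roi_name %in% c("brain", "tissue")) {
      zext[1] + c(0.25, 0.75) * diff(zext)
    } else {
      mean(zext)
    }
    roi_statistics(slice, mask, dd, centers_at, roi = roi_name,
                   ctc = ctc_nom)
  })
  out <- do.call(rbind, rows)
  tmean <- out$Dmean[match("target", out$roi)]
  if (is.na(tmean) || tmean <= 0)
    stop("no target ROI dose found; cannot normalize")
  for (cn in c("Dmean", "Dpeak", "Dvalley")) out[[cn]] <- out[[cn]] / tmean * 100
  attr(out, "units") <- "percent_of_target_mean"
  attr(out, "slice_thickness") <- slice_thickness
  class(out) <- c("dose_summary", "data.frame")
  out
}

#' Convert a relative summary to absolute doses
#'
#' Multiplies every dose by `prescription / 100` so the target mean equals
#' the prescription; PVDR is unchanged.
#'
#' @param summary A relative `dose_summary` (target Dmean = 100).
#' @param prescription Prescribed mean target dose, Gy.
#' @return The summary in Gy, with a `units` attribute of "Gy".
#' @export
scale_to_prescription <- function(summary, prescription = 30) {
  stopifnot(prescription > 0)
  tmean <- summary$Dmean[match("target", summary$roi)]
  if (!is.na(tmean) && abs(tmean - 100) > 1e-6)
    stop("summary is not relative (target Dmean must be 100)")
  out <- summary
  for (cn in c("Dmean", "Dpeak", "Dvalley"))
    out[[cn]] <- out[[cn]] * prescription / 100
  attr(out, "units") <- "Gy"
  attr(out, "prescription_Gy") <- prescription
  out
}

#' Region-restricted global uncertainty
#'
#' Mean over the analysis mask of the per-voxel relative standard deviation
#' (std / dose). Zero-dose voxels are excluded and counted in the
#' `n_zero_dose` attribute; restricting the mask to the analysed region
#' excludes very-low-dose voxels that would inflate the score.
#'
#' @param grid A `dose_grid` with per-voxel `sd`.
#' @param mask Logical array of the analysed region (same shape as the
#'   dose).
#' @return Relative mean uncertainty (fraction), with attributes `n_used`
#'   and `n_zero_dose`.
#' @export
global_uncertainty <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), !is.null(grid$sd))
  if (!any(mask)) stop("empty analysis mask")
  d <- grid$dose[mask]
  s <- grid$sd[mask]
  nz <- d > 0
  if (!any(nz)) stop("all-zero dose inside the analysis mask")
  structure(mean(s[nz] / d[nz]), n_used = sum(nz), n_zero_dose = sum(!nz))
}

#' Build a beam-region analysis mask
#'
#' Rectangular region covering the minibeam array laterally and a depth
#' interval longitudinally, within the central slice slab; mirrors the
#' region-restriction used for the global uncertainty score.
#'
#' @param grid A `dose_grid`.
#' @param lateral_halfwidth Half-extent in x, mm.
#' @param depth_range Depth interval `c(zmin, zmax)` in mm (grid frame).
#' @param slab_halfwidth Half-extent in y, mm.
#' @return Logical array.
#' @export
analysis_mask <- function(grid, lateral_halfwidth, depth_range,
                          slab_halfwidth = lateral_halfwidth) {
  co <- grid_coords(grid)
  mx <- abs(co$x) <= lateral_halfwidth
  my <- abs(co$y) <= slab_halfwidth
  mz <- co$z >= depth_range[1] & co$z <= depth_range[2]
  array(outer(outer(mx, my, `&`), mz, `&`), dim = dim(grid$dose))
}

#' FWHM and centre-to-centre table vs depth
#'
#' Evaluates the central-beamlet FWHM and the central-to-adjacent ctc
#' spacing at the stated tissue depths, mirroring the standard minibeam
#' pattern report (surface and target depth by default).
#'
#' @param grid A `dose_grid`.
#' @param setup The [irradiation_setup()] used.
#' @param depths Depths below the phantom surface, mm.
#' @param surface_z Grid-frame z of the phantom surface (default 0).
#' @param slice_thickness Analysis slice thickness, mm.
#' @param average_mm Longitudinal averaging per profile, mm.
#' @return Data frame with `depth`, `fwhm_mm`, `ctc_mm`.
#' @export
fwhm_ctc_table <- function(grid, setup, depths = c(0, 20), surface_z = 0,
                           slice_thickness = NULL, average_mm = 0.5) {
  if (is.null(slice_thickness))
    slice_thickness <- max(0.1, grid$voxel_size[2])
  geom <- setup$collimator
  slice <- extract_slice(grid, axis = "y", at = 0,
                         thickness = slice_thickness)
  rows <- lapply(depths, function(dz) {
    pp <- projected_pattern(geom, setup$air_gap + dz)
    prof <- lateral_profile(slice, surface_z + dz, average_mm = average_mm)
    pv <- find_peaks_valleys(prof, pp$center_mm, ctc = geom$ctc1 / 1000)
    ic <- which.min(abs(pv$peaks$centroid))        # central beamlet
    iadj <- order(abs(pp$center_mm))[2]            # an adjacent one
    ja <- which.min(abs(pv$peaks$centroid - pp$center_mm[iadj]))
    ctc_meas <- abs(pv$peaks$centroid[ic] - pv$peaks$centroid[ja])
    data.frame(depth = dz,
               fwhm_mm = fwhm(prof, pv$peaks$index[ic],
                              window = geom$ctc1 / 2000),
               ctc_mm = ctc_meas)
  })
  do.call(rbind, rows)
}
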