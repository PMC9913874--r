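# Synthetic eye/head voxel phantom generation and CT-like raster ingestion.
#
# The phantom is built in a beam-aligned frame: the beam travels along +z,
# x is the lateral direction of the minibeam array (the direction in which
# the slits are spaced), y is the slit-height direction (slice-normal for
# the analysis). Depth z is measured from the phantom surface (anterior
# cornea pole at z = 0); a thin air layer precedes the surface.

.ROI_LEVELS <- c("none", "target", "anterior_chamber", "skin", "lens",
                 "retina", "bone", "brain", "tissue")

#' ROI label dictionary
#'
#' @return Named integer vector mapping ROI names to label codes
#'   (0 = none).
#' @export
roi_labels <- function() {
  stats::setNames(seq_along(.ROI_LEVELS) - 1L, .ROI_LEVELS)
}

#' Head phantom configuration
#'
#' Defaults emulate the study geometry: a 24 mm eye with a 3 mm anterior
#' chamber, 4 mm thick lens, vitreous, a ~1 mm retina shell, a spherical
#' intraocular target centred at 20 mm depth, an orbital bone slab and
#' brain/soft tissue behind it. All extents are configurable; each ROI is
#' defined constructively from this config and recorded with the phantom.
#'
#' @param position Irradiation position label, one of "P1".."P4". P1 is a
#'   central head-on setup through the lens; P2 a peripheral entry through
#'   skin (eye offset in y so the lens lies outside the central slice and
#'   the entry ROI is skin); P3 a partially offset setup keeping the lens;
#'   P4 an oblique-like setup traversing more bone, with the distal ROI
#'   labelled "tissue" instead of "brain".
#' @param voxel_size Voxel size in mm, `c(dx, dy, dz)` (lateral, height,
#'   longitudinal). Scoring-region voxels must be <= 0.5 mm.
#' @param lateral_extent Half-extent of the grid in x and y, mm.
#' @param depth Longitudinal extent of the grid below the surface, mm.
#' @param air_gap_mm Air layer included in front of the surface, mm.
#' @param eye_diameter Eye diameter, mm.
#' @param anterior_chamber_depth Depth of the cornea/anterior chamber
#'   water-equivalent layer, mm.
#' @param lens_depth,lens_thickness,lens_diameter Lens position/extents, mm.
#' @param retina_thickness Retina shell thickness, mm.
#' @param target_depth,target_radius Target centre depth and radius, mm.
#' @param bone_start,bone_thickness Bone slab position/extent, mm.
#' @param roi_halfwidth Lateral half-extent of the ROI labels (the region
#'   covered by the minibeam array), mm.
#' @param eye_offset_y Lateral (y) offset of the eye centre, mm; set by the
#'   position label when `NULL`.
#' @return A config list of class `head_phantom_config`.
#' @export
head_phantom_config <- function(position = "P1",
                                voxel_size = c(0.1, 0.1, 0.5),
                                lateral_extent = 8, depth = 45,
                                air_gap_mm = 2,
                                eye_diameter = 24,
                                anterior_chamber_depth = 3,
                                lens_depth = 3, lens_thickness = 4,
                                lens_diameter = 9,
                                retina_thickness = 1,
                                target_depth = 20, target_radius = 4,
                                bone_start = 26,
                                bone_thickness = if (position == "P4") 9 else 6,
                                roi_halfwidth = 4.5,
                                eye_offset_y = NULL) {
  position <- match.arg(position, c("P1", "P2", "P3", "P4"))
  if (is.null(eye_offset_y))
    eye_offset_y <- switch(position, P1 = 0, P2 = 6, P3 = 2, P4 = 0)
  stopifnot(all(voxel_size > 0), lateral_extent > 0, depth > 0,
            eye_diameter > 0, target_radius > 0)
  if (any(voxel_size > 0.5))
    stop("scoring-region voxel size must be <= 0.5 mm in every direction")
  structure(as.list(environment()), class = "head_phantom_config")
}

.new_phantom <- function(material_index, voxel_size, origin, materials,
                         labels, config = NULL) {
  structure(list(material_index = material_index,
                 voxel_size = voxel_size, origin = origin,
                 materials = materials, roi_label_map = labels,
                 config = config),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material_index)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels of %g x %g x %g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat("  materials:", paste(vapply(x$materials, `[[`, "", "name"),
                            collapse = " "), "\n")
  present <- names(roi_labels())[1 + sort(unique(as.integer(x$roi_label_map)))]
  cat("  ROIs:", paste(setdiff(present, "none"), collapse = " "), "\n")
  invisible(x)
}

#' Voxel centre coordinates of a phantom or dose grid
#'
#' @param x A `voxel_phantom` or `dose_grid`.
#' @return List with vectors `x`, `y`, `z` (mm, grid frame).
#' @export
grid_coords <- function(x) {
  d <- if (inherits(x, "voxel_phantom")) dim(x$material_index)
       else dim(x$dose)
  lapply(stats::setNames(1:3, c("x", "y", "z")), function(a)
    x$origin[a] + (seq_len(d[a]) - 0.5) * x$voxel_size[a])
}

#' Generate the synthetic eye/head phantom
#'
#' Builds the layered geometry along the beam axis (air, cornea/anterior
#' chamber, optional lens, vitreous, retina shell, intraocular target,
#' bone slab, brain/soft tissue) and assigns ROI labels per structure.
#'
#' @param config A [head_phantom_config()].
#' @return A `voxel_phantom` with materials air, water, soft_tissue, lens
#'   and bone, and the ROI label grid.
#' @export
make_head_phantom <- function(config = head_phantom_config()) {
  stopifnot(inherits(config, "head_phantom_config"))
  cf <- config
  eye_r <- cf$eye_diameter / 2
  eye_c <- c(0, cf$eye_offset_y, eye_r)  # anterior pole on the surface
  # consistency checks
  lens_c <- c(0, cf$eye_offset_y, cf$lens_depth + cf$lens_thickness / 2)
  lens_a <- cf$lens_thickness / 2        # axial semi-axis
  lens_b <- cf$lens_diameter / 2         # lateral semi-axis
  lens_reach <- sqrt(lens_b^2 + (abs(lens_c[3] - eye_c[3]) + lens_a)^2)
  if (lens_reach > eye_r + 1e-9)
    stop("inconsistent geometry: lens extends outside the eye")
  # target sits on the beam axis at its configured depth; for offset-eye
  # setups it may extend into retro-ocular tissue, but never into bone
  if (cf$target_depth + cf$target_radius > cf$bone_start + 1e-9)
    stop("inconsistent geometry: target overlaps the bone slab")
  if (cf$eye_offset_y == 0 &&
      cf$target_depth + cf$target_radius > eye_c[3] + eye_r + 1e-9)
    stop("inconsistent geometry: target extends outside the eye")
  if (cf$bone_start < cf$eye_diameter - 1e-9)
    stop("inconsistent geometry: bone slab overlaps the eye")

  vs <- cf$voxel_size
  nx <- ceiling(2 * cf$lateral_extent / vs[1])
  ny <- ceiling(2 * cf$lateral_extent / vs[2])
  nz <- ceiling((cf$depth + cf$air_gap_mm) / vs[3])
  origin <- c(-nx / 2 * vs[1], -ny / 2 * vs[2], -cf$air_gap_mm)
  xs <- origin[1] + (seq_len(nx) - 0.5) * vs[1]
  ys <- origin[2] + (seq_len(ny) - 0.5) * vs[2]
  zs <- origin[3] + (seq_len(nz) - 0.5) * vs[3]

  mats <- default_materials()[c("air", "water", "soft_tissue", "lens",
                                "bone")]
  M <- c(air = 0L, water = 1L, soft_tissue = 2L, lens = 3L, bone = 4L)
  L <- roi_labels()

  X <- array(rep(xs, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), dim = c(nx, ny, nz))

  mat <- array(M[["air"]], dim = c(nx, ny, nz))
  lab <- array(L[["none"]], dim = c(nx, ny, nz))

  body <- Z >= 0
  mat[body] <- M[["soft_tissue"]]
  r2eye <- (X - eye_c[1])^2 + (Y - eye_c[2])^2 + (Z - eye_c[3])^2
  in_eye <- r2eye <= eye_r^2
  mat[in_eye] <- M[["water"]]                       # vitreous / aqueous
  in_lens <- ((X - lens_c[1])^2 + (Y - lens_c[2])^2) / lens_b^2 +
    (Z - lens_c[3])^2 / lens_a^2 <= 1
  mat[in_lens] <- M[["lens"]]
  bone_zone <- Z >= cf$bone_start & Z < cf$bone_start + cf$bone_thickness &
    !in_eye
  mat[bone_zone] <- M[["bone"]]

  lat_ok <- abs(X) <= cf$roi_halfwidth
  # retina: posterior spherical shell lining the eye
  in_retina <- in_eye & r2eye >= (eye_r - cf$retina_thickness)^2 &
    Z > eye_c[3]
  in_target <- (X^2 + Y^2 + (Z - cf$target_depth)^2) <= cf$target_radius^2
  entry_layer <- if (cf$position == "P2") {
    body & Z < 1.5 & !in_eye                         # skin at beam entry
  } else {
    in_eye & Z < cf$anterior_chamber_depth
  }
  distal <- Z >= cf$bone_start + cf$bone_thickness &
    Z < cf$bone_start + cf$bone_thickness + 10

  lab[entry_layer & lat_ok] <-
    if (cf$position == "P2") L[["skin"]] else L[["anterior_chamber"]]
  if (cf$position != "P2") lab[in_lens & lat_ok] <- L[["lens"]]
  lab[in_retina & lat_ok] <- L[["retina"]]
  lab[bone_zone & lat_ok] <- L[["bone"]]
  lab[distal & lat_ok] <-
    if (cf$position == "P4") L[["tissue"]] else L[["brain"]]
  lab[in_target] <- L[["target"]]

  .new_phantom(mat, vs, origin, mats, lab, config = cf)
}

#' Homogeneous water phantom
#'
#' A water box used for physics validation runs; the whole scoring volume
#' doubles as an unlabelled target-free medium.
#'
#' @param lateral_extent Half-extent in x and y, mm.
#' @param depth Extent in z, mm.
#' @param voxel_size Voxel size `c(dx, dy, dz)` in mm.
#' @return A `voxel_phantom` containing only water.
#' @export
make_water_phantom <- function(lateral_extent = 6, depth = 40,
                               voxel_size = c(0.1, 0.1, 0.5)) {
  nx <- ceiling(2 * lateral_extent / voxel_size[1])
  ny <- ceiling(2 * lateral_extent / voxel_size[2])
  nz <- ceiling(depth / voxel_size[3])
  mats <- default_materials()["water"]
  .new_phantom(array(0L, dim = c(nx, ny, nz)), voxel_size,
               c(-nx / 2 * voxel_size[1], -ny / 2 * voxel_size[2], 0),
               mats, array(0L, dim = c(nx, ny, nz)))
}

#' Default HU-to-material conversion table
#'
#' Piecewise-constant mapping of Hounsfield units to materials:
#' below -400 air, -400..150 soft tissue, above 150 bone.
#'
#' @return Data frame with columns `lower`, `upper`, `material`.
#' @export
default_hu_table <- function() {
  data.frame(lower = c(-Inf, -400, 150), upper = c(-400, 150, Inf),
             material = c("air", "soft_tissue", "bone"),
             stringsAsFactors = FALSE)
}

#' Ingest a CT-like volumetric raster
#'
#' Maps HU intervals to materials with a piecewise-constant table. ROI
#' labels are never inferred from the image; supply a label volume if
#' needed.
#'
#' @param image A NIfTI file path, an `RNifti` image, or a 3D array (in
#'   which case `voxel_size` is required).
#' @param hu_table Conversion table as in [default_hu_table()]; intervals
#'   are `[lower, upper)` and must be contiguous and increasing.
#' @param voxel_size Voxel spacing in mm (taken from the NIfTI header when
#'   the image carries one).
#' @param label_image Optional integer array/NIfTI of ROI labels (codes as
#'   in [roi_labels()]), same shape as `image`.
#' @return A `voxel_phantom`.
#' @export
ingest_ct <- function(image, hu_table = default_hu_table(),
                      voxel_size = NULL, label_image = NULL) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  if (inherits(image, "niftiImage")) {
    pd <- RNifti::pixdim(image)
    if (is.null(voxel_size)) voxel_size <- pd[1:3]
    image <- as.array(image)
  }
  if (is.null(voxel_size) || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("missing or invalid voxel spacing metadata")
  if (length(dim(image)) != 3) stop("image must be a 3D volume")
  if (any(hu_table$lower[-1] != hu_table$upper[-nrow(hu_table)]) ||
      any(diff(hu_table$lower) <= 0))
    stop("HU intervals must be contiguous and increasing")
  mats_all <- default_materials()
  if (!all(hu_table$material %in% names(mats_all)))
    stop("unknown material in HU table")
  mats <- mats_all[unique(hu_table$material)]
  idx <- findInterval(as.numeric(image), hu_table$lower)
  code <- match(hu_table$material, names(mats)) - 1L
  mat <- array(code[idx], dim = dim(image))
  lab <- if (is.null(label_image)) {
    array(0L, dim = dim(image))
  } else {
    if (is.character(label_image)) label_image <- RNifti::readNifti(label_image)
    la <- array(as.integer(as.array(label_image)), dim = dim(image))
    stopifnot(identical(dim(la), dim(image)))
    la
  }
  .new_phantom(mat, voxel_size, c(0, 0, 0), mats, lab)
}

#' Render a phantom to Hounsfield units
#'
#' Inverse of the default HU mapping (air -1000, water/soft tissue 0,
#' lens 20, bone 1000); used to round-trip synthetic phantoms through
#' [ingest_ct()].
#'
#' @param phantom A `voxel_phantom`.
#' @param hu_values Named vector of HU per material name.
#' @return 3D numeric array of HU.
#' @export
phantom_to_hu <- function(phantom,
                          hu_values = c(air = -1000, water = 0,
                                        soft_tissue = 40, lens = 60,
                                        bone = 1000)) {
  nms <- vapply(phantom$materials, `[[`, "", "name")
  vals <- hu_values[nms]
  if (any(is.na(vals))) stop("hu_values missing for some materials")
  array(vals[phantom$material_index + 1L], dim = dim(phantom$material_index))
}

#' Write phantom volumes to NIfTI
#'
#' Writes the material index and ROI label grids as integer NIfTI volumes.
#'
#' @param phantom A `voxel_phantom`.
#' @param material_path,label_path Output file paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the paths.
#' @export
write_phantom_nifti <- function(phantom, material_path, label_path = NULL) {
  RNifti::writeNifti(.as_nifti_spaced(phantom$material_index,
                                      phantom$voxel_size), material_path)
  if (!is.null(label_path)) {
    RNifti::writeNifti(.as_nifti_spaced(phantom$roi_label_map,
                                        phantom$voxel_size), label_path)
  }
  invisible(c(material_path, label_path))
}

# array -> NIfTI with voxel spacing set in the header
.as_nifti_spaced <- function(arr, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  img
}

#' Irradiation setup
#'
#' Couples a position label with the collimator choice, air gap and source
#' model. The beam axis is +z in the phantom frame.
#'
#' @param position Position label ("P1".."P4").
#' @param collimator Collimator label or `collimator_geometry` (or `NULL`
#'   for an open beam).
#' @param air_gap Air gap between collimator exit and surface, mm.
#' @param source_type One of "aligned" (per-slit fans along the slit axes;
#'   the design geometry of a matched divergent collimator), "point"
#'   (point source at `source_distance` behind the entrance), "parallel",
#'   or "pencil".
#' @param source_distance Source-to-collimator-entrance distance, mm.
#' @return An `irradiation_setup`.
#' @export
irradiation_setup <- function(position = "P1", collimator = "A",
                              air_gap = 30, source_type = "aligned",
                              source_distance = 350) {
  if (is.character(collimator)) collimator <- build_collimator(collimator)
  stopifnot(air_gap >= 0)
  source_type <- match.arg(source_type,
                           c("aligned", "point", "parallel", "pencil"))
  structure(list(position_label = position, beam_axis = c(0, 0, 1),
                 collimator = collimator, air_gap = air_gap,
                 source_type = source_type,
                 source_distance = source_distance),
            class = "irradiation_setup")
}
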