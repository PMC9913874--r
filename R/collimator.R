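# Parametric model of the 3 cm brass divergent multi-slit collimators used
# for planar minibeam generation, and ray transmission through them.
#
# Slit widths are given at axial stations (entrance w1, mid-plane w2, exit w3
# for the 5-slit geometries; entrance w1, exit w2 for the 3-slit ones) and
# interpolated linearly in between. Each slit is a divergent prism tilted by
# its axis angle; the slit height limits the aperture vertically with
# straight edges. The slit layout is mirror-symmetric about the central slit.

# manufacturer-style preset dimensions (widths/spacings in um, angles in deg)
.COLLI_PRESETS <- list(
  A   = list(n_slits = 5, slit_height = 10, w1 = 400, w2 = 400, w3 = 425,
             alpha = 0.595, beta = 0.632, ctc1 = 1150, ctc2 = 1275),
  Ah  = list(n_slits = 5, slit_height = 5, w1 = 400, w2 = 400, w3 = 425,
             alpha = 0.595, beta = 0.632, ctc1 = 1150, ctc2 = 1275),
  A3s = list(n_slits = 3, slit_height = 10, w1 = 400, w2 = 400, w3 = NA,
             alpha = 0.595, beta = NA, ctc1 = 1150, ctc2 = NA),
  B   = list(n_slits = 5, slit_height = 10, w1 = 400, w2 = 409, w3 = 500,
             alpha = 0.611, beta = 0.744, ctc1 = 1900, ctc2 = 1875),
  C   = list(n_slits = 3, slit_height = 10, w1 = 400, w2 = 425, w3 = NA,
             alpha = 0.632, beta = NA, ctc1 = 2425, ctc2 = NA)
)

#' Construct a collimator geometry
#'
#' @param label Geometry label.
#' @param n_slits Odd number of slits (3 or 5).
#' @param slit_height Slit height in mm.
#' @param w1,w2,w3 Slit widths in um at the axial stations (entrance, mid,
#'   exit); `w3` must be `NA` for 3-slit geometries, where `w2` is the exit
#'   width.
#' @param alpha,beta Divergence angles in degrees of the adjacent and outer
#'   slit axes; `beta` must be `NA` for 3-slit geometries.
#' @param ctc1,ctc2 Centre-to-centre spacings at the exit plane in um
#'   (central-adjacent, adjacent-outer); `ctc2` must be `NA` for 3-slit
#'   geometries.
#' @param thickness Collimator thickness in mm (default 30).
#' @param wall_material Wall material id (default "brass").
#' @return A `collimator_geometry` object.
#' @export
collimator_geometry <- function(label, n_slits, slit_height, w1, w2, w3 = NA,
                                alpha, beta = NA, ctc1, ctc2 = NA,
                                thickness = 30, wall_material = "brass") {
  if (n_slits %% 2 != 1) stop("n_slits must be odd")
  widths <- if (n_slits >= 5) c(w1, w2, w3) else c(w1, w2)
  if (any(is.na(widths))) stop("slit widths incomplete for this layout")
  if (any(diff(widths) < 0))
    stop("slits must widen toward the exit (w1 <= w2 <= w3)")
  if (!is.na(alpha) && alpha <= 0) stop("alpha must be positive")
  if (n_slits >= 5 && (is.na(beta) || beta <= 0 || is.na(ctc2) || ctc2 <= 0))
    stop("5-slit geometries need positive beta and ctc2")
  if (ctc1 <= 0) stop("ctc1 must be positive")
  structure(list(label = label, n_slits = n_slits,
                 slit_height = slit_height,
                 w1 = w1, w2 = w2, w3 = if (n_slits >= 5) w3 else NA,
                 alpha = alpha, beta = if (n_slits >= 5) beta else NA,
                 ctc1 = ctc1, ctc2 = if (n_slits >= 5) ctc2 else NA,
                 thickness = thickness, wall_material = wall_material),
            class = "collimator_geometry")
}

#' Build a preset collimator geometry
#'
#' Presets A, Ah, A3s, B and C cover the investigated slit dimensions,
#' divergence angles and exit spacings.
#'
#' @param label One of "A", "Ah", "A3s", "B", "C".
#' @return A `collimator_geometry`.
#' @export
build_collimator <- function(label) {
  p <- .COLLI_PRESETS[[label]]
  if (is.null(p)) stop("unknown collimator label: ", label)
  collimator_geometry(label = label, n_slits = p$n_slits,
                      slit_height = p$slit_height, w1 = p$w1, w2 = p$w2,
                      w3 = p$w3, alpha = p$alpha, beta = p$beta,
                      ctc1 = p$ctc1, ctc2 = p$ctc2)
}

#' Read a collimator library file
#'
#' YAML file mapping labels to the fields of [collimator_geometry()];
#' user-defined geometries use the same schema as the bundled presets
#' (see `system.file("extdata", "collimators.yaml", package = "mbrt")`).
#'
#' @param path YAML file path.
#' @return Named list of `collimator_geometry` objects.
#' @export
read_collimator_library <- function(path) {
  lib <- yaml::read_yaml(path)
  out <- lapply(names(lib), function(nm) {
    p <- lib[[nm]]
    collimator_geometry(label = nm, n_slits = p$n_slits,
                        slit_height = p$slit_height, w1 = p$w1, w2 = p$w2,
                        w3 = if (is.null(p$w3)) NA else p$w3,
                        alpha = p$alpha,
                        beta = if (is.null(p$beta)) NA else p$beta,
                        ctc1 = p$ctc1,
                        ctc2 = if (is.null(p$ctc2)) NA else p$ctc2,
                        thickness = if (is.null(p$thickness)) 30
                                    else p$thickness)
  })
  names(out) <- names(lib)
  out
}

#' @export
print.collimator_geometry <- function(x, ...) {
  cat(sprintf(
    "<collimator_geometry> colli %s: %d slits x %g mm, w %g/%g%s um\n",
    x$label, x$n_slits, x$slit_height, x$w1, x$w2,
    if (!is.na(x$w3)) sprintf("/%g", x$w3) else ""))
  cat(sprintf("  angles %g%s deg, exit ctc %g%s um, thickness %g mm (%s)\n",
              x$alpha, if (!is.na(x$beta)) sprintf("/%g", x$beta) else "",
              x$ctc1, if (!is.na(x$ctc2)) sprintf("/%g", x$ctc2) else "",
              x$thickness, x$wall_material))
  invisible(x)
}

#' Slit axis angles and exit-centre offsets
#'
#' The central slit sits at 0 deg / 0 um; adjacent slits at +/-alpha with
#' exit offsets +/-ctc1; outer slits (5-slit layouts) at +/-beta with exit
#' offsets +/-(ctc1 + ctc2).
#'
#' @param geometry A `collimator_geometry`.
#' @return Data frame with columns `slit`, `angle_deg`, `offset_um`, ordered
#'   from the most negative offset to the most positive.
#' @export
slit_axes <- function(geometry) {
  stopifnot(inherits(geometry, "collimator_geometry"))
  if (geometry$n_slits == 1) {
    return(data.frame(slit = 1L, angle_deg = 0, offset_um = 0))
  }
  if (geometry$n_slits == 3) {
    ang <- c(-geometry$alpha, 0, geometry$alpha)
    off <- c(-geometry$ctc1, 0, geometry$ctc1)
  } else {
    oo <- geometry$ctc1 + geometry$ctc2
    ang <- c(-geometry$beta, -geometry$alpha, 0, geometry$alpha,
             geometry$beta)
    off <- c(-oo, -geometry$ctc1, 0, geometry$ctc1, oo)
  }
  data.frame(slit = seq_along(ang), angle_deg = ang, offset_um = off)
}

# internal: C++-side parameter pack (mm, tangents)
.colli_pack <- function(geometry, ideal = FALSE) {
  ax <- slit_axes(geometry)
  Tm <- geometry$thickness
  if (geometry$n_slits >= 5) {
    station_z <- c(0, Tm / 2, Tm)
    station_w <- c(geometry$w1, geometry$w2, geometry$w3) / 1000
  } else {
    station_z <- c(0, Tm)
    station_w <- c(geometry$w1, geometry$w2) / 1000
  }
  list(n_slits = geometry$n_slits,
       tan_ang = tan(ax$angle_deg * pi / 180),
       offset_mm = ax$offset_um / 1000,
       station_z = station_z, station_w = station_w,
       thickness = Tm, half_height = geometry$slit_height / 2,
       ideal = ideal)
}

#' Ray transmission through the collimator
#'
#' Computes the path length through the brass wall by exact 3D intersection
#' of each ray with the union of the divergent slit apertures. The entrance
#' plane is z = 0 and the exit plane z = thickness; rays are propagated to
#' the entrance plane first.
#'
#' @param geometry A `collimator_geometry`.
#' @param origin Numeric vector of length 3, or n x 3 matrix (mm).
#' @param direction Direction vector(s), same shape; normalized internally.
#' @param ideal If `TRUE`, any non-zero brass path blocks the ray (ideal
#'   absorber).
#' @return Data frame with `brass_path` (mm) and logical `transmitted`
#'   (`TRUE` when the ray carries non-zero weight: zero brass path in ideal
#'   mode, always `TRUE` otherwise since attenuation is applied by the
#'   caller as `exp(-mu * path)`).
#' @export
transmit <- function(geometry, origin, direction, ideal = FALSE) {
  stopifnot(inherits(geometry, "collimator_geometry"))
  origin <- matrix(as.numeric(origin), ncol = 3)
  direction <- matrix(as.numeric(direction), ncol = 3)
  stopifnot(nrow(origin) == nrow(direction))
  bp <- cpp_brass_path(origin, direction, .colli_pack(geometry, ideal))
  data.frame(brass_path = bp,
             transmitted = if (ideal) bp <= 0 else rep(TRUE, length(bp)))
}

#' Geometric minibeam pattern at a downstream plane
#'
#' Projects each slit axis to a plane at `plane_distance` mm beyond the
#' collimator exit: the centre of slit k is
#' `exit_offset_k + z * tan(angle_k)` and the geometric width is the slit
#' exit width projected along its axis.
#'
#' @param geometry A `collimator_geometry`.
#' @param plane_distance Distance beyond the exit plane in mm (>= 0).
#' @return Data frame with `slit`, `center_mm`, `width_mm`.
#' @export
projected_pattern <- function(geometry, plane_distance) {
  stopifnot(inherits(geometry, "collimator_geometry"), plane_distance >= 0)
  ax <- slit_axes(geometry)
  w_exit <- if (geometry$n_slits >= 5) geometry$w3 else geometry$w2
  data.frame(slit = ax$slit,
             center_mm = ax$offset_um / 1000 +
               plane_distance * tan(ax$angle_deg * pi / 180),
             width_mm = (w_exit / 1000) / cos(ax$angle_deg * pi / 180))
}
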