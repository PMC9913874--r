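# Material definitions and photon mass attenuation tables for the 10-300 keV
# range. The incoherent component is the exact Klein-Nishina free-electron
# cross section; photoelectric and coherent components are parametric
# power-law approximations anchored to water at 30 keV. These are stand-in
# tables: adequate for the bone/soft-tissue contrast and scatter physics at
# orthovoltage energies, not a substitute for evaluated cross-section data.

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca",
             "Cu", "Zn"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20, 29, 30),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06, 35.45,
        39.948, 39.098, 40.078, 63.546, 65.38),
  stringsAsFactors = FALSE
)

.AVOGADRO <- 6.02214076e23
.RE_CM <- 2.8179403262e-13    # classical electron radius, cm
# photoelectric tau/rho = C_PE * sum(w Z^4.5 / A) / E^3   [cm^2/g, E in keV]
.C_PE <- 5.67
# coherent sigma/rho = C_COH * sum(w Z^2.5 / A) / E^1.9
.C_COH <- 3.57

#' Total Klein-Nishina cross section per electron
#'
#' Closed-form integral of the Klein-Nishina differential cross section over
#' all angles, for a free electron at rest.
#'
#' @param energy_keV Photon energy in keV.
#' @return Cross section in cm^2 per electron.
#' @export
klein_nishina_total <- function(energy_keV) {
  k <- energy_keV / 510.998950
  pre <- 2 * pi * .RE_CM^2
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  pre * (t1 + t2 - t3)
}

#' Logarithmic energy grid for attenuation tables
#'
#' @param n Number of nodes.
#' @return Energies in keV, uniform in log between 10 and 300 keV.
#' @export
mbrt_energy_grid <- function(n = 64) {
  exp(seq(log(10), log(300), length.out = n))
}

.element_mu <- function(symbol, energy_keV) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (is.na(i)) stop("unknown element: ", symbol)
  Z <- .ELEMENTS$Z[i]; A <- .ELEMENTS$A[i]
  list(
    photoelectric = .C_PE * Z^4.5 / A / energy_keV^3,
    incoherent = klein_nishina_total(energy_keV) * .AVOGADRO * Z / A,
    coherent = .C_COH * Z^2.5 / A / energy_keV^1.9
  )
}

#' Define a material
#'
#' A material couples a mass density with an elemental composition (mass
#' fractions) and a tabulated mass attenuation decomposition
#' (photoelectric, incoherent, coherent) on a logarithmic 10-300 keV grid.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3.
#' @param composition Named numeric vector of elemental mass fractions
#'   (normalized internally).
#' @param energies Tabulation grid in keV (default [mbrt_energy_grid()]).
#' @return An object of class `mbrt_material`.
#' @export
material <- function(name, density, composition,
                     energies = mbrt_energy_grid()) {
  stopifnot(density > 0, length(composition) > 0,
            !is.null(names(composition)), all(composition >= 0))
  composition <- composition / sum(composition)
  pe <- inc <- coh <- numeric(length(energies))
  for (el in names(composition)) {
    w <- composition[[el]]
    m <- .element_mu(el, energies)
    pe <- pe + w * m$photoelectric
    inc <- inc + w * m$incoherent
    coh <- coh + w * m$coherent
  }
  tab <- data.frame(energy = energies, photoelectric = pe,
                    incoherent = inc, coherent = coh,
                    total = pe + inc + coh)
  structure(list(name = name, mass_density = density,
                 composition = composition, attenuation_table = tab),
            class = "mbrt_material")
}

#' @export
print.mbrt_material <- function(x, ...) {
  cat(sprintf("<mbrt_material> %s  (rho = %.4g g/cm^3)\n", x$name,
              x$mass_density))
  cat("  elements:", paste(names(x$composition), collapse = " "), "\n")
  invisible(x)
}

#' Standard material set
#'
#' Air, water, soft tissue, eye lens, cortical-bone-like bone and Cu70/Zn30
#' brass, with ICRU-style tissue-substitute compositions.
#'
#' @return Named list of `mbrt_material` objects.
#' @export
default_materials <- function() {
  list(
    air = material("air", 0.001205,
      c(C = 0.000124, N = 0.755267, O = 0.231781, Ar = 0.012827)),
    water = material("water", 1.0, c(H = 0.111898, O = 0.888102)),
    soft_tissue = material("soft_tissue", 1.04,
      c(H = 0.102, C = 0.143, N = 0.034, O = 0.708, Na = 0.002, P = 0.003,
        S = 0.003, Cl = 0.002, K = 0.003)),
    lens = material("lens", 1.07,
      c(H = 0.096, C = 0.195, N = 0.057, O = 0.646, Na = 0.001, P = 0.001,
        S = 0.003, Cl = 0.001)),
    bone = material("bone", 1.92,
      c(H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001, Mg = 0.002,
        P = 0.103, S = 0.003, Ca = 0.225)),
    brass = material("brass", 8.5, c(Cu = 0.70, Zn = 0.30))
  )
}

#' Mass attenuation coefficient lookup
#'
#' Linear interpolation in log(energy) of the tabulated components; the same
#' convention is used by the transport engine.
#'
#' @param mat An `mbrt_material`.
#' @param energy_keV Energies in keV (clamped to the 10-300 keV table range).
#' @param component One of "total", "photoelectric", "incoherent", "coherent".
#' @return Mass attenuation in cm^2/g.
#' @export
mass_attenuation <- function(mat, energy_keV, component = "total") {
  stopifnot(inherits(mat, "mbrt_material"))
  tab <- mat$attenuation_table
  component <- match.arg(component,
    c("total", "photoelectric", "incoherent", "coherent"))
  le <- pmin(pmax(log(energy_keV), log(tab$energy[1])),
             log(tab$energy[nrow(tab)]))
  stats::approx(log(tab$energy), tab[[component]], xout = le)$y
}

#' Linear attenuation coefficient
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation in 1/cm.
#' @export
linear_attenuation <- function(mat, energy_keV, component = "total") {
  mass_attenuation(mat, energy_keV, component) * mat$mass_density
}

# Linear attenuation tables (per mm) for the transport engine, with physics
# toggles applied by zeroing components.
.build_mu_tables <- function(materials, brass,
                             compton = TRUE, photoelectric = TRUE,
                             rayleigh = TRUE, energies = mbrt_energy_grid()) {
  nE <- length(energies)
  nm <- length(materials)
  pe <- inc <- coh <- matrix(0, nE, nm)
  for (j in seq_len(nm)) {
    m <- materials[[j]]
    scale <- m$mass_density * 0.1  # cm^2/g * g/cm^3 -> 1/cm -> 1/mm
    if (photoelectric)
      pe[, j] <- mass_attenuation(m, energies, "photoelectric") * scale
    if (compton)
      inc[, j] <- mass_attenuation(m, energies, "incoherent") * scale
    if (rayleigh)
      coh[, j] <- mass_attenuation(m, energies, "coherent") * scale
  }
  lg <- log(energies)
  list(pe = pe, inc = inc, coh = coh,
       logE0 = lg[1], dlog = lg[2] - lg[1],
       majorant = apply(pe + inc + coh, 1, max),
       brass = mass_attenuation(brass, energies, "total") *
         brass$mass_density * 0.1)
}
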