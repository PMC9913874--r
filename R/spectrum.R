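# Discretized orthovoltage source spectra: construction from raw
# (energy, fluence) pairs on a 1 keV grid with a low-energy cutoff, file
# input, a generic 220 kVp default, and reproducible sampling.

#' Construct a discretized energy spectrum
#'
#' @param bin_energies Bin energies in keV (uniform grid).
#' @param bin_probabilities Sampling weight per bin; renormalized to sum 1.
#' @param tube_potential Maximum energy in keV (defaults to `max(bin_energies)`).
#' @param low_cutoff Minimum retained energy in keV (defaults to
#'   `min(bin_energies)`).
#' @return An `energy_spectrum` object.
#' @export
energy_spectrum <- function(bin_energies, bin_probabilities,
                            tube_potential = max(bin_energies),
                            low_cutoff = min(bin_energies)) {
  stopifnot(length(bin_energies) == length(bin_probabilities),
            length(bin_energies) >= 1)
  if (any(bin_probabilities < 0))
    stop("bin probabilities must be non-negative")
  tot <- sum(bin_probabilities)
  if (tot <= 0)
    stop("empty spectrum: all bin probabilities are zero")
  p <- bin_probabilities / tot
  if (length(bin_energies) > 1) {
    d <- diff(bin_energies)
    if (any(abs(d - d[1]) > 1e-9))
      stop("bin energies must lie on a uniform grid")
  }
  if (any(bin_energies < low_cutoff - 1e-9) ||
      any(bin_energies > tube_potential + 1e-9))
    stop("bin energies outside [low_cutoff, tube_potential]")
  structure(list(bin_energies = as.numeric(bin_energies),
                 bin_probabilities = p,
                 tube_potential = tube_potential,
                 low_cutoff = low_cutoff),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf(
    "<energy_spectrum> %d bins, %g-%g keV (cutoff %g keV), mean %.1f keV\n",
    length(x$bin_energies), min(x$bin_energies), max(x$bin_energies),
    x$low_cutoff, sum(x$bin_energies * x$bin_probabilities)))
  invisible(x)
}

#' Discretize a raw fluence spectrum
#'
#' Snaps raw (energy, fluence) samples to a uniform bin grid (bins centred on
#' multiples of `bin_width`), accumulates fluence per bin, removes bins below
#' the cutoff and renormalizes the remainder to unit probability. The
#' relative ratios of retained bins are conserved.
#'
#' @param raw_pairs Two-column matrix or data frame: energy (keV, strictly
#'   increasing) and relative fluence (non-negative).
#' @param bin_width Bin width in keV (default 1).
#' @param cutoff Low-energy cutoff in keV; bins below it are discarded
#'   (default 21).
#' @return An `energy_spectrum`.
#' @export
discretize_spectrum <- function(raw_pairs, bin_width = 1, cutoff = 21) {
  raw_pairs <- as.matrix(raw_pairs)
  if (nrow(raw_pairs) < 1 || ncol(raw_pairs) < 2)
    stop("raw_pairs must have at least one (energy, fluence) row")
  e <- raw_pairs[, 1]; fl <- raw_pairs[, 2]
  if (any(diff(e) <= 0)) stop("raw energies must be strictly increasing")
  if (any(fl < 0)) stop("fluences must be non-negative")
  centres <- round(e / bin_width) * bin_width
  agg <- tapply(fl, centres, sum)
  be <- as.numeric(names(agg))
  bp <- as.numeric(agg)
  keep <- be >= cutoff
  if (!any(keep) || sum(bp[keep]) <= 0)
    stop("empty spectrum: no fluence remains above the cutoff")
  be <- be[keep]; bp <- bp[keep]
  # fill unobserved bins with zero probability so the grid is uniform
  grid <- seq(min(be), max(be), by = bin_width)
  p <- numeric(length(grid))
  p[match(be, grid)] <- bp
  energy_spectrum(grid, p, tube_potential = max(grid), low_cutoff = cutoff)
}

#' Read a spectrum file
#'
#' Two-column whitespace-separated text (energy keV, relative fluence);
#' lines starting with `#` are comments.
#'
#' @param path File path.
#' @inheritParams discretize_spectrum
#' @return An `energy_spectrum`.
#' @export
read_spectrum <- function(path, bin_width = 1, cutoff = 21) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy", "fluence"))
  discretize_spectrum(tab, bin_width = bin_width, cutoff = cutoff)
}

#' Generic 220 kVp spectrum
#'
#' A bundled stand-in for a 220 kV small-animal-irradiator tube spectrum:
#' Kramers bremsstrahlung from a thick tungsten-like anode filtered by
#' 0.15 mm copper, discretized in 1 keV steps with contributions below
#' 21 keV omitted. Characteristic lines are not modelled. This generic
#' spectrum is clearly a surrogate; measured spectra can be supplied via
#' [read_spectrum()].
#'
#' @param tube_potential Tube potential in keV (default 220).
#' @param cutoff Low-energy cutoff in keV (default 21).
#' @param cu_filter_mm Copper filtration thickness in mm (default 0.15).
#' @return An `energy_spectrum`.
#' @export
default_spectrum_220kv <- function(tube_potential = 220, cutoff = 21,
                                   cu_filter_mm = 0.15) {
  e <- seq(10, tube_potential, by = 1)
  kramers <- (tube_potential - e) / e
  cu <- material("copper_filter", 8.96, c(Cu = 1))
  filt <- exp(-mass_attenuation(cu, e) * 8.96 * cu_filter_mm / 10)
  discretize_spectrum(cbind(e, kramers * filt), bin_width = 1,
                      cutoff = cutoff)
}

#' Sample photon energies from a spectrum
#'
#' Uses R's RNG; results are reproducible under `set.seed()`.
#'
#' @param spectrum An `energy_spectrum`.
#' @param n Number of draws.
#' @return Energies in keV (each a bin energy).
#' @export
sample_energy <- function(spectrum, n = 1) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (length(spectrum$bin_energies) == 1L)
    return(rep(spectrum$bin_energies, n))
  spectrum$bin_energies[sample.int(length(spectrum$bin_energies), n,
                                   replace = TRUE,
                                   prob = spectrum$bin_probabilities)]
}

# cumulative distribution used by the transport engine
.spectrum_cdf <- function(spectrum) {
  cdf <- cumsum(spectrum$bin_probabilities)
  cdf[length(cdf)] <- 1
  cdf
}
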