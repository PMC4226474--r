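#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.25 -> 0.3` at one digit), the
#' convention under which the published linker property table reproduces
#' exactly. Base R's [round()] rounds half to even, which disagrees on ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round() gives 0.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 guards against representation error in values like 0.56*10
  floor(x * p + 0.5 + 1e-9) / p
}

#' Specification of a PEG linker
#'
#' Describes a poly(ethylene glycol) linker by molecular weight and converts
#' it to ethylene-oxide (PEO) repeat units. The exact (unrounded) unit count
#' `mw / monomer_mass` is kept alongside the integer count: derived chain
#' dimensions use the exact count, the integer is display-only.
#'
#' @param mw Molecular weight in Dalton; must be positive.
#' @param unit_length Length of one PEO unit in nm. Default 0.28 nm, the
#'   accepted value for PEO in water.
#' @param monomer_mass Mass of one PEO unit in Dalton (default 44).
#' @return An object of class `polymer_spec` with fields `mw`,
#'   `n_units_exact`, `n_units`, `unit_length`, `monomer_mass`.
#' @seealso [contour_length()], [flory_radius()], [peo_unit_count()]
#' @export
#' @examples
#' polymer_spec(2000)
polymer_spec <- function(mw, unit_length = 0.28, monomer_mass = 44) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("`mw` must be a single positive molecular weight in Dalton")
  if (!is.numeric(unit_length) || unit_length <= 0)
    stop("`unit_length` must be positive (nm)")
  if (!is.numeric(monomer_mass) || monomer_mass <= 0)
    stop("`monomer_mass` must be positive (Dalton)")
  n_exact <- mw / monomer_mass
  structure(
    list(mw = mw,
         n_units_exact = n_exact,
         n_units = as.integer(round_half_up(n_exact, 0)),
         unit_length = unit_length,
         monomer_mass = monomer_mass),
    class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("PEG linker: MW %g Da, %d PEO units (%.2f exact), unit length %.2f nm\n",
              x$mw, x$n_units, x$n_units_exact, x$unit_length))
  cat(sprintf("  contour length %.2f nm, Flory radius %.2f nm\n",
              contour_length(x), flory_radius(x)))
  invisible(x)
}

as_polymer_spec <- function(x, ...) {
  if (inherits(x, "polymer_spec")) x else polymer_spec(x, ...)
}

#' Number of PEO repeat units of a PEG linker
#'
#' Nearest integer of `mw / monomer_mass`, ties rounding half up.
#'
#' @inheritParams polymer_spec
#' @return Integer unit count.
#' @export
#' @examples
#' peo_unit_count(2000)  # 45
peo_unit_count <- function(mw, monomer_mass = 44) {
  spec <- polymer_spec(mw, monomer_mass = monomer_mass)
  spec$n_units
}

#' Contour length of a PEG linker
#'
#' Fully extended chain length, `n * a` with `n = mw/monomer_mass` unrounded
#' and `a` the PEO unit length (0.28 nm in water).
#'
#' @param spec A [polymer_spec()] or a molecular weight in Dalton.
#' @return Contour length in nm.
#' @export
#' @examples
#' contour_length(2000)  # ~12.7 nm
contour_length <- function(spec) {
  spec <- as_polymer_spec(spec)
  spec$n_units_exact * spec$unit_length
}

#' Flory radius of a PEG linker
#'
#' Equilibrium coil size of a self-avoiding chain, `a * n^(3/5)` with the
#' unrounded unit count `n = mw/monomer_mass`.
#'
#' @inheritParams contour_length
#' @return Flory radius in nm.
#' @export
#' @examples
#' flory_radius(2000)  # ~2.8 nm
flory_radius <- function(spec) {
  spec <- as_polymer_spec(spec)
  spec$unit_length * spec$n_units_exact^0.6
}

#' Entropic restoring force of a Gaussian chain at given extension
#'
#' Ideal-chain spring law `f = 3 kT x / (n a^2)`: the tension a flexible
#' tether exerts when its end is held at extension `x`. Valid well below the
#' contour length; used as an order-of-magnitude cross-check of the
#' simulator's PMF slope. Inversely proportional to chain length at fixed
#' extension.
#'
#' @inheritParams contour_length
#' @param extension End-to-end extension in nm, `0 <= extension <
#'   contour_length`.
#' @param kT Thermal energy in pN nm (default 4.11, i.e. 300 K).
#' @return Force in pN.
#' @export
#' @examples
#' entropic_extension_force(4000, extension = 9)
entropic_extension_force <- function(spec, extension, kT = 4.11) {
  spec <- as_polymer_spec(spec)
  if (!is.numeric(extension) || any(extension < 0))
    stop("`extension` must be non-negative (nm)")
  if (any(extension >= contour_length(spec)))
    stop("`extension` must be below the contour length: the Gaussian-chain ",
         "approximation is invalid near full stretch")
  3 * kT * extension / (spec$n_units_exact * spec$unit_length^2)
}

#' Rouse estimate of the longest chain relaxation time
#'
#' Standard Rouse scaling, `tau_1 = b^2 N^2 / (3 pi^2 D)` for `N` beads of
#' segment length `b` and single-bead diffusion coefficient `D`. Used to size
#' simulation and equilibration lengths; not calibrated to physical seconds.
#'
#' @param n_beads Number of beads (>= 2).
#' @param segment_length Segment (bond) length in nm.
#' @param bead_diffusion Bead diffusion coefficient in nm^2 per unit time
#'   (default 1, the reduced-unit convention of [run_brownian()]).
#' @return Relaxation time in the same time unit as `bead_diffusion`.
#' @export
#' @examples
#' rouse_time_estimate(30, 0.84)
rouse_time_estimate <- function(n_beads, segment_length, bead_diffusion = 1) {
  if (n_beads < 2) stop("`n_beads` must be at least 2")
  segment_length^2 * n_beads^2 / (3 * pi^2 * bead_diffusion)
}
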