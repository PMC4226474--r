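#' FRET model parameters
#'
#' Parameters of the tether-distance FRET model: the Forster distance of the
#' donor/acceptor dye pair and the radius of the tethered ligand, which
#' offsets the donor position from the polymer's free end.
#'
#' @param forster_distance Forster distance R0 in nm (default 5, the
#'   DyLight 549/649 pair).
#' @param ligand_radius Ligand (pMHC) radius in nm added to the coil radius
#'   (default 2).
#' @return An object of class `fret_params`.
#' @export
fret_params <- function(forster_distance = 5, ligand_radius = 2) {
  if (forster_distance <= 0) stop("`forster_distance` must be positive (nm)")
  if (ligand_radius < 0) stop("`ligand_radius` must be non-negative (nm)")
  structure(list(forster_distance = forster_distance,
                 ligand_radius = ligand_radius),
            class = "fret_params")
}

#' Predicted donor-acceptor distance for a tethered ligand
#'
#' The average distance between a surface dye and a ligand tethered by a PEG
#' coil: Flory radius of the polymer plus the ligand radius.
#'
#' @inheritParams contour_length
#' @param params A [fret_params()] object.
#' @return Distance in nm.
#' @export
#' @examples
#' predicted_distance(2000)  # Flory radius + 2 nm
predicted_distance <- function(spec, params = fret_params()) {
  stopifnot(inherits(params, "fret_params"))
  flory_radius(spec) + params$ligand_radius
}

#' Theoretical FRET efficiency at a given distance
#'
#' Standard Forster form `E = 1 / (1 + (r/R0)^6)`; strictly decreasing in
#' `r`, 1 at contact, 1/2 at the Forster distance.
#'
#' @param r Donor-acceptor distance in nm (vectorised, `r >= 0`).
#' @inheritParams predicted_distance
#' @return Efficiency fraction in (0, 1].
#' @export
#' @examples
#' theoretical_fret(5)    # 0.5 at the Forster distance
#' theoretical_fret(2.5)  # short tether, near-complete transfer
theoretical_fret <- function(r, params = fret_params()) {
  stopifnot(inherits(params, "fret_params"))
  if (any(r < 0)) stop("`r` must be non-negative (nm)")
  1 / (1 + (r / params$forster_distance)^6)
}

#' FRET efficiency from acceptor photobleaching
#'
#' Efficiency estimated from the donor intensity before and after the
#' acceptor is photobleached: `E = 1 - I_before / I_after`. Measurement
#' noise can leave `I_before > I_after`; such estimates are clamped to 0 and
#' flagged (attribute `"clamped"`), with a warning.
#'
#' @param donor_before,donor_after Donor intensities before/after acceptor
#'   photobleaching (arbitrary units, vectorised); `donor_after` must be
#'   positive.
#' @return Efficiency fraction(s) in `[0, 1)` with logical attribute
#'   `"clamped"`.
#' @export
#' @examples
#' fret_from_photobleach(42, 100)  # 0.58
fret_from_photobleach <- function(donor_before, donor_after) {
  if (any(!is.finite(donor_after)) || any(donor_after <= 0))
    stop("`donor_after` must be positive: no donor signal after photobleach")
  if (any(donor_before < 0)) stop("`donor_before` must be non-negative")
  eff <- 1 - donor_before / donor_after
  clamped <- eff < 0
  if (any(clamped)) {
    warning(sum(clamped), " efficiency estimate(s) below 0 clamped ",
            "(donor brighter before photobleach; noise)")
    eff[clamped] <- 0
  }
  attr(eff, "clamped") <- clamped
  eff
}

#' Normalize a series of efficiencies (or rates) to a reference element
#'
#' Divides every value by the value at `reference_index`, so the reference
#' maps to 1. Used to place measured and theoretical FRET efficiencies (or
#' response rates) on a common scale relative to the shortest linker.
#' Missing values pass through as `NA`.
#'
#' @param values Numeric vector.
#' @param reference_index Index of the reference element (default 1, by
#'   convention the shortest linker of an ordered series).
#' @return Numeric vector of the same length, `values / values[reference_index]`.
#' @export
#' @examples
#' normalize_series(c(58, 53, 34))  # shortest linker -> 1
normalize_series <- function(values, reference_index = 1L) {
  if (reference_index < 1L || reference_index > length(values))
    stop("`reference_index` out of range")
  ref <- values[reference_index]
  if (!is.finite(ref) || ref <= 0)
    stop("reference value must be positive and non-missing")
  values / ref
}
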