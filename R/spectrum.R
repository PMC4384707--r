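#' Define an alpha-emission spectrum
#'
#' An alpha spectrum holds the emission lines considered for energy
#' deposition: per-decay yields \eqn{n_i} (dimensionless) and energies
#' \eqn{E_i} (MeV), together with the physical half-life of the nuclide.
#' Only alpha lines belong here; photon and electron contributions are out of
#' scope for short-range alpha dosimetry.
#'
#' @param yield Per-decay yields, each in (0, 1].
#' @param energy_mev Line energies in MeV, all > 0.
#' @param half_life_h Physical half-life in hours, > 0.
#' @return A tibble of class `alpha_spectrum` with columns `yield` and
#'   `energy_mev` and attribute `half_life_h`.
#' @seealso [at211_spectrum()] for the bundled astatine-211 default,
#'   [mean_alpha_energy()] for the per-decay energy sum.
#' @examples
#' alpha_spectrum(yield = 1, energy_mev = 5.87, half_life_h = 7.214)
#' @export
alpha_spectrum <- function(yield, energy_mev, half_life_h) {
  if (length(yield) == 0) {
    stop_atdose("alpha_spectrum(): no emission lines given; nuclide definition unusable")
  }
  if (length(yield) != length(energy_mev)) {
    stop_atdose("alpha_spectrum(): 'yield' and 'energy_mev' lengths differ")
  }
  if (any(!is.finite(yield)) || any(yield <= 0) || any(yield > 1)) {
    stop_atdose("alpha_spectrum(): yields must lie in (0, 1]")
  }
  if (any(!is.finite(energy_mev)) || any(energy_mev <= 0)) {
    stop_atdose("alpha_spectrum(): energies must be positive")
  }
  if (!is.numeric(half_life_h) || length(half_life_h) != 1 || half_life_h <= 0) {
    stop_atdose("alpha_spectrum(): half_life_h must be a single positive number")
  }
  out <- tibble(yield = as.numeric(yield), energy_mev = as.numeric(energy_mev))
  attr(out, "half_life_h") <- as.numeric(half_life_h)
  class(out) <- c("alpha_spectrum", class(out))
  out
}

#' Default astatine-211 alpha spectrum
#'
#' ^211^At decays through two branches that each end in one main alpha
#' emission: the direct alpha branch (5.87 MeV) and the electron-capture
#' branch through the ^211^Po daughter (7.45 MeV). Branching fractions and
#' the 7.214 h half-life are external decay-data constants, exposed here as
#' editable arguments rather than hard-wired physics.
#'
#' @param yield_at,yield_po Branch yields of the 5.87 and 7.45 MeV lines.
#' @param half_life_h Physical half-life in hours.
#' @return An [alpha_spectrum()].
#' @examples
#' mean_alpha_energy(at211_spectrum())
#' @export
at211_spectrum <- function(yield_at = 0.418, yield_po = 0.582, half_life_h = 7.214) {
  alpha_spectrum(
    yield = c(yield_at, yield_po),
    energy_mev = c(5.87, 7.45),
    half_life_h = half_life_h
  )
}

#' Half-life of a spectrum
#' @param spectrum An [alpha_spectrum()].
#' @return Half-life in hours.
#' @export
spectrum_half_life <- function(spectrum) {
  hl <- attr(spectrum, "half_life_h")
  if (is.null(hl)) stop_atdose("spectrum has no half_life_h attribute")
  hl
}

#' Mean alpha energy emitted per decay
#'
#' The per-decay energy term of the MIRD dose equation,
#' \eqn{\sum_i n_i E_i}, in MeV per decay. Independent of line ordering.
#'
#' @param spectrum An [alpha_spectrum()].
#' @return Energy in MeV per decay.
#' @examples
#' mean_alpha_energy(alpha_spectrum(c(0.5, 0.5), c(2, 4), 7.2)) # 3 MeV
#' @export
mean_alpha_energy <- function(spectrum) {
  if (!inherits(spectrum, "alpha_spectrum")) {
    spectrum <- alpha_spectrum(spectrum$yield, spectrum$energy_mev,
                               attr(spectrum, "half_life_h") %||% 1)
  }
  if (nrow(spectrum) == 0) {
    stop_atdose("mean_alpha_energy(): empty spectrum; nuclide definition unusable")
  }
  sum(spectrum$yield * spectrum$energy_mev)
}
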