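#' Organ mean absorbed dose from cumulated activity
#'
#' The MIRD mean absorbed dose for a source organ irradiating itself:
#' \deqn{\bar D = \tilde A \, \sum_i n_i E_i \Phi_i / m}
#' with cumulated activity \eqn{\tilde A} in decays, per-decay alpha energy
#' in MeV (converted at 1.602176634e-13 J/MeV), absorbed fraction
#' \eqn{\Phi} (1 for short-range alpha particles) and organ mass in kg.
#' Homogeneous activity distribution within the organ is assumed.
#'
#' @param decays Cumulated activity in decays (>= 0); vectorised.
#' @param spectrum An [alpha_spectrum()].
#' @param mass_kg Organ mass in kg (> 0).
#' @param absorbed_fraction Absorbed fraction in (0, 1]; default 1.
#' @return Mean absorbed dose in mGy.
#' @examples
#' organ_dose(1e9, alpha_spectrum(1, 1, 7.2), mass_kg = 1e-3) # 160.2 mGy
#' @export
organ_dose <- function(decays, spectrum, mass_kg, absorbed_fraction = 1) {
  if (any(decays < 0)) stop_atdose("organ_dose(): cumulated activity must be >= 0")
  if (any(mass_kg <= 0)) stop_atdose("organ_dose(): organ mass must be > 0")
  if (any(absorbed_fraction <= 0 | absorbed_fraction > 1)) {
    stop_atdose("organ_dose(): absorbed fraction must lie in (0, 1]")
  }
  e_mev <- mean_alpha_energy(spectrum)
  gy <- decays * e_mev * MEV_TO_J * absorbed_fraction / mass_kg
  gy * 1000
}

#' Scale a dose linearly with injected activity
#'
#' For a fixed per-unit-activity biodistribution the cumulated activity, and
#' hence the mean absorbed dose, is linear in the injected activity, so a
#' dose known at a reference activity transfers to any other activity by the
#' activity ratio. Rounding for report tables is a separate, explicit step
#' ([signif_report()]).
#'
#' @param dose_mgy Dose at the reference activity (mGy); vectorised.
#' @param activity_ref_kbq Reference injected activity in kBq (> 0).
#' @param activity_new_kbq Target injected activity in kBq.
#' @return Dose at the target activity in mGy (unrounded).
#' @examples
#' signif_report(scale_dose(0.29, 1.7, 105)) # 18
#' @export
scale_dose <- function(dose_mgy, activity_ref_kbq, activity_new_kbq) {
  if (any(activity_ref_kbq <= 0)) stop_atdose("scale_dose(): reference activity must be > 0")
  dose_mgy * activity_new_kbq / activity_ref_kbq
}

#' Organ dose table over exposure windows
#'
#' Builds the per-organ dose table for a set of exposure windows (injected
#' activity, integration end time). Curves are taken at the reference
#' injected activity; each curve is extended to the longest requested
#' horizon by held-biodistribution physical decay, integrated from
#' `t_start = 0` with the trapezoidal rule, converted to dose, and scaled
#' linearly to each window's activity.
#'
#' @param curves `tac` table covering every organ in `organs`, measured at
#'   `reference_activity_kbq` injected activity.
#' @param organs Tibble with columns `organ`, `mass_kg` and optionally
#'   `absorbed_fraction` (default 1).
#' @param spectrum An [alpha_spectrum()]; its half-life drives curve
#'   extension and decay-corrected conversion.
#' @param windows Tibble with columns `activity_kbq`, `t_end_h` — one row
#'   per exposure window.
#' @param reference_activity_kbq Injected activity the curves correspond to.
#' @param step_h Extension grid spacing in hours.
#' @return A tibble, one row per organ x window: `organ`, `activity_kbq`,
#'   `time_h`, `decays`, `dose_mgy`, `dose_report` (2 significant figures).
#' @examples
#' crv <- tac("spleen", c(0, 24), c(20, 15))
#' org <- tibble::tibble(organ = "spleen", mass_kg = 1e-4)
#' win <- tibble::tibble(activity_kbq = c(1.7, 105), t_end_h = c(1, 1))
#' dose_table(crv, org, at211_spectrum(), win)
#' @export
dose_table <- function(curves, organs, spectrum, windows,
                       reference_activity_kbq = 1.7, step_h = 1) {
  curves <- as_tac(curves)
  organs <- as_tibble(organs)
  if (!"absorbed_fraction" %in% names(organs)) organs$absorbed_fraction <- 1
  windows <- as_tibble(windows)
  miss <- setdiff(organs$organ, unique(curves$organ))
  if (length(miss)) stop_atdose("dose_table(): no curve for organ(s): %s", toString(miss))
  miss <- setdiff(unique(curves$organ), organs$organ)
  if (length(miss)) stop_atdose("dose_table(): no geometry for organ(s): %s", toString(miss))

  hl <- spectrum_half_life(spectrum)
  horizon <- max(windows$t_end_h)
  curves <- extend_tac(curves, horizon, half_life_h = hl, step_h = step_h)

  purrr::pmap_dfr(windows, function(activity_kbq, t_end_h, ...) {
    ca <- cumulated_activity(curves, 0, t_end_h, half_life_h = hl)
    ca |>
      inner_join(organs, by = "organ") |>
      mutate(
        activity_kbq = activity_kbq,
        time_h = t_end_h,
        decays = .data$decays * activity_kbq / reference_activity_kbq,
        dose_mgy = organ_dose(.data$decays, spectrum, .data$mass_kg,
                              .data$absorbed_fraction),
        dose_report = signif_report(.data$dose_mgy)
      ) |>
      select("organ", "activity_kbq", "time_h", "decays", "dose_mgy", "dose_report")
  }) |>
    arrange(.data$organ, .data$activity_kbq, .data$time_h)
}
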