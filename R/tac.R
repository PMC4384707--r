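#' Build a time-activity curve table
#'
#' A time-activity curve records the physical (or decay-corrected) activity
#' in a whole organ over time after injection; it is the integrand of the
#' cumulated activity. One table may hold several organs.
#'
#' @param organ Organ label(s).
#' @param time_h Sampling times in hours; strictly increasing within organ.
#' @param activity_bq Activity in Bq in the whole organ; non-negative. If
#'   `decay_corrected`, physical decay has been divided out and the physical
#'   activity at time t is `activity_bq * exp(-lambda * t)`.
#' @param decay_corrected Logical flag (recycled), whether activities are
#'   decay-corrected.
#' @return A tibble of class `tac` with columns `organ`, `time_h`,
#'   `activity_bq`, `decay_corrected`.
#' @examples
#' tac("liver", c(0, 1, 6, 24), c(0, 50, 40, 10))
#' @export
tac <- function(organ, time_h, activity_bq, decay_corrected = FALSE) {
  out <- tibble(
    organ = as.character(organ),
    time_h = as.numeric(time_h),
    activity_bq = as.numeric(activity_bq),
    decay_corrected = as.logical(decay_corrected)
  )
  as_tac(out)
}

#' Coerce and validate a time-activity curve table
#'
#' @param x A data frame with columns `organ`, `time_h`, `activity_bq` and
#'   optionally `decay_corrected` (default FALSE).
#' @return A validated `tac` tibble.
#' @export
as_tac <- function(x) {
  x <- as_tibble(x)
  if (!"decay_corrected" %in% names(x)) x$decay_corrected <- FALSE
  need <- c("organ", "time_h", "activity_bq", "decay_corrected")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_atdose("as_tac(): missing columns: %s", toString(miss))
  x <- x[, need]
  if (nrow(x) == 0) stop_atdose("as_tac(): curve has no samples")
  if (any(!is.finite(x$time_h))) stop_atdose("as_tac(): non-finite times")
  if (any(!is.finite(x$activity_bq)) || any(x$activity_bq < 0)) {
    stop_atdose("as_tac(): activities must be finite and >= 0")
  }
  x <- arrange(x, .data$organ, .data$time_h)
  bad <- x |>
    group_by(.data$organ) |>
    summarise(
      ok = all(diff(.data$time_h) > 0) && length(unique(.data$decay_corrected)) == 1,
      .groups = "drop"
    ) |>
    filter(!.data$ok)
  if (nrow(bad)) {
    stop_atdose("as_tac(): non-increasing times or mixed decay_corrected flag for organ(s): %s",
                toString(bad$organ))
  }
  class(x) <- unique(c("tac", class(x)))
  x
}

# physical activity at the curve's own sample times
tac_physical <- function(curve, half_life_h = NULL) {
  if (any(curve$decay_corrected)) {
    if (is.null(half_life_h)) {
      stop_atdose("decay-corrected curve: half_life_h is required to recover physical activity")
    }
    lambda <- log(2) / half_life_h
    curve$activity_bq <- ifelse(curve$decay_corrected,
                                curve$activity_bq * exp(-lambda * curve$time_h),
                                curve$activity_bq)
    curve$decay_corrected <- FALSE
  }
  curve
}

#' Extend a time-activity curve beyond its last sample
#'
#' Biodistribution is held invariant past the last sampled time: the organ's
#' decay-corrected level stays at its last value, so the physical activity
#' continues as pure exponential physical decay (`exp(-lambda * dt)`,
#' `lambda = log(2)/half_life_h`). For a decay-corrected curve the held level
#' is appended as-is (conversion to physical activity happens at integration
#' time); for a physical curve the last activity is propagated with decay.
#'
#' A horizon at or before the last sample returns the input unchanged.
#'
#' @param curve A `tac` table (one or more organs).
#' @param horizon_h Extension horizon in hours.
#' @param half_life_h Physical half-life in hours.
#' @param step_h Grid spacing of appended samples (default 1 h).
#' @return A `tac` table with appended samples.
#' @examples
#' crv <- tac("spleen", c(0, 24), c(10, 8))
#' extend_tac(crv, 48, half_life_h = 7.214)
#' @export
extend_tac <- function(curve, horizon_h, half_life_h, step_h = 1) {
  curve <- as_tac(curve)
  if (step_h <= 0) stop_atdose("extend_tac(): step_h must be > 0")
  lambda <- log(2) / half_life_h
  ext <- curve |>
    group_by(.data$organ) |>
    dplyr::group_modify(function(d, key) {
      t_last <- max(d$time_h)
      if (horizon_h <= t_last) return(d)
      grid <- seq(t_last + step_h, horizon_h, by = step_h)
      if (length(grid) == 0 || max(grid) < horizon_h) grid <- c(grid, horizon_h)
      a_last <- d$activity_bq[which.max(d$time_h)]
      dc <- d$decay_corrected[1]
      app <- tibble(
        time_h = grid,
        activity_bq = if (dc) a_last else a_last * exp(-lambda * (grid - t_last)),
        decay_corrected = dc
      )
      bind_rows(d, app)
    }) |>
    ungroup()
  as_tac(ext)
}

#' Cumulated activity over a time window
#'
#' Integrates the physical organ activity over `[t_start, t_end]` with the
#' trapezoidal rule on the curve's sample grid (window endpoints off the grid
#' are linearly interpolated) and converts Bq·h to decays (factor 3600). The
#' window must lie within the curve's support; extend the curve first if the
#' horizon exceeds the last sample.
#'
#' @param curve A `tac` table (one or more organs).
#' @param t_start,t_end Window in hours, `t_end > t_start`.
#' @param half_life_h Physical half-life in hours; required only when the
#'   curve is decay-corrected.
#' @return A tibble with one row per organ: `organ`, `t_start_h`, `t_end_h`,
#'   `decays` (the cumulated activity as a dimensionless decay count).
#' @examples
#' crv <- tac("x", c(0, 1), c(1, 1))
#' cumulated_activity(crv, 0, 1)$decays # 3600
#' @export
cumulated_activity <- function(curve, t_start, t_end, half_life_h = NULL) {
  curve <- as_tac(curve)
  if (t_end <= t_start) stop_atdose("cumulated_activity(): t_end must exceed t_start")
  curve <- tac_physical(curve, half_life_h)
  curve |>
    group_by(.data$organ) |>
    summarise(
      t_start_h = t_start,
      t_end_h = t_end,
      decays = {
        tt <- .data$time_h
        aa <- .data$activity_bq
        if (t_start < min(tt) - 1e-9 || t_end > max(tt) + 1e-9) {
          stop_atdose(
            "cumulated_activity(): window [%g, %g] h outside curve support [%g, %g] h for organ '%s'",
            t_start, t_end, min(tt), max(tt), .data$organ[1]
          )
        }
        knots <- sort(unique(c(t_start, tt[tt > t_start & tt < t_end], t_end)))
        vals <- stats::approx(tt, aa, xout = knots, rule = 1)$y
        pracma::trapz(knots, vals) * 3600
      },
      .groups = "drop"
    )
}
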