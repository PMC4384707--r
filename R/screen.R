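#' Define a dose-rate exposure grid
#'
#' The grid pairs a reference injected activity observed at several times
#' with elevated-activity arms that each share a time point with the
#' reference, enabling matched-time dose-rate comparisons. The default
#' mirrors the emulated design: 1.7 kBq at 1 h, 6 h and 7 d, with elevated
#' arms 105 kBq at 1 h and 7.5 kBq at 6 h.
#'
#' @param reference_activity_kbq Reference injected activity.
#' @param reference_times_h Times at which the reference arm is observed.
#' @param elevated Tibble `activity_kbq`, `time_h`; every elevated time must
#'   be one of `reference_times_h`.
#' @return An object of class `exposure_grid`.
#' @export
exposure_grid <- function(reference_activity_kbq = 1.7,
                          reference_times_h = c(1, 6, 168),
                          elevated = tibble(activity_kbq = c(105, 7.5),
                                            time_h = c(1, 6))) {
  elevated <- as_tibble(elevated)
  if (!all(elevated$time_h %in% reference_times_h)) {
    stop_atdose("exposure_grid(): every elevated condition must share a time with the reference arm")
  }
  structure(
    list(
      reference = tibble(activity_kbq = reference_activity_kbq,
                         time_h = reference_times_h),
      elevated = elevated
    ),
    class = "exposure_grid"
  )
}

#' @export
print.exposure_grid <- function(x, ...) {
  cat("<exposure_grid>\n reference:",
      toString(condition_label(x$reference$activity_kbq, x$reference$time_h)),
      "\n elevated: ",
      toString(condition_label(x$elevated$activity_kbq, x$elevated$time_h)), "\n")
  invisible(x)
}

# all condition labels of a grid (reference first)
grid_conditions <- function(grid) {
  c(condition_label(grid$reference$activity_kbq, grid$reference$time_h),
    condition_label(grid$elevated$activity_kbq, grid$elevated$time_h))
}

#' Genes significant at every condition
#'
#' Set intersection of per-condition significant sets. Probe variants of one
#' gene are distinct entries at the probe level; collapse happens later in
#' the screen.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Character vector of members common to all sets.
#' @export
intersect_all_conditions <- function(sets) {
  if (length(sets) < 2) stop_atdose("intersect_all_conditions(): need >= 2 condition sets")
  Reduce(intersect, sets)
}

#' Direction consistency of a fold-change vector
#'
#' TRUE iff all signed fold changes share one sign — no change in direction
#' of regulation across exposure conditions.
#'
#' @param fc Signed fold changes at all grid conditions (no NAs).
#' @return Logical flag.
#' @export
direction_consistent <- function(fc) {
  if (anyNA(fc)) stop_atdose("direction_consistent(): missing condition fold change")
  all(fc > 0) || all(fc < 0)
}

#' Classify the dose-rate response pattern
#'
#' Compares regulation intensity `|FC|` at the elevated activity against the
#' reference activity at each shared time point: `direct` iff strictly
#' higher at both times, `inverse` iff strictly lower at both, `mixed`
#' otherwise (equality at either time counts as mixed — "higher or lower"
#' is read strictly). Classification presumes a direction-consistent gene
#' and is refused otherwise.
#'
#' @param fc_ref,fc_elev Signed fold changes at the shared time points,
#'   reference and elevated activity respectively (same length/order).
#' @return `"direct"`, `"inverse"` or `"mixed"`.
#' @examples
#' classify_pattern(c(2.0, 2.2), c(3.0, 3.1)) # direct
#' @export
classify_pattern <- function(fc_ref, fc_elev) {
  if (length(fc_ref) != length(fc_elev) || !length(fc_ref)) {
    stop_atdose("classify_pattern(): reference and elevated vectors must align")
  }
  if (!direction_consistent(c(fc_ref, fc_elev))) {
    stop_atdose("classify_pattern(): direction of regulation changes across conditions; classification refused",
                class = "atdose_direction_error")
  }
  hi <- abs_fc(fc_elev) > abs_fc(fc_ref)
  lo <- abs_fc(fc_elev) < abs_fc(fc_ref)
  if (all(hi)) "direct" else if (all(lo)) "inverse" else "mixed"
}

#' Near-tie flag for matched fold changes
#'
#' TRUE iff the relative difference in regulation intensity between the
#' elevated and reference activity, `||FC_elev| - |FC_ref|| / |FC_ref|`,
#' falls below `threshold` at any shared time point. Such genes keep their
#' pattern label but are flagged as effectively tied.
#'
#' @param fc_ref,fc_elev Signed fold changes at the shared time points.
#' @param threshold Relative-difference threshold (default 0.03).
#' @return Logical flag.
#' @examples
#' near_tie(2.00, 2.05) # 2.5% -> TRUE
#' near_tie(2.00, 2.10) # 5%   -> FALSE
#' @export
near_tie <- function(fc_ref, fc_elev, threshold = 0.03) {
  any(abs(abs_fc(fc_elev) - abs_fc(fc_ref)) / abs_fc(fc_ref) < threshold)
}

#' Screen for dose-rate-sensitive biomarker candidates
#'
#' Runs the full candidate screen over per-condition differential-expression
#' results: probes significant at every grid condition are intersected,
#' checked for direction consistency, classified as direct / inverse / mixed
#' on the matched-time elevated-vs-reference comparison, and flagged when
#' the intensity difference is a near tie. The late reference-only time
#' point (7 d by default) participates in the intersection but not in
#' pattern classification — no elevated arm exists there.
#'
#' Gene-level view: probe variants of one gene stay as rows; a gene whose
#' probes disagree in direction is flagged `gene_discordant`.
#'
#' @param de_list Named list of `de_result` covering every grid condition.
#' @param grid An [exposure_grid()].
#' @param tie_threshold Relative near-tie threshold (default 0.03).
#' @return A `biomarker_screen`: tibble with one row per candidate probe
#'   (`gene`, `probe`, `direction`, `pattern`, `near_tie`, `min_abs_fc`,
#'   `gene_discordant`, one `fc_*` column per grid condition), sorted by
#'   `min_abs_fc` descending. Attribute `trajectories` holds a long table
#'   for plotting. Empty input intersections yield an empty (zero-row)
#'   result, not an error.
#' @export
screen_biomarkers <- function(de_list, grid = exposure_grid(), tie_threshold = 0.03) {
  conds <- grid_conditions(grid)
  miss <- setdiff(conds, names(de_list))
  if (length(miss)) {
    stop_atdose("screen_biomarkers(): missing DE results for condition(s): %s", toString(miss))
  }
  de_list <- de_list[conds]
  common <- intersect_all_conditions(significant_sets(de_list, by = "probe"))

  fc_wide <- purrr::imap_dfr(de_list, function(d, cond) {
    tidy(d) |>
      filter(.data$probe %in% common) |>
      select("probe", "gene", "fold_change") |>
      mutate(condition = cond)
  })

  shared_times <- grid$elevated$time_h
  ref_conds <- condition_label(grid$reference$activity_kbq[1], shared_times)
  elev_conds <- condition_label(grid$elevated$activity_kbq, grid$elevated$time_h)

  empty <- tibble(
    gene = character(), probe = character(), direction = character(),
    pattern = character(), near_tie = logical(), min_abs_fc = numeric(),
    gene_discordant = logical()
  )
  if (!length(common)) {
    out <- empty
    for (cc in conds) out[[paste0("fc_", cc)]] <- numeric()
    attr(out, "trajectories") <- fc_wide
    class(out) <- c("biomarker_screen", class(out))
    return(out)
  }

  per_probe <- fc_wide |>
    tidyr::pivot_wider(names_from = "condition", values_from = "fold_change")
  rows <- purrr::pmap_dfr(per_probe, function(probe, gene, ...) {
    fc <- c(...)
    consistent <- direction_consistent(unname(fc[conds]))
    fr <- unname(fc[ref_conds]); fe <- unname(fc[elev_conds])
    tibble(
      gene = gene, probe = probe,
      direction = if (!consistent) NA_character_ else if (fc[[1]] > 0) "up" else "down",
      pattern = if (consistent) classify_pattern(fr, fe) else NA_character_,
      near_tie = if (consistent) near_tie(fr, fe, tie_threshold) else NA,
      min_abs_fc = min(abs_fc(fc[conds]))
    )
  })

  discord <- rows |>
    group_by(.data$gene) |>
    summarise(gene_discordant = dplyr::n_distinct(.data$direction) > 1 | anyNA(.data$direction),
              .groups = "drop")

  out <- rows |>
    left_join(discord, by = "gene") |>
    left_join(per_probe |> rename_fc(conds), by = c("probe", "gene")) |>
    arrange(dplyr::desc(.data$min_abs_fc))
  attr(out, "trajectories") <- fc_wide
  attr(out, "grid") <- grid
  class(out) <- c("biomarker_screen", class(out))
  out
}

rename_fc <- function(tbl, conds) {
  nm <- names(tbl)
  names(tbl)[nm %in% conds] <- paste0("fc_", nm[nm %in% conds])
  tbl
}

#' @export
print.biomarker_screen <- function(x, ...) {
  cat(sprintf("<biomarker_screen> %d candidate probe(s) significant at all conditions\n", nrow(x)))
  if (nrow(x)) NextMethod() else invisible(x)
}

#' @rdname screen_biomarkers
#' @param x A `biomarker_screen`.
#' @param ... Unused.
#' @export
tidy.biomarker_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "biomarker_screen")
  out
}

#' @rdname screen_biomarkers
#' @export
glance.biomarker_screen <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_genes = dplyr::n_distinct(x$gene),
    n_direct = sum(x$pattern == "direct", na.rm = TRUE),
    n_inverse = sum(x$pattern == "inverse", na.rm = TRUE),
    n_mixed = sum(x$pattern == "mixed", na.rm = TRUE),
    n_near_tie = sum(x$near_tie, na.rm = TRUE)
  )
}
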