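#' Call differentially expressed transcripts for one exposure condition
#'
#' Contrasts one (activity, time) treatment group against the study's
#' controls: a detection floor filters probes, each filtered probe gets a
#' signed fold change and a two-sided Welch p-value, Benjamini-Hochberg
#' adjustment runs across the condition's filtered probe set, and a probe is
#' called significant when `p_adj < alpha` and `|FC| >= fc_threshold`
#' (defaults 0.01 and 1.5).
#'
#' The test unit defaults to individual arrays (`unit = "array"`), i.e.
#' technical replicates enter the test directly — the behaviour that
#' reproduces detectable regulation in the two-animal arms of the emulated
#' design. `unit = "biological"` collapses technical replicates first
#' ([collapse_technical()]) and tests across biological replicates; with two
#' animals per group this is a valid but severely low-powered test, and the
#' result carries a `low_power` flag.
#'
#' The detection floor keeps probes whose mean log2 intensity exceeds the
#' `floor_quantile` quantile of the whole matrix; the filtered set is also
#' the enrichment universe downstream.
#'
#' @param study An [expression_study()].
#' @param activity_kbq,time_h The exposure condition to contrast.
#' @param fc_threshold Minimum `|FC|` for significance (default 1.5).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param floor_quantile Detection-floor quantile of the matrix (default 0.2).
#' @param unit `"array"` (default) or `"biological"`; see Details.
#' @return A `de_result`: tibble with columns `probe`, `gene`, `condition`,
#'   `fold_change`, `p_raw`, `p_adj`, `significant`, plus attributes
#'   `condition`, `universe` (filtered probes), `universe_genes`,
#'   `thresholds`, `low_power`.
#' @seealso [call_de_all()], [de_summary()], [tidy.de_result()]
#' @export
call_de <- function(study, activity_kbq, time_h, fc_threshold = 1.5,
                    alpha = 0.01, floor_quantile = 0.2,
                    unit = c("array", "biological")) {
  unit <- match.arg(unit)
  if (unit == "biological") study <- collapse_technical(study)
  s <- study$samples
  treated <- s$sample_id[!s$is_control &
                           s$activity_kbq == activity_kbq & s$time_h == time_h]
  control <- s$sample_id[s$is_control]
  if (!length(treated)) {
    avail <- study_conditions(study)
    stop_atdose("call_de(): condition %s not present; available: %s",
                condition_label(activity_kbq, time_h), toString(avail$condition))
  }
  if (length(treated) < 2 || length(control) < 2) {
    stop_atdose("call_de(): need >= 2 replicates per group for a finite statistic")
  }
  low_power <- min(length(treated), length(control)) < 3

  floor <- quantile(study$matrix, floor_quantile, names = FALSE)
  keep <- rowMeans(study$matrix) > floor
  mat <- study$matrix[keep, , drop = FALSE]

  w <- welch_rows(mat[, treated, drop = FALSE], mat[, control, drop = FALSE])
  p_adj <- unname(benjamini_hochberg(w$p))
  fc <- unname(signed_fc(w$dlog2))
  cond <- condition_label(activity_kbq, time_h)

  calls <- tibble(
    probe = rownames(mat),
    condition = cond,
    fold_change = fc,
    p_raw = unname(w$p),
    p_adj = p_adj,
    significant = p_adj < alpha & abs(fc) >= fc_threshold
  ) |>
    left_join(study$probe_genes, by = "probe") |>
    mutate(gene = dplyr::coalesce(.data$gene, .data$probe)) |>
    select("probe", "gene", "condition", "fold_change", "p_raw", "p_adj", "significant")

  structure(
    calls,
    class = c("de_result", class(calls)),
    condition = cond,
    activity_kbq = activity_kbq,
    time_h = time_h,
    universe = rownames(mat),
    universe_genes = unique(calls$gene),
    thresholds = c(fc = fc_threshold, alpha = alpha, floor_quantile = floor_quantile),
    unit = unit,
    low_power = low_power
  )
}

#' Call differential expression for every condition in a study
#'
#' @param study An [expression_study()].
#' @param ... Passed to [call_de()].
#' @return Named list of `de_result`, keyed by condition label.
#' @export
call_de_all <- function(study, ...) {
  conds <- study_conditions(study)
  out <- purrr::pmap(conds[, c("activity_kbq", "time_h")], function(activity_kbq, time_h) {
    call_de(study, activity_kbq, time_h, ...)
  })
  setNames(out, conds$condition)
}

#' @export
print.de_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<de_result> %s: %d up / %d down of %d filtered probes%s\n",
              attr(x, "condition"), g$n_up, g$n_down, g$n_filtered,
              if (isTRUE(attr(x, "low_power"))) " [low power: < 3 replicates]" else ""))
  NextMethod()
}

#' Tidy a differential-expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return A plain tibble of per-probe calls.
#' @export
tidy.de_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "de_result")
  out
}

#' One-row summary of a differential-expression result
#'
#' Up/down counts partition the significant calls by fold-change sign —
#' the per-condition numbers behind the regulation-count bar chart.
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return Tibble: `condition`, `activity_kbq`, `time_h`, `n_filtered`,
#'   `n_up`, `n_down`, `low_power`.
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    condition = attr(x, "condition"),
    activity_kbq = attr(x, "activity_kbq"),
    time_h = attr(x, "time_h"),
    n_filtered = length(attr(x, "universe")),
    n_up = sum(x$significant & x$fold_change > 0),
    n_down = sum(x$significant & x$fold_change < 0),
    low_power = isTRUE(attr(x, "low_power"))
  )
}

#' Up/down regulation counts across conditions
#'
#' @param de_list Named list of `de_result` (e.g. from [call_de_all()]).
#' @return Tibble with one row per condition (see [glance.de_result()]).
#' @export
de_summary <- function(de_list) {
  purrr::map_dfr(de_list, glance)
}

#' Significant probe sets per condition
#' @param de_list Named list of `de_result`.
#' @param by `"probe"` (default) or `"gene"`.
#' @return Named list of character vectors.
#' @export
significant_sets <- function(de_list, by = c("probe", "gene")) {
  by <- match.arg(by)
  purrr::map(de_list, function(d) unique(d[[by]][d$significant]))
}
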