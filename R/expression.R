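#' Assemble an expression study
#'
#' Couples a normalized log2 expression matrix (probes x sample arrays) with
#' the sample metadata that defines the exposure conditions, and an optional
#' probe-to-gene map. Arrays are technical replicates nested in biological
#' replicates; technical replicates of one biological replicate must share
#' the replicate's exposure condition.
#'
#' @param log2_matrix Numeric matrix, probes in rows (rownames = probe ids),
#'   sample arrays in columns (colnames = sample ids).
#' @param samples Tibble with columns `sample_id`, `activity_kbq`, `time_h`,
#'   `bio_rep`, `tech_rep`, `is_control` — one row per array.
#' @param probe_genes Optional tibble `probe`, `gene`; defaults to
#'   gene = probe.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(log2_matrix, samples, probe_genes = NULL) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "activity_kbq", "time_h", "bio_rep", "tech_rep", "is_control")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_atdose("expression_study(): samples missing columns: %s", toString(miss))
  if (is.null(colnames(log2_matrix)) || is.null(rownames(log2_matrix))) {
    stop_atdose("expression_study(): matrix needs probe rownames and sample colnames")
  }
  if (!setequal(colnames(log2_matrix), samples$sample_id)) {
    stop_atdose("expression_study(): matrix columns and sample metadata do not match")
  }
  if (anyNA(samples$bio_rep) || anyNA(samples$tech_rep)) {
    stop_atdose("expression_study(): orphan technical replicate (missing bio_rep/tech_rep annotation)")
  }
  if (!any(samples$is_control)) {
    stop_atdose("expression_study(): at least one control replicate is required")
  }
  bad <- samples |>
    filter(!.data$is_control) |>
    group_by(.data$bio_rep) |>
    summarise(ok = dplyr::n_distinct(.data$activity_kbq) == 1 &&
                dplyr::n_distinct(.data$time_h) == 1, .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    stop_atdose("expression_study(): technical replicates of bio_rep(s) %s disagree on condition",
                toString(bad$bio_rep))
  }
  if (is.null(probe_genes)) {
    probe_genes <- tibble(probe = rownames(log2_matrix), gene = rownames(log2_matrix))
  }
  probe_genes <- as_tibble(probe_genes)
  structure(
    list(
      matrix = log2_matrix[, samples$sample_id, drop = FALSE],
      samples = samples,
      probe_genes = probe_genes
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cond <- x$samples |>
    filter(!.data$is_control) |>
    distinct(.data$activity_kbq, .data$time_h)
  cat(sprintf(
    "<expression_study> %d probes x %d arrays (%d biological replicates; %d exposure conditions)\n",
    nrow(x$matrix), ncol(x$matrix), dplyr::n_distinct(x$samples$bio_rep), nrow(cond)
  ))
  invisible(x)
}

#' Conditions present in a study
#' @param study An [expression_study()].
#' @return Tibble `activity_kbq`, `time_h`, `condition` (label) for all
#'   non-control groups.
#' @export
study_conditions <- function(study) {
  study$samples |>
    filter(!.data$is_control) |>
    distinct(.data$activity_kbq, .data$time_h) |>
    arrange(.data$activity_kbq, .data$time_h) |>
    mutate(condition = condition_label(.data$activity_kbq, .data$time_h))
}

#' Collapse technical replicates
#'
#' Averages log2 values over the technical replicates of each biological
#' replicate (arithmetic mean per probe), yielding one column per biological
#' replicate. Applying it twice is a no-op.
#'
#' @param study An [expression_study()].
#' @return An [expression_study()] with one array per biological replicate
#'   (`tech_rep` set to 1).
#' @export
collapse_technical <- function(study) {
  s <- study$samples
  groups <- split(s$sample_id, s$bio_rep)
  bio_ids <- names(groups)
  mat <- vapply(groups, function(ids) {
    rowMeans(study$matrix[, ids, drop = FALSE])
  }, numeric(nrow(study$matrix)))
  if (is.null(dim(mat))) {
    mat <- matrix(mat, nrow = nrow(study$matrix), byrow = FALSE)
    rownames(mat) <- rownames(study$matrix)
  }
  colnames(mat) <- bio_ids
  meta <- s |>
    group_by(.data$bio_rep) |>
    summarise(
      activity_kbq = .data$activity_kbq[1],
      time_h = .data$time_h[1],
      is_control = .data$is_control[1],
      .groups = "drop"
    ) |>
    mutate(sample_id = as.character(.data$bio_rep), tech_rep = 1L) |>
    select("sample_id", "activity_kbq", "time_h", "bio_rep", "tech_rep", "is_control")
  expression_study(mat, meta, study$probe_genes)
}

#' Signed fold change from log2 group values
#'
#' The expression ratio `r = 2^(mean(treated) - mean(control))`, reported on
#' the signed convention used throughout: `r` itself when `r >= 1` (up),
#' `-1/r` otherwise (down). `|FC| >= 1` always, and swapping the groups
#' flips the sign for unequal means.
#'
#' @param treated_log2,control_log2 Numeric vectors of log2 intensities.
#' @return Signed fold change (scalar).
#' @examples
#' fold_change(c(3, 3), c(1, 1)) # +4
#' fold_change(c(1, 1), c(3, 3)) # -4
#' @export
fold_change <- function(treated_log2, control_log2) {
  if (!length(treated_log2) || !length(control_log2)) {
    stop_atdose("fold_change(): both groups must be non-empty")
  }
  signed_fc(mean(treated_log2) - mean(control_log2))
}

# signed FC from a log2 difference (vectorised)
signed_fc <- function(dlog2) {
  r <- 2^dlog2
  ifelse(r >= 1, r, -1 / r)
}

# |FC| on the signed convention
abs_fc <- function(fc) abs(fc)

#' Welch two-sample test on one probe
#'
#' Two-sided Welch t-test p-value on log2 values; the per-probe test behind
#' [call_de()]. Probes with fewer than 2 values in either group have no
#' finite statistic and are excluded upstream with a warning.
#'
#' @param treated_log2,control_log2 Numeric vectors (each length >= 2).
#' @return Two-sided p-value.
#' @export
probe_test <- function(treated_log2, control_log2) {
  if (length(treated_log2) < 2 || length(control_log2) < 2) {
    stop_atdose("probe_test(): need >= 2 values per group for a finite statistic")
  }
  welch_rows(matrix(treated_log2, nrow = 1), matrix(control_log2, nrow = 1))$p
}

# vectorised row-wise Welch t-test; identical groups get p = 1
welch_rows <- function(mt, mc) {
  n1 <- ncol(mt); n2 <- ncol(mc)
  m1 <- rowMeans(mt); m2 <- rowMeans(mc)
  v1 <- rowSums((mt - m1)^2) / (n1 - 1)
  v2 <- rowSums((mc - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate variance: equal groups are null (t = 0), unequal are extreme
  zero_se <- se2 == 0
  p[zero_se & m1 == m2] <- 1
  p[zero_se & m1 != m2] <- 0
  list(t = tstat, df = df, p = p, dlog2 = m1 - m2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate: sort
#' ascending, multiply by m/rank, enforce monotonicity from the largest rank
#' down, cap at 1, and return in input order (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @examples
#' benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041))
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_atdose("benjamini_hochberg(): p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
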