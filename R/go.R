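#' One-sided over-representation p-value
#'
#' Hypergeometric upper tail: the probability of drawing at least `overlap`
#' term-annotated genes when `draw_size` genes are sampled without
#' replacement from a universe of `universe_size` genes of which `term_size`
#' carry the term (via [stats::phyper()]).
#'
#' @param overlap Significant genes annotated to the term.
#' @param term_size Universe genes annotated to the term.
#' @param draw_size Number of significant genes.
#' @param universe_size Universe size.
#' @return Upper-tail p-value; vectorised.
#' @export
overrep_p <- function(overlap, term_size, draw_size, universe_size) {
  phyper(overlap - 1, term_size, universe_size - term_size, draw_size,
         lower.tail = FALSE)
}

#' GO term over-representation in a significant gene set
#'
#' Tests each annotated term for over-representation of the significant
#' genes within the universe (the filtered probe set of the differential
#' expression stage) with a one-sided hypergeometric test. Terms with
#' p below `alpha` (default 0.05, uncorrected) are the enriched set; per
#' term the result carries `scored` (significant genes annotated) and
#' `filtered` (universe genes annotated).
#'
#' @param significant Character vector of significant genes (subset of
#'   `universe`; members outside the universe are dropped with a warning).
#' @param universe Character vector, the analysis-eligible genes.
#' @param annotation Tibble `gene`, `go_id` (one row per association).
#' @param alpha Retention cutoff on the enrichment p (default 0.05).
#' @param keep_all Keep non-enriched terms too (flagged)? Default FALSE.
#' @return Tibble `go_id`, `scored`, `filtered`, `p_value`, `enriched`,
#'   sorted by `p_value`.
#' @export
enrich_go <- function(significant, universe, annotation, alpha = 0.05,
                      keep_all = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop_atdose("enrich_go(): empty universe")
  significant <- unique(significant)
  outside <- setdiff(significant, universe)
  if (length(outside)) {
    warn(sprintf("enrich_go(): %d significant gene(s) outside the universe dropped",
                 length(outside)))
    significant <- intersect(significant, universe)
  }
  ann <- annotation |>
    filter(.data$gene %in% universe) |>
    distinct(.data$gene, .data$go_id)
  n_draw <- length(significant)
  n_univ <- length(universe)
  res <- ann |>
    group_by(.data$go_id) |>
    summarise(
      scored = sum(.data$gene %in% significant),
      filtered = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      p_value = overrep_p(.data$scored, .data$filtered, n_draw, n_univ),
      enriched = .data$p_value < alpha
    ) |>
    arrange(.data$p_value)
  if (!keep_all) res <- filter(res, .data$enriched)
  res
}

#' Bin a response intensity percentage
#'
#' Maps the scored-vs-filtered percentage onto the five-level intensity
#' scale: `[0,3)` very_low, `[3,10)` low, `[10,30)` medium, `[30,50)` high,
#' `[50,100]` very_high. The half-open interiors make the scale total while
#' honouring the anchor points (<3% very low, >=50% very high) exactly.
#'
#' @param intensity Percentages in [0, 100].
#' @return Ordered factor with levels none < very_low < low < medium <
#'   high < very_high (`none` is used for subcategories without enriched
#'   terms and never produced here).
#' @examples
#' bin_intensity(c(2.9, 9.5, 50))
#' @export
bin_intensity <- function(intensity) {
  if (any(!is.finite(intensity)) || any(intensity < 0) || any(intensity > 100)) {
    stop_atdose("bin_intensity(): intensity must lie in [0, 100]")
  }
  cut(intensity,
      breaks = c(0, 3, 10, 30, 50, 100),
      labels = c("very_low", "low", "medium", "high", "very_high"),
      right = FALSE, include.lowest = TRUE) |>
    factor(levels = intensity_levels(), ordered = TRUE)
}

intensity_levels <- function() {
  c("none", "very_low", "low", "medium", "high", "very_high")
}

#' Ordinal encoding of intensity bins
#' @param bin Factor/character of bin labels.
#' @return Integer 0 (none) .. 5 (very_high).
#' @export
bin_ordinal <- function(bin) {
  match(as.character(bin), intensity_levels()) - 1L
}

#' Cellular-function response profile from enriched terms
#'
#' Pools enriched terms within each (category, subcategory) of the category
#' map: intensity = 100 * sum(scored) / sum(filtered) over the
#' subcategory's enriched terms (count-pooled, not per-term averaged), then
#' binned on the five-level scale. Subcategories of the map without any
#' enriched term get bin `none` (intensity NA). Terms annotated to several
#' subcategories count in each (warning); enriched terms absent from the
#' map are logged as uncategorized (warning) and dropped.
#'
#' @param enrichment Tibble from [enrich_go()] (enriched terms).
#' @param catmap Tibble `go_id`, `category`, `subcategory`.
#' @return Tibble `category`, `subcategory`, `n_terms`, `scored`,
#'   `filtered`, `intensity`, `bin` — one row per subcategory of the map.
#' @export
category_profile <- function(enrichment, catmap) {
  catmap <- distinct(as_tibble(catmap), .data$go_id, .data$category, .data$subcategory)
  enr <- as_tibble(enrichment)
  if ("enriched" %in% names(enr)) enr <- filter(enr, .data$enriched)
  uncat <- setdiff(enr$go_id, catmap$go_id)
  if (length(uncat)) {
    warn(sprintf("category_profile(): %d enriched term(s) uncategorized: %s",
                 length(uncat), toString(head(uncat, 5))))
  }
  multi <- catmap |>
    filter(.data$go_id %in% enr$go_id) |>
    dplyr::count(.data$go_id) |>
    filter(.data$n > 1)
  if (nrow(multi)) {
    warn(sprintf("category_profile(): %d term(s) map to multiple subcategories; counted in each",
                 nrow(multi)))
  }
  scheme <- distinct(catmap, .data$category, .data$subcategory)
  hits <- enr |>
    inner_join(catmap, by = "go_id") |>
    group_by(.data$category, .data$subcategory) |>
    summarise(
      n_terms = dplyr::n(),
      scored = sum(.data$scored),
      filtered = sum(.data$filtered),
      .groups = "drop"
    )
  out <- scheme |>
    left_join(hits, by = c("category", "subcategory")) |>
    mutate(
      n_terms = dplyr::coalesce(.data$n_terms, 0L),
      intensity = ifelse(.data$n_terms > 0, 100 * .data$scored / .data$filtered, NA_real_),
      bin = factor(ifelse(.data$n_terms > 0,
                          as.character(bin_intensity(dplyr::coalesce(.data$intensity, 0))),
                          "none"),
                   levels = intensity_levels(), ordered = TRUE)
    ) |>
    arrange(.data$category, .data$subcategory)
  out
}

#' Profile matrix across conditions
#'
#' Combines per-condition profiles into long and wide (subcategory x
#' condition) views with bins as labels and as ordinals 0-5.
#'
#' @param profiles Named list of [category_profile()] tibbles, keyed by
#'   condition label.
#' @return List with `long` (condition, category, subcategory, intensity,
#'   bin, ordinal), `bins` (wide, bin labels) and `ordinal` (wide, 0-5).
#' @export
profile_matrix <- function(profiles) {
  if (!length(profiles)) stop_atdose("profile_matrix(): need >= 1 condition")
  long <- purrr::imap_dfr(profiles, function(p, cond) {
    mutate(p, condition = cond, .before = 1)
  }) |>
    mutate(ordinal = bin_ordinal(.data$bin))
  bins <- long |>
    mutate(bin = as.character(.data$bin)) |>
    select("category", "subcategory", "condition", "bin") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "bin")
  ordinal <- long |>
    select("category", "subcategory", "condition", "ordinal") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "ordinal")
  list(long = long, bins = bins, ordinal = ordinal)
}
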