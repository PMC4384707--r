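#' Simulation design for the synthetic study
#'
#' Captures every parameter of the synthetic-data generator in one object.
#' The defaults emulate the underlying study design: five organs with
#' organ-specific uptake/clearance kinetics for a 7.214 h half-life
#' alpha emitter; a 5,000-probe log2 expression matrix over six groups
#' (control; 1.7 kBq at 1 h, 6 h and 7 d with 3 animals each; 105 kBq at
#' 1 h and 7.5 kBq at 6 h with 2 animals each) with technical triplicates;
#' planted differential expression (50 up / 30 down per condition at
#' |FC| 4); planted biomarker genes realizing direct, inverse and mixed
#' dose-rate patterns plus one near-tie gene; and planted GO-term
#' enrichment. Gaussian noise acts on the log2 scale per array
#' (sd 0.25 measurement + 0.1 technical); no animal-level random effect is
#' simulated.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param organs Tibble `organ`, `uptake_fraction`, `k_uptake`, `k_clear`
#'   (1/h), `mass_kg`.
#' @param half_life_h Physical half-life (hours).
#' @param injected_bq Reference injected activity in Bq (1.7 kBq).
#' @param curve_times_h Sampling grid of the biodistribution curves (the
#'   emulated literature data covers 0-24 h).
#' @param n_probes Number of probes.
#' @param n_up,n_down Planted up/down probes per condition.
#' @param planted_fc Planted |FC| of per-condition DE probes.
#' @param sd,sd_tech Log2 noise: per-array measurement sd and additional
#'   technical sd.
#' @param n_bio_ref,n_bio_elev,n_tech Biological replicates in the
#'   reference/control and elevated arms; technical replicates per animal.
#' @param grid An [exposure_grid()].
#' @param biomarkers Tibble of planted all-condition genes: `gene`,
#'   `pattern` (direct/inverse/mixed or NA for the near-tie gene),
#'   `direction` (1/-1), `n_probes` (probe variants), `near_tie` flag and
#'   planted |FC| columns `ref_1h`, `ref_6h`, `ref_7d`, `elev_1h`,
#'   `elev_6h`; NULL uses the bundled default set (5 direct, 5 inverse,
#'   5 mixed, 1 near-tie; one direct gene carries two probe variants).
#' @param n_terms Background GO terms.
#' @param term_size Genes annotated per term.
#' @param n_planted_terms Planted enriched terms (each in its own
#'   subcategory).
#' @param planted_overlap Planted-term members drawn from the planted DE
#'   genes of the reference 1 h condition.
#' @param enrichment_odds Sampling odds of significant genes for planted
#'   terms (1 = null).
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(
    seed = 1,
    organs = default_sim_organs(),
    half_life_h = 7.214,
    injected_bq = 1700,
    curve_times_h = seq(0, 24, by = 0.5),
    n_probes = 5000,
    n_up = 50, n_down = 30, planted_fc = 4,
    sd = 0.25, sd_tech = 0.1,
    n_bio_ref = 3, n_bio_elev = 2, n_tech = 3,
    grid = exposure_grid(),
    biomarkers = NULL,
    n_terms = 60, term_size = 40,
    n_planted_terms = 3, planted_overlap = 12, enrichment_odds = 50) {
  if (any(organs$k_uptake < 0) || any(organs$k_clear < 0)) {
    stop_atdose("simulation_design(): rates must be >= 0")
  }
  if (planted_fc < 1) stop_atdose("simulation_design(): planted |FC| must be >= 1")
  if (is.null(biomarkers)) biomarkers <- default_sim_biomarkers()
  n_cond <- nrow(grid$reference) + nrow(grid$elevated)
  need <- n_cond * (n_up + n_down) + sum(biomarkers$n_probes)
  if (n_probes < need) {
    stop_atdose("simulation_design(): n_probes too small for planted layout (need > %d)", need)
  }
  structure(
    list(
      seed = as.integer(seed), organs = as_tibble(organs),
      half_life_h = half_life_h, injected_bq = injected_bq,
      curve_times_h = curve_times_h,
      n_probes = n_probes, n_up = n_up, n_down = n_down,
      planted_fc = planted_fc, sd = sd, sd_tech = sd_tech,
      n_bio_ref = n_bio_ref, n_bio_elev = n_bio_elev, n_tech = n_tech,
      grid = grid, biomarkers = as_tibble(biomarkers),
      n_terms = n_terms, term_size = term_size,
      n_planted_terms = n_planted_terms, planted_overlap = planted_overlap,
      enrichment_odds = enrichment_odds
    ),
    class = "simulation_design"
  )
}

#' Default organ kinetics of the synthetic biodistribution
#'
#' Synthetic whole-organ uptake fractions, first-order uptake and
#' biological clearance rates, and organ masses for five mouse tissues —
#' plausible magnitudes for a free radiohalogen, not literature values.
#'
#' @return Tibble `organ`, `uptake_fraction`, `k_uptake`, `k_clear`,
#'   `mass_kg`.
#' @export
default_sim_organs <- function() {
  tibble(
    organ = c("kidney_cortex", "kidney_medulla", "liver", "lungs", "spleen"),
    uptake_fraction = c(0.010, 0.004, 0.050, 0.020, 0.005),
    k_uptake = c(3, 3, 4, 5, 3),
    k_clear = c(0.05, 0.05, 0.04, 0.02, 0.03),
    mass_kg = c(2.0e-4, 1.0e-4, 1.3e-3, 1.5e-4, 1.0e-4)
  )
}

#' Default planted biomarker genes
#'
#' Fifteen clear-gap genes (five per pattern) plus one near-tie gene whose
#' elevated-vs-reference intensity gap at 1 h is 2% — below the 3% tie
#' rule. Planted |FC| stay at or above 4 in the two-animal arms so the
#' genes remain reliably callable there; gaps between reference and
#' elevated intensity are 50% of the smaller member, several times the
#' fold-change sampling jitter at the default noise level. The near-tie
#' gene's pattern is recorded as NA in the truth: at full noise its 2%
#' planted gap does not identify a stable pattern class. One direct gene
#' has two probe variants.
#'
#' @return Tibble as required by [simulation_design()].
#' @export
default_sim_biomarkers <- function() {
  direct <- tibble(
    gene = sprintf("bmk_dir%02d", 1:5), pattern = "direct",
    direction = c(1, 1, 1, -1, -1), n_probes = c(2L, 1L, 1L, 1L, 1L),
    near_tie = FALSE,
    ref_1h = c(4.0, 4.2, 4.4, 4.6, 4.8),
    ref_6h = c(4.2, 4.4, 4.6, 4.8, 5.0),
    ref_7d = c(3.0, 3.1, 3.2, 3.3, 3.4),
    elev_1h = c(6.0, 6.3, 6.6, 6.9, 7.2),
    elev_6h = c(6.3, 6.6, 6.9, 7.2, 7.5)
  )
  inverse <- tibble(
    gene = sprintf("bmk_inv%02d", 1:5), pattern = "inverse",
    direction = c(1, 1, -1, -1, 1), n_probes = 1L, near_tie = FALSE,
    ref_1h = c(6.0, 6.3, 6.6, 6.9, 7.2),
    ref_6h = c(6.3, 6.6, 6.9, 7.2, 7.5),
    ref_7d = c(3.0, 3.1, 3.2, 3.3, 3.4),
    elev_1h = c(4.0, 4.2, 4.4, 4.6, 4.8),
    elev_6h = c(4.2, 4.4, 4.6, 4.8, 5.0)
  )
  mixed <- tibble(
    gene = sprintf("bmk_mix%02d", 1:5), pattern = "mixed",
    direction = c(1, -1, 1, 1, -1), n_probes = 1L, near_tie = FALSE,
    ref_1h = c(4.0, 4.2, 4.4, 4.6, 4.8),
    ref_6h = c(6.3, 6.6, 6.9, 7.2, 7.5),
    ref_7d = c(3.0, 3.1, 3.2, 3.3, 3.4),
    elev_1h = c(6.0, 6.3, 6.6, 6.9, 7.2),
    elev_6h = c(4.2, 4.4, 4.6, 4.8, 5.0)
  )
  tie <- tibble(
    gene = "bmk_tie01", pattern = NA_character_, direction = 1, n_probes = 1L,
    near_tie = TRUE,
    ref_1h = 4.00, ref_6h = 4.20, ref_7d = 3.0, elev_1h = 4.08, elev_6h = 6.3
  )
  bind_rows(direct, inverse, mixed, tie)
}

#' Generate synthetic time-activity curves
#'
#' Per organ, the physical activity follows a double-exponential
#' uptake/clearance form damped by physical decay:
#' `A(t) = A0 * f * (exp(-k_clear t) - exp(-k_uptake t)) * exp(-lambda t)`,
#' with the `k_uptake == k_clear` degenerate case handled by its
#' `k t exp(-k t)` limit. Deterministic given the design.
#'
#' @param design A [simulation_design()].
#' @return A `tac` table over `design$curve_times_h`.
#' @export
simulate_curves <- function(design) {
  lambda <- log(2) / design$half_life_h
  purrr::pmap_dfr(design$organs, function(organ, uptake_fraction, k_uptake, k_clear, ...) {
    t <- design$curve_times_h
    shape <- if (isTRUE(all.equal(k_uptake, k_clear))) {
      k_uptake * t * exp(-k_uptake * t)
    } else if (is.infinite(k_uptake)) {
      exp(-k_clear * t) * (t > 0 | k_clear == 0)
    } else {
      exp(-k_clear * t) - exp(-k_uptake * t)
    }
    tibble(
      organ = organ, time_h = t,
      activity_bq = design$injected_bq * uptake_fraction * shape * exp(-lambda * t),
      decay_corrected = FALSE
    )
  }) |>
    as_tac()
}

# per-condition planted truth layout: which probes carry which log2 effect
plan_truth <- function(design) {
  conds <- study_conditions_from_grid(design$grid)
  n_cond <- nrow(conds)
  bm <- design$biomarkers
  bm_probes <- tibble(gene = character(), probe = character())
  if (nrow(bm)) {
    bm_probes <- purrr::pmap_dfr(bm, function(gene, n_probes, ...) {
      tibble(gene = gene, probe = sprintf("%s_p%d", gene, seq_len(n_probes)))
    })
  }
  n_bulk <- design$n_probes - nrow(bm_probes)
  need <- n_cond * (design$n_up + design$n_down)
  if (n_bulk < need) stop_atdose("simulation_design(): n_probes too small for planted layout")
  bulk <- tibble(
    probe = sprintf("p%05d", seq_len(n_bulk)),
    gene = sprintf("g%05d", seq_len(n_bulk))
  )
  # disjoint planted blocks per condition so only biomarkers survive the
  # all-condition intersection
  per_cond <- purrr::map_dfr(seq_len(n_cond), function(i) {
    off <- (i - 1) * (design$n_up + design$n_down)
    idx_up <- off + seq_len(design$n_up)
    idx_dn <- off + design$n_up + seq_len(design$n_down)
    bind_rows(
      tibble(probe = bulk$probe[idx_up], condition = conds$condition[i],
             true_fc = design$planted_fc, status = "up"),
      tibble(probe = bulk$probe[idx_dn], condition = conds$condition[i],
             true_fc = -design$planted_fc, status = "down")
    )
  })
  bm_cols <- c(ref_1h = NA, ref_6h = NA, ref_7d = NA, elev_1h = NA, elev_6h = NA)
  cond_of <- c(
    ref_1h = condition_label(design$grid$reference$activity_kbq[1], 1),
    ref_6h = condition_label(design$grid$reference$activity_kbq[1], 6),
    ref_7d = condition_label(design$grid$reference$activity_kbq[1], 168),
    elev_1h = condition_label(design$grid$elevated$activity_kbq[1], design$grid$elevated$time_h[1]),
    elev_6h = condition_label(design$grid$elevated$activity_kbq[2], design$grid$elevated$time_h[2])
  )
  bm_truth <- tibble(probe = character(), condition = character(),
                     true_fc = numeric(), status = character())
  if (nrow(bm)) {
    bm_truth <- purrr::pmap_dfr(bm, function(gene, direction, ...) {
      vals <- list(...)
      purrr::imap_dfr(cond_of, function(cond, col) {
        tibble(gene = gene, condition = cond,
               true_fc = direction * vals[[col]],
               status = if (direction > 0) "up" else "down")
      })
    }) |>
      inner_join(bm_probes, by = "gene", relationship = "many-to-many") |>
      select("probe", "condition", "true_fc", "status")
  }
  list(
    probes = bind_rows(bulk, bm_probes[, c("probe", "gene")]),
    probe_genes = bind_rows(bulk, bm_probes[, c("probe", "gene")]),
    effects = bind_rows(per_cond, bm_truth),
    biomarkers = bm,
    conditions = conds
  )
}

study_conditions_from_grid <- function(grid) {
  bind_rows(grid$reference, grid$elevated) |>
    mutate(condition = condition_label(.data$activity_kbq, .data$time_h))
}

#' Generate a synthetic expression study with ground truth
#'
#' Builds the log2 matrix column by column: per-probe baselines (uniform
#' 6-12; planted probes 8-12 so the detection floor never removes signal),
#' plus the planted log2 effect of the column's condition, plus per-array
#' Gaussian measurement noise (`sd`) and technical jitter (`sd_tech`).
#' Biomarker genes receive fold-change trajectories realizing their
#' planted pattern labels on the exposure grid. Deterministic given
#' `design$seed`.
#'
#' @param design A [simulation_design()].
#' @return List: `study` (an [expression_study()]) and `truth` (list with
#'   per-probe `effects`, `biomarkers`, `conditions`, `seed`).
#' @export
simulate_expression <- function(design) {
  layout <- plan_truth(design)
  withr::with_seed(design$seed, {
    probes <- layout$probes$probe
    n <- length(probes)
    planted <- unique(layout$effects$probe)
    bm_probes <- probes[startsWith(probes, "bmk_")]
    baseline <- runif(n, 6, 12)
    # planted probes start above the detection floor; all-condition
    # (biomarker) down-regulation pulls a probe's study-wide mean down by up
    # to ~2 log2 units, so those probes start higher still
    baseline[probes %in% planted] <- runif(sum(probes %in% planted), 8, 12)
    baseline[probes %in% bm_probes] <- runif(length(bm_probes), 10, 12)

    arms <- bind_rows(
      tibble(condition = "control", activity_kbq = 0, time_h = 24,
             is_control = TRUE, n_bio = design$n_bio_ref),
      layout$conditions |>
        mutate(is_control = FALSE,
               n_bio = ifelse(.data$activity_kbq ==
                                design$grid$reference$activity_kbq[1],
                              design$n_bio_ref, design$n_bio_elev)) |>
        select("condition", "activity_kbq", "time_h", "is_control", "n_bio")
    )
    samples <- purrr::pmap_dfr(arms, function(condition, activity_kbq, time_h, is_control, n_bio) {
      tidyr::expand_grid(b = seq_len(n_bio), k = seq_len(design$n_tech)) |>
        mutate(
          sample_id = sprintf("%s_b%d_t%d", condition, .data$b, .data$k),
          activity_kbq = activity_kbq, time_h = time_h,
          bio_rep = sprintf("%s_b%d", condition, .data$b),
          tech_rep = .data$k, is_control = is_control
        ) |>
        select("sample_id", "activity_kbq", "time_h", "bio_rep", "tech_rep", "is_control")
    })

    eff <- layout$effects |> mutate(dlog2 = sign(.data$true_fc) * log2(abs(.data$true_fc)))
    eff_by_cond <- split(eff, eff$condition)
    cond_lab <- ifelse(samples$is_control, "control",
                       condition_label(samples$activity_kbq, samples$time_h))
    mat <- matrix(0, nrow = n, ncol = nrow(samples),
                  dimnames = list(probes, samples$sample_id))
    for (j in seq_len(ncol(mat))) {
      mu <- baseline
      ec <- eff_by_cond[[cond_lab[j]]]
      if (!is.null(ec)) {
        mu[match(ec$probe, probes)] <- mu[match(ec$probe, probes)] + ec$dlog2
      }
      mat[, j] <- mu + rnorm(n, 0, design$sd) + rnorm(n, 0, design$sd_tech)
    }
    study <- expression_study(mat, samples, layout$probe_genes)
    list(
      study = study,
      truth = list(effects = layout$effects, biomarkers = layout$biomarkers,
                   conditions = layout$conditions,
                   probe_genes = layout$probe_genes, seed = design$seed)
    )
  })
}

#' Default cellular-function category scheme
#'
#' Two-level scheme (category, subcategory) mirroring the cellular-function
#' grouping used for the response profiles. Loaded from the bundled
#' editable TSV.
#'
#' @return Tibble `category`, `subcategory`.
#' @export
default_category_scheme <- function() {
  readr::read_tsv(
    system.file("extdata", "category_scheme.tsv", package = "atdose"),
    show_col_types = FALSE
  )
}

#' Generate a synthetic GO annotation and category map
#'
#' Background terms annotate genes uniformly at random; planted enriched
#' terms draw `planted_overlap` of their members from the planted
#' up/down genes of the reference 1 h condition with sampling odds
#' `enrichment_odds` (odds 1 reduces to the uniform null). Every term gets
#' one (category, subcategory) from the default scheme; planted terms
#' occupy distinct subcategories. Deterministic given `design$seed`
#' (offset substream).
#'
#' @param design A [simulation_design()].
#' @param truth Truth list from [simulate_expression()].
#' @return List: `annotation` (`gene`, `go_id`), `catmap` (`go_id`,
#'   `category`, `subcategory`), `planted_terms` (tibble `go_id`,
#'   `subcategory`).
#' @export
simulate_annotation <- function(design, truth) {
  layout_genes <- unique(truth$probe_genes$gene)
  ref1_cond <- condition_label(design$grid$reference$activity_kbq[1], 1)
  de_probes <- truth$effects |> filter(.data$condition == ref1_cond) |> pull("probe")
  de_genes <- unique(truth$probe_genes$gene[truth$probe_genes$probe %in% de_probes])
  withr::with_seed(design$seed + 104729L, {
    scheme <- default_category_scheme()
    n_all <- design$n_terms + design$n_planted_terms
    term_ids <- sprintf("GO:%07d", seq_len(n_all))
    planted_ids <- utils::tail(term_ids, design$n_planted_terms)
    sub_idx <- sample(nrow(scheme), design$n_planted_terms, replace = TRUE)
    idx <- c(rep_len(seq_len(nrow(scheme)), design$n_terms), sub_idx)
    catmap <- dplyr::bind_cols(tibble(go_id = term_ids),
                               scheme[utils::head(idx, n_all), ])
    proto <- tibble(go_id = character(), gene = character())
    ann_bg <- bind_rows(proto, purrr::map_dfr(
      utils::head(term_ids, design$n_terms),
      function(id) tibble(go_id = id, gene = sample(layout_genes, design$term_size))
    ))
    w <- ifelse(layout_genes %in% de_genes, design$enrichment_odds, 1)
    ann_pl <- bind_rows(proto, purrr::map_dfr(
      planted_ids,
      function(id) tibble(go_id = id, gene = sample(layout_genes, design$term_size, prob = w))
    ))
    list(
      annotation = bind_rows(ann_bg, ann_pl)[, c("gene", "go_id")],
      catmap = catmap,
      planted_terms = tibble(go_id = planted_ids,
                             subcategory = scheme$subcategory[sub_idx])
    )
  })
}

#' Generate the full synthetic study
#'
#' Curves, expression matrix with ground truth, and annotation in one call.
#'
#' @param design A [simulation_design()].
#' @return List: `curves`, `study`, `truth`, `annotation`, `catmap`,
#'   `planted_terms`, `design`.
#' @export
simulate_study <- function(design = simulation_design()) {
  curves <- simulate_curves(design)
  expr <- simulate_expression(design)
  ann <- simulate_annotation(design, expr$truth)
  list(
    curves = curves, study = expr$study, truth = expr$truth,
    annotation = ann$annotation, catmap = ann$catmap,
    planted_terms = ann$planted_terms, design = design
  )
}
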