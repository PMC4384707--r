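# small simulation design for fast pipeline-level tests
small_design <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_probes = 600, n_up = 15, n_down = 10,
         n_terms = 20, term_size = 15, planted_overlap = 8),
    list(...)
  )
  do.call(simulation_design, args)
}

# construct a de_result-shaped object from a table of calls (for testing the
# screen in isolation, without noise)
fake_de_result <- function(condition, probe, gene, fold_change, significant = TRUE) {
  tbl <- tibble::tibble(
    probe = probe, gene = gene, condition = condition,
    fold_change = fold_change,
    p_raw = ifelse(significant, 1e-6, 0.5),
    p_adj = ifelse(significant, 1e-4, 0.9),
    significant = significant
  )
  structure(tbl, class = c("de_result", class(tbl)),
            condition = condition, universe = probe,
            universe_genes = unique(gene))
}

# DE-call lists with planted biomarker trajectories on the default grid;
# trajectories is a tibble: gene, (optional n_probes), fc_ref_1h, fc_ref_6h,
# fc_ref_7d, fc_elev_1h, fc_elev_6h
fake_de_list <- function(trajectories, extra_null = 5) {
  tr <- trajectories
  if (!"n_probes" %in% names(tr)) tr$n_probes <- 1L
  probes <- purrr::pmap_dfr(tr[, c("gene", "n_probes")], function(gene, n_probes) {
    tibble::tibble(gene = gene, probe = sprintf("%s_p%d", gene, seq_len(n_probes)))
  })
  conds <- list(
    "1.7kBq_1h" = "fc_ref_1h", "1.7kBq_6h" = "fc_ref_6h",
    "1.7kBq_168h" = "fc_ref_7d", "105kBq_1h" = "fc_elev_1h",
    "7.5kBq_6h" = "fc_elev_6h"
  )
  purrr::imap(conds, function(col, cond) {
    dat <- dplyr::left_join(probes, tr[, c("gene", col)], by = "gene")
    nulls <- tibble::tibble(gene = sprintf("null%02d", seq_len(extra_null)),
                            probe = sprintf("null%02d_p1", seq_len(extra_null)))
    fake_de_result(
      cond,
      probe = c(dat$probe, nulls$probe),
      gene = c(dat$gene, nulls$gene),
      fold_change = c(dat[[col]], rep(1.1, extra_null)),
      significant = c(rep(TRUE, nrow(dat)), rep(FALSE, extra_null))
    )
  })
}
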