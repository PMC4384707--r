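# combinatorial brute-force tail: P(X >= k) for the 2x2 margins
brute_tail <- function(k, K, n, N) {
  kk <- max(0, n + K - N):min(K, n)
  sum(choose(K, kk[kk >= k]) * choose(N - K, n - kk[kk >= k])) / choose(N, n)
}

test_that("over-representation p equals the combinatorial brute force", {
  # worked margins: universe 20, term 5, significant 6, overlap 4
  expect_equal(overrep_p(4, 5, 6, 20), brute_tail(4, 5, 6, 20), tolerance = 1e-12)
  # exhaustive sweep of every margin configuration, universe <= 12
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    k <- max(0, n + K - N):min(K, n)
    expect_equal(overrep_p(k, K, n, N),
                 vapply(k, brute_tail, numeric(1), K = K, n = n, N = N),
                 tolerance = 1e-10)
  }
  # monotone decreasing in overlap for fixed margins
  expect_true(all(diff(overrep_p(0:5, 5, 6, 20)) <= 0))
})

test_that("term enrichment respects the universe contract", {
  universe <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(gene = universe[1:5], go_id = "GO:1")
  res <- enrich_go(universe[c(1:4, 6, 7)], universe, ann, keep_all = TRUE)
  expect_equal(res$scored, 4)
  expect_equal(res$filtered, 5)
  expect_equal(res$p_value, brute_tail(4, 5, 6, 20), tolerance = 1e-12)
  # zero overlap cannot be over-represented
  res0 <- enrich_go(universe[6:11], universe, ann)
  expect_equal(nrow(res0), 0)
  # degenerate: significant = universe -> p = 1 everywhere
  res1 <- enrich_go(universe, universe, ann, keep_all = TRUE)
  expect_equal(res1$p_value, 1)
  expect_error(enrich_go("g01", character(), ann), "empty universe")
  expect_warning(enrich_go(c("g01", "zzz"), universe, ann, keep_all = TRUE),
                 "outside the universe")
  # gene relabeling leaves p unchanged
  relab <- setNames(sprintf("x%02d", 1:20), universe)
  res_r <- enrich_go(relab[universe[c(1:4, 6, 7)]], relab[universe],
                     dplyr::mutate(ann, gene = relab[gene]), keep_all = TRUE)
  expect_equal(res_r$p_value, res$p_value)
})

test_that("intensity binning honours the five-level boundaries exactly", {
  expect_equal(as.character(bin_intensity(c(0, 2.9))), rep("very_low", 2))
  expect_equal(as.character(bin_intensity(c(3, 9, 9.5, 9.99))), rep("low", 4))
  expect_equal(as.character(bin_intensity(c(10, 29, 29.99))), rep("medium", 3))
  expect_equal(as.character(bin_intensity(c(30, 49, 49.99))), rep("high", 3))
  expect_equal(as.character(bin_intensity(c(50, 75, 100))), rep("very_high", 3))
  expect_error(bin_intensity(-0.1), "\\[0, 100\\]")
  expect_error(bin_intensity(100.1), "\\[0, 100\\]")
  # total monotone step function on a fine grid
  grid <- seq(0, 100, by = 0.01)
  ord <- bin_ordinal(bin_intensity(grid))
  expect_true(all(!is.na(ord)))
  expect_true(all(diff(ord) >= 0))
  expect_equal(bin_ordinal(factor("none", levels = levels(bin_intensity(0)))), 0L)
})

test_that("subcategory profiles pool counts across enriched terms", {
  catmap <- tibble::tibble(
    go_id = c("GO:1", "GO:2", "GO:3"),
    category = c("metabolism", "metabolism", "stress response"),
    subcategory = c("lipid metabolism", "lipid metabolism", "immune response")
  )
  enr <- tibble::tibble(
    go_id = c("GO:1", "GO:2"), scored = c(3, 6), filtered = c(50, 50),
    p_value = 0.01, enriched = TRUE
  )
  prof <- category_profile(enr, catmap)
  lip <- prof[prof$subcategory == "lipid metabolism", ]
  expect_equal(lip$intensity, 9)               # (3+6)/(50+50) pooled
  expect_equal(as.character(lip$bin), "low")
  imm <- prof[prof$subcategory == "immune response", ]
  expect_equal(as.character(imm$bin), "none")
  expect_true(is.na(imm$intensity))
  # single-term anchors from the quoted scale
  one <- function(s, f) category_profile(
    tibble::tibble(go_id = "GO:1", scored = s, filtered = f,
                   p_value = 0.01, enriched = TRUE), catmap[1, ])
  expect_equal(as.character(one(2, 100)$bin[1]), "very_low")
  expect_equal(as.character(one(50, 100)$bin[1]), "very_high")
  # pooled intensity lies between the per-term extremes
  withr::with_seed(14, {
    for (i in 1:10) {
      sc <- sample(0:20, 4, replace = TRUE); fl <- sc + sample(5:40, 4, replace = TRUE)
      e <- tibble::tibble(go_id = paste0("GO:", 1:4), scored = sc, filtered = fl,
                          p_value = 0.01, enriched = TRUE)
      cm <- tibble::tibble(go_id = paste0("GO:", 1:4), category = "c", subcategory = "s")
      pooled <- category_profile(e, cm)$intensity[1]
      expect_gte(pooled, 100 * min(sc / fl))
      expect_lte(pooled, 100 * max(sc / fl))
    }
  })
  # uncategorized enriched terms and multi-subcategory terms are reported
  expect_warning(category_profile(
    tibble::tibble(go_id = "GO:9", scored = 1, filtered = 5, p_value = 0.01,
                   enriched = TRUE), catmap), "uncategorized")
  cm_multi <- dplyr::bind_rows(catmap, tibble::tibble(
    go_id = "GO:1", category = "stress response", subcategory = "immune response"))
  expect_warning(category_profile(enr, cm_multi), "multiple subcategories")
})

test_that("profile matrices carry labels and ordinals per condition", {
  catmap <- tibble::tibble(go_id = "GO:1", category = "c", subcategory = "s")
  enr <- tibble::tibble(go_id = "GO:1", scored = 5, filtered = 10,
                        p_value = 0.01, enriched = TRUE)
  p1 <- category_profile(enr, catmap)
  p0 <- category_profile(enr[0, ], catmap) # condition with no significant genes
  pm <- profile_matrix(list(A = p1, B = p0))
  expect_equal(dim(pm$bins), c(1, 4))
  expect_equal(pm$bins$A, "very_high")
  expect_equal(pm$bins$B, "none")
  expect_equal(pm$ordinal$A, 5L)
  expect_equal(pm$ordinal$B, 0L)
  expect_error(profile_matrix(list()), ">= 1")
})
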