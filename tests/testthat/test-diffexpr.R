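make_study <- function(mat_means, n_bio = 3, n_tech = 3, sd = 0,
                       conds = tibble::tibble(activity_kbq = 1.7, time_h = 1),
                       seed = 5) {
  # mat_means: probes x (1 control + nrow(conds)) matrix of group means
  withr::with_seed(seed, {
    groups <- dplyr::bind_rows(
      tibble::tibble(label = "control", activity_kbq = 0, time_h = 24, is_control = TRUE),
      dplyr::mutate(conds, label = condition_label(activity_kbq, time_h), is_control = FALSE)
    )
    samples <- purrr::pmap_dfr(groups, function(label, activity_kbq, time_h, is_control) {
      tidyr::expand_grid(b = seq_len(n_bio), k = seq_len(n_tech)) |>
        dplyr::mutate(sample_id = sprintf("%s_b%d_t%d", label, b, k),
                      activity_kbq = activity_kbq, time_h = time_h,
                      bio_rep = sprintf("%s_b%d", label, b), tech_rep = k,
                      is_control = is_control) |>
        dplyr::select(sample_id, activity_kbq, time_h, bio_rep, tech_rep, is_control)
    })
    mat <- vapply(seq_len(nrow(samples)), function(j) {
      g <- match(sub("_b\\d+$", "", samples$bio_rep[j]), groups$label)
      mat_means[, g] + rnorm(nrow(mat_means), 0, sd)
    }, numeric(nrow(mat_means)))
    rownames(mat) <- rownames(mat_means)
    colnames(mat) <- samples$sample_id
    expression_study(mat, samples)
  })
}

test_that("technical collapse averages arrays per animal and is idempotent", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("p1", paste0("s", 1:6)))
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:6), activity_kbq = c(0, 0, 0, 1.7, 1.7, 1.7),
    time_h = c(24, 24, 24, 1, 1, 1),
    bio_rep = rep(c("c1", "t1"), each = 3), tech_rep = rep(1:3, 2),
    is_control = rep(c(TRUE, FALSE), each = 3)
  )
  st <- expression_study(m, samples)
  cl <- collapse_technical(st)
  expect_equal(ncol(cl$matrix), 2)
  expect_equal(unname(cl$matrix["p1", "c1"]), 2) # mean of 1,2,3
  expect_equal(unname(cl$matrix["p1", "t1"]), 5)
  # identical technical columns collapse to the same column
  m2 <- m; m2[1, ] <- rep(c(7, 9), each = 3)
  cl2 <- collapse_technical(expression_study(m2, samples))
  expect_equal(unname(cl2$matrix[1, ]), c(7, 9))
  # idempotent
  expect_equal(collapse_technical(cl)$matrix, cl$matrix)
  # orphan technical replicate annotation
  s_bad <- samples; s_bad$bio_rep[4] <- NA
  expect_error(expression_study(m, s_bad), "orphan")
})

test_that("signed fold change follows the reciprocal convention", {
  expect_equal(fold_change(c(3, 3), c(1, 1)), 4)
  expect_equal(fold_change(c(1, 1), c(3, 3)), -4)
  expect_equal(fold_change(c(2, 2), c(2, 2)), 1)
  expect_error(fold_change(numeric(), 1), "non-empty")
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(3); b <- rnorm(3)
      expect_equal(fold_change(a, b), -fold_change(b, a))
      expect_gte(abs(fold_change(a, b)), 1)
    }
  })
})

test_that("per-probe Welch test matches stats::t.test and handles edge cases", {
  expect_equal(probe_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # widely separated tight groups; frozen from the textbook Welch formula:
  # t = 10 / (0.01*sqrt(2/3)), df = 4 -> p << 1e-4
  withr::with_seed(2, {
    a <- rnorm(3, 10, 0.01); b <- rnorm(3, 0, 0.01)
  })
  expect_lt(probe_test(a, b), 1e-4)
  expect_equal(probe_test(a, b), probe_test(b, a))
  expect_error(probe_test(1, c(1, 2)), ">= 2")
  # row-wise implementation agrees with stats::t.test across random probes
  withr::with_seed(31, {
    mt <- matrix(rnorm(20 * 4), 20)
    mc <- matrix(rnorm(20 * 5, 0.5), 20)
  })
  w <- atdose:::welch_rows(mt, mc)
  ref <- vapply(1:20, function(i) t.test(mt[i, ], mc[i, ])$p.value, numeric(1))
  expect_equal(w$p, ref, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up construction", {
  expect_equal(benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_equal(benjamini_hochberg(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle: sort, p*m/i, cummin from the top, restore order
  stepup <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  withr::with_seed(99, {
    for (n in c(1, 2, 7, 50, 500)) {
      p <- runif(n)^2
      got <- benjamini_hochberg(p)
      expect_equal(got, stepup(p), tolerance = 1e-12)
      expect_true(all(got >= p & got <= 1))
      expect_equal(order(got[order(p)]), seq_len(n)) # order-preserving
    }
  })
})

test_that("planted effects are recovered at the stated thresholds", {
  d <- simulation_design(seed = 21, biomarkers = default_sim_biomarkers()[0, ])
  sim <- simulate_expression(d)
  de <- call_de(sim$study, 1.7, 1)
  g <- glance(de)
  expect_true(g$n_up >= 45 && g$n_up <= 55)   # 50 planted up, within 10%
  expect_true(g$n_down >= 27 && g$n_down <= 33) # 30 planted down
  truth1 <- dplyr::filter(sim$truth$effects, condition == "1.7kBq_1h")
  called <- de$probe[de$significant]
  expect_gte(mean(truth1$probe %in% called), 0.9)
  fdr <- mean(!(called %in% truth1$probe))
  expect_lte(fdr, 0.05)
})

test_that("a null matrix yields at most a couple of false positives", {
  d <- simulation_design(seed = 22, n_up = 0, n_down = 0,
                         biomarkers = default_sim_biomarkers()[0, ])
  sim <- simulate_expression(d)
  de <- call_de(sim$study, 1.7, 1)
  expect_lte(sum(de$significant), 2)
})

test_that("up-only planted signal yields no down calls", {
  d <- simulation_design(seed = 23, n_probes = 800, n_up = 25, n_down = 0,
                         biomarkers = default_sim_biomarkers()[0, ])
  sim <- simulate_expression(d)
  g <- glance(call_de(sim$study, 1.7, 6))
  expect_equal(g$n_down, 0)
  expect_gt(g$n_up, 0)
})

test_that("significant calls are invariant under probe and column permutation", {
  d <- small_design(seed = 24)
  sim <- simulate_expression(d)
  de1 <- call_de(sim$study, 105, 1)
  withr::with_seed(1, {
    pi_r <- sample(nrow(sim$study$matrix))
    pi_c <- sample(ncol(sim$study$matrix))
  })
  st2 <- expression_study(sim$study$matrix[pi_r, pi_c],
                          sim$study$samples[match(colnames(sim$study$matrix)[pi_c],
                                                  sim$study$samples$sample_id), ],
                          sim$study$probe_genes)
  de2 <- call_de(st2, 105, 1)
  expect_setequal(de1$probe[de1$significant], de2$probe[de2$significant])
})

test_that("an absent condition names the available ones", {
  d <- small_design(seed = 25)
  sim <- simulate_expression(d)
  expect_error(call_de(sim$study, 33, 1), "available.*1.7kBq_1h")
  expect_true(attr(call_de(sim$study, 105, 1, unit = "biological"), "low_power"))
})
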