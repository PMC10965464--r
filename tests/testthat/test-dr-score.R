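make_sig <- function(m) {
  signature_pair(gene_set("POS", rownames(m)[1:12]),
                 gene_set("NEG", rownames(m)[21:32]))
}

test_that("dr_score equals the NES difference and is exactly antisymmetric", {
  m <- tiny_expr(60, 6, seed = 21)
  sig <- make_sig(m)
  dr <- compute_dr_scores(m, sig)
  expect_equal(dr$dr_score, dr$nes_positive - dr$nes_negative, tolerance = 0)
  swapped <- compute_dr_scores(m, signature_pair(sig$negative, sig$positive))
  expect_identical(swapped$dr_score, -dr$dr_score)
})

test_that("equal positive and negative enrichment gives score exactly zero", {
  # sample 1 ranks G1 > G2 > G3 > G4; with tau = 0 the set at positions
  # {1, 4} and the set at positions {2, 3} both have ES = 0 by hand:
  # A: (1/2-0) + (1/2-1/2) + (1/2-1) + (1-1) = 0; B symmetric
  m <- matrix(c(8, 6, 4, 2, 5, 50, 1, 3), nrow = 4,
              dimnames = list(paste0("G", 1:4), c("s1", "s2")))
  sig <- signature_pair(gene_set("POS", c("G1", "G4")),
                        gene_set("NEG", c("G2", "G3")))
  expect_warning(
    dr <- compute_dr_scores(expression_matrix(m, "TPM"), sig,
                            ssgsea_params(tau = 0, min_size = 2)),
    "zero raw enrichment range")  # both raw ES rows are identically zero here
  expect_identical(dr$nes_positive[1], dr$nes_negative[1])
  expect_identical(dr$dr_score[1], 0)
})

test_that("planted positive shift raises DR scores in the active group", {
  sim <- simulate_expression(sim_config(n_genes = 800, n_samples = 40, seed = 5))
  dr <- compute_dr_scores(sim$matrix)
  expect_gt(mean(dr$dr_score[sim$truth$active]),
            mean(dr$dr_score[!sim$truth$active]))
})

test_that("mean DR score increases monotonically with planted effect size", {
  means <- vapply(c(0, 0.5, 1), function(es) {
    sim <- simulate_expression(sim_config(n_genes = 800, n_samples = 40,
                                          effect_size = es, seed = 17))
    dr <- compute_dr_scores(sim$matrix)
    mean(dr$dr_score[sim$truth$active]) - mean(dr$dr_score[!sim$truth$active])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("permutation test is reproducible, bounded below, and errors on tiny matrices", {
  m <- tiny_expr(80, 4, seed = 31)
  sig <- make_sig(m)
  cfg <- permutation_config(n_reps = 50, seed = 7)
  p1 <- permutation_test(m, sig, cfg)
  p2 <- permutation_test(m, sig, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$perm_p > 0 & p1$perm_p <= 1))
  expect_true(all(p1$perm_p >= 1 / 51))

  # observed beating every null draw attains the add-one lower bound:
  # plant an extreme signal for the positive set in one sample
  x <- unclass(tiny_expr(80, 1, seed = 32))
  x[1:12, 1] <- max(x) * 1e3
  one <- permutation_test(expression_matrix(x, "TPM"), sig, cfg)
  expect_equal(one$perm_p, 1 / 51)

  small <- tiny_expr(20, 2)
  expect_error(permutation_test(small, sig, cfg), "min_size|disjoint")
})

test_that("null permutation p-values are calibrated", {
  # baseline_sd = 0 gives an iid matrix, so per-sample p-values are
  # independent and the binomial envelope applies
  sim <- simulate_expression(sim_config(n_genes = 500, n_samples = 60,
                                        effect_size = 0, frac_signature = 0.4,
                                        baseline_sd = 0, seed = 19))
  sig <- load_dr_signature()
  p <- permutation_test(sim$matrix, sig, permutation_config(n_reps = 100, seed = 3))
  frac <- mean(p$perm_p <= 0.05)
  # binomial 99% envelope around 0.05, n = 60
  expect_lt(abs(frac - 0.05), 2.576 * sqrt(0.05 * 0.95 / 60) + 1e-9)
})

test_that("median stratification splits at the median with ties going low", {
  tab <- data.frame(sample_id = letters[1:4], dr_score = c(1, 2, 3, 4))
  out <- stratify_median(tab)
  expect_equal(out$stratum, c("low", "low", "high", "high"))

  tie <- stratify_median(data.frame(dr_score = c(1, 2, 2, 4)))
  expect_equal(tie$stratum, c("low", "low", "low", "high"))

  odd <- stratify_median(data.frame(dr_score = c(1, 5, 9)))
  expect_equal(odd$stratum, c("low", "low", "high"))

  expect_error(stratify_median(data.frame(dr_score = rep(2, 5))), "degenerate")
  expect_error(stratify_median(data.frame(dr_score = 1)), ">= 2")
})

test_that("quartile stratification follows the linear-interpolation convention", {
  tab <- data.frame(dr_score = 1:8)
  out <- stratify_quartiles(tab)
  # type-7 quartiles of 1..8 are Q1 = 2.75, Q3 = 6.25
  expect_equal(out$stratum, c("low", "low", rep("medium", 4), "high", "high"))
  expect_equal(sum(out$stratum == "high") + sum(out$stratum == "medium") +
                 sum(out$stratum == "low"), 8)

  scaled <- stratify_quartiles(data.frame(dr_score = 3 * (1:8)))
  expect_equal(scaled$stratum, out$stratum)

  expect_error(stratify_quartiles(data.frame(dr_score = c(1, 2, 2, 2, 2, 9))), "degenerate")
  expect_error(stratify_quartiles(data.frame(dr_score = 1:3)), ">= 4")
})

test_that("both stratifications are invariant to adding a constant", {
  set.seed(12)
  tab <- data.frame(dr_score = rnorm(20))
  shifted <- data.frame(dr_score = tab$dr_score + 5)
  expect_equal(stratify_median(tab)$stratum, stratify_median(shifted)$stratum)
  expect_equal(stratify_quartiles(tab)$stratum, stratify_quartiles(shifted)$stratum)
})
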