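test_that("overlap test computes the exact binomial upper tail", {
  bg <- sprintf("G%02d", 1:10)
  a <- gene_list(bg[1:5])
  b <- gene_list(bg[c(1:4, 6:9)][1:4])   # 4 symbols, all within a
  res <- overlap_test(a, b, bg)
  expect_equal(res$observed, 4)
  expect_equal(res$expected, 10 * 0.5 * 0.4)
  expect_equal(res$p, binom_tail_oracle(4, 10, 0.2), tolerance = 1e-12)
  expect_equal(res$p, 0.12087, tolerance = 1e-4)

  disjoint <- overlap_test(gene_list(bg[1:3]), gene_list(bg[4:6]), bg)
  expect_equal(disjoint$observed, 0)
  expect_equal(disjoint$p, 1)

  expect_error(overlap_test(gene_list("NOTTHERE"), b, bg), "NOTTHERE")
})

test_that("overlap p is monotone in the observed count", {
  p <- vapply(0:10, function(k) {
    sdarray:::binom_upper_tail(k, 100, 0.02)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("overlap p tracks a same-size-list permutation oracle", {
  # Drawing two fixed-size lists at random from the background makes the
  # overlap hypergeometric; the binomial test models per-gene significance
  # as independent, so the two tails differ by a small deterministic model
  # gap on small backgrounds. The oracle must match the hypergeometric
  # within Monte Carlo error, and the binomial p must sit within the
  # analytic model gap of the oracle.
  set.seed(5)
  bg <- sprintf("G%02d", 1:40)
  a <- gene_list(sample(bg, 12))
  b <- gene_list(sample(bg, 9))
  res <- overlap_test(a, b, bg)

  draws <- 50000
  perm <- replicate(draws,
                    length(intersect(sample(bg, 12), sample(bg, 9))))
  emp <- mean(perm >= res$observed)
  mc_se <- sqrt(emp * (1 - emp) / draws)
  p_hyper <- phyper(res$observed - 1, 12, 40 - 12, 9, lower.tail = FALSE)
  expect_lt(abs(emp - p_hyper), 4 * mc_se)

  model_gap <- abs(res$p - p_hyper)
  expect_lt(abs(res$p - emp), 4 * mc_se + model_gap)
  expect_lt(model_gap, 0.1)
})

test_that("directional agreement counts matching signs over the overlap", {
  a <- gene_list(c("A", "B", "C"), c("up", "down", "up"))
  expect_equal(directional_agreement(a, a)$fraction, 1)

  b <- gene_list(c("A", "B", "C"), c("down", "up", "down"))
  expect_equal(directional_agreement(a, b)$fraction, 0)

  c_ <- gene_list(c("A", "B", "D"), c("up", "up", "down"))
  got <- directional_agreement(a, c_)
  expect_equal(got$n_total, 2)
  expect_equal(got$n_agree, 1)

  expect_error(directional_agreement(a, gene_list("A", "unsigned")), "signed")
})

test_that("multiway same-direction expectation follows the 2^(1-m) model", {
  bg <- sprintf("G%03d", 1:495)
  lists <- list(gene_list(bg[1:169], "up"), gene_list(bg[1:148], "up"),
                gene_list(bg[1:63], "up"))
  got <- multiway_same_direction_test(lists, bg)
  expect_equal(got$expected,
               495 * (169 / 495) * (148 / 495) * (63 / 495) / 4)
  expect_equal(got$expected, 1.61, tolerance = 0.01)
  expect_equal(got$observed, 63)

  ident <- list(gene_list(bg[1:20], "up"), gene_list(bg[1:20], "up"))
  same <- multiway_same_direction_test(ident, bg)
  expect_equal(same$observed, 20)
  expect_lt(same$p, 1e-10)

  disj <- list(gene_list(bg[1:10], "up"), gene_list(bg[11:20], "down"))
  got0 <- multiway_same_direction_test(disj, bg)
  expect_equal(got0$observed, 0)
  expect_equal(got0$p, 1)
  expect_error(multiway_same_direction_test(list(gene_list("G001", "up")), bg),
               "at least 2")
})

test_that("fixed-baseline list comparisons use the exact binomial tail", {
  expect_equal(list_comparison_test(15, 7, 0.175),
               binom_tail_oracle(7, 15, 0.175), tolerance = 1e-12)
  expect_equal(list_comparison_test(15, 0, 0.175), 1)
  expect_lt(list_comparison_test(28, 12, 0.175), 0.05)
  expect_lt(list_comparison_test(15, 7, 0.175), 0.05)
  expect_lt(list_comparison_test(141, 50, 0.175), 0.05)
  expect_error(list_comparison_test(10, 3, 1.5), "baseline_p")
})

test_that("recovered significant lists carry template-sign directions", {
  sim <- generate_study(synthetic_spec(
    n_genes = 300, effect_size = 3, cohort_offset = 0,
    frac_per_template = c(sustained = 0.2), seed = 8))
  study <- standardize_by_cohort(sim$study)
  de <- differential_expression(study)
  asg <- assign_templates(group_mean_matrix(de)[de$significant, , drop = FALSE])
  gl <- significant_gene_list(de, asg)
  expect_true(all(gl$direction %in% c("up", "down")))
  truth <- sim$truth[match(gl$symbol, sim$truth$symbol), ]
  planted <- truth$status == "planted"
  expect_gt(mean(gl$direction[planted] == truth$direction[planted]), 0.95)
})
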