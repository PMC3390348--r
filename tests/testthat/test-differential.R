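test_that("per-gene ANOVA matches the hand-decomposed F statistic", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, SSW = 6, F = 3 with df (2, 6)
  st <- toy_study(list(A = matrix(1:3, 1), B = matrix(2:4, 1),
                       C = matrix(3:5, 1)))
  de <- anova_per_gene(st)
  expect_equal(de$F, 3)
  expect_equal(de$p, pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(de$mean_A, 2)
  expect_equal(de$n_C, 3)
})

test_that("ANOVA agrees with stats::aov on masked unbalanced data", {
  set.seed(31)
  st <- toy_study(list(A = matrix(rnorm(40), 5), B = matrix(rnorm(35), 5),
                       C = matrix(rnorm(45), 5)))
  st$mask[cbind(sample(5, 8, replace = TRUE), sample(24, 8))] <- TRUE
  de <- anova_per_gene(st)
  x <- st$signal
  x[st$mask] <- NA
  for (g in 1:5) {
    keep <- !is.na(x[g, ])
    fit <- summary(aov(x[g, keep] ~ st$samples$group[keep]))[[1]]
    expect_equal(de$F[g], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(de$p[g], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("degenerate genes are flagged, equal means give F = 0", {
  st <- toy_study(list(A = rbind(c(1, 2), c(5, 5), c(1, 2)),
                       B = rbind(c(2, 1), c(5, 5), c(3, 4))))
  st$mask[3, 3] <- TRUE  # leaves group B of gene 3 with 1 value
  de <- anova_per_gene(st)
  expect_equal(de$flag, c("ok", "zero_variance", "insufficient_n"))
  expect_true(all(is.na(de$p[2:3])))
  expect_equal(de$F[1], 0)  # identical group means, nonzero within-variance
  expect_equal(de$p[1], 1)
})

test_that("BH q-values follow the step-up rule and brute-force oracle", {
  got <- bh_fdr(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(got$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(got$n_significant, 3)
  expect_equal(got$median_fdr, 0.04)

  expect_equal(bh_fdr(rep(0.5, 6))$q, rep(0.5, 6))

  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(5:60, 1))
    expect_equal(bh_fdr(p)$q, brute_force_bh(p), tolerance = 1e-12)
  }

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # q returned in input order: reversal of input reverses q
  p <- runif(20)
  expect_equal(rev(bh_fdr(rev(p))$q), bh_fdr(p)$q)
})

test_that("median FDR is undefined without significant genes", {
  got <- bh_fdr(c(0.2, 0.7, 0.9), alpha = 0.05)
  expect_equal(got$n_significant, 0)
  expect_true(is.na(got$median_fdr))
})

test_that("effect sizes are standardized mean differences", {
  st <- toy_study(list(A = rbind(c(-1, 0, 1), c(0, 1, 2)),
                       B = rbind(c(0, 1, 2), c(0, 1, 2))))
  d <- effect_size(st, "A", "B")
  expect_equal(unname(d[1]), 1)   # means 0 vs 1, pooled SD 1
  expect_equal(unname(d[2]), 0)   # identical groups

  cst <- toy_study(list(A = matrix(rep(1, 3), 1), B = matrix(rep(1, 3), 1)))
  expect_true(is.na(effect_size(cst, "A", "B")))
  expect_error(effect_size(st, "A", "Z"), "unknown group")
})

test_that("planted effect sizes are recovered without bias", {
  spec <- synthetic_spec(n_genes = 600, cohort_offset = 0,
                         frac_per_template = c(sustained = 1/3),
                         effect_size = 2, noise_sd = 1, seed = 19)
  sim <- generate_study(spec)
  d <- effect_size(sim$study, "HC", "24SD")
  planted <- sim$truth$status == "planted"
  signed <- ifelse(sim$truth$direction[planted] == "up", 1, -1)
  est <- d[planted] * signed
  # ~200 genes, per-gene SE of d ~ 0.45 -> SE of the mean ~ 0.033
  expect_equal(mean(est), 2, tolerance = 3 * 0.45 / sqrt(sum(planted)))
})

test_that("null significant fraction tracks alpha and median FDR falls with effect size", {
  st <- generate_null_matrix(2000, c(6, 6, 6), seed = 23)
  de <- differential_expression(st, alpha = 0.05)
  n_sig <- attr(de, "n_significant")
  expect_lt(abs(n_sig - 100), 3 * sqrt(2000 * 0.05 * 0.95))

  fdrs <- vapply(c(0.5, 2), function(es) {
    sim <- generate_study(synthetic_spec(
      n_genes = 500, effect_size = es, cohort_offset = 0,
      frac_per_template = c(sustained = 0.1, transient = 0.1), seed = 4))
    attr(differential_expression(sim$study), "median_fdr")
  }, numeric(1))
  expect_true(all(fdrs >= 0 & fdrs <= 1))
  expect_lt(fdrs[2], fdrs[1])
})
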