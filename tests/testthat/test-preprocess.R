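test_that("probe-set filter applies grade, symbol and presence rules", {
  # 5 genes: ok / low presence / no symbol / grade B / duplicate symbol
  st <- toy_study(list(HC = matrix(rnorm(20), 5), SD = matrix(rnorm(20), 5)),
                  symbols = c("G1", "G2", NA, "G4", "G1"),
                  grades = c("A", "A", "A", "B", "A"))
  st$present[2, ] <- c(rep(TRUE, 5), rep(FALSE, 3))   # only 5 presence calls
  st$present[5, 1] <- FALSE                            # duplicate, fewer calls
  res <- filter_probesets(st, min_present = 6)

  expect_equal(res$study$genes$symbol, "G1")
  expect_equal(res$study$genes$probe_id, "p001")
  expect_equal(res$report$n_input, 5)
  expect_equal(res$report$n_grade_pass, 4)   # grade B dropped
  expect_equal(res$report$n_symbol_pass, 2)  # NA symbol + duplicate collapsed
  expect_equal(res$report$n_presence_pass, 1 + 1 - 1)  # G2 fails presence
  expect_equal(res$study$genes$n_present, 8)

  expect_error(filter_probesets(st, min_present = 99), "exceeds")
})

test_that("probe-set filter is idempotent", {
  set.seed(3)
  st <- toy_study(list(HC = matrix(rnorm(40), 10), SD = matrix(rnorm(40), 10)),
                  symbols = c(sprintf("G%d", 1:8), "G1", NA),
                  grades = c(rep("A", 9), "B"))
  once <- filter_probesets(st, min_present = 4)$study
  twice <- filter_probesets(once, min_present = 4)
  expect_identical(twice$study$signal, once$signal)
  expect_equal(twice$report$n_input, twice$report$n_presence_pass)
})

test_that("outlier masking follows the single-pass 2-SD group rule", {
  # hand-computed: (0,0,0,10) mean 2.5 sd 5 -> 7.5 <= 10, kept;
  # (0,0,0,0,0,10) mean 1.667 sd 4.082 -> 8.33 > 8.16, masked
  st <- toy_study(list(A = matrix(c(0, 0, 0, 10), 1),
                       B = matrix(c(0, 0, 0, 0, 0, 10), 1)))
  out <- mask_outliers(st, k_sd = 2)
  expect_equal(sum(out$mask[, 1:4]), 0)
  expect_equal(unname(which(out$mask[1, ])), 10L)

  # constant group: SD 0, nothing masked
  cst <- toy_study(list(A = matrix(rep(5, 4), 1)))
  expect_equal(sum(mask_outliers(cst)$mask), 0)
})

test_that("masking perturbed fixtures touches only the perturbed cell", {
  set.seed(21)
  for (rep in 1:20) {
    vals <- rnorm(8)
    hit <- sample(8, 1)
    vals[hit] <- vals[hit] + 12
    st <- toy_study(list(A = matrix(vals, 1)))
    out <- mask_outliers(st, k_sd = 2)
    expect_lte(sum(out$mask), 1)
    if (sum(out$mask) == 1) expect_equal(unname(which(out$mask[1, ])), hit)
  }
})

test_that("cohort standardization yields mean 0 / SD 1 per (gene, cohort)", {
  set.seed(8)
  st <- toy_study(list(HC = matrix(rnorm(20, 5), 4),
                       SD = matrix(rnorm(20, 5), 4)),
                  cohort = rep(c("c1", "c2"), 5))
  st$mask[1, 2] <- TRUE
  z <- standardize_by_cohort(st)
  x <- z$signal
  x[z$mask] <- NA
  for (co in c("c1", "c2")) {
    cols <- z$samples$cohort == co
    expect_equal(unname(rowMeans(x[, cols], na.rm = TRUE)), rep(0, 4),
                 tolerance = 1e-12)
    expect_equal(unname(apply(x[, cols], 1, sd, na.rm = TRUE)), rep(1, 4),
                 tolerance = 1e-12)
  }
})

test_that("standardization removes an additive cohort offset exactly", {
  spec <- synthetic_spec(n_genes = 200, cohort_offset = -10,
                         frac_per_template = c(sustained = 0.5),
                         effect_size = 2, seed = 14)
  sim <- generate_study(spec)
  flat <- sim$study
  flat$signal[, flat$samples$cohort == "cohort2"] <-
    flat$signal[, flat$samples$cohort == "cohort2"] + 10  # undo the offset

  z_off <- standardize_by_cohort(sim$study)
  z_flat <- standardize_by_cohort(flat)
  # per-cohort centering/scaling is invariant to a per-cohort constant
  expect_equal(z_off$signal, z_flat$signal, tolerance = 1e-12)

  # group contrasts survive: planted genes keep a 24SD-vs-HC separation
  de <- anova_per_gene(z_off)
  planted_up <- sim$truth$status == "planted" & sim$truth$direction == "up"
  expect_gt(mean(de$mean_24SD[planted_up] - de$mean_HC[planted_up]), 1)
})

test_that("single-cohort standardization is a plain per-gene z-score", {
  set.seed(2)
  st <- toy_study(list(HC = matrix(rnorm(12), 2), SD = matrix(rnorm(12), 2)))
  z <- standardize_by_cohort(st)
  manual <- t(apply(st$signal, 1, function(v) (v - mean(v)) / sd(v)))
  dimnames(manual) <- dimnames(st$signal)
  expect_equal(z$signal, manual, tolerance = 1e-12)
})

test_that("zero-variance genes are flagged and masked during standardization", {
  st <- toy_study(list(HC = rbind(c(1, 1), c(2, 3)),
                       SD = rbind(c(1, 1), c(1, 5))))
  z <- standardize_by_cohort(st)
  expect_equal(attr(z, "flagged_genes"), "p001")
  expect_true(all(z$mask[1, ]))
  expect_false(any(z$mask[2, ]))
})
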