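#' Configuration for the end-to-end pipeline
#'
#' Collects every tunable of [run_pipeline()]: the synthetic-study
#' specification, significance gate, filter and outlier parameters, Monte
#' Carlo and resampling iteration counts, and the master seed from which
#' each stochastic stage's seed is derived.
#'
#' @param synthetic A [synthetic_spec()] describing the simulated study.
#' @param alpha Raw-p significance gate in (0, 1) (or 0 for a degenerate
#'   run).
#' @param min_present Presence-call filter threshold.
#' @param k_sd Outlier-masking threshold in group SD units.
#' @param templates A `template_set`.
#' @param mc_iterations Monte Carlo iterations for the template null.
#' @param resample_iterations Subsampling iterations.
#' @param resample_subset_size Arrays per subsample draw.
#' @param resample_stratified Use group-proportional subsampling.
#' @param gmt_path Optional GMT file for the enrichment stage; when `NULL`,
#'   gene sets are built from the planted ground truth (one set per
#'   template).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            alpha = 0.05,
                            min_present = 6,
                            k_sd = 2,
                            templates = default_templates(),
                            mc_iterations = 100,
                            resample_iterations = 200,
                            resample_subset_size = 21,
                            resample_stratified = FALSE,
                            gmt_path = NULL,
                            seed = 1) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

derive_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1, 3)
  list(simulate = s[1], mcnull = s[2], resample = s[3])
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: simulate, preprocess (filter, outlier masking,
#' per-cohort standardization), per-gene ANOVA + FDR, template assignment of
#' significant genes, Monte Carlo template null with binomial count tests,
#' overlap of the recovered signed gene list against the planted truth,
#' power-equalization resampling, and EASE enrichment. Per-stage tables are
#' written as TSVs under `output_dir` together with a JSON manifest of
#' seeds, parameters and headline counts. The run is a pure function of the
#' configuration: identical seeds give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for stage outputs (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed)
  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   alpha = config$alpha, stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- c(list(status = "ok"), value)
  }

  # --- simulate ---------------------------------------------------------
  spec <- config$synthetic
  spec$seed <- seeds$simulate
  sim <- tryCatch(generate_study(spec),
                  error = function(e) stop("stage simulate: ",
                                           conditionMessage(e)))
  write_expression_study(sim$study, output_dir, prefix = "synthetic")
  utils::write.table(sim$truth, file.path(output_dir, "synthetic_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  stage("simulate", list(n_genes = nrow(sim$study$signal),
                         n_samples = ncol(sim$study$signal),
                         n_planted = sum(sim$truth$status == "planted")))

  # --- preprocess -------------------------------------------------------
  prep <- tryCatch({
    filt <- filter_probesets(sim$study, min_present = config$min_present)
    masked <- mask_outliers(filt$study, k_sd = config$k_sd)
    list(study = standardize_by_cohort(masked), report = filt$report)
  }, error = function(e) stop("stage preprocess: ", conditionMessage(e)))
  rep <- prep$report
  utils::write.table(as.data.frame(unclass(rep)),
                     file.path(output_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("preprocess", list(n_input = rep$n_input,
                           n_grade_pass = rep$n_grade_pass,
                           n_symbol_pass = rep$n_symbol_pass,
                           n_presence_pass = rep$n_presence_pass,
                           n_masked_cells = sum(prep$study$mask)))
  study <- prep$study

  # --- differential expression -----------------------------------------
  de <- tryCatch(differential_expression(study, alpha = config$alpha),
                 error = function(e) stop("stage de: ", conditionMessage(e)))
  write_gene_table(de, file.path(output_dir, "de_results.tsv"))
  stage("de", list(n_tested = sum(de$flag == "ok"),
                   n_significant = attr(de, "n_significant"),
                   median_fdr = attr(de, "median_fdr")))

  # --- template assignment ---------------------------------------------
  sig <- de[de$significant, , drop = FALSE]
  asg <- tryCatch({
    if (nrow(sig) > 0) {
      assign_templates(group_mean_matrix(de)[de$significant, , drop = FALSE],
                       config$templates)
    } else {
      assign_templates(matrix(numeric(), 0, ncol(config$templates)),
                       config$templates)
    }
  }, error = function(e) stop("stage templates: ", conditionMessage(e)))
  utils::write.table(asg, file.path(output_dir, "template_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  tcounts <- table(factor(asg$template, levels = rownames(config$templates)),
                   factor(asg$direction, levels = c("up", "down")))
  stage("templates", list(n_assigned = sum(asg$flag == "ok"),
                          counts = as.list(as.data.frame(tcounts))))

  # --- Monte Carlo template null ---------------------------------------
  mc <- tryCatch(
    monte_carlo_template_null(nrow(study$signal),
                              tabulate(study$samples$group),
                              iterations = config$mc_iterations,
                              alpha = max(config$alpha, 0),
                              seed = seeds$mcnull,
                              templates = config$templates),
    error = function(e) stop("stage mcnull: ", conditionMessage(e)))
  null_tab <- data.frame(template = rep(rownames(mc$mean_count), 2),
                         direction = rep(c("up", "down"),
                                         each = nrow(mc$mean_count)),
                         mean_count = c(mc$mean_count),
                         sd_count = c(mc$sd_count))
  null_tab$observed <- mapply(function(tm, dr) tcounts[tm, dr],
                              null_tab$template, null_tab$direction)
  null_tab$p <- mapply(function(obs, mu) {
    if (mu > 0) template_count_test(obs, mu, nrow(study$signal)) else NA_real_
  }, null_tab$observed, null_tab$mean_count)
  utils::write.table(null_tab, file.path(output_dir, "template_null.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  stage("mcnull", list(iterations = mc$iterations,
                       total_mean_count = sum(mc$mean_count)))

  # --- overlap vs planted truth ----------------------------------------
  ovl <- tryCatch({
    background <- study$genes$symbol
    recovered <- significant_gene_list(de, asg)
    truth_sub <- sim$truth[sim$truth$status == "planted" &
                             sim$truth$symbol %in% background, ]
    planted <- gene_list(truth_sub$symbol, truth_sub$direction)
    res <- overlap_test(recovered, planted, background)
    agree <- if (nrow(recovered) > 0 && nrow(planted) > 0) {
      directional_agreement(recovered, planted)
    } else {
      list(n_agree = 0L, n_total = 0L, fraction = NA_real_)
    }
    list(res = res, agree = agree)
  }, error = function(e) stop("stage overlap: ", conditionMessage(e)))
  stage("overlap", list(background_n = ovl$res$background_n,
                        size_recovered = ovl$res$size_a,
                        size_planted = ovl$res$size_b,
                        observed = ovl$res$observed,
                        expected = ovl$res$expected, p = ovl$res$p,
                        direction_agreement = ovl$agree$fraction))

  # --- power-equalization resampling -----------------------------------
  rs <- tryCatch({
    counts <- subsample_significance_counts(
      study, config$resample_subset_size,
      iterations = config$resample_iterations, alpha = config$alpha,
      seed = seeds$resample, stratified = config$resample_stratified)
    fit <- tryCatch(fit_gaussian_to_histogram(counts),
                    error = function(e) NULL)
    list(counts = counts, fit = fit)
  }, error = function(e) stop("stage resample: ", conditionMessage(e)))
  utils::write.table(data.frame(iteration = seq_along(rs$counts),
                                n_significant = as.integer(rs$counts)),
                     file.path(output_dir, "resample_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("resample", list(
    iterations = config$resample_iterations,
    mean_count = mean(rs$counts),
    fit = if (is.null(rs$fit)) "degenerate histogram, fit skipped" else
      list(mu = rs$fit$mu, sigma = rs$fit$sigma,
           r_squared = rs$fit$r_squared)))

  # --- enrichment -------------------------------------------------------
  enr <- tryCatch({
    background <- study$genes$symbol
    sets <- if (!is.null(config$gmt_path)) {
      read_gene_sets(config$gmt_path)
    } else {
      truth_sets(sim$truth, background)
    }
    query <- de$symbol[de$significant]
    enrich(query, sets, background)
  }, error = function(e) stop("stage enrich: ", conditionMessage(e)))
  utils::write.table(enr, file.path(output_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  stage("enrich", list(n_sets_tested = nrow(enr),
                       top_set = if (nrow(enr) > 0) enr$set_name[1] else NA))

  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# gene sets from the planted ground truth: one set per template
truth_sets <- function(truth, background) {
  planted <- truth[truth$status == "planted" & truth$symbol %in% background, ]
  sets <- split(planted$symbol, planted$template)
  sets <- sets[lengths(sets) > 0]
  structure(sets,
            descriptions = stats::setNames(
              paste("planted", names(sets), "genes"), names(sets)),
            class = "gene_set_collection")
}
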