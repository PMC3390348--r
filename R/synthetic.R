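#' Specification for a synthetic expression study
#'
#' Describes the statistical structure of a simulated three-group,
#' two-cohort study: sample sizes, a cohort background offset, planted
#' differential genes following the four temporal templates, within-group
#' noise, and presence-call rates. The defaults emulate the design the
#' pipeline targets: 2167 filtered genes on 53 chips (HC n = 17, 24SD
#' n = 16, 72SD n = 20) split over two cohorts with a lower background in
#' cohort 2.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of samples per group, in design
#'   order.
#' @param cohort_split Fraction of each group's samples assigned to cohort 1
#'   (default 37/69, the cohort-1 share of profiled animals).
#' @param cohort_offset Additive shift applied to every cohort-2 cell,
#'   log-signal units (default -0.5: a lower background in cohort 2).
#' @param frac_per_template Named fractions of genes planted with each
#'   temporal template; remainder are null. Fractions must sum to <= 1.
#' @param effect_size Planted mean shift, in units of `noise_sd`, at template
#'   value 1.
#' @param noise_sd Within-group standard deviation.
#' @param presence_rate Probability a cell is called present.
#' @param baseline Null mean signal.
#' @param seed RNG seed (required by [generate_study()]).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2167,
                           group_sizes = c(HC = 17, "24SD" = 16, "72SD" = 20),
                           cohort_split = 37 / 69,
                           cohort_offset = -0.5,
                           frac_per_template = c(sustained = 0.05,
                                                 transient = 0.05,
                                                 delayed = 0.05,
                                                 linear = 0.05),
                           effect_size = 2,
                           noise_sd = 1,
                           presence_rate = 0.9,
                           baseline = 0,
                           seed = NULL) {
  if (any(group_sizes < 2)) stop("each group needs at least 2 samples")
  if (sum(frac_per_template) > 1 + 1e-12) {
    stop("template fractions sum to more than 1")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (cohort_split < 0 || cohort_split > 1) stop("cohort_split must be in [0,1]")
  structure(list(n_genes = n_genes, group_sizes = group_sizes,
                 cohort_split = cohort_split, cohort_offset = cohort_offset,
                 frac_per_template = frac_per_template,
                 effect_size = effect_size, noise_sd = noise_sd,
                 presence_rate = presence_rate, baseline = baseline,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic study with recorded ground truth
#'
#' Null genes are iid Normal(baseline, noise_sd) in every group. A planted
#' gene adds `direction * effect_size * noise_sd * template(group)` to its
#' group means, where `template` is one of the four temporal profiles of
#' [default_templates()]. Cohort-2 samples receive an additive
#' `cohort_offset` on all genes (the batch effect that per-cohort
#' standardization must remove). Presence calls are iid Bernoulli.
#'
#' @param spec A [synthetic_spec()]; `spec$seed` must be set.
#' @return A list with elements `study` (an `expression_study`) and `truth`
#'   (data frame: `probe_id`, `symbol`, `status`, `template`, `direction`,
#'   `effect_size`).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$seed)) stop("spec$seed must be set for reproducibility")
  set.seed(spec$seed)

  groups <- names(spec$group_sizes)
  if (is.null(groups)) groups <- paste0("g", seq_along(spec$group_sizes))
  n_samples <- sum(spec$group_sizes)
  group_of <- rep(groups, spec$group_sizes)

  # deterministic cohort assignment: first round(n * split) chips of each
  # group are cohort 1, so both cohorts contain every group
  cohort_of <- unlist(lapply(spec$group_sizes, function(n) {
    n1 <- round(n * spec$cohort_split)
    rep(c("cohort1", "cohort2"), c(n1, n - n1))
  }), use.names = FALSE)

  samples <- data.frame(
    sample_id = sprintf("chip_%02d", seq_len(n_samples)),
    group = group_of, cohort = cohort_of, stringsAsFactors = FALSE)

  probe_id <- sprintf("probe_%04d_at", seq_len(spec$n_genes))
  symbol <- sprintf("Gene%04d", seq_len(spec$n_genes))

  # planted assignment: random gene subsets per template, 50/50 up/down
  n_planted <- round(spec$frac_per_template * spec$n_genes)
  status <- rep("null", spec$n_genes)
  template <- rep(NA_character_, spec$n_genes)
  direction <- rep(NA_character_, spec$n_genes)
  pool <- sample.int(spec$n_genes)
  offset <- 0
  for (tm in names(n_planted)) {
    idx <- pool[seq_len(n_planted[[tm]]) + offset]
    offset <- offset + n_planted[[tm]]
    status[idx] <- "planted"
    template[idx] <- tm
    direction[idx] <- rep_len(c("up", "down"), length(idx))[sample.int(length(idx))]
  }

  signal <- matrix(
    stats::rnorm(spec$n_genes * n_samples, spec$baseline, spec$noise_sd),
    spec$n_genes, n_samples)

  profiles <- default_templates(length(groups))
  grp_idx <- match(group_of, groups)
  planted <- which(status == "planted")
  for (g in planted) {
    prof <- profiles[template[g], ]
    sgn <- if (direction[g] == "up") 1 else -1
    signal[g, ] <- signal[g, ] +
      sgn * spec$effect_size * spec$noise_sd * prof[grp_idx]
  }
  signal[, cohort_of == "cohort2"] <-
    signal[, cohort_of == "cohort2"] + spec$cohort_offset

  present <- matrix(
    stats::runif(spec$n_genes * n_samples) < spec$presence_rate,
    spec$n_genes, n_samples)

  genes <- data.frame(probe_id = probe_id, symbol = symbol, grade = "A",
                      stringsAsFactors = FALSE)
  rownames(signal) <- probe_id
  colnames(signal) <- samples$sample_id

  truth <- data.frame(
    probe_id = probe_id, symbol = symbol, status = status,
    template = template, direction = direction,
    effect_size = ifelse(status == "planted", spec$effect_size, 0),
    stringsAsFactors = FALSE)

  list(study = expression_study(signal, samples, genes, present = present,
                                group_levels = groups),
       truth = truth)
}

#' Generate a pure-noise study for Monte Carlo null calibration
#'
#' All signal values are iid standard normal, all cells present, single
#' cohort. This is the random-data matrix used to calibrate how many
#' significant "genes" each temporal template captures by chance.
#'
#' @param n_genes Number of genes (rows).
#' @param group_sizes Integer vector of samples per group (each >= 2).
#' @param seed RNG seed.
#' @return An `expression_study`.
#' @export
generate_null_matrix <- function(n_genes, group_sizes, seed) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (any(group_sizes < 2)) stop("each group needs at least 2 samples")
  set.seed(seed)
  groups <- names(group_sizes)
  if (is.null(groups)) groups <- paste0("g", seq_along(group_sizes))
  n_samples <- sum(group_sizes)
  signal <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  samples <- data.frame(
    sample_id = sprintf("chip_%02d", seq_len(n_samples)),
    group = rep(groups, group_sizes), cohort = "cohort1",
    stringsAsFactors = FALSE)
  expression_study(signal, samples, group_levels = groups)
}
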