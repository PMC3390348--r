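#' Pre-statistical probe-set filtering
#'
#' Retains grade-"A" probe sets that are uniquely annotated with a gene
#' symbol and have at least `min_present` presence calls across the study's
#' chips. When several probe sets map to the same symbol, one representative
#' is kept: the one with the most presence calls, ties broken by higher mean
#' signal, then by lexical probe id.
#'
#' @param study An `expression_study`.
#' @param min_present Minimum number of presence calls (default 6).
#' @return A list with `study` (the filtered study) and `report` (a
#'   `filter_report` with the gene count after each stage: `n_input`,
#'   `n_grade_pass`, `n_symbol_pass`, `n_presence_pass`).
#' @export
filter_probesets <- function(study, min_present = 6) {
  if (min_present > ncol(study$signal)) {
    stop("min_present (", min_present, ") exceeds sample count (",
         ncol(study$signal), ")")
  }
  n_input <- nrow(study$signal)

  keep <- !is.na(study$genes$grade) & study$genes$grade == "A"
  n_grade <- sum(keep)

  has_symbol <- keep & !is.na(study$genes$symbol) & nzchar(study$genes$symbol)
  n_pres <- rowSums(study$present)
  mean_sig <- rowMeans(study$signal, na.rm = TRUE)

  # collapse probe sets sharing a symbol to a single representative
  idx <- which(has_symbol)
  if (length(idx) > 0) {
    ord <- idx[order(study$genes$symbol[idx], -n_pres[idx], -mean_sig[idx],
                     study$genes$probe_id[idx])]
    rep_idx <- ord[!duplicated(study$genes$symbol[ord])]
  } else {
    rep_idx <- integer()
  }
  symbol_keep <- logical(n_input)
  symbol_keep[rep_idx] <- TRUE
  n_symbol <- sum(symbol_keep)

  final <- symbol_keep & n_pres >= min_present
  n_presence <- sum(final)

  out <- subset_study(study, which(final))
  out$genes$n_present <- n_pres[final]

  report <- structure(list(n_input = n_input, n_grade_pass = n_grade,
                           n_symbol_pass = n_symbol,
                           n_presence_pass = n_presence,
                           min_present = min_present),
                      class = "filter_report")
  list(study = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("probe-set filter: ", x$n_input, " input -> ", x$n_grade_pass,
      " grade A -> ", x$n_symbol_pass, " unique symbol -> ",
      x$n_presence_pass, " with >= ", x$min_present, " presence calls\n",
      sep = "")
  invisible(x)
}

subset_study <- function(study, gene_idx, sample_idx = NULL) {
  if (is.null(sample_idx)) sample_idx <- seq_len(ncol(study$signal))
  samples <- study$samples[sample_idx, , drop = FALSE]
  rownames(samples) <- NULL
  expression_study(study$signal[gene_idx, sample_idx, drop = FALSE],
                   samples,
                   study$genes[gene_idx, , drop = FALSE],
                   present = study$present[gene_idx, sample_idx, drop = FALSE],
                   mask = study$mask[gene_idx, sample_idx, drop = FALSE],
                   group_levels = group_levels(study))
}

#' Mask within-group outlier values
#'
#' Cells farther than `k_sd` sample standard deviations from their
#' treatment-group mean are treated as missing. Mean and SD are computed in
#' a single pass over the group's unmasked values, including the candidate
#' cell; the rule is not iterated.
#'
#' @param study An `expression_study` with groups assigned.
#' @param k_sd Threshold in group SD units (default 2).
#' @return The study with the outlier cells added to the mask.
#' @export
mask_outliers <- function(study, k_sd = 2) {
  x <- masked_signal(study)
  mask <- study$mask
  for (g in group_levels(study)) {
    cols <- which(study$samples$group == g)
    xg <- x[, cols, drop = FALSE]
    n <- rowSums(!is.na(xg))
    m <- rowMeans(xg, na.rm = TRUE)
    ss <- rowSums(xg^2, na.rm = TRUE) - n * m^2
    sd <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
    out <- abs(xg - m) > k_sd * sd
    out[is.na(out)] <- FALSE
    out[sd == 0 | n < 2, ] <- FALSE
    mask[, cols] <- mask[, cols] | out
  }
  study$mask <- mask
  study
}

#' Standardize expression within each cohort
#'
#' Per gene and per cohort, unmasked values are centered at the cohort mean
#' and scaled by the cohort sample SD, then the cohorts are recombined. This
#' retains each cohort's variability while removing any per-gene additive
#' cohort effect (e.g. a global background shift) exactly. Output is in
#' z-units.
#'
#' @param study An `expression_study` with >= 2 samples per cohort.
#' @return The standardized study. Genes with zero within-cohort SD have
#'   that cohort's cells masked and are listed in attribute
#'   `flagged_genes`.
#' @export
standardize_by_cohort <- function(study) {
  x <- masked_signal(study)
  out <- x
  flagged <- character()
  for (co in levels(study$samples$cohort)) {
    cols <- which(study$samples$cohort == co)
    if (length(cols) < 2) {
      stop("cohort '", co, "' has fewer than 2 samples")
    }
    xc <- x[, cols, drop = FALSE]
    n <- rowSums(!is.na(xc))
    m <- rowMeans(xc, na.rm = TRUE)
    ss <- rowSums(xc^2, na.rm = TRUE) - n * m^2
    sd <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
    z <- (xc - m) / sd
    bad <- sd == 0 | n < 2
    if (any(bad)) {
      z[bad, ] <- NA_real_
      flagged <- union(flagged, rownames(x)[bad])
    }
    out[, cols] <- z
  }
  study$signal <- out
  study$mask <- study$mask | is.na(out)
  attr(study, "flagged_genes") <- flagged
  validate_study(study)
  study
}
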