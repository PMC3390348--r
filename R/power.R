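#' Significant-gene counts over repeated subsampling
#'
#' Equalizes discovery power between studies of different size: repeatedly
#' draws `subset_size` arrays from the study (without replacement), reruns
#' the per-gene one-way ANOVA on the subset, and counts genes with
#' `p <= alpha`. Draws leaving any treatment group with fewer than 2 arrays
#' are rejected and redrawn. With `stratified = TRUE` the draw instead keeps
#' each group's share of arrays proportional to the full design.
#'
#' @param study An `expression_study`.
#' @param subset_size Number of arrays per draw (>= 2 per group).
#' @param iterations Number of draws (default 1000).
#' @param alpha Raw-p significance gate (default 0.05).
#' @param seed RNG seed.
#' @param stratified Use group-proportional sampling (default `FALSE`).
#' @return Integer vector of length `iterations` (class `resample_counts`),
#'   with attributes `subset_size` and `alpha`.
#' @export
subsample_significance_counts <- function(study, subset_size,
                                          iterations = 1000, alpha = 0.05,
                                          seed = 1, stratified = FALSE) {
  n_total <- ncol(study$signal)
  groups <- group_levels(study)
  if (subset_size < 2 * length(groups)) {
    stop("subset_size must be at least 2 per group (>= ",
         2 * length(groups), ")")
  }
  if (subset_size > n_total) stop("subset_size exceeds study size")
  set.seed(seed)

  grp_cols <- lapply(groups, function(g) which(study$samples$group == g))
  names(grp_cols) <- groups
  draw <- function() {
    if (stratified) {
      per_group <- round(subset_size * lengths(grp_cols) / n_total)
      # fix rounding drift while keeping >= 2 per group
      while (sum(per_group) != subset_size) {
        j <- if (sum(per_group) < subset_size) {
          which.max(lengths(grp_cols) - per_group)
        } else {
          which.max(per_group)
        }
        per_group[j] <- per_group[j] + sign(subset_size - sum(per_group))
      }
      unlist(mapply(function(cols, k) cols[sample.int(length(cols), k)],
                    grp_cols, pmax(per_group, 2), SIMPLIFY = FALSE),
             use.names = FALSE)
    } else {
      repeat {
        idx <- sample.int(n_total, subset_size)
        if (all(tabulate(study$samples$group[idx],
                         nbins = length(groups)) >= 2)) {
          return(idx)
        }
      }
    }
  }

  counts <- integer(iterations)
  for (i in seq_len(iterations)) {
    sub <- subset_study(study, seq_len(nrow(study$signal)), sort(draw()))
    de <- anova_per_gene(sub)
    counts[i] <- sum(!is.na(de$p) & de$p <= alpha)
  }
  structure(counts, subset_size = subset_size, alpha = alpha,
            class = c("resample_counts", "integer"))
}

#' Least-squares Gaussian fit to a count histogram
#'
#' Bins the subsampling counts into a frequency histogram and fits
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the (bin center, frequency)
#' pairs by Levenberg-Marquardt least squares, initialized at the sample
#' mean, SD and modal frequency. `r_squared` is `1 - SS_resid / SS_total`
#' over the bins.
#'
#' @param counts Integer vector of per-iteration significant-gene counts.
#' @param bin_width Histogram bin width in counts (default 10).
#' @return A list of class `gaussian_fit`: `mu`, `sigma`, `amplitude`,
#'   `r_squared`, and `bins` (data frame of centers and frequencies).
#' @export
fit_gaussian_to_histogram <- function(counts, bin_width = 10) {
  if (length(unique(counts)) == 1) {
    stop("degenerate histogram: all counts identical")
  }
  breaks <- seq(floor(min(counts) / bin_width) * bin_width,
                ceiling((max(counts) + 1) / bin_width) * bin_width,
                by = bin_width)
  h <- hist(counts, breaks = breaks, plot = FALSE, right = FALSE)
  bins <- data.frame(center = h$mids, freq = h$counts)
  if (sum(bins$freq > 0) < 5) {
    stop("need at least 5 non-empty bins; reduce bin_width or add iterations")
  }
  start <- list(A = max(bins$freq), mu = mean(counts), sigma = stats::sd(counts))
  fit <- minpack.lm::nlsLM(
    freq ~ A * exp(-(center - mu)^2 / (2 * sigma^2)),
    data = bins, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  resid <- bins$freq - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((bins$freq - mean(bins$freq))^2)
  structure(list(mu = unname(est["mu"]), sigma = abs(unname(est["sigma"])),
                 amplitude = unname(est["A"]), r_squared = r2, bins = bins),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: mu = %.1f, sigma = %.1f, A = %.1f, R^2 = %.3f\n",
              x$mu, x$sigma, x$amplitude, x$r_squared))
  invisible(x)
}

#' Power-equalized p-value from the fitted count distribution
#'
#' The probability, under the fitted Gaussian, that a power-equalized rerun
#' of the larger study finds no more significant genes than the comparison
#' study did: the integrated area of the fitted curve below
#' `comparison_count`, i.e. `Phi((comparison_count - mu) / sigma)`.
#'
#' @param fit A `gaussian_fit` (or any list with `mu` and `sigma`).
#' @param comparison_count Significant-gene count of the comparison study.
#' @return The lower-tail area, in \[0, 1\].
#' @export
power_equalized_p <- function(fit, comparison_count) {
  if (is.null(fit$sigma) || fit$sigma <= 0) stop("fit sigma must be > 0")
  stats::pnorm((comparison_count - fit$mu) / fit$sigma)
}
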