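#' Per-gene one-way ANOVA across treatment groups
#'
#' Classic unbalanced one-way ANOVA on the unmasked values of every gene:
#' `F = MS_between / MS_within` with (k-1, N-k) degrees of freedom, where k
#' is the number of groups and N the number of values used for that gene.
#' Fully vectorized across genes.
#'
#' Genes with fewer than 2 unmasked values in any group, or with zero total
#' variance, carry `NA` statistics and are flagged in the `flag` column
#' (`"ok"`, `"insufficient_n"`, `"zero_variance"`).
#'
#' @param study An `expression_study` with >= 2 groups.
#' @return A data frame of class `de_result`: `probe_id`, `symbol`, one
#'   `mean_<group>` and `n_<group>` column per group, `F`, `p`, `flag`.
#' @export
anova_per_gene <- function(study) {
  groups <- group_levels(study)
  k <- length(groups)
  if (k < 2) stop("ANOVA requires at least 2 groups")
  x <- masked_signal(study)

  n_g <- matrix(0L, nrow(x), k, dimnames = list(NULL, groups))
  mean_g <- matrix(NA_real_, nrow(x), k, dimnames = list(NULL, groups))
  ss_within <- numeric(nrow(x))
  for (j in seq_len(k)) {
    cols <- which(study$samples$group == groups[j])
    xg <- x[, cols, drop = FALSE]
    n <- rowSums(!is.na(xg))
    m <- rowMeans(xg, na.rm = TRUE)
    n_g[, j] <- n
    mean_g[, j] <- m
    ss_within <- ss_within +
      ifelse(n > 0, rowSums(xg^2, na.rm = TRUE) - n * m^2, 0)
  }
  N <- rowSums(n_g)
  grand <- rowSums(mean_g * n_g, na.rm = TRUE) / N
  ss_between <- rowSums(n_g * (mean_g - grand)^2, na.rm = TRUE)

  df1 <- k - 1
  df2 <- N - k
  msb <- ss_between / df1
  msw <- pmax(ss_within, 0) / df2

  flag <- rep("ok", nrow(x))
  flag[apply(n_g < 2, 1, any)] <- "insufficient_n"
  tol <- 1e-12
  zero_var <- flag == "ok" & (ss_between + ss_within) <= tol * pmax(abs(grand), 1)
  flag[zero_var] <- "zero_variance"

  F <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, NA_real_))
  p <- ifelse(is.finite(F), stats::pf(F, df1, df2, lower.tail = FALSE),
              ifelse(is.infinite(F), 0, NA_real_))
  F[flag != "ok"] <- NA_real_
  p[flag != "ok"] <- NA_real_

  out <- data.frame(probe_id = study$genes$probe_id,
                    symbol = study$genes$symbol,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("mean_", groups[j])]] <- mean_g[, j]
  for (j in seq_len(k)) out[[paste0("n_", groups[j])]] <- n_g[, j]
  out$F <- F
  out$p <- p
  out$flag <- flag
  attr(out, "df") <- c(df1 = df1, df2 = NA)
  attr(out, "groups") <- groups
  class(out) <- c("de_result", "data.frame")
  out
}

#' Extract the group-mean matrix from a differential-expression table
#'
#' Returns the per-gene treatment-group means as a genes x groups matrix,
#' the input to [assign_templates()].
#'
#' @param de A `de_result` from [anova_per_gene()] or
#'   [differential_expression()].
#' @return Numeric matrix with probe ids as row names and groups as columns.
#' @export
group_mean_matrix <- function(de) {
  groups <- attr(de, "groups")
  m <- as.matrix(de[, paste0("mean_", groups), drop = FALSE])
  colnames(m) <- groups
  rownames(m) <- de$probe_id
  m
}

#' Benjamini-Hochberg FDR with a median-FDR summary
#'
#' Step-up Benjamini-Hochberg q-values (monotone-enforced), returned in
#' input order. `NA` p-values (flagged genes) are excluded from the
#' multiplicity family and carry `NA` q. The summary `median_fdr` is the
#' median q-value among genes with `p <= alpha` - the "median FDR" reported
#' alongside a significant-gene count.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @param alpha Significance gate on raw p (default 0.05).
#' @return A list: `q` (same length/order as input), `n_significant`
#'   (count of `p <= alpha`), `median_fdr` (`NA` if nothing significant).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  sig <- ok & p_values <= alpha
  list(q = q,
       n_significant = sum(sig),
       median_fdr = if (any(sig)) stats::median(q[sig]) else NA_real_)
}

#' Per-gene standardized effect size between two groups
#'
#' `(mean_b - mean_a) / pooled within-group SD`, the difference in mean
#' expression expressed in standard deviations. Genes where either group has
#' fewer than 2 unmasked values, or the pooled SD is zero, return `NA`.
#'
#' @param study An `expression_study`.
#' @param group_a Reference group label.
#' @param group_b Comparison group label.
#' @return Named numeric vector (one value per gene).
#' @export
effect_size <- function(study, group_a, group_b) {
  groups <- group_levels(study)
  if (!all(c(group_a, group_b) %in% groups)) {
    stop("unknown group label")
  }
  x <- masked_signal(study)
  stat <- function(g) {
    xg <- x[, study$samples$group == g, drop = FALSE]
    n <- rowSums(!is.na(xg))
    m <- rowMeans(xg, na.rm = TRUE)
    ss <- rowSums(xg^2, na.rm = TRUE) - n * m^2
    list(n = n, m = m, ss = pmax(ss, 0))
  }
  a <- stat(group_a)
  b <- stat(group_b)
  pooled <- sqrt((a$ss + b$ss) / (a$n + b$n - 2))
  d <- (b$m - a$m) / pooled
  d[a$n < 2 | b$n < 2 | pooled == 0] <- NA_real_
  names(d) <- study$genes$probe_id
  d
}

#' Differential-expression table for a study
#'
#' Convenience wrapper: runs [anova_per_gene()], attaches BH q-values and a
#' significance flag at `alpha`, and per-group effect sizes against the
#' first (reference) group.
#'
#' @param study An `expression_study` (typically standardized).
#' @param alpha Raw-p significance gate (default 0.05).
#' @return The `de_result` table with extra columns `q`, `significant`, and
#'   `d_<group>` effect sizes; attributes `n_significant` and `median_fdr`.
#' @export
differential_expression <- function(study, alpha = 0.05) {
  de <- anova_per_gene(study)
  fdr <- bh_fdr(de$p, alpha = alpha)
  de$q <- fdr$q
  de$significant <- !is.na(de$p) & de$p <= alpha
  groups <- attr(de, "groups")
  for (g in groups[-1]) {
    de[[paste0("d_", g)]] <- effect_size(study, groups[1], g)
  }
  attr(de, "alpha") <- alpha
  attr(de, "n_significant") <- fdr$n_significant
  attr(de, "median_fdr") <- fdr$median_fdr
  de
}
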