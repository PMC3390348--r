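#' The four temporal expression templates
#'
#' Artificial profiles over the ordered treatment groups (control, 24 h,
#' 72 h) describing how a responsive gene may evolve: *sustained* (shifts
#' and stays), *transient* (shifts and recovers), *delayed* (shifts only at
#' the late time point), *linear* (monotone drift). Encoded as
#' `(0,1,1)`, `(0,1,0)`, `(0,0,1)` and `(0,0.5,1)`; since assignment uses
#' Pearson correlation, any affine rescaling of a profile is equivalent.
#'
#' @param n_groups Number of treatment groups; only the 3-group design is
#'   defined.
#' @return A numeric matrix of class `template_set`, one row per template.
#' @export
default_templates <- function(n_groups = 3) {
  if (n_groups != 3) {
    stop("templates are defined for the 3-group design (control, 24 h, 72 h)")
  }
  tm <- rbind(sustained = c(0, 1, 1),
              transient = c(0, 1, 0),
              delayed   = c(0, 0, 1),
              linear    = c(0, 0.5, 1))
  structure(tm, class = c("template_set", "matrix"))
}

# row-normalize after centering; rows must be non-constant
center_normalize <- function(m) {
  mc <- m - rowMeans(m)
  nrm <- sqrt(rowSums(mc^2))
  list(mat = mc / nrm, degenerate = nrm == 0)
}

#' Assign significant genes to temporal templates
#'
#' Pearson-correlates each gene's vector of treatment-group means with every
#' template profile and assigns the gene to the template with the highest
#' absolute correlation. A positive correlation is read as *increased* with
#' treatment (`"up"`), negative as *decreased* (`"down"`). Intended for
#' ANOVA-significant genes on standardized data.
#'
#' Ties in absolute correlation (measure-zero for continuous data) are
#' broken by template order as listed in `templates`. Genes with constant
#' group means cannot be correlated and are returned unassigned
#' (`NA` template, flag `"constant_means"`).
#'
#' @param group_means Numeric matrix, genes in rows, one column per ordered
#'   group (row names are gene ids).
#' @param templates A `template_set` (default [default_templates()]); must
#'   have as many columns as `group_means`.
#' @return Data frame: `id`, `template`, `r`, `direction`, `flag`.
#' @export
assign_templates <- function(group_means, templates = default_templates()) {
  group_means <- as.matrix(group_means)
  if (ncol(group_means) != ncol(templates)) {
    stop("group_means has ", ncol(group_means), " columns but templates have ",
         ncol(templates))
  }
  tn <- center_normalize(unclass(templates))
  if (any(tn$degenerate)) stop("constant template profile")
  gn <- center_normalize(group_means)

  R <- gn$mat %*% t(tn$mat)
  best <- max.col(abs(R), ties.method = "first")
  r <- R[cbind(seq_len(nrow(R)), best)]
  template <- rownames(templates)[best]
  direction <- ifelse(r > 0, "up", "down")

  bad <- gn$degenerate | !is.finite(r) | r == 0
  template[bad] <- NA_character_
  direction[bad] <- NA_character_
  r[bad] <- NA_real_

  ids <- rownames(group_means)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(group_means)))
  data.frame(id = ids, template = template, r = r, direction = direction,
             flag = ifelse(bad, "constant_means", "ok"),
             stringsAsFactors = FALSE)
}

#' Monte Carlo null for template-assignment counts
#'
#' Calibrates how many significant "genes" each (template, direction) cell
#' captures when the data are pure noise: each iteration draws a fresh
#' standard-normal matrix of the study's dimensions, runs the per-gene
#' one-way ANOVA, assigns genes with `p <= alpha` to templates by maximum
#' absolute correlation of their group means, and tallies counts per
#' template and direction.
#'
#' @param n_genes Number of genes (rows).
#' @param group_sizes Integer vector of chips per group.
#' @param iterations Number of Monte Carlo iterations (default 1000).
#' @param alpha Raw-p significance gate (default 0.05).
#' @param seed RNG seed.
#' @param templates A `template_set`.
#' @return An object of class `template_null`: list with `iterations`,
#'   `alpha`, `counts` (iterations x template x direction array),
#'   `mean_count` and `sd_count` (template x direction matrices).
#' @export
monte_carlo_template_null <- function(n_genes, group_sizes, iterations = 1000,
                                      alpha = 0.05, seed = 1,
                                      templates = default_templates()) {
  if (iterations < 1) stop("iterations must be >= 1")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, iterations)

  tnames <- rownames(templates)
  counts <- array(0L, dim = c(iterations, length(tnames), 2),
                  dimnames = list(NULL, tnames, c("up", "down")))
  for (i in seq_len(iterations)) {
    study <- generate_null_matrix(n_genes, group_sizes, seed = iter_seeds[i])
    de <- anova_per_gene(study)
    sig <- which(!is.na(de$p) & de$p <= alpha)
    if (length(sig) > 0) {
      gm <- group_mean_matrix(de)[sig, , drop = FALSE]
      asg <- assign_templates(gm, templates)
      asg <- asg[asg$flag == "ok", , drop = FALSE]
      tab <- table(factor(asg$template, levels = tnames),
                   factor(asg$direction, levels = c("up", "down")))
      counts[i, , ] <- as.integer(tab)
    }
  }
  mean_count <- apply(counts, c(2, 3), mean)
  sd_count <- apply(counts, c(2, 3), stats::sd)
  structure(list(iterations = iterations, alpha = alpha, counts = counts,
                 mean_count = mean_count, sd_count = sd_count),
            class = "template_null")
}

#' @export
print.template_null <- function(x, ...) {
  cat("Monte Carlo template null: ", x$iterations, " iterations, alpha = ",
      x$alpha, "\nmean counts per (template, direction):\n", sep = "")
  print(round(x$mean_count, 2))
  invisible(x)
}

#' Binomial test of an observed template count against its Monte Carlo null
#'
#' Upper-tail exact binomial test: with per-gene null probability
#' `null_mean / n_genes`, the p-value is `P(X >= observed)` for
#' `X ~ Binomial(n_genes, null_mean / n_genes)`.
#'
#' @param observed Observed number of genes assigned to the cell.
#' @param null_mean Monte Carlo mean count for the cell (> 0).
#' @param n_genes Number of genes tested.
#' @return The upper-tail p-value.
#' @export
template_count_test <- function(observed, null_mean, n_genes) {
  if (observed < 0) stop("observed must be >= 0")
  if (null_mean <= 0) stop("null_mean must be > 0")
  if (null_mean >= n_genes) stop("null_mean must be < n_genes")
  stats::pbinom(observed - 1, n_genes, null_mean / n_genes,
                lower.tail = FALSE)
}
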