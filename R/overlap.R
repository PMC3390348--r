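#' Cross-study overlap test on a common background
#'
#' Given two significant-gene lists drawn from a shared background of testable
#' genes, compares the observed overlap with its chance expectation
#' `N * (|A|/N) * (|B|/N)`. The default p-value is the exact upper-tail
#' binomial `P(X >= observed)` with `X ~ Binomial(N, (|A|/N)(|B|/N))`; a
#' one-sided normal approximation (with continuity correction) is available
#' as `method = "normal"`. At extreme tails the two can diverge severalfold;
#' the exact tail is the reference. When both lists are signed, directional
#' concordance over the overlap is tallied.
#'
#' @param list_a,list_b [gene_list()] objects, subsets of `background`.
#' @param background Character vector of all testable symbols.
#' @param method `"exact"` (default) or `"normal"`.
#' @return An object of class `overlap_result`: `background_n`, `size_a`,
#'   `size_b`, `observed`, `expected`, `p`, `method`, and (for signed lists)
#'   `concordant_up`, `concordant_down`, `discordant`.
#' @export
overlap_test <- function(list_a, list_b, background,
                         method = c("exact", "normal")) {
  method <- match.arg(method)
  background <- unique(as.character(background))
  for (nm in list(a = list_a, b = list_b)) {
    out <- setdiff(nm$symbol, background)
    if (length(out) > 0) {
      stop("gene list member(s) outside background: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  N <- length(background)
  size_a <- nrow(list_a)
  size_b <- nrow(list_b)
  shared <- intersect(list_a$symbol, list_b$symbol)
  observed <- length(shared)
  p_chance <- (size_a / N) * (size_b / N)
  expected <- N * p_chance
  p <- binom_upper_tail(observed, N, p_chance, method)

  res <- list(background_n = N, size_a = size_a, size_b = size_b,
              observed = observed, expected = expected, p = p,
              method = method)
  if (is_signed(list_a) && is_signed(list_b)) {
    da <- list_a$direction[match(shared, list_a$symbol)]
    db <- list_b$direction[match(shared, list_b$symbol)]
    res$concordant_up <- sum(da == "up" & db == "up")
    res$concordant_down <- sum(da == "down" & db == "down")
    res$discordant <- observed - res$concordant_up - res$concordant_down
  }
  structure(res, class = "overlap_result")
}

binom_upper_tail <- function(observed, n, prob, method = "exact") {
  if (observed == 0) return(1)
  if (method == "exact") {
    stats::pbinom(observed - 1, n, prob, lower.tail = FALSE)
  } else {
    mu <- n * prob
    sd <- sqrt(n * prob * (1 - prob))
    stats::pnorm((observed - 0.5 - mu) / sd, lower.tail = FALSE)
  }
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: ", x$observed, " of lists ", x$size_a, " & ", x$size_b,
      " on background ", x$background_n, " (expected ",
      format(x$expected, digits = 4), ")\n", sep = "")
  cat("  ", x$method, " binomial p = ", format(x$p, digits = 4), "\n",
      sep = "")
  if (!is.null(x$concordant_up)) {
    cat("  direction: ", x$concordant_up, " up + ", x$concordant_down,
        " down concordant, ", x$discordant, " discordant\n", sep = "")
  }
  invisible(x)
}

#' Directional agreement between two signed gene lists
#'
#' Over the intersection of the two lists, counts genes whose up/down calls
#' match.
#'
#' @param list_a,list_b Signed [gene_list()] objects.
#' @return A list: `n_agree`, `n_total` (overlap size), `fraction`.
#' @export
directional_agreement <- function(list_a, list_b) {
  if (!is_signed(list_a) || !is_signed(list_b)) {
    stop("both gene lists must be fully signed (up/down)")
  }
  shared <- intersect(list_a$symbol, list_b$symbol)
  da <- list_a$direction[match(shared, list_a$symbol)]
  db <- list_b$direction[match(shared, list_b$symbol)]
  n_agree <- sum(da == db)
  list(n_agree = n_agree, n_total = length(shared),
       fraction = if (length(shared) > 0) n_agree / length(shared) else NA_real_)
}

#' Multi-study same-direction overlap test
#'
#' For m signed lists on a common background, the chance expectation of
#' genes significant in *all* studies *with identical direction* is
#' `N * prod(|L_i|/N) * 2^(1-m)` under independent, equiprobable signs. The
#' p-value is the exact upper-tail binomial with per-gene success
#' probability `expected / N`.
#'
#' @param lists List of >= 2 signed [gene_list()] objects.
#' @param background Character vector of all testable symbols.
#' @return A list: `expected`, `observed`, `p`.
#' @export
multiway_same_direction_test <- function(lists, background) {
  if (length(lists) < 2) stop("need at least 2 gene lists")
  background <- unique(as.character(background))
  N <- length(background)
  for (l in lists) {
    if (!is_signed(l)) stop("all gene lists must be fully signed")
    out <- setdiff(l$symbol, background)
    if (length(out) > 0) {
      stop("gene list member(s) outside background: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  m <- length(lists)
  expected <- N * prod(vapply(lists, nrow, 1L) / N) * 2^(1 - m)

  shared <- Reduce(intersect, lapply(lists, function(l) l$symbol))
  if (length(shared) > 0) {
    dirs <- vapply(lists, function(l) l$direction[match(shared, l$symbol)],
                   character(length(shared)))
    dirs <- matrix(dirs, nrow = length(shared))
    same <- apply(dirs, 1, function(d) length(unique(d)) == 1)
    observed <- sum(same)
  } else {
    observed <- 0L
  }
  p <- binom_upper_tail(observed, N, expected / N)
  list(expected = expected, observed = observed, p = p)
}

#' List-based comparison at a fixed baseline rate
#'
#' For an external study that published only a selected gene list, tests how
#' many of its `n_selected` genes replicate (are significant with the same
#' direction) in the present study, against a fixed baseline probability
#' (e.g. significant fraction x 1/2 for direction). Exact upper-tail
#' binomial.
#'
#' @param n_selected Number of genes in the external list.
#' @param n_hits Number replicating in the present study.
#' @param baseline_p Chance probability of a replication, in (0, 1).
#' @return The upper-tail p-value.
#' @export
list_comparison_test <- function(n_selected, n_hits, baseline_p) {
  if (baseline_p <= 0 || baseline_p >= 1) stop("baseline_p must be in (0, 1)")
  if (n_hits < 0 || n_hits > n_selected) {
    stop("n_hits must be between 0 and n_selected")
  }
  binom_upper_tail(n_hits, n_selected, baseline_p)
}

#' Signed gene lists from a differential-expression + template table
#'
#' Consolidates a study's significant genes into a signed [gene_list()]:
#' direction is the sign of the best-template correlation (up for positive,
#' down for negative).
#'
#' @param de A `de_result` table with a `significant` column (from
#'   [differential_expression()]).
#' @param assignments The matching [assign_templates()] table for the
#'   significant genes.
#' @return A signed `gene_list`.
#' @export
significant_gene_list <- function(de, assignments) {
  sig <- de[de$significant, c("probe_id", "symbol")]
  m <- match(sig$probe_id, assignments$id)
  keep <- !is.na(m) & assignments$flag[m] == "ok"
  gene_list(sig$symbol[keep], assignments$direction[m[keep]])
}
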