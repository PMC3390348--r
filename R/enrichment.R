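#' EASE score (conservative one-tailed Fisher exact)
#'
#' The EASE variant of the one-tailed Fisher exact test for a 2x2
#' overrepresentation table: the overlap cell is decremented by one before
#' taking the hypergeometric upper tail, penalizing categories supported by
#' a single gene. With `X ~ Hypergeometric(N, K, n_list)`,
#' `p = P(X >= k - 1)`; overlaps of 0 or 1 score `p = 1` by construction.
#' The EASE p-value is always >= the classical Fisher p for the same table.
#'
#' @param k Overlap: query genes inside the category.
#' @param n_list Query list size.
#' @param K Category size within the background.
#' @param N Background size.
#' @return The EASE p-value in (0, 1].
#' @export
ease_score <- function(k, n_list, K, N) {
  if (K > N || n_list > N) stop("category/list larger than background")
  if (k < 0 || k > min(n_list, K)) {
    stop("overlap k must be in [0, min(n_list, K)]")
  }
  if (k <= 1) return(1)
  stats::phyper(k - 2, K, N - K, n_list, lower.tail = FALSE)
}

#' Gene-set overrepresentation with EASE scoring
#'
#' For each gene set, restricts membership to the background, counts the
#' overlap with the query list, and keeps categories whose overlap lies in
#' `[min_size, max_size]` (the bound applies to the query genes found in the
#' category). Each retained category is scored with [ease_score()]; a BH
#' q-value column is appended for convenience, though raw EASE p is the
#' headline statistic.
#'
#' @param query A [gene_list()] (or character vector) of significant
#'   symbols, a subset of `background`.
#' @param sets A `gene_set_collection` from [read_gene_sets()].
#' @param background Character vector of all testable symbols.
#' @param min_size,max_size Bounds on the query overlap per category
#'   (defaults 3 and 50).
#' @return Data frame sorted by ascending `ease_p`: `set_name`, `k`,
#'   `n_list`, `K`, `N`, `ease_p`, `q`.
#' @export
enrich <- function(query, sets, background, min_size = 3, max_size = 50) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background is empty")
  if (inherits(query, "gene_list")) query <- query$symbol
  query <- unique(as.character(query))
  out <- setdiff(query, background)
  if (length(out) > 0) {
    stop("query symbol(s) outside background: ",
         paste(utils::head(out, 5), collapse = ", "))
  }
  N <- length(background)
  n_list <- length(query)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    k <- length(intersect(members, query))
    if (k < min_size || k > max_size) return(NULL)
    data.frame(set_name = nm, k = k, n_list = n_list, K = length(members),
               N = N, ease_p = ease_score(k, n_list, length(members), N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(set_name = character(), k = integer(),
                       n_list = integer(), K = integer(), N = integer(),
                       ease_p = numeric(), q = numeric(),
                       stringsAsFactors = FALSE)
    return(rows)
  }
  rows$q <- stats::p.adjust(rows$ease_p, method = "BH")
  rows <- rows[order(rows$ease_p, rows$set_name), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
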