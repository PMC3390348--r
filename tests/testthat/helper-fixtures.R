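# Build a small study from a per-group list of value matrices.
# `groups` is a named list: group label -> genes x n_g matrix (or vector for
# a single gene). All groups share the gene axis.
toy_study <- function(groups, cohort = NULL, symbols = NULL, grades = NULL,
                      present = NULL) {
  mats <- lapply(groups, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
  })
  signal <- do.call(cbind, mats)
  n_g <- nrow(signal)
  group <- rep(names(mats), vapply(mats, ncol, 1L))
  if (is.null(cohort)) cohort <- rep("c1", ncol(signal))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(ncol(signal))),
    group = group, cohort = cohort, stringsAsFactors = FALSE)
  rownames(signal) <- sprintf("p%03d", seq_len(n_g))
  if (is.null(symbols)) symbols <- sprintf("G%03d", seq_len(n_g))
  if (is.null(grades)) grades <- rep("A", n_g)
  genes <- data.frame(probe_id = rownames(signal), symbol = symbols,
                      grade = grades, stringsAsFactors = FALSE)
  expression_study(signal, samples, genes, present = present,
                   group_levels = names(mats))
}

# brute-force BH step-up: q_i = min_{j >= i} p_(j) * m / j, in input order
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- cummin(rev(p[o] * m / seq_len(m)))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  pmin(q, 1)
}

# exact upper-tail binomial by direct summation
binom_tail_oracle <- function(k, n, prob) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, prob))
}
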