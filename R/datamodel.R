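#' Construct an expression study
#'
#' Bundles a gene-by-sample signal matrix with sample metadata (treatment
#' group, cohort), per-probe annotation, detection ("presence") calls, and a
#' missingness mask into a single validated object. All downstream stages of
#' the pipeline consume this container; no stage re-reads files.
#'
#' @param signal Numeric matrix, genes in rows, samples in columns. Row names
#'   are probe-set ids, column names are sample ids.
#' @param samples Data frame with columns `sample_id`, `group`, `cohort`,
#'   one row per column of `signal`, in column order.
#' @param genes Optional data frame with columns `probe_id`, `symbol`,
#'   `grade`, one row per row of `signal`. Defaults to grade-"A" probes whose
#'   symbol equals the probe id.
#' @param present Optional logical matrix of detection calls, same dimensions
#'   as `signal` (`TRUE` = present). Defaults to all-present.
#' @param mask Optional logical matrix, same dimensions; `TRUE` marks a cell
#'   treated as missing. Defaults to all-`FALSE`, plus any `NA` in `signal`.
#' @param group_levels Character vector giving the ordered treatment groups
#'   of the design (e.g. `c("HC", "24SD", "72SD")`). Defaults to the order of
#'   first appearance in `samples$group`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `signal`, `present`, `mask` (matrices), `samples`, `genes` (data frames).
#' @export
expression_study <- function(signal, samples, genes = NULL, present = NULL,
                             mask = NULL, group_levels = NULL) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(rownames(signal))) {
    rownames(signal) <- sprintf("probe_%04d", seq_len(nrow(signal)))
  }
  if (is.null(colnames(signal))) {
    colnames(signal) <- samples$sample_id
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "cohort")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "))
  }
  if (is.null(group_levels)) {
    group_levels <- unique(as.character(samples$group))
  }
  bad <- setdiff(unique(as.character(samples$group)), group_levels)
  if (length(bad) > 0) {
    stop("sample group(s) not in declared group levels: ",
         paste(bad, collapse = ", "))
  }
  samples$group <- factor(as.character(samples$group), levels = group_levels)
  samples$cohort <- factor(as.character(samples$cohort))

  if (is.null(genes)) {
    genes <- data.frame(probe_id = rownames(signal),
                        symbol = rownames(signal),
                        grade = "A",
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol", "grade") %in% names(genes))) {
    stop("gene annotation must have columns probe_id, symbol, grade")
  }
  if (anyDuplicated(genes$probe_id)) {
    stop("duplicate probe_id in annotation")
  }

  if (is.null(present)) {
    present <- matrix(TRUE, nrow(signal), ncol(signal))
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(signal), ncol(signal))
  }
  for (nm in c("present", "mask")) {
    m <- get(nm)
    if (!identical(dim(m), dim(signal))) {
      stop("matrix '", nm, "' does not match signal dimensions (",
           nrow(signal), " x ", ncol(signal), ")")
    }
  }
  mask <- mask | is.na(signal)
  dimnames(present) <- dimnames(mask) <- dimnames(signal)

  study <- structure(
    list(signal = signal, present = present, mask = mask,
         samples = samples, genes = genes),
    class = "expression_study")
  validate_study(study)
  study
}

validate_study <- function(study) {
  d <- dim(study$signal)
  for (nm in c("present", "mask")) {
    if (!identical(dim(study[[nm]]), d)) {
      stop("matrix '", nm, "' does not match signal dimensions (",
           d[1], " x ", d[2], ")")
    }
  }
  if (nrow(study$samples) != d[2]) {
    stop("sample metadata has ", nrow(study$samples),
         " rows but signal has ", d[2], " columns")
  }
  if (!identical(as.character(study$samples$sample_id), colnames(study$signal))) {
    stop("sample_id order does not match signal column names")
  }
  if (nrow(study$genes) != d[1]) {
    stop("gene annotation has ", nrow(study$genes),
         " rows but signal has ", d[1], " rows")
  }
  if (!identical(as.character(study$genes$probe_id), rownames(study$signal))) {
    stop("probe_id order does not match signal row names")
  }
  if (any(!is.finite(study$signal[!study$mask]))) {
    stop("non-finite signal values outside the mask")
  }
  invisible(study)
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study: ", nrow(x$signal), " genes x ", ncol(x$signal),
      " samples\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (n=%d)", levels(x$samples$group),
                                  tabulate(x$samples$group)), collapse = ", "),
      "\n", sep = "")
  cat("  cohorts: ", paste(levels(x$samples$cohort), collapse = ", "), "\n",
      sep = "")
  cat("  masked cells: ", sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' Ordered treatment groups of a study
#' @param study An `expression_study`.
#' @return Character vector of group labels in design order.
#' @export
group_levels <- function(study) levels(study$samples$group)

# signal with masked cells set NA; all computations go through this
masked_signal <- function(study) {
  x <- study$signal
  x[study$mask] <- NA_real_
  x
}

#' Construct a signed gene list
#'
#' A set of gene symbols, each carrying an optional direction of change.
#' Used for cross-study overlap and enrichment queries.
#'
#' @param symbols Character vector of gene symbols (must be unique).
#' @param direction Either a single value recycled to all symbols or a vector
#'   the same length as `symbols`; each entry one of `"up"`, `"down"`,
#'   `"unsigned"`.
#' @return A data frame of class `gene_list` with columns `symbol`,
#'   `direction`.
#' @export
gene_list <- function(symbols, direction = "unsigned") {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) {
    stop("duplicate symbols in gene list: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  direction <- rep_len(as.character(direction), length(symbols))
  bad <- setdiff(unique(direction), c("up", "down", "unsigned"))
  if (length(bad) > 0) {
    stop("invalid direction value(s): ", paste(bad, collapse = ", "))
  }
  structure(data.frame(symbol = symbols, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("gene_list", "data.frame"))
}

is_signed <- function(x) all(x$direction %in% c("up", "down"))
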