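#' Read an expression study from TSV files
#'
#' Reads a gene-by-sample signal matrix, sample metadata and gene annotation
#' (plus an optional presence-call matrix) and assembles a validated
#' [expression_study()]. Missing matrix cells (empty fields) become masked
#' values.
#'
#' @param matrix_path TSV, first column `probe_id`, remaining columns one per
#'   sample.
#' @param metadata_path TSV with columns `sample_id`, `group`, `cohort`.
#' @param annotation_path TSV with columns `probe_id`, `symbol`, `grade`.
#' @param presence_path Optional TSV shaped like the signal matrix with cells
#'   `P` (present) / `A` (absent); when absent, all cells are taken present.
#' @param group_levels Optional ordered group labels; defaults to order of
#'   appearance in the metadata.
#' @return An `expression_study`.
#' @export
read_expression_study <- function(matrix_path, metadata_path, annotation_path,
                                  presence_path = NULL, group_levels = NULL) {
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (names(mat_df)[1] != "probe_id") {
    stop("expression matrix must have 'probe_id' as its first column")
  }
  signal <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(signal) <- "double"
  rownames(signal) <- mat_df$probe_id

  samples <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  extra <- setdiff(colnames(signal), samples$sample_id)
  if (length(extra) > 0) {
    stop("matrix column(s) absent from sample metadata: ",
         paste(extra, collapse = ", "))
  }
  unused <- setdiff(samples$sample_id, colnames(signal))
  if (length(unused) > 0) {
    stop("metadata sample(s) absent from matrix columns: ",
         paste(unused, collapse = ", "))
  }
  samples <- samples[match(colnames(signal), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  genes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!identical(nrow(genes), nrow(signal))) {
    stop("annotation has ", nrow(genes), " rows but matrix has ",
         nrow(signal), " gene rows")
  }
  if (!identical(genes$probe_id, rownames(signal))) {
    stop("annotation probe_id order does not match matrix rows")
  }
  genes$symbol[!is.na(genes$symbol) & genes$symbol == ""] <- NA_character_

  present <- NULL
  if (!is.null(presence_path)) {
    pr_df <- utils::read.delim(presence_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
    pr <- as.matrix(pr_df[, -1, drop = FALSE])
    if (!identical(dim(pr), dim(signal))) {
      stop("presence matrix dimensions do not match signal matrix")
    }
    present <- pr == "P"
    dimnames(present) <- dimnames(signal)
  }

  expression_study(signal, samples, genes, present = present,
                   group_levels = group_levels)
}

#' Write an expression study as TSV files
#'
#' Inverse of [read_expression_study()]: writes the signal matrix (masked
#' cells as empty fields), sample metadata, gene annotation and presence
#' calls (`P`/`A`).
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_matrix.tsv`,
#'   `<prefix>_metadata.tsv`, `<prefix>_annotation.tsv`,
#'   `<prefix>_presence.tsv`.
#' @return Invisibly, the named character vector of paths written.
#' @export
write_expression_study <- function(study, dir, prefix = "study") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    presence = file.path(dir, paste0(prefix, "_presence.tsv")))

  sig <- masked_signal(study)
  mat_df <- data.frame(probe_id = rownames(sig), sig, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(mat_df, paths["matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  utils::write.table(study$samples, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(study$genes, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  pr <- ifelse(study$present, "P", "A")
  pr_df <- data.frame(probe_id = rownames(sig), pr, check.names = FALSE,
                      stringsAsFactors = FALSE)
  utils::write.table(pr_df, paths["presence"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member
#' TAB member ...`. Members are de-duplicated.
#'
#' @param gmt_path Path to the GMT file.
#' @return An object of class `gene_set_collection`: a named list of unique
#'   symbol vectors, with a `descriptions` attribute.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, ": expected at least 3 tab-separated fields, got ",
           length(fields))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("GMT line ", i, ": set '", fields[1], "' has no members")
    }
    sets[[fields[1]]] <- members
    desc[[fields[1]]] <- fields[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection: ", length(x), " sets\n", sep = "")
  invisible(x)
}

#' Write a per-gene result table
#'
#' Writes a TSV with a deterministic row order: ascending p-value, ties
#' broken alphabetically by symbol. Mirrors the layout of a supplementary
#' significant-gene table (probe id, symbol, statistics, template,
#' direction).
#'
#' @param rows Data frame; must contain columns `p` and `symbol`.
#' @param path Output path.
#' @return Invisibly, the reordered data frame as written.
#' @export
write_gene_table <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) > 0) {
    if (!all(c("p", "symbol") %in% names(rows))) {
      stop("gene table requires 'p' and 'symbol' columns")
    }
    rows <- rows[order(rows$p, rows$symbol), , drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(rows)
}
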