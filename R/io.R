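#' Construct and validate a count table
#'
#' A count table holds non-negative integer read counts with samples as rows
#' and taxa (zOTUs) as columns. Columns that represent artificial spike-in
#' standards are flagged so that downstream normalization can separate
#' bacterial reads from spike reads.
#'
#' @param counts numeric matrix, samples x taxa, non-negative integers with
#'   unique row and column names.
#' @param spike_ids character vector of column names flagged as spike-in
#'   standards (may be empty).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `spike_ids`.
#' @export
count_table <- function(counts, spike_ids = character()) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort_located("`counts` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_located("`counts` must have sample row names and taxon column names")
  if (anyDuplicated(rownames(counts)))
    abort_located("duplicate sample ids: ",
                  paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                        collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort_located("duplicate taxon ids: ",
                  paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                        collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | abs(counts - round(counts)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_located("non-integer or negative count at sample '",
                  rownames(counts)[bad[1, 1]], "', taxon '",
                  colnames(counts)[bad[1, 2]], "'")
  spike_ids <- as.character(spike_ids)
  missing_spike <- setdiff(spike_ids, colnames(counts))
  if (length(missing_spike) > 0)
    abort_located("spike ids not present in table: ",
                  paste(missing_spike, collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, spike_ids = spike_ids), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa (",
      length(x$spike_ids), "spike features )\n")
  invisible(x)
}

sample_ids <- function(ct) rownames(ct$counts)
taxon_ids <- function(ct) colnames(ct$counts)
bacterial_ids <- function(ct) setdiff(colnames(ct$counts), ct$spike_ids)

#' Read a count table from TSV
#'
#' Expects a tab-separated file with a header row of taxon ids and the first
#' column holding sample ids. Taxa whose id matches `spike_prefix` are flagged
#' as artificial spike-in standards.
#'
#' @param path file path.
#' @param spike_prefix regular expression matched against taxon ids to flag
#'   spike features (default `"^SPIKE"`).
#' @return A [count_table].
#' @export
read_count_table <- function(path, spike_prefix = "^SPIKE") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2)
    abort_located("count table '", path, "' needs a sample id column and >= 1 taxon")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    abort_located("non-numeric entries in count table '", path, "'")
  rownames(m) <- ids
  spikes <- grep(spike_prefix, colnames(m), value = TRUE)
  count_table(m, spike_ids = spikes)
}

#' Write a count table to TSV
#'
#' Round-trips losslessly through [read_count_table()].
#' @param ct a [count_table].
#' @param path output file path.
#' @export
write_count_table <- function(ct, path) {
  write_tsv_stable(ct$counts, path, row_label = "sample_id")
}

#' Read and validate per-sample metadata
#'
#' Requires columns `sample_id`, `subject_id`, `time_h`, `group`. Optional
#' columns `condition`, `mass_g` and `spike_copies` are validated when present.
#' Sampling times are folded into \[0, 24); the raw value is retained in
#' `time_raw_h` so series that extend past 24 h (e.g. starvation time courses)
#' keep their provenance.
#'
#' @param path TSV file path.
#' @return A validated `data.frame`, one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  validate_metadata(df)
}

#' Validate a metadata data frame
#'
#' @param df data.frame as documented in [read_metadata()].
#' @return The validated (time-folded) data.frame.
#' @export
validate_metadata <- function(df) {
  required <- c("sample_id", "subject_id", "time_h", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort_located("metadata missing required column(s): ",
                  paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    abort_located("duplicate sample_id in metadata: ",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", "))
  if (!is.numeric(df$time_h) || any(!is.finite(df$time_h)))
    abort_located("metadata time_h must be finite numeric hours")
  if ("mass_g" %in% names(df) && any(df$mass_g <= 0))
    abort_located("metadata mass_g must be > 0 (offending sample: ",
                  df$sample_id[which(df$mass_g <= 0)[1]], ")")
  if ("spike_copies" %in% names(df) && any(df$spike_copies <= 0))
    abort_located("metadata spike_copies must be > 0")
  df$time_raw_h <- df$time_h
  df$time_h <- fold_24(df$time_h)
  # preserve categorical levels in file order
  df$group <- factor(df$group, levels = unique(df$group))
  if ("condition" %in% names(df))
    df$condition <- factor(df$condition, levels = unique(df$condition))
  rownames(df) <- df$sample_id
  df
}

#' Write metadata to TSV
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$group <- as.character(out$group)
  if ("condition" %in% names(out)) out$condition <- as.character(out$condition)
  rownames(out) <- NULL
  write_tsv_stable(out, path)
}

#' Read a rooted phylogenetic tree
#'
#' Reads newick via \pkg{ape} and validates that every leaf is labeled and no
#' branch length is negative.
#'
#' @param path newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort_located("could not parse newick tree from '", path, "'")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    abort_located("tree has unlabeled leaves")
  if (anyDuplicated(tree$tip.label))
    abort_located("tree has duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    abort_located("tree has negative branch lengths")
  tree
}

#' Write a tree as newick
#' @param tree `ape::phylo`.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a metabolite concentration table
#'
#' TSV with `sample_id` first column and one column per metabolite
#' (concentrations, non-negative; missing values allowed and propagated to
#' pairwise-complete correlation downstream).
#'
#' @param path TSV path.
#' @return numeric matrix samples x metabolites.
#' @export
read_metabolites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0, na.rm = TRUE))
    abort_located("negative metabolite concentration in '", path, "'")
  m
}

#' Write a numeric matrix (samples x features) to TSV
#' @param m matrix with row names.
#' @param path output path.
#' @param row_label header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, row_label = "sample_id") {
  write_tsv_stable(m, path, row_label = row_label)
}
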