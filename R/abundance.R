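#' Sample quality-control filter on sequencing depth
#'
#' Removes samples whose bacterial (non-spike) read sum is not strictly above
#' `min_reads`. The threshold follows the common amplicon QC convention of
#' keeping samples with read counts > 5000.
#'
#' @param ct a [count_table].
#' @param min_reads minimum bacterial read sum (strict inequality), default 5000.
#' @param quiet suppress the removal message.
#' @return Filtered [count_table].
#' @export
qc_filter_samples <- function(ct, min_reads = 5000, quiet = FALSE) {
  stopifnot(inherits(ct, "count_table"))
  bact <- ct$counts[, bacterial_ids(ct), drop = FALSE]
  depth <- rowSums(bact)
  keep <- depth > min_reads
  if (!any(keep))
    abort_located("all samples removed by QC (min_reads = ", min_reads, ")")
  if (!all(keep) && !quiet)
    message("qc_filter_samples: removed ", sum(!keep), " sample(s): ",
            paste(rownames(ct$counts)[!keep], collapse = ", "))
  count_table(ct$counts[keep, , drop = FALSE], spike_ids = ct$spike_ids)
}

#' Relative abundance over bacterial taxa
#'
#' Row-normalizes counts to fractions. Spike-in features are excluded from
#' both the numerator set and the denominator, so fractions sum to one over
#' bacterial taxa only.
#'
#' @param ct a [count_table].
#' @return numeric matrix samples x bacterial taxa; rows sum to 1.
#' @export
relative_abundance <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  bact <- ct$counts[, bacterial_ids(ct), drop = FALSE]
  depth <- rowSums(bact)
  if (any(depth == 0))
    abort_located("zero bacterial reads in sample(s): ",
                  paste(rownames(bact)[depth == 0], collapse = ", "))
  sweep(bact, 1, depth, "/")
}

#' Spike-in based quantitative abundance (copies per gram)
#'
#' Converts read counts to 16S copy numbers per gram of sample using the
#' artificial spike-in standard: a known number of spike copies is added to
#' each weighed sample before extraction, so the ratio of a taxon's reads to
#' the spike reads estimates its copy number relative to the spike.
#'
#' Q(s, i) = counts(s, i) / spike_reads(s) * spike_copies(s) / mass_g(s)
#'
#' The result is quantitative *between* samples (relative quantification); no
#' absolute cell-count claim is made.
#'
#' @param ct a [count_table] with flagged spike features.
#' @param meta metadata containing `mass_g` and (unless overridden)
#'   `spike_copies` for every sample.
#' @param spike_copies_per_sample optional scalar or named vector overriding
#'   the metadata `spike_copies` column.
#' @return list with `quant` (samples x bacterial taxa copies-per-gram matrix)
#'   and `total_copies_per_g` (per-sample row sum, the total 16S load).
#' @export
quantitative_abundance <- function(ct, meta, spike_copies_per_sample = NULL) {
  stopifnot(inherits(ct, "count_table"))
  if (length(ct$spike_ids) == 0)
    abort_located("no spike features flagged; quantitative normalization needs spikes")
  ids <- sample_ids(ct)
  if (!all(ids %in% meta$sample_id))
    abort_located("samples missing from metadata: ",
                  paste(setdiff(ids, meta$sample_id), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (!("mass_g" %in% names(meta)) || any(meta$mass_g <= 0))
    abort_located("metadata must provide mass_g > 0 for every sample")
  spike_copies <- spike_copies_per_sample %||% meta$spike_copies
  if (is.null(spike_copies))
    abort_located("spike copies not given (metadata column `spike_copies` or argument)")
  spike_copies <- rep_len(spike_copies, length(ids))
  spike_reads <- rowSums(ct$counts[, ct$spike_ids, drop = FALSE])
  if (any(spike_reads == 0))
    abort_located("zero spike reads in sample(s): ",
                  paste(ids[spike_reads == 0], collapse = ", "))
  bact <- ct$counts[, bacterial_ids(ct), drop = FALSE]
  quant <- bact / spike_reads * spike_copies / meta$mass_g
  list(quant = quant, total_copies_per_g = rowSums(quant))
}

#' Abundance/prevalence taxon filter
#'
#' Keeps taxa with mean relative abundance strictly above `mean_min` (default
#' 0.1%) and detected (abundance > 0) in strictly more than `prevalence_min`
#' (default 10%) of samples. Apply the returned subset to any companion
#' count/quantitative table.
#'
#' @param rel relative abundance matrix (samples x taxa).
#' @param mean_min mean relative-abundance threshold (fraction), default 0.001.
#' @param prevalence_min detection-prevalence threshold (fraction), default 0.10.
#' @return character vector of retained taxon ids.
#' @export
filter_taxa <- function(rel, mean_min = 0.001, prevalence_min = 0.10) {
  mean_ab <- colMeans(rel)
  prev <- colMeans(rel > 0)
  keep <- mean_ab > mean_min & prev > prevalence_min
  if (!any(keep))
    abort_located("no taxa pass the abundance/prevalence filter")
  colnames(rel)[keep]
}

#' Collapse a table to a taxonomic rank
#'
#' Sums columns that share a rank label. Taxa without an assignment at the
#' rank are pooled under `"Unknown"`, so totals (e.g. row sums of relative
#' abundance) are conserved.
#'
#' @param table samples x taxa numeric matrix (relative or quantitative).
#' @param taxonomy data.frame with column `taxon_id` and one column per rank.
#' @param rank rank column name, e.g. `"phylum"`.
#' @return samples x rank-labels matrix.
#' @export
collapse_taxonomy <- function(table, taxonomy, rank) {
  if (!(rank %in% names(taxonomy)))
    abort_located("rank '", rank, "' not present in taxonomy (have: ",
                  paste(setdiff(names(taxonomy), "taxon_id"), collapse = ", "), ")")
  idx <- match(colnames(table), taxonomy$taxon_id)
  if (anyNA(idx))
    abort_located("taxa without lineage entry: ",
                  paste(colnames(table)[is.na(idx)], collapse = ", "))
  labels <- as.character(taxonomy[[rank]][idx])
  labels[is.na(labels) | !nzchar(labels)] <- "Unknown"
  groups <- unique(labels)
  out <- vapply(groups, function(g)
    rowSums(table[, labels == g, drop = FALSE]), numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), groups))
  out
}
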