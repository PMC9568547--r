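#' Per-taxon rhythmicity calls for one group
#'
#' Runs [jtk_test()] (or [fit_cosinor()]) on every taxon of an abundance
#' table within one sample group, adjusts JTK p-values by Bonferroni across
#' taxa, and reports the conventional mixed parameterization: amplitude from
#' the JTK output, peak phase from the cosinor fit. A taxon is called
#' rhythmic when the Bonferroni-adjusted JTK p-value is at most `alpha`
#' (cosinor-based calls use the raw cosinor p-value).
#'
#' @param table samples x taxa numeric matrix (typically relative abundance).
#' @param meta metadata data.frame with `sample_id`, `time_h`, `group`.
#' @param group group label to analyze.
#' @param method `"jtk"` (default) or `"cosinor"`.
#' @param alpha significance level, default 0.05.
#' @param period_h fixed period, default 24.
#' @return data.frame of class `rhythm_calls` with one row per taxon:
#'   `taxon`, `jtk_p`, `jtk_adj_p`, `best_lag_h`, `kendall_tau`,
#'   `amplitude_jtk`, `mesor`, `amplitude_cosinor`, `phase_h`, `cosinor_p`,
#'   `is_rhythmic`. Attributes `summary` (counts, rhythmic fraction and the
#'   total relative abundance carried by rhythmic taxa) and `group`.
#' @export
rhythm_calls <- function(table, meta, group, method = c("jtk", "cosinor"),
                         alpha = 0.05, period_h = 24) {
  method <- match.arg(method)
  if (!(group %in% as.character(meta$group)))
    abort_located("group '", group, "' not present in metadata")
  meta_g <- meta[as.character(meta$group) == group, , drop = FALSE]
  missing_s <- setdiff(meta_g$sample_id, rownames(table))
  if (length(missing_s) > 0)
    abort_located("samples in metadata but not in table: ",
                  paste(missing_s, collapse = ", "))
  tab <- table[meta_g$sample_id, , drop = FALSE]
  tt <- meta_g$time_h
  reps <- table(tt)
  if (any(reps < 2))
    warning("fewer than 2 replicates at time point(s): ",
            paste(names(reps)[reps < 2], collapse = ", "))
  prep <- jtk_prepare(tt, period_h = period_h)
  res <- lapply(colnames(tab), function(tx) {
    y <- tab[, tx]
    cf <- fit_cosinor(tt, y, period_h = period_h)
    j <- jtk_score(prep, y)
    data.frame(taxon = tx, jtk_p = j$p_value, best_lag_h = j$best_lag_h,
               kendall_tau = j$kendall_tau, amplitude_jtk = j$amplitude_estimate,
               mesor = cf$mesor, amplitude_cosinor = cf$amplitude,
               phase_h = cf$phase_h, cosinor_p = cf$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$jtk_adj_p <- stats::p.adjust(out$jtk_p, method = "bonferroni")
  out$is_rhythmic <- if (method == "jtk") out$jtk_adj_p <= alpha else
    out$cosinor_p <= alpha
  out <- out[, c("taxon", "jtk_p", "jtk_adj_p", "best_lag_h", "kendall_tau",
                 "amplitude_jtk", "mesor", "amplitude_cosinor", "phase_h",
                 "cosinor_p", "is_rhythmic")]
  rownames(out) <- out$taxon
  mean_ab <- colMeans(tab)
  attr(out, "summary") <- list(
    group = group, method = method, alpha = alpha,
    n_taxa = ncol(tab), n_rhythmic = sum(out$is_rhythmic),
    fraction_rhythmic = mean(out$is_rhythmic),
    rhythmic_abundance_share = sum(mean_ab[out$is_rhythmic]) / sum(mean_ab))
  class(out) <- c("rhythm_calls", "data.frame")
  out
}

#' Peak-normalized, phase-ordered abundance matrix
#'
#' For heatmap display: per taxon, time-point means across subjects divided
#' by their maximum (the peak becomes 1), with rows ordered by the cosinor
#' peak phase of an ordering group's calls. Arrhythmic taxa keep their fitted
#' phase for ordering.
#'
#' @param table samples x taxa matrix.
#' @param meta metadata with `sample_id`, `time_h`, `group`.
#' @param calls a [rhythm_calls()] result for the ordering group.
#' @param group group whose samples are averaged; defaults to the calls' group.
#' @return list with `matrix` (taxa x time points, peak-normalized, rows in
#'   phase order) and `phase_order` (taxon ids).
#' @export
peak_phase_matrix <- function(table, meta, calls, group = NULL) {
  group <- group %||% attr(calls, "summary")$group
  meta_g <- meta[as.character(meta$group) == group, , drop = FALSE]
  tab <- table[meta_g$sample_id, , drop = FALSE]
  tp <- sort(unique(meta_g$time_h))
  means <- vapply(tp, function(t0)
    colMeans(tab[meta_g$time_h == t0, , drop = FALSE]), numeric(ncol(tab)))
  means <- matrix(means, nrow = ncol(tab),
                  dimnames = list(colnames(tab), paste0("t", tp)))
  mx <- apply(means, 1, max)
  if (any(mx == 0))
    abort_located("taxa with all-zero time-point means: ",
                  paste(rownames(means)[mx == 0], collapse = ", "))
  norm <- means / mx
  ord <- calls$taxon[order(calls$phase_h)]
  ord <- ord[ord %in% rownames(norm)]
  list(matrix = norm[ord, , drop = FALSE], phase_order = ord)
}
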