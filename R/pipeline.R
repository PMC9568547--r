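#' Configuration for a full pipeline run
#'
#' Bundles either a simulation block ([synth_config()]) or paths to input
#' files, together with every analysis threshold and the master seed. Each
#' stochastic stage receives a sub-seed derived from the master seed, so
#' stages can be re-run in isolation with identical results.
#'
#' @param simulate a [synth_config()], or `NULL` to read inputs from paths.
#' @param counts_path,meta_path,taxonomy_path,tree_path,metabolites_path
#'   input file paths (used when `simulate` is `NULL`).
#' @param outdir output directory.
#' @param alpha significance level for rhythm and differential calls.
#' @param min_reads sample QC threshold (bacterial reads, strict).
#' @param mean_min,prevalence_min taxon filter thresholds.
#' @param assoc_prevalence_min prevalence threshold for clock-controlled
#'   taxon selection.
#' @param gunifrac_alpha generalized UniFrac weighting exponent.
#' @param n_perm permutations for PERMANOVA/Procrustes.
#' @param ref_time_h reference time for distance quantification.
#' @param run_diversity,run_associations stage toggles.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = synth_config(), counts_path = NULL,
                       meta_path = NULL, taxonomy_path = NULL,
                       tree_path = NULL, metabolites_path = NULL,
                       outdir = tempfile("rhythmbiome_run_"),
                       alpha = 0.05, min_reads = 5000, mean_min = 0.001,
                       prevalence_min = 0.10, assoc_prevalence_min = 0.30,
                       gunifrac_alpha = 0.5, n_perm = 999, ref_time_h = 1,
                       run_diversity = TRUE, run_associations = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  # pre-flight validation: fail before any computation
  if (is.null(cfg$simulate)) {
    for (p in c("counts_path", "meta_path")) {
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        abort_located("pre-flight: required input ", p, " missing")
    }
    if (cfg$run_diversity &&
        (is.null(cfg$tree_path) || !file.exists(cfg$tree_path)))
      abort_located("pre-flight: diversity stage enabled but tree_path missing")
    if (cfg$run_associations &&
        (is.null(cfg$metabolites_path) || !file.exists(cfg$metabolites_path)))
      abort_located("pre-flight: associations enabled but metabolites_path missing")
  } else {
    stopifnot(inherits(cfg$simulate, "synth_config"))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort_located("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, normalization, rhythmicity detection,
#' differential rhythmicity, beta-diversity statistics and taxon-metabolite
#' association as one reproducible run. Every intermediate table is written
#' as TSV under `config$outdir` together with a `manifest.txt` recording the
#' package version, seeds, thresholds and file digests. The same config and
#' seed produce a byte-identical output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all intermediate and final objects.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  groups <- NULL

  if (!is.null(config$simulate)) {
    data <- run_stage("simulate", generate_dataset(config$simulate))
    truth <- data$truth
  } else {
    data <- run_stage("load", list(
      counts = read_count_table(config$counts_path),
      meta = read_metadata(config$meta_path),
      taxonomy = if (!is.null(config$taxonomy_path))
        utils::read.table(config$taxonomy_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else NULL,
      tree = if (!is.null(config$tree_path)) read_tree(config$tree_path) else NULL,
      metabolites = if (!is.null(config$metabolites_path))
        read_metabolites(config$metabolites_path) else NULL))
    truth <- NULL
  }
  groups <- levels(data$meta$group)

  norm <- run_stage("normalize", {
    ct <- qc_filter_samples(data$counts, min_reads = config$min_reads,
                            quiet = TRUE)
    meta <- data$meta[data$meta$sample_id %in% rownames(ct$counts), ,
                      drop = FALSE]
    rel_full <- relative_abundance(ct)
    keep <- filter_taxa(rel_full, mean_min = config$mean_min,
                        prevalence_min = config$prevalence_min)
    rel <- rel_full[, keep, drop = FALSE]
    quant <- if ("spike_copies" %in% names(meta) &&
                 length(ct$spike_ids) > 0)
      quantitative_abundance(ct, meta) else NULL
    list(counts = ct, meta = meta, rel_full = rel_full, rel = rel,
         kept_taxa = keep, quant = quant)
  })

  rhythm <- run_stage("rhythm", {
    calls <- lapply(stats::setNames(groups, groups), function(g)
      rhythm_calls(norm$rel, norm$meta, g, alpha = config$alpha))
    ppm <- peak_phase_matrix(norm$rel, norm$meta, calls[[1]])
    list(calls = calls, peak_matrix = ppm)
  })

  diff <- run_stage("compare", compare_rhythms(
    norm$rel, norm$meta, groups[1], groups[2], alpha = config$alpha))

  diversity <- if (config$run_diversity) run_stage("diversity", {
    alpha_div <- alpha_diversity(norm$rel_full)
    dist <- gunifrac(norm$rel, data$tree, alpha = config$gunifrac_alpha)
    perm <- permanova(dist, norm$meta[rownames(dist), "group"],
                      n_perm = config$n_perm,
                      seed = derive_seed(config$seed, "permanova"))
    ord <- pcoa(dist, k = 2)
    d2r <- distance_to_reference(dist, norm$meta,
                                 ref_time_h = config$ref_time_h)
    list(alpha = alpha_div, dist = dist, permanova = perm, pcoa = ord,
         dist_to_ref = d2r)
  }) else NULL

  assoc <- if (config$run_associations && !is.null(data$metabolites))
    run_stage("associations", {
      ccm <- select_clock_controlled(diff, norm$rel,
                                     prevalence_min = config$assoc_prevalence_min)
      corr <- if (length(ccm) > 0)
        spearman_matrix(norm$rel[, ccm, drop = FALSE], data$metabolites)
      else NULL
      proc <- if (config$run_diversity) {
        mb <- data$metabolites[rownames(diversity$pcoa$coords), , drop = FALSE]
        mb_ord <- pcoa(stats::dist(scale(log(mb + 1e-9))), k = 2)
        procrustes_fit(diversity$pcoa$coords, mb_ord$coords,
                       n_perm = config$n_perm,
                       seed = derive_seed(config$seed, "procrustes"))
      } else NULL
      list(clock_controlled = ccm, correlation = corr, procrustes = proc)
    }) else NULL

  bundle <- list(config = config, data = data, truth = truth, norm = norm,
                 rhythm = rhythm, diff = diff, diversity = diversity,
                 associations = assoc,
                 summary = pipeline_summary(truth, norm, rhythm, diff))
  run_stage("write", write_run_outputs(bundle, config$outdir))
  invisible(bundle)
}

pipeline_summary <- function(truth, norm, rhythm, diff) {
  s <- attr(diff, "summary")
  out <- list(
    n_samples = nrow(norm$rel), n_taxa_analyzed = ncol(norm$rel),
    fraction_rhythmic_control = attr(rhythm$calls[[1]], "summary")$fraction_rhythmic,
    fraction_rhythmic_knockout = attr(rhythm$calls[[2]], "summary")$fraction_rhythmic,
    rhythmic_ratio_b_over_a = s$rhythmic_ratio_b_over_a,
    rhythmic_abundance_share_control =
      attr(rhythm$calls[[1]], "summary")$rhythmic_abundance_share)
  if (!is.null(truth)) {
    analyzed <- colnames(norm$rel)
    tt <- truth$taxa[match(analyzed, truth$taxa$taxon), ]
    true_loss <- tt$taxon[tt$rhythmic_control & !tt$rhythmic_knockout]
    called_loss <- diff$taxon[diff$category == "loss"]
    tp <- length(intersect(called_loss, true_loss))
    out$loss_sensitivity <- if (length(true_loss) > 0)
      tp / length(true_loss) else NA_real_
    out$loss_fdr <- if (length(called_loss) > 0)
      1 - tp / length(called_loss) else 0
  }
  out
}

write_run_outputs <- function(bundle, outdir) {
  cfg <- bundle$config
  paths <- character()
  wr <- function(fun, obj, name, ...) {
    p <- file.path(outdir, name)
    fun(obj, p, ...)
    paths[[length(paths) + 1]] <<- p
    p
  }
  wr(write_count_table, bundle$norm$counts, "counts.tsv")
  wr(write_metadata, bundle$norm$meta, "metadata.tsv")
  wr(write_matrix_tsv, bundle$norm$rel, "relative_abundance.tsv")
  if (!is.null(bundle$norm$quant))
    wr(write_matrix_tsv, bundle$norm$quant$quant, "quantitative_abundance.tsv")
  if (!is.null(bundle$data$taxonomy))
    wr(write_tsv_stable, bundle$data$taxonomy, "taxonomy.tsv")
  if (!is.null(bundle$data$tree))
    wr(write_tree, bundle$data$tree, "tree.nwk")
  if (!is.null(bundle$data$metabolites))
    wr(write_matrix_tsv, bundle$data$metabolites, "metabolites.tsv")
  if (!is.null(bundle$truth))
    wr(write_tsv_stable, bundle$truth$taxa, "truth_taxa.tsv")
  for (g in names(bundle$rhythm$calls))
    wr(write_tsv_stable, as.data.frame(bundle$rhythm$calls[[g]]),
       paste0("rhythm_calls_", g, ".tsv"))
  wr(write_matrix_tsv, bundle$rhythm$peak_matrix$matrix,
     "peak_phase_matrix.tsv", row_label = "taxon")
  wr(write_tsv_stable, as.data.frame(bundle$diff), "differential_rhythms.tsv")
  if (!is.null(bundle$diversity)) {
    wr(write_tsv_stable, bundle$diversity$alpha, "alpha_diversity.tsv")
    wr(write_matrix_tsv, bundle$diversity$dist, "gunifrac_distance.tsv")
    wr(write_matrix_tsv, bundle$diversity$pcoa$coords, "pcoa_coords.tsv")
    wr(write_tsv_stable, bundle$diversity$dist_to_ref$distances,
       "distance_to_reference.tsv")
  }
  if (!is.null(bundle$associations$correlation)) {
    wr(write_matrix_tsv, bundle$associations$correlation$rho,
       "correlation_rho.tsv", row_label = "taxon")
    wr(write_tsv_stable, bundle$associations$correlation$pairs,
       "correlation_pairs.tsv")
  }
  # flat key = value manifest; deterministic content only
  su <- bundle$summary
  lines <- c(
    paste0("package_version = ", as.character(utils::packageVersion("rhythmbiome"))),
    paste0("seed = ", cfg$seed),
    paste0("alpha = ", cfg$alpha),
    paste0("min_reads = ", cfg$min_reads),
    paste0("mean_min = ", cfg$mean_min),
    paste0("prevalence_min = ", cfg$prevalence_min),
    paste0("gunifrac_alpha = ", cfg$gunifrac_alpha),
    paste0("n_perm = ", cfg$n_perm),
    vapply(names(su), function(k)
      paste0("summary.", k, " = ", format(su[[k]], digits = 10)),
      character(1)),
    vapply(sort(unlist(paths)), function(p)
      paste0("md5.", basename(p), " = ", unname(tools::md5sum(p))),
      character(1)))
  writeLines(lines, file.path(outdir, "manifest.txt"))
  invisible(outdir)
}
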