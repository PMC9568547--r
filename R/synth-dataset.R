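#' Generate a random rooted binary tree over given taxa
#'
#' Thin deterministic wrapper around \code{ape::rtree}: a rooted binary tree
#' with the given leaf labels and strictly positive branch lengths,
#' reproducible per seed.
#'
#' @param taxon_ids unique leaf labels (>= 2).
#' @param seed integer seed.
#' @return `ape::phylo` tree.
#' @export
generate_tree <- function(taxon_ids, seed = 1L) {
  if (length(taxon_ids) < 2) abort_located("need >= 2 taxa for a tree")
  if (anyDuplicated(taxon_ids))
    abort_located("duplicate taxon ids: ",
                  paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  tree <- with_seed(seed, ape::rtree(length(taxon_ids), rooted = TRUE))
  tree$tip.label <- taxon_ids[as.integer(sub("^t", "", tree$tip.label))]
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  tree
}

#' Generate metabolite concentrations coupled to taxa
#'
#' Each coupled metabolite is a weighted taxon relative abundance plus
#' Gaussian noise calibrated so that the pair reaches approximately the
#' target |Spearman| correlation; the monotone exponential link keeps the
#' rank correlation intact while producing positive concentration-like
#' values. Uncoupled metabolites are pure noise.
#'
#' @param rel_abund samples x taxa relative abundance matrix.
#' @param truth a `synth_truth` object carrying the `couplings` table
#'   (metabolite, taxon, weight).
#' @param config the [synth_config()].
#' @param seed integer seed (default derived from the config seed).
#' @return samples x metabolites concentration matrix.
#' @export
generate_metabolites <- function(rel_abund, truth, config,
                                 seed = derive_seed(config$seed, "metabolites")) {
  coup <- truth$couplings
  absent <- setdiff(coup$taxon[coup$weight != 0], colnames(rel_abund))
  if (length(absent) > 0)
    abort_located("coupling to absent taxa: ", paste(absent, collapse = ", "))
  n <- nrow(rel_abund)
  met_names <- unique(coup$metabolite)
  with_seed(seed, {
    out <- matrix(NA_real_, n, length(met_names),
                  dimnames = list(rownames(rel_abund), met_names))
    for (j in seq_along(met_names)) {
      row <- coup[coup$metabolite == met_names[j], , drop = FALSE]
      if (nrow(row) == 1 && row$weight != 0) {
        x <- rel_abund[, row$taxon]
        signal <- row$weight * scale(x)[, 1]
        rho <- config$coupling_strength
        noise_sd <- if (rho >= 1) 0 else abs(row$weight) * sqrt(1 / rho^2 - 1)
        raw <- signal + stats::rnorm(n, sd = noise_sd)
      } else {
        raw <- stats::rnorm(n)
      }
      # monotone positive link: concentrations in micromol-per-gram style units
      out[, j] <- 50 * exp(0.5 * raw)
    }
    out
  })
}

#' Generate a complete synthetic study dataset
#'
#' Produces count table, sample metadata, taxonomy, phylogenetic tree,
#' metabolite panel and the ground-truth object for recovery testing. The
#' expected log abundance of taxon i for subject m at time t is
#' mu_i + u_m + A_i cos(2 pi (t - phi_i)/24), with A_i = 0 for taxa that are
#' not rhythmic in the subject's group; the total bacterial load per gram
#' follows its own cosine; reads are drawn multinomially at a log-normal
#' library size over taxon proportions plus one aggregate spike feature whose
#' expected read share is spike_copies / (spike_copies + load x mass).
#'
#' @param config a [synth_config()].
#' @return list with `counts` ([count_table]), `meta` (metadata data.frame),
#'   `taxonomy` (lineage data.frame), `tree` (`phylo`), `metabolites`
#'   (matrix) and `truth` (`synth_truth` list).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  taxa <- sprintf("zOTU_%04d", seq_len(cfg$n_taxa))
  truth <- with_seed(derive_seed(cfg$seed, "truth"), {
    n_r <- round(cfg$n_taxa * cfg$frac_rhythmic_control)
    rhythmic_control <- logical(cfg$n_taxa)
    rhythmic_control[sample.int(cfg$n_taxa, n_r)] <- TRUE
    idx_r <- which(rhythmic_control)
    n_keep <- round(n_r * cfg$frac_retained_knockout)
    rhythmic_knockout <- logical(cfg$n_taxa)
    if (n_keep > 0)
      rhythmic_knockout[sample(idx_r, n_keep)] <- TRUE
    baseline <- stats::rnorm(cfg$n_taxa, 0, cfg$baseline_logmean_sd)
    amp <- stats::runif(cfg$n_taxa, cfg$amplitude_log_range[1],
                        cfg$amplitude_log_range[2])
    amp[!rhythmic_control] <- 0
    mode <- sample.int(length(cfg$phase_modes_h), cfg$n_taxa, replace = TRUE,
                       prob = cfg$phase_mode_weights)
    phase <- (cfg$phase_modes_h[mode] +
                stats::rnorm(cfg$n_taxa, 0, cfg$phase_mode_sd_h)) %% 24
    phylum <- ifelse(mode == 1, "Phylum_day", "Phylum_night")
    fam <- sprintf("Family_%02d", 1 + (seq_len(cfg$n_taxa) %% 20))
    taxa_truth <- data.frame(
      taxon = taxa, baseline = baseline,
      rhythmic_control = rhythmic_control,
      rhythmic_knockout = rhythmic_knockout,
      amplitude_control = amp,
      amplitude_knockout = ifelse(rhythmic_knockout, amp, 0),
      phase_h = phase, phylum = phylum, family = fam,
      stringsAsFactors = FALSE)
    # couple metabolites to clock-controlled (control-only rhythmic) taxa,
    # preferring abundant ones so the coupling survives count sampling
    loss_taxa <- taxa[rhythmic_control & !rhythmic_knockout]
    loss_taxa <- loss_taxa[order(-baseline[match(loss_taxa, taxa)])]
    met <- sprintf("metabolite_%02d", seq_len(cfg$n_metabolites))
    if (cfg$coupling_strength > 0 && length(loss_taxa) > 0) {
      coupled_taxon <- rep_len(loss_taxa, cfg$n_metabolites)
      weight <- rep_len(c(1, -1), cfg$n_metabolites)
    } else {
      coupled_taxon <- rep(NA_character_, cfg$n_metabolites)
      weight <- rep(0, cfg$n_metabolites)
    }
    couplings <- data.frame(metabolite = met, taxon = coupled_taxon,
                            weight = weight, stringsAsFactors = FALSE)
    structure(list(taxa = taxa_truth, couplings = couplings,
                   load = list(baseline = cfg$total_load_baseline,
                               amplitude = cfg$total_load_amplitude,
                               phase_h = cfg$total_load_phase_h),
                   config = cfg),
              class = "synth_truth")
  })

  tt <- truth$taxa
  sim <- with_seed(derive_seed(cfg$seed, "samples"), {
    grid <- expand.grid(time_h = cfg$timepoints_h,
                        subject = seq_len(cfg$n_subjects_per_timepoint),
                        group = cfg$groups, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid$subject_id <- paste0(substr(grid$group, 1, 2), "_s",
                              sprintf("%02d", grid$subject))
    grid$sample_id <- paste0(grid$subject_id, "_t",
                             sprintf("%02d", grid$time_h))
    n_samp <- nrow(grid)
    subj_ids <- unique(grid$subject_id)
    u <- stats::setNames(stats::rnorm(length(subj_ids), 0, cfg$subject_sd),
                         subj_ids)
    is_ctrl <- grid$group == cfg$groups[1]
    amp_mat <- outer(rep(1, n_samp), tt$amplitude_control)
    amp_mat[!is_ctrl, ] <- matrix(tt$amplitude_knockout, sum(!is_ctrl),
                                  cfg$n_taxa, byrow = TRUE)
    cos_term <- cos(2 * pi * outer(grid$time_h, tt$phase_h, "-") / 24)
    log_ab <- matrix(tt$baseline, n_samp, cfg$n_taxa, byrow = TRUE) +
      u[grid$subject_id] + amp_mat * cos_term +
      matrix(stats::rnorm(n_samp * cfg$n_taxa, 0, cfg$noise_sd),
             n_samp, cfg$n_taxa)
    prop <- exp(log_ab)
    prop <- prop / rowSums(prop)
    load <- cfg$total_load_baseline *
      (1 + cfg$total_load_amplitude *
         cos(2 * pi * (grid$time_h - cfg$total_load_phase_h) / 24))
    mass <- stats::runif(n_samp, cfg$mass_g_range[1], cfg$mass_g_range[2])
    bact_copies <- load * mass
    spike_share <- cfg$spike_copies / (cfg$spike_copies + bact_copies)
    lib <- round(stats::rlnorm(n_samp, cfg$library_size_logmean,
                               cfg$library_size_logsd))
    counts <- matrix(0L, n_samp, cfg$n_taxa + 1,
                     dimnames = list(grid$sample_id, c(tt$taxon, "SPIKE_std")))
    for (s in seq_len(n_samp)) {
      pvec <- c(prop[s, ] * (1 - spike_share[s]), spike_share[s])
      counts[s, ] <- as.integer(stats::rmultinom(1, lib[s], pvec))
    }
    meta <- data.frame(sample_id = grid$sample_id,
                       subject_id = grid$subject_id,
                       time_h = grid$time_h, group = grid$group,
                       condition = "LD", mass_g = mass,
                       spike_copies = cfg$spike_copies,
                       stringsAsFactors = FALSE)
    list(counts = counts, meta = meta, prop = prop, load = load)
  })

  ct <- count_table(sim$counts, spike_ids = "SPIKE_std")
  meta <- validate_metadata(sim$meta)
  taxonomy <- data.frame(taxon_id = tt$taxon, kingdom = "Bacteria",
                         phylum = tt$phylum,
                         class = paste0(tt$phylum, "_class"),
                         order = paste0(tt$phylum, "_order"),
                         family = tt$family,
                         genus = sub("zOTU", "Genus", tt$taxon),
                         stringsAsFactors = FALSE)
  tree <- generate_tree(tt$taxon, seed = derive_seed(cfg$seed, "tree"))
  rel <- relative_abundance(ct)
  metabolites <- generate_metabolites(rel, truth, cfg)
  truth$expected_load_per_g <- stats::setNames(sim$load, rownames(sim$counts))
  list(counts = ct, meta = meta, taxonomy = taxonomy, tree = tree,
       metabolites = metabolites, truth = truth)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("synth_truth:", nrow(x$taxa), "taxa;",
      sum(x$taxa$rhythmic_control), "rhythmic in control,",
      sum(x$taxa$rhythmic_knockout), "in knockout;",
      sum(x$couplings$weight != 0), "metabolite coupling(s)\n")
  invisible(x)
}
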