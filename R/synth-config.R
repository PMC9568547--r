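#' Configuration for the synthetic study generator
#'
#' Describes a two-group, repeated-measures circadian microbiome study:
#' subjects sampled every 3 hours across a 24-h day, a fixed fraction of taxa
#' rhythmic in the control group of which a fraction retains rhythmicity in
#' the clock-deficient group, a rhythmic total bacterial load, one aggregate
#' artificial spike-in standard per sample, and a metabolite panel coupled to
#' clock-controlled taxa. All quantities on the log scale are natural logs.
#'
#' @param n_taxa number of bacterial taxa (default 580).
#' @param timepoints_h sampling times in hours (default 1, 4, ..., 22, i.e. a
#'   3-h grid over the 24-h day).
#' @param n_subjects_per_timepoint subjects per group; each subject is
#'   sampled at every time point (repeated measures), so this is also the
#'   replicate count per time point (default 6).
#' @param groups two group labels, reference first (default control,
#'   knockout).
#' @param frac_rhythmic_control fraction of taxa rhythmic in the control
#'   group (default 0.60).
#' @param frac_retained_knockout fraction of control-rhythmic taxa that stay
#'   rhythmic in the knockout (default 1/3); the knockout rhythmic set is a
#'   subset of the control rhythmic set.
#' @param amplitude_log_range range of per-taxon log-scale cosine amplitudes
#'   (default 0.75-1.5, i.e. roughly 2-4.5 fold peak-to-trough).
#' @param phase_modes_h peak-phase cluster centers (default ZT6 and ZT18,
#'   mimicking day- and night-peaking communities).
#' @param phase_mode_sd_h within-cluster phase spread (default 1.5 h).
#' @param phase_mode_weights mixture weights for the phase modes.
#' @param baseline_logmean_sd SD of taxon log-baselines (default 1.0).
#' @param subject_sd subject random-effect SD on the log scale (default 0.15).
#' @param noise_sd residual log-scale SD (default 0.30).
#' @param total_load_baseline mean total 16S copies per gram (default 5e9).
#' @param total_load_amplitude relative amplitude of the total-load cosine
#'   (default 0.3).
#' @param total_load_phase_h peak phase of the total load (default 18).
#' @param library_size_logmean,library_size_logsd log-normal sequencing depth
#'   parameters (defaults log(1e5) and 0.2).
#' @param spike_copies copies of the artificial standard added per sample
#'   (default 1e8).
#' @param mass_g_range fecal sample mass range in grams (default 0.02-0.05).
#' @param n_metabolites number of metabolites in the panel (default 8).
#' @param coupling_strength target |Spearman| between a coupled
#'   taxon-metabolite pair (default 0.7); 0 means no couplings.
#' @param seed integer seed; fully determines the generated dataset.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 580,
                         timepoints_h = seq(1, 22, by = 3),
                         n_subjects_per_timepoint = 6,
                         groups = c("control", "knockout"),
                         frac_rhythmic_control = 0.60,
                         frac_retained_knockout = 1 / 3,
                         amplitude_log_range = c(0.75, 1.5),
                         phase_modes_h = c(6, 18),
                         phase_mode_sd_h = 1.5,
                         phase_mode_weights = c(0.5, 0.5),
                         baseline_logmean_sd = 1.0,
                         subject_sd = 0.15,
                         noise_sd = 0.30,
                         total_load_baseline = 5e9,
                         total_load_amplitude = 0.3,
                         total_load_phase_h = 18,
                         library_size_logmean = log(1e5),
                         library_size_logsd = 0.2,
                         spike_copies = 1e8,
                         mass_g_range = c(0.02, 0.05),
                         n_metabolites = 8,
                         coupling_strength = 0.7,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_taxa < 2) abort_located("n_taxa must be >= 2")
  if (length(cfg$timepoints_h) == 0) abort_located("timepoints_h must be non-empty")
  if (any(cfg$timepoints_h < 0 | cfg$timepoints_h >= 24))
    abort_located("timepoints_h must lie in [0, 24)")
  for (f in c("frac_rhythmic_control", "frac_retained_knockout"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      abort_located(f, " must be in [0, 1]")
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1)
    abort_located("coupling_strength must be in [0, 1]")
  if (any(cfg$amplitude_log_range < 0) || cfg$total_load_amplitude < 0)
    abort_located("amplitudes must be >= 0")
  if (length(cfg$groups) != 2) abort_located("exactly two groups are supported")
  if (cfg$total_load_amplitude >= 1)
    abort_located("total_load_amplitude must be < 1 (load stays positive)")
  if (any(cfg$mass_g_range <= 0)) abort_located("mass_g_range must be > 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_taxa, "taxa,", length(x$timepoints_h),
      "time points x", x$n_subjects_per_timepoint, "subjects x 2 groups;",
      sprintf("%.0f%% rhythmic, %.0f%% retained; seed %d\n",
              100 * x$frac_rhythmic_control, 100 * x$frac_retained_knockout,
              x$seed))
  invisible(x)
}
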