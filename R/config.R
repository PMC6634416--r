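#' Canonical cytoarchitectonic ROI labels
#'
#' The 13 cytoarchitectonic regions of interest (cROIs) of human
#' occipitotemporal cortex in canonical posterior-to-anterior label order.
#' Rank 1 is hOc1 (striate cortex) and rank 13 is FG4 on the fusiform gyrus.
#'
#' @return Character vector of length 13.
#' @export
croi_labels <- function() {
  c("hOc1", "hOc2", "hOc3v", "hOc3d", "hOc4v", "hOc4d",
    "hOc4lp", "hOc4la", "hOc5", "FG1", "FG2", "FG3", "FG4")
}

# default per-cROI tissue-sample counts (total 331, hOc5 carries only 2)
.default_roi_counts <- function() {
  c(90L, 50L, 35L, 25L, 20L, 15L, 12L, 12L, 2L, 18L, 18L, 17L, 17L)
}

.default_stages <- function() {
  c("10-12 pcw", "13-18 pcw", "19-24 pcw", "25-38 pcw",
    "0-5 mos", "6 mos-5 yrs", "6-18 yrs", "19-40 yrs")
}

#' Configuration for the synthetic data generators
#'
#' Collects every tunable of the synthetic-data module in one validated
#' object.  The defaults define the reference simulation: 20,000 genes of
#' which 200 carry a planted expression gradient (140 ascending, 60
#' descending), 331 tissue samples from 6 donors spread unevenly over 13
#' cROIs (hOc5 receives only 2), log-normal baseline intensities, 1-3
#' microarray probes per gene with a fraction lacking annotation, donor
#' offsets and Gaussian measurement noise.
#'
#' The planted signal of gene j in a sample from the ROI of canonical rank
#' r is `g_j * effect_size * (r - (n_rois+1)/2) + u_jr`, where `g_j` is +1
#' (ascending), -1 (descending) or 0 (null), and `u_jr` is a gene-specific
#' regional deviation with standard deviation `effect_size * profile_curve`
#' drawn once per planted gene and ROI.  The deviation term models the
#' idiosyncratic, non-linear component of real regional expression profiles;
#' it scales with `effect_size` so that `effect_size = 0` yields a fully
#' null dataset.
#'
#' @param n_rois Number of cROIs (default 13).
#' @param roi_labels Labels; defaults to [croi_labels()] when `n_rois` is 13.
#' @param roi_sample_counts Samples per ROI; default uneven, total 331.
#' @param n_donors Number of donors (default 6).
#' @param n_genes Number of genes (default 20000).
#' @param n_ascending,n_descending Planted gradient gene counts (140 / 60).
#' @param effect_size Expression units per hierarchy step (default 0.25).
#' @param profile_curve Ratio of the gene-by-ROI deviation sd to
#'   `effect_size` (default 1.6).
#' @param noise_sd Probe-level Gaussian noise sd (default 1).
#' @param donor_sd Sd of per-donor per-gene offsets (default 0.3).
#' @param probes_per_gene Integer range (min, max) of probes per gene.
#' @param unannotated_probe_fraction Fraction of null-gene probes written
#'   without gene symbol / Entrez ID (default 0.05).
#' @param centroid_spacing_mm Spacing of ROI centroids along the
#'   posterior-anterior axis (default 8 mm).
#' @param cloud_sd_mm Isotropic sd of each ROI's spatial point cloud; clouds
#'   are truncated so nearest-centroid assignment stays correct.
#' @param n_cloud_points Spatial representatives per ROI (default 20).
#' @param n_subjects Subjects in the anatomy dataset (default 100).
#' @param thickness_base,thickness_step Cortical thickness mean at rank 1
#'   and increment per rank (mm).
#' @param thickness_sd Per-cell thickness noise sd (mm).
#' @param t1t2_base,t1t2_step,t1t2_sd Same for the T1w/T2w ratio
#'   (dimensionless, decreasing with rank).
#' @param stages Ordered developmental stage labels.
#' @param flip_stage Index of the stage at which the descending gradient's
#'   developmental slope changes sign (default 3, i.e. 19-24 pcw).
#' @param dev_donors_per_stage Donors per developmental stage (default 3).
#' @param dev_slope_ascending Late-minus-early expression difference (RPKM)
#'   of ascending genes at every stage (default 2).
#' @param dev_slope_desc_early,dev_slope_desc_late Descending-gene slopes
#'   before and from the flip stage (defaults 1.5 and -2).
#' @param dev_noise_sd Developmental measurement noise sd (RPKM).
#' @param mac_n_early,mac_n_late Macaque tissue samples in early (V1+V2)
#'   and late (TE) visual cortex (35 + 17 = 52).
#' @param mac_n_layers Cortical layers per macaque sample (default 6).
#' @param mapped_fraction Probability that a human gradient gene has a
#'   macaque homolog (default 0.765, i.e. about 75% mapped).
#' @param mac_margin Group-mean late-minus-early expression margin (RPKM).
#' @param mac_slope_sd Between-gene sd of macaque slopes; large enough that
#'   individual genes show mixed slope signs within a group.
#' @param mac_noise_sd,mac_layer_sd Macaque sample- and layer-level noise.
#' @param seed Integer seed; all generators derive their streams from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_rois = 13L,
                         roi_labels = NULL,
                         roi_sample_counts = NULL,
                         n_donors = 6L,
                         n_genes = 20000L,
                         n_ascending = 140L,
                         n_descending = 60L,
                         effect_size = 0.25,
                         profile_curve = 1.6,
                         noise_sd = 1,
                         donor_sd = 0.3,
                         probes_per_gene = c(1L, 3L),
                         unannotated_probe_fraction = 0.05,
                         centroid_spacing_mm = 8,
                         cloud_sd_mm = 1.5,
                         n_cloud_points = 20L,
                         n_subjects = 100L,
                         thickness_base = 1.9,
                         thickness_step = 0.07,
                         thickness_sd = 0.15,
                         t1t2_base = 1.9,
                         t1t2_step = -0.045,
                         t1t2_sd = 0.08,
                         stages = .default_stages(),
                         flip_stage = 3L,
                         dev_donors_per_stage = 3L,
                         dev_slope_ascending = 2,
                         dev_slope_desc_early = 1.5,
                         dev_slope_desc_late = -2,
                         dev_noise_sd = 0.5,
                         mac_n_early = 35L,
                         mac_n_late = 17L,
                         mac_n_layers = 6L,
                         mapped_fraction = 0.765,
                         mac_margin = 0.5,
                         mac_slope_sd = 1,
                         mac_noise_sd = 0.5,
                         mac_layer_sd = 0.3,
                         seed = 1L) {
  cfg <- list(
    n_rois = as.integer(n_rois), roi_labels = roi_labels,
    roi_sample_counts = roi_sample_counts, n_donors = as.integer(n_donors),
    n_genes = as.integer(n_genes), n_ascending = as.integer(n_ascending),
    n_descending = as.integer(n_descending), effect_size = effect_size,
    profile_curve = profile_curve, noise_sd = noise_sd, donor_sd = donor_sd,
    probes_per_gene = as.integer(probes_per_gene),
    unannotated_probe_fraction = unannotated_probe_fraction,
    centroid_spacing_mm = centroid_spacing_mm, cloud_sd_mm = cloud_sd_mm,
    n_cloud_points = as.integer(n_cloud_points),
    n_subjects = as.integer(n_subjects),
    thickness_base = thickness_base, thickness_step = thickness_step,
    thickness_sd = thickness_sd, t1t2_base = t1t2_base,
    t1t2_step = t1t2_step, t1t2_sd = t1t2_sd,
    stages = stages, flip_stage = as.integer(flip_stage),
    dev_donors_per_stage = as.integer(dev_donors_per_stage),
    dev_slope_ascending = dev_slope_ascending,
    dev_slope_desc_early = dev_slope_desc_early,
    dev_slope_desc_late = dev_slope_desc_late,
    dev_noise_sd = dev_noise_sd,
    mac_n_early = as.integer(mac_n_early), mac_n_late = as.integer(mac_n_late),
    mac_n_layers = as.integer(mac_n_layers),
    mapped_fraction = mapped_fraction, mac_margin = mac_margin,
    mac_slope_sd = mac_slope_sd, mac_noise_sd = mac_noise_sd,
    mac_layer_sd = mac_layer_sd, seed = as.integer(seed)
  )
  if (is.null(cfg$roi_labels)) {
    cfg$roi_labels <- if (cfg$n_rois == 13L) croi_labels() else
      sprintf("R%02d", seq_len(cfg$n_rois))
  }
  if (is.null(cfg$roi_sample_counts)) {
    cfg$roi_sample_counts <- if (cfg$n_rois == 13L) .default_roi_counts() else
      rep(10L, cfg$n_rois)
  }
  cfg$roi_sample_counts <- as.integer(cfg$roi_sample_counts)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  counts <- c(n_rois = cfg$n_rois, n_donors = cfg$n_donors,
              n_genes = cfg$n_genes, n_subjects = cfg$n_subjects,
              n_cloud_points = cfg$n_cloud_points,
              dev_donors_per_stage = cfg$dev_donors_per_stage,
              mac_n_early = cfg$mac_n_early, mac_n_late = cfg$mac_n_late,
              mac_n_layers = cfg$mac_n_layers)
  bad <- counts <= 0L | is.na(counts)
  if (any(bad)) stop_cfg(paste(names(counts)[bad], collapse = ", "),
                         " must be positive")
  if (cfg$n_rois < 2L) stop_cfg("n_rois must be at least 2")
  if (cfg$n_ascending < 0L || cfg$n_descending < 0L)
    stop_cfg("gradient gene counts must be non-negative")
  if (cfg$n_ascending + cfg$n_descending > cfg$n_genes)
    stop_cfg("n_ascending + n_descending exceeds n_genes")
  if (length(cfg$roi_sample_counts) != cfg$n_rois)
    stop_cfg("roi_sample_counts length must equal n_rois")
  if (any(cfg$roi_sample_counts <= 0L))
    stop_cfg("roi_sample_counts must all be positive")
  if (length(cfg$roi_labels) != cfg$n_rois ||
      anyDuplicated(cfg$roi_labels) > 0L)
    stop_cfg("roi_labels must be n_rois unique labels")
  if (length(cfg$probes_per_gene) != 2L ||
      cfg$probes_per_gene[1] < 1L ||
      cfg$probes_per_gene[2] < cfg$probes_per_gene[1])
    stop_cfg("probes_per_gene must be an increasing positive range")
  sds <- c(noise_sd = cfg$noise_sd, donor_sd = cfg$donor_sd,
           thickness_sd = cfg$thickness_sd, t1t2_sd = cfg$t1t2_sd,
           dev_noise_sd = cfg$dev_noise_sd, mac_noise_sd = cfg$mac_noise_sd,
           mac_layer_sd = cfg$mac_layer_sd, mac_slope_sd = cfg$mac_slope_sd,
           cloud_sd_mm = cfg$cloud_sd_mm)
  bad <- sds < 0 | is.na(sds)
  if (any(bad)) stop_cfg(paste(names(sds)[bad], collapse = ", "),
                         " must be non-negative")
  if (cfg$unannotated_probe_fraction < 0 || cfg$unannotated_probe_fraction >= 1)
    stop_cfg("unannotated_probe_fraction must lie in [0, 1)")
  if (cfg$mapped_fraction <= 0 || cfg$mapped_fraction > 1)
    stop_cfg("mapped_fraction must lie in (0, 1]")
  if (length(cfg$stages) < 3L)
    stop_cfg("at least 3 developmental stages are required")
  if (cfg$flip_stage < 1L || cfg$flip_stage > length(cfg$stages))
    stop_cfg("flip_stage outside the stage range")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  %d cROIs, %d samples, %d donors\n",
              x$n_rois, sum(x$roi_sample_counts), x$n_donors))
  cat(sprintf("  %d genes (%d ascending + %d descending planted)\n",
              x$n_genes, x$n_ascending, x$n_descending))
  cat(sprintf("  effect %.3g per step, noise sd %.3g, donor sd %.3g, seed %d\n",
              x$effect_size, x$noise_sd, x$donor_sd, x$seed))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param cfg A `synth_config` object.
#' @param path File path.
#' @return `read_config_yaml` returns a `synth_config`.
#' @export
write_config_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}
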