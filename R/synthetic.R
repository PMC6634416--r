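# Synthetic-data generators.  Every generator seeds its own RNG stream from
# config$seed (plus a fixed per-generator offset) so that datasets are
# reproducible individually and jointly.

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

.gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# Planted gradient membership is drawn from its own stream so that the
# expression, developmental and macaque generators agree on which genes are
# planted without sharing state.
.planted_membership <- function(cfg) {
  genes <- .gene_ids(cfg$n_genes)
  membership <- rep("null", cfg$n_genes)
  names(membership) <- genes
  n_pl <- cfg$n_ascending + cfg$n_descending
  if (n_pl > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(.derive_seed(cfg$seed, 101L))
    planted <- sample(genes, n_pl)
    membership[planted[seq_len(cfg$n_ascending)]] <- "ascending"
    if (cfg$n_descending > 0L)
      membership[planted[cfg$n_ascending + seq_len(cfg$n_descending)]] <-
        "descending"
  }
  membership
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cROI atlas
#'
#' Places `n_rois` region centroids along the posterior-anterior (MNI y)
#' axis with strictly increasing coordinates, assigns canonical ranks
#' 1..n_rois in centroid order, and surrounds each centroid with a small
#' isotropic Gaussian point cloud of spatial representatives.  Clouds are
#' truncated at 45% of the smallest inter-centroid distance so that
#' nearest-representative assignment recovers the generating ROI for
#' effectively all points.
#'
#' @param config A [synth_config()].
#' @return A `croi_atlas`: list with `regions` (roi_label, rank, centroid
#'   coordinates in mm) and `points` (roi_label, x, y, z).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.derive_seed(config$seed, 0L))
  R <- config$n_rois
  sp <- config$centroid_spacing_mm
  cy <- -95 + (seq_len(R) - 1L) * sp + stats::runif(R, -0.1 * sp, 0.1 * sp)
  cx <- stats::rnorm(R, 0, 0.25 * sp)
  cz <- stats::rnorm(R, 0, 0.25 * sp)
  cent <- cbind(x = cx, y = cy, z = cz)
  dmin <- min(stats::dist(cent))
  trunc_r <- min(0.45 * dmin, 2.5 * config$cloud_sd_mm)
  pts <- do.call(rbind, lapply(seq_len(R), function(r) {
    p <- .rtrunc_ball(config$n_cloud_points, config$cloud_sd_mm, trunc_r)
    data.frame(roi_label = config$roi_labels[r],
               x = cent[r, 1] + p[, 1], y = cent[r, 2] + p[, 2],
               z = cent[r, 3] + p[, 3])
  }))
  structure(list(
    regions = data.frame(roi_label = config$roi_labels, rank = seq_len(R),
                         centroid_x = cx, centroid_y = cy, centroid_z = cz),
    points = pts, trunc_radius_mm = trunc_r
  ), class = "croi_atlas")
}

# isotropic gaussian triplets rejected outside radius r (resampled)
.rtrunc_ball <- function(n, sd, r) {
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  while (length(need) > 0L) {
    p <- matrix(stats::rnorm(3 * length(need), 0, sd), ncol = 3)
    ok <- sqrt(rowSums(p^2)) <= r
    out[need[ok], ] <- p[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' @export
print.croi_atlas <- function(x, ...) {
  cat(sprintf("cROI atlas: %d regions, %d spatial representatives\n",
              nrow(x$regions), nrow(x$points)))
  invisible(x)
}

#' Generate a synthetic AHBA-style expression dataset
#'
#' Emulates the Allen-Human-Brain-Atlas microarray triplet: a probe
#' annotation table, a sample annotation table with MNI coordinates and
#' donor IDs, and a probe x sample expression matrix.  Probe-level
#' expression of gene j in sample i from ROI rank r is
#'
#'   baseline_j + g_j * effect_size * (r - (n_rois+1)/2) + u_jr
#'     + donor_offset(donor_i, j) + noise,
#'
#' with `g_j` = +1/-1/0 for ascending/descending/null genes, `u_jr` a
#' gene-specific regional deviation (sd `effect_size * profile_curve`,
#' planted genes only), baselines log-normal, and independent Gaussian
#' probe noise.  Genes carry 1-3 probes; a configured fraction of
#' null-gene probes is written without gene symbol or Entrez ID so that
#' annotation filtering never removes planted signal.
#'
#' @param config A [synth_config()].
#' @param atlas The matching [generate_atlas()] result.
#' @return List with `probes` (probe_id, gene_symbol, entrez_id),
#'   `samples` (sample_id, donor_id, mni_x/y/z), `expression`
#'   (probe x sample matrix) and `truth` (a `ground_truth`: planted
#'   membership, ROI ranks, true ROI per sample, effect size, seed).
#' @export
generate_expression_dataset <- function(config, atlas) {
  stopifnot(inherits(config, "synth_config"), inherits(atlas, "croi_atlas"))
  if (sum(config$roi_sample_counts) == 0L)
    stop("invalid config: roi_sample_counts sum to 0", call. = FALSE)
  membership <- .planted_membership(config)
  set.seed(.derive_seed(config$seed, 1L))

  R <- config$n_rois
  G <- config$n_genes
  genes <- names(membership)
  g_sign <- c(ascending = 1, descending = -1, null = 0)[membership]
  ranks_centered <- seq_len(R) - (R + 1) / 2

  counts <- config$roi_sample_counts
  N <- sum(counts)
  roi_idx <- rep(seq_len(R), counts)
  donor_id <- sprintf("D%02d", sample(rep_len(seq_len(config$n_donors), N)))
  sample_id <- sprintf("S%04d", seq_len(N))

  # sample coordinates: near the ROI point cloud (same truncated gaussian)
  offs <- .rtrunc_ball(N, config$cloud_sd_mm, atlas$trunc_radius_mm)
  cent <- as.matrix(atlas$regions[, c("centroid_x", "centroid_y", "centroid_z")])
  coords <- cent[roi_idx, , drop = FALSE] + offs
  samples <- data.frame(sample_id = sample_id, donor_id = donor_id,
                        mni_x = coords[, 1], mni_y = coords[, 2],
                        mni_z = coords[, 3])

  baseline <- stats::rlnorm(G, meanlog = 2, sdlog = 0.7)
  curve_sd <- config$effect_size * config$profile_curve
  curve <- matrix(0, G, R)
  planted <- membership != "null"
  if (any(planted) && curve_sd > 0)
    curve[planted, ] <- stats::rnorm(sum(planted) * R, 0, curve_sd)
  donor_off <- matrix(stats::rnorm(G * config$n_donors, 0, config$donor_sd),
                      G, config$n_donors)
  donor_idx <- as.integer(factor(donor_id,
                                 levels = sprintf("D%02d",
                                                  seq_len(config$n_donors))))

  # gene-level mean per sample
  mu <- outer(g_sign * config$effect_size, ranks_centered)[, roi_idx] +
    curve[, roi_idx, drop = FALSE] + donor_off[, donor_idx, drop = FALSE] +
    baseline

  # probes
  k <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
              G, replace = TRUE)
  probe_gene <- rep(seq_len(G), k)
  n_probe <- length(probe_gene)
  probe_id <- sprintf("P%06d", seq_len(n_probe))
  expr <- mu[probe_gene, , drop = FALSE]
  if (config$noise_sd > 0)
    expr <- expr + stats::rnorm(length(expr), 0, config$noise_sd)
  dimnames(expr) <- list(probe_id, sample_id)

  gene_symbol <- genes[probe_gene]
  entrez_id <- as.character(10000L + probe_gene)
  # unannotated probes come only from null genes (never hide planted signal)
  null_probes <- which(!planted[probe_gene])
  n_blank <- round(config$unannotated_probe_fraction * n_probe)
  if (n_blank > 0L && length(null_probes) > 0L) {
    blank <- sample(null_probes, min(n_blank, length(null_probes)))
    gene_symbol[blank] <- ""
    entrez_id[blank] <- ""
  }
  probes <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       entrez_id = entrez_id)

  truth <- structure(list(
    membership = membership,
    roi_rank = stats::setNames(seq_len(R), config$roi_labels),
    sample_roi = stats::setNames(config$roi_labels[roi_idx], sample_id),
    effect_size = config$effect_size, seed = config$seed
  ), class = "ground_truth")

  list(probes = probes, samples = samples, expression = expr, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d ascending, %d descending, %d null genes\n",
              sum(x$membership == "ascending"),
              sum(x$membership == "descending"),
              sum(x$membership == "null")))
  invisible(x)
}

#' Generate a synthetic anatomy dataset
#'
#' Subject x ROI table of mean cortical thickness (mm, increasing linearly
#' with canonical rank) and mean T1w/T2w ratio (dimensionless, decreasing
#' with rank), with independent Gaussian noise per cell.
#'
#' @param config A [synth_config()].
#' @param n_subjects Override for the number of subjects.
#' @return Data frame with columns subject, roi_label, rank, thickness, t1t2.
#' @export
generate_anatomy_dataset <- function(config, n_subjects = config$n_subjects) {
  stopifnot(inherits(config, "synth_config"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L)
    stop("invalid config: n_subjects must be at least 2", call. = FALSE)
  set.seed(.derive_seed(config$seed, 2L))
  R <- config$n_rois
  grid <- expand.grid(subject = sprintf("sub%04d", seq_len(n_subjects)),
                      rank = seq_len(R), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$roi_label <- config$roi_labels[grid$rank]
  th_mu <- config$thickness_base + config$thickness_step * (grid$rank - 1L)
  t1_mu <- config$t1t2_base + config$t1t2_step * (grid$rank - 1L)
  grid$thickness <- th_mu + stats::rnorm(nrow(grid), 0, config$thickness_sd)
  grid$t1t2 <- t1_mu + stats::rnorm(nrow(grid), 0, config$t1t2_sd)
  grid[, c("subject", "roi_label", "rank", "thickness", "t1t2")]
}

#' Generate a synthetic developmental expression series
#'
#' Stage x donor x region (early / late visual cortex) x gene RPKM-like
#' table for the planted gradient genes, emulating a developmental
#' transcriptome.  Ascending genes have a positive late-minus-early slope
#' at every stage; descending genes have a positive slope before the
#' configured flip stage and a negative slope from it onwards.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns stage, stage_index, donor, region
#'   ("early"/"late"), gene, gradient, rpkm.
#' @export
generate_developmental_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  membership <- .planted_membership(config)
  planted <- membership[membership != "null"]
  if (length(planted) == 0L)
    stop("invalid config: no planted gradient genes", call. = FALSE)
  set.seed(.derive_seed(config$seed, 3L))

  genes <- names(planted)
  n_st <- length(config$stages)
  base <- stats::setNames(stats::rlnorm(length(genes), 1.5, 0.5), genes)
  grid <- expand.grid(gene = genes, region = c("early", "late"),
                      donor = seq_len(config$dev_donors_per_stage),
                      stage_index = seq_len(n_st),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$stage <- config$stages[grid$stage_index]
  grid$donor <- sprintf("B%02d_%02d", grid$stage_index, grid$donor)
  grid$gradient <- planted[grid$gene]
  slope <- ifelse(grid$gradient == "ascending", config$dev_slope_ascending,
                  ifelse(grid$stage_index < config$flip_stage,
                         config$dev_slope_desc_early,
                         config$dev_slope_desc_late))
  grid$rpkm <- base[grid$gene] + (grid$region == "late") * slope
  if (config$dev_noise_sd > 0)
    grid$rpkm <- grid$rpkm + stats::rnorm(nrow(grid), 0, config$dev_noise_sd)
  grid[, c("stage", "stage_index", "donor", "region", "gene",
           "gradient", "rpkm")]
}

#' Generate a synthetic macaque expression dataset
#'
#' Emulates a non-human-primate atlas extract: a partial human-to-macaque
#' homolog map covering about `mapped_fraction` of the human gradient
#' genes, and region x layer x gene expression over tissue samples from
#' V1, V2 (early visual cortex) and TE (late visual cortex), six layers
#' per sample.  Per-gene early-to-late slopes are drawn with mixed signs
#' within each human gradient group (sd `mac_slope_sd`), centred so each
#' group's realized mean slope equals `mac_margin` exactly.
#'
#' @param config A [synth_config()].
#' @param ground_truth The `truth` element of
#'   [generate_expression_dataset()] (defines the human gradient genes).
#' @return List with `homolog_map` (human_gene, macaque_gene) and
#'   `expression` (long data frame: sample_id, region, layer, gene, rpkm,
#'   where gene is the human symbol of the mapped homolog).
#' @export
generate_macaque_dataset <- function(config, ground_truth) {
  stopifnot(inherits(config, "synth_config"),
            inherits(ground_truth, "ground_truth"))
  planted <- ground_truth$membership[ground_truth$membership != "null"]
  if (length(planted) == 0L)
    stop("invalid input: ground truth has no gradient genes", call. = FALSE)
  set.seed(.derive_seed(config$seed, 4L))

  genes <- names(planted)
  mapped <- stats::runif(length(genes)) <= config$mapped_fraction
  homolog_map <- data.frame(
    human_gene = genes[mapped],
    macaque_gene = paste0("mmul_", tolower(genes[mapped]))
  )
  mg <- genes[mapped]
  if (length(mg) == 0L)
    stop("invalid input: no genes mapped to macaque homologs", call. = FALSE)
  mgrad <- planted[mg]

  # per-gene slopes, centred within gradient group so the group mean slope
  # is exactly mac_margin
  slope <- stats::rnorm(length(mg), 0, config$mac_slope_sd)
  for (gr in unique(mgrad)) {
    i <- mgrad == gr
    slope[i] <- slope[i] - mean(slope[i]) + config$mac_margin
  }
  base <- stats::rlnorm(length(mg), 1.5, 0.5)

  n_v1 <- ceiling(config$mac_n_early / 2)
  region <- c(rep("V1", n_v1), rep("V2", config$mac_n_early - n_v1),
              rep("TE", config$mac_n_late))
  n_samp <- length(region)
  sample_id <- sprintf("M%03d", seq_len(n_samp))
  late <- region == "TE"

  # sample-level value per (gene, sample), then layer-level replicates
  val <- base + outer(slope, as.numeric(late))
  if (config$mac_noise_sd > 0)
    val <- val + matrix(stats::rnorm(length(mg) * n_samp, 0,
                                     config$mac_noise_sd),
                        length(mg), n_samp)
  grid <- expand.grid(gene = mg, sample = seq_len(n_samp),
                      layer = seq_len(config$mac_n_layers),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rpkm <- val[cbind(match(grid$gene, mg), grid$sample)]
  if (config$mac_layer_sd > 0)
    grid$rpkm <- grid$rpkm + stats::rnorm(nrow(grid), 0, config$mac_layer_sd)
  expr <- data.frame(sample_id = sample_id[grid$sample],
                     region = region[grid$sample],
                     layer = grid$layer, gene = grid$gene,
                     rpkm = grid$rpkm)
  list(homolog_map = homolog_map, expression = expr)
}
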