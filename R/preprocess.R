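# Preprocessing: probe -> gene collapsing, donor-wise z-scoring, spatial
# assignment of tissue samples to cROIs, ANOVA grouping, per-cROI averaging.

#' Filter unannotated probes and collapse to gene level
#'
#' Removes probes lacking a gene symbol or an Entrez ID, then averages the
#' expression profiles of all probes targeting the same gene (unweighted
#' arithmetic mean).
#'
#' @param probe_expression Numeric matrix, probes x samples, rownames =
#'   probe IDs.
#' @param probe_table Data frame with columns probe_id, gene_symbol,
#'   entrez_id (empty string or NA meaning unannotated).
#' @return Gene x sample matrix, rownames = gene symbols.
#' @export
filter_and_collapse_probes <- function(probe_expression, probe_table) {
  stopifnot(is.matrix(probe_expression),
            all(c("probe_id", "gene_symbol", "entrez_id") %in%
                  names(probe_table)))
  if (anyDuplicated(probe_table$probe_id) > 0L)
    stop("invalid input: duplicate probe IDs in probe table", call. = FALSE)
  if (anyDuplicated(rownames(probe_expression)) > 0L)
    stop("invalid input: duplicate probe rows in expression matrix",
         call. = FALSE)
  idx <- match(rownames(probe_expression), probe_table$probe_id)
  if (anyNA(idx))
    stop("invalid input: expression rows missing from probe table",
         call. = FALSE)
  annotated <- function(x) !is.na(x) & nzchar(as.character(x))
  keep <- annotated(probe_table$gene_symbol[idx]) &
    annotated(probe_table$entrez_id[idx])
  if (!any(keep))
    stop("no probes survive annotation filtering", call. = FALSE)
  expr <- probe_expression[keep, , drop = FALSE]
  gene <- as.character(probe_table$gene_symbol[idx][keep])
  sums <- rowsum(expr, group = gene)
  n <- as.vector(table(gene)[rownames(sums)])
  sums / n
}

#' Z-score expression separately within each donor
#'
#' For every donor and every gene, centres and scales that donor's samples
#' to mean 0 and sample standard deviation 1 (n - 1 denominator).  Genes
#' with zero variance within a donor are set to 0 for that donor so the
#' gene set stays identical across donors.
#'
#' @param gene_matrix Gene x sample numeric matrix.
#' @param donor_ids Donor label per sample (length = ncol).
#' @return Matrix of the same shape, z-scored within donor.
#' @export
zscore_by_donor <- function(gene_matrix, donor_ids) {
  stopifnot(is.matrix(gene_matrix), length(donor_ids) == ncol(gene_matrix))
  donor_ids <- as.character(donor_ids)
  out <- gene_matrix
  for (d in unique(donor_ids)) {
    cols <- which(donor_ids == d)
    if (length(cols) < 2L)
      stop("donor ", d, " has fewer than 2 samples; cannot z-score",
           call. = FALSE)
    block <- gene_matrix[, cols, drop = FALSE]
    m <- rowMeans(block)
    s <- sqrt(rowSums((block - m)^2) / (length(cols) - 1L))
    z <- (block - m) / s
    z[s == 0, ] <- 0
    out[, cols] <- z
  }
  out
}

#' Assign tissue samples to cROIs by Euclidean distance
#'
#' Each sample is assigned to the ROI owning its nearest spatial
#' representative (both hemispheres pooled; coordinates used as given).
#' Distance ties break towards the ROI of lower canonical rank, making the
#' assignment deterministic and independent of sample order.
#'
#' @param sample_table Data frame with sample_id, mni_x, mni_y, mni_z.
#' @param atlas A `croi_atlas`.
#' @param max_distance_mm Optional exclusion radius; samples farther than
#'   this from every representative are dropped.
#' @return Data frame: sample_id, roi_label, rank, distance_mm.
#' @export
assign_samples_to_crois <- function(sample_table, atlas,
                                    max_distance_mm = NULL) {
  stopifnot(inherits(atlas, "croi_atlas"),
            all(c("sample_id", "mni_x", "mni_y", "mni_z") %in%
                  names(sample_table)))
  if (nrow(atlas$points) == 0L)
    stop("atlas has no spatial representatives", call. = FALSE)
  coords <- as.matrix(sample_table[, c("mni_x", "mni_y", "mni_z")])
  if (!all(is.finite(coords)))
    stop("invalid input: non-finite sample coordinates", call. = FALSE)
  pts <- as.matrix(atlas$points[, c("x", "y", "z")])
  pt_rank <- atlas$regions$rank[match(atlas$points$roi_label,
                                      atlas$regions$roi_label)]
  # squared distances samples x points
  d2 <- outer(rowSums(coords^2), rowSums(pts^2), "+") -
    2 * coords %*% t(pts)
  d2[d2 < 0] <- 0
  # per sample: min distance to any point of each ROI
  roi_of <- integer(nrow(coords))
  dist_of <- numeric(nrow(coords))
  ranks <- sort(unique(pt_rank))
  dmin <- sapply(ranks, function(r)
    apply(d2[, pt_rank == r, drop = FALSE], 1, min))
  dmin <- matrix(dmin, nrow = nrow(coords))
  best <- apply(dmin, 1, function(row) {
    # tolerance-free exact tie-break: which.min returns the first (lowest
    # rank) among exact ties because columns are ordered by rank
    which.min(row)
  })
  roi_of <- ranks[best]
  dist_of <- sqrt(dmin[cbind(seq_len(nrow(dmin)), best)])
  out <- data.frame(
    sample_id = sample_table$sample_id,
    roi_label = atlas$regions$roi_label[match(roi_of, atlas$regions$rank)],
    rank = roi_of, distance_mm = dist_of
  )
  if (!is.null(max_distance_mm))
    out <- out[out$distance_mm <= max_distance_mm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# canonical four-group partition used by the gene-selection ANOVA
.croi_groups <- function() {
  list(`1` = "hOc1",
       `2` = c("hOc2", "hOc3v", "hOc3d"),
       `3` = c("hOc4v", "hOc4d", "hOc4lp", "hOc4la"),
       `4` = c("FG1", "FG2", "FG3", "FG4"))
}

#' Group cROIs into the four ANOVA neighbourhoods
#'
#' The 13 cROIs are pooled into four cytoarchitectonic neighbourhoods with
#' approximately equal sample counts for the gene-selection ANOVA: hOc1;
#' hOc2 with the hOc3 areas; the hOc4 areas; and FG1-FG4.  hOc5 samples
#' are flagged as excluded (too few samples) but retained in the table.
#'
#' @param assignment Output of [assign_samples_to_crois()].
#' @return The assignment with added columns `group` (factor "1".."4",
#'   NA for excluded) and `excluded` (logical).
#' @export
group_crois <- function(assignment) {
  stopifnot(all(c("sample_id", "roi_label") %in% names(assignment)))
  groups <- .croi_groups()
  known <- c(unlist(groups), "hOc5")
  bad <- setdiff(unique(assignment$roi_label), known)
  if (length(bad) > 0L)
    stop("unknown ROI label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lookup <- rep(names(groups), lengths(groups))
  names(lookup) <- unlist(groups)
  out <- assignment
  out$group <- factor(lookup[out$roi_label], levels = names(groups))
  out$excluded <- out$roi_label == "hOc5"
  out
}

#' Average expression within each cROI
#'
#' Builds the ROI x gene matrix of mean expression: entry (i, j) is the
#' mean of gene j over all samples assigned to ROI i (all donors, both
#' hemispheres pooled).  Rows are ordered by canonical rank.
#'
#' @param normalized_matrix Gene x sample matrix (donor z-scored).
#' @param assignment Output of [assign_samples_to_crois()].
#' @param gene_subset Optional character vector of genes to keep (order
#'   preserved).
#' @param atlas Optional `croi_atlas`; when supplied, every atlas ROI must
#'   have at least one assigned sample (error otherwise).
#' @return ROI x gene matrix, rownames = roi labels in rank order.
#' @export
croi_mean_matrix <- function(normalized_matrix, assignment,
                             gene_subset = NULL, atlas = NULL) {
  stopifnot(is.matrix(normalized_matrix),
            all(c("sample_id", "roi_label", "rank") %in% names(assignment)))
  keep <- intersect(assignment$sample_id, colnames(normalized_matrix))
  a <- assignment[match(keep, assignment$sample_id), , drop = FALSE]
  X <- normalized_matrix[, keep, drop = FALSE]
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(X))
    if (length(missing) > 0L)
      stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "), call. = FALSE)
    X <- X[gene_subset, , drop = FALSE]
  }
  rois <- unique(a[order(a$rank), c("roi_label", "rank")])
  if (!is.null(atlas)) {
    empty <- setdiff(atlas$regions$roi_label, a$roi_label)
    if (length(empty) > 0L)
      stop("ROI(s) with zero samples: ", paste(empty, collapse = ", "),
           call. = FALSE)
  }
  out <- t(sapply(rois$roi_label, function(r) {
    cols <- which(a$roi_label == r)
    rowMeans(X[, cols, drop = FALSE])
  }))
  rownames(out) <- rois$roi_label
  colnames(out) <- rownames(X)
  out
}
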