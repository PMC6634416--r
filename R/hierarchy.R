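# Rooted-leaf transcriptomic hierarchy of cROIs, ordering bootstrap, and the
# leave-one-out winner-take-all tissue-origin classifier.

#' Mean expression profile of each gradient across cROIs
#'
#' Z-scores each gene across ROIs and averages over the genes of each
#' gradient, giving the ROI-wise mean ascending and descending profiles.
#'
#' @param croi_means ROI x gene matrix (rows in canonical rank order).
#' @param partition A `gradient_partition` or named membership vector
#'   covering the matrix columns.
#' @return ROI x 2 matrix with columns ascending, descending.
#' @export
mean_gradient_profiles <- function(croi_means, partition) {
  membership <- if (inherits(partition, "gradient_partition"))
    partition$membership else partition
  stopifnot(is.matrix(croi_means),
            all(names(membership) %in% colnames(croi_means)))
  Z <- .zscore_cols(croi_means[, names(membership), drop = FALSE])
  out <- vapply(c("ascending", "descending"), function(gr) {
    cols <- names(membership)[membership == gr]
    if (length(cols) == 0L)
      stop("empty gradient: ", gr, call. = FALSE)
    rowMeans(Z[, cols, drop = FALSE])
  }, numeric(nrow(Z)))
  rownames(out) <- rownames(croi_means)
  out
}

#' Rooted-leaf WPGMA dendrogram of cROIs
#'
#' Agglomerative clustering of the ROI expression profiles (Euclidean
#' distance, WPGMA linkage) with a deterministic leaf arrangement that
#' makes the left-to-right leaf order meaningful: at every merge, the
#' child whose member set contains the ROI closest (Euclidean distance of
#' its full expression profile) to the anchor ROI is placed on the left.
#' The anchor is therefore always the leftmost leaf, and the leaf order
#' reflects transcriptomic distance from the anchor -- the leaves are
#' "rooted" and not freely rotatable.  Exact ties (duplicate profiles)
#' break towards the lower canonical rank.
#'
#' @param croi_means ROI x gene matrix restricted to the selected genes,
#'   rownames = ROI labels in canonical rank order.
#' @param anchor Label of the anchor ROI (default "hOc1").
#' @return A `croi_hierarchy`: list with `ordering` (leaf labels left to
#'   right), `ordering_ranks` (canonical ranks in leaf order), `positions`
#'   (leaf position per label), `merge`, `heights`, `anchor`,
#'   `anchor_dist`, and the underlying `hclust` object (`tree`).
#' @export
rooted_leaf_dendrogram <- function(croi_means, anchor = "hOc1") {
  stopifnot(is.matrix(croi_means), !is.null(rownames(croi_means)))
  labels <- rownames(croi_means)
  if (!anchor %in% labels)
    stop("anchor ROI ", anchor, " not present", call. = FALSE)
  R <- nrow(croi_means)
  a_idx <- match(anchor, labels)
  anchor_dist <- sqrt(rowSums((croi_means -
                                 rep(croi_means[a_idx, ],
                                     each = R))^2))
  hc <- stats::hclust(stats::dist(croi_means), method = "mcquitty")
  if (any(diff(hc$height) < -1e-8))
    warning("WPGMA linkage has height inversions on these data")

  # deterministic rooted-leaf arrangement over the merge record
  node <- vector("list", R - 1L)
  leaf <- function(i) list(order = i, ad = anchor_dist[i], rank = i)
  get_child <- function(x) if (x < 0) leaf(-x) else node[[x]]
  for (m in seq_len(R - 1L)) {
    ch1 <- get_child(hc$merge[m, 1])
    ch2 <- get_child(hc$merge[m, 2])
    left_first <- ch1$ad < ch2$ad ||
      (ch1$ad == ch2$ad && ch1$rank < ch2$rank)
    left <- if (left_first) ch1 else ch2
    right <- if (left_first) ch2 else ch1
    node[[m]] <- list(order = c(left$order, right$order),
                      ad = min(left$ad, right$ad),
                      rank = min(left$rank, right$rank))
  }
  ord <- node[[R - 1L]]$order
  structure(list(
    ordering = labels[ord],
    ordering_ranks = ord,
    positions = stats::setNames(match(seq_len(R), ord), labels),
    merge = hc$merge, heights = hc$height,
    anchor = anchor,
    anchor_dist = stats::setNames(anchor_dist, labels),
    tree = hc
  ), class = "croi_hierarchy")
}

#' @export
print.croi_hierarchy <- function(x, ...) {
  cat("Rooted-leaf cROI hierarchy (anchor ", x$anchor, "):\n  ",
      paste(x$ordering, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Euclidean distance between two leaf orderings
#'
#' Orderings are integer vectors of canonical ranks in leaf order (or
#' `croi_hierarchy` objects); the distance is the plain Euclidean norm of
#' their difference, so identical orderings give 0.
#'
#' @param a,b Integer vectors or `croi_hierarchy` objects.
#' @return Non-negative number.
#' @export
ordering_distance <- function(a, b) {
  va <- if (inherits(a, "croi_hierarchy")) a$ordering_ranks else as.numeric(a)
  vb <- if (inherits(b, "croi_hierarchy")) b$ordering_ranks else as.numeric(b)
  stopifnot(length(va) == length(vb))
  sqrt(sum((va - vb)^2))
}

#' Bootstrap significance of the hierarchy ordering
#'
#' On every iteration the gene values are shuffled independently within
#' each cROI row of the matrix, the rooted-leaf dendrogram is rebuilt, and
#' the Euclidean distance between the resulting ordering vector and the
#' reference ordering is computed.  The p-value is the fraction of
#' iterations with distance exactly 0 (a chance reproduction of the full
#' ordering), displayed as "< 1/n_boot" when none occurs.
#'
#' @param croi_means ROI x gene matrix used to build the hierarchy.
#' @param hierarchy The `croi_hierarchy` built from the unshuffled matrix.
#' @param n_boot Iterations (default 10000).
#' @param seed Integer seed.
#' @return List with `p`, `p_display`, `n_zero`, `distances`, `n_boot`.
#' @export
ordering_significance <- function(croi_means, hierarchy, n_boot = 10000L,
                                  seed = 1L) {
  stopifnot(inherits(hierarchy, "croi_hierarchy"))
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  set.seed(.derive_seed(seed, 0L))
  ref <- hierarchy$ordering_ranks
  distances <- vapply(seq_len(n_boot), function(b) {
    Eb <- t(apply(croi_means, 1, sample))
    rownames(Eb) <- rownames(croi_means)
    hb <- rooted_leaf_dendrogram(Eb, anchor = hierarchy$anchor)
    ordering_distance(hb$ordering_ranks, ref)
  }, numeric(1))
  n_zero <- sum(distances == 0)
  p <- n_zero / n_boot
  list(p = p,
       p_display = if (n_zero == 0L) sprintf("< %g", 1 / n_boot) else
         format(p, digits = 3),
       n_zero = n_zero, distances = distances, n_boot = n_boot)
}

# correlation between paired columns of two equal-shaped matrices
.cor_pairs <- function(A, B) {
  n <- nrow(A)
  am <- colMeans(A); bm <- colMeans(B)
  Ac <- sweep(A, 2, am); Bc <- sweep(B, 2, bm)
  colSums(Ac * Bc) / sqrt(colSums(Ac^2) * colSums(Bc^2))
}

.rank_cols <- function(m) apply(m, 2, rank)

#' Leave-one-out winner-take-all origin classifier
#'
#' Each tissue sample is held out in turn; the expression fingerprint of
#' every cROI is the mean selected-gene vector over the remaining samples
#' of that ROI, and the held-out sample is assigned to the ROI whose
#' fingerprint correlates maximally with its own expression vector (ties
#' break to the lower canonical rank).  The error of a prediction is the
#' number of hierarchical steps between the predicted and the true ROI in
#' the rooted-leaf ordering.  The null distribution repeats the whole
#' cross-validation `n_boot_null` times with a single random permutation
#' of the gene labels applied to all fingerprints, recording the median
#' error of each repetition.
#'
#' Samples from an ROI with a single sample in total are skipped (their
#' fingerprint would be empty) and recorded in `skipped`.
#'
#' @param expr Selected-gene x sample matrix (donor z-scored).
#' @param assignment Output of [assign_samples_to_crois()].
#' @param hierarchy A `croi_hierarchy` giving leaf positions.
#' @param n_boot_null Null repetitions (default 1000; 0 skips the null).
#' @param seed Integer seed for the null permutations.
#' @param method "pearson" (default) or "spearman" winner-take-all
#'   correlation.
#' @return A `croi_classifier`: list with `results` (sample, true,
#'   predicted, step_error), `median_error`, `null_medians`, `skipped`,
#'   `n_boot_null`.
#' @export
loo_classify <- function(expr, assignment, hierarchy, n_boot_null = 1000L,
                         seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), inherits(hierarchy, "croi_hierarchy"))
  ids <- intersect(colnames(expr), assignment$sample_id)
  a <- assignment[match(ids, assignment$sample_id), , drop = FALSE]
  X <- expr[, ids, drop = FALSE]
  rois <- unique(a[order(a$rank), c("roi_label", "rank")])
  Rn <- nrow(rois)
  roi_idx <- match(a$roi_label, rois$roi_label)
  counts <- tabulate(roi_idx, nbins = Rn)

  skipped <- ids[counts[roi_idx] == 1L]
  if (length(skipped) > 0L)
    warning(length(skipped),
            " sample(s) from single-sample ROIs skipped in LOO")
  use <- counts[roi_idx] > 1L

  ind <- matrix(0, length(ids), Rn)
  ind[cbind(seq_along(ids), roi_idx)] <- 1
  S <- X %*% ind                                  # gene sums per ROI
  Fg <- sweep(S, 2, pmax(counts, 1L), "/")        # global fingerprints

  # per-ROI leave-one-out fingerprints for the samples of that ROI
  loo_fp <- lapply(seq_len(Rn), function(r) {
    idx <- which(roi_idx == r)
    if (counts[r] <= 1L) return(NULL)
    (S[, r] - X[, idx, drop = FALSE]) / (counts[r] - 1L)
  })

  classify_pass <- function(perm = NULL) {
    Fp <- if (is.null(perm)) Fg else Fg[perm, , drop = FALSE]
    Xc <- X; Fpc <- Fp
    if (method == "spearman") { Xc <- .rank_cols(X); Fpc <- .rank_cols(Fp) }
    C <- stats::cor(Xc, Fpc)                       # samples x ROIs
    for (r in seq_len(Rn)) {
      fp <- loo_fp[[r]]
      if (is.null(fp)) next
      fpp <- if (is.null(perm)) fp else fp[perm, , drop = FALSE]
      idx <- which(roi_idx == r)
      xi <- X[, idx, drop = FALSE]
      if (method == "spearman") { xi <- .rank_cols(xi); fpp <- .rank_cols(fpp) }
      C[idx, r] <- .cor_pairs(xi, fpp)
    }
    # which.max takes the first maximum: columns are in canonical rank
    # order, so exact ties break to the lower rank
    pred <- apply(C[use, , drop = FALSE], 1, which.max)
    pos_pred <- hierarchy$positions[rois$roi_label[pred]]
    pos_true <- hierarchy$positions[a$roi_label[use]]
    list(pred = pred, errors = abs(pos_pred - pos_true))
  }

  obs <- classify_pass()
  results <- data.frame(sample_id = ids[use], true = a$roi_label[use],
                        predicted = rois$roi_label[obs$pred],
                        step_error = as.integer(obs$errors),
                        row.names = NULL)

  null_medians <- numeric(0)
  if (n_boot_null > 0L) {
    set.seed(.derive_seed(seed, 0L))
    null_medians <- vapply(seq_len(n_boot_null), function(b)
      stats::median(classify_pass(perm = sample(nrow(X)))$errors),
      numeric(1))
  }
  structure(list(results = results,
                 median_error = stats::median(obs$errors),
                 null_medians = null_medians, skipped = skipped,
                 n_boot_null = as.integer(n_boot_null)),
            class = "croi_classifier")
}

#' @export
print.croi_classifier <- function(x, ...) {
  cat(sprintf(
    "LOO winner-take-all classifier: %d samples, median step error %g\n",
    nrow(x$results), x$median_error))
  if (length(x$null_medians) > 0)
    cat(sprintf("  shuffled-gene null: median of medians %g (n = %d)\n",
                stats::median(x$null_medians), x$n_boot_null))
  invisible(x)
}
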