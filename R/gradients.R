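# Gradient partition of selected genes and the bootstrap test of the
# two-gradient structure against a linear hypothesis matrix.

# z-score each column (gene) of an ROI x gene matrix across ROIs
.zscore_cols <- function(m) {
  z <- scale(m, center = TRUE, scale = TRUE)
  z[, attr(z, "scaled:scale") == 0] <- 0
  attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
  z
}

#' Partition selected genes into ascending and descending gradients
#'
#' Gene columns of the ROI x gene mean-expression matrix are z-scored
#' across ROIs, then clustered agglomeratively (Euclidean distance, WPGMA
#' linkage).  Cutting at the final merge yields two clusters; the cluster
#' whose mean ROI profile correlates positively with canonical rank is
#' labelled ascending, the other descending.  If both cluster profiles
#' correlate with rank in the same direction the gradient structure is
#' degenerate and an error is raised.
#'
#' @param croi_means ROI x gene matrix restricted to the selected genes,
#'   rows in canonical rank order.
#' @return A `gradient_partition`: list with `membership` (named vector,
#'   "ascending"/"descending"), `tree` (hclust), `zmatrix` (the z-scored
#'   matrix), `profiles` (ROI x 2 mean profile per gradient) and
#'   `height_ratio` (final merge height / second-to-last).
#' @export
cluster_genes <- function(croi_means) {
  stopifnot(is.matrix(croi_means), ncol(croi_means) >= 2L)
  Z <- .zscore_cols(croi_means)
  hc <- stats::hclust(stats::dist(t(Z)), method = "mcquitty")
  cl <- stats::cutree(hc, k = 2)
  ranks <- seq_len(nrow(Z))
  lab <- vapply(1:2, function(i) {
    prof <- rowMeans(Z[, cl == i, drop = FALSE])
    if (stats::sd(prof) == 0) return(NA_real_)
    stats::cor(prof, ranks)
  }, numeric(1))
  if (anyNA(lab) || all(lab > 0) || all(lab < 0))
    stop("degenerate gradient structure: both clusters trend in the same ",
         "direction", call. = FALSE)
  names_cl <- ifelse(lab > 0, "ascending", "descending")
  membership <- stats::setNames(names_cl[cl], colnames(Z))
  profiles <- cbind(
    ascending = rowMeans(Z[, membership == "ascending", drop = FALSE]),
    descending = rowMeans(Z[, membership == "descending", drop = FALSE]))
  rownames(profiles) <- rownames(Z)
  h <- sort(hc$height)
  ratio <- h[length(h)] / h[length(h) - 1L]
  structure(list(membership = membership, tree = hc, zmatrix = Z,
                 profiles = profiles, height_ratio = ratio),
            class = "gradient_partition")
}

#' @export
print.gradient_partition <- function(x, ...) {
  cat(sprintf(
    "Gradient partition: %d ascending, %d descending genes (top-merge ratio %.2f)\n",
    sum(x$membership == "ascending"), sum(x$membership == "descending"),
    x$height_ratio))
  invisible(x)
}

#' Build the linear hypothesis matrix
#'
#' One column per gene: a ramp over canonical ranks 1..n_rois, z-scored to
#' mean 0 / sample sd 1, multiplied by +1 for ascending genes and -1 for
#' descending genes.  This is the idealized expression pattern the
#' observed matrix is correlated against.
#'
#' @param partition A `gradient_partition`, or a named membership vector.
#' @param n_rois Number of ROIs (rows); must be at least 3.
#' @return ROI x gene matrix `H`.
#' @export
build_hypothesis_matrix <- function(partition, n_rois) {
  membership <- if (inherits(partition, "gradient_partition"))
    partition$membership else partition
  stopifnot(all(membership %in% c("ascending", "descending")))
  if (n_rois < 3L) stop("n_rois must be at least 3", call. = FALSE)
  ramp <- as.vector(scale(seq_len(n_rois)))
  signs <- ifelse(membership == "ascending", 1, -1)
  H <- outer(ramp, signs)
  colnames(H) <- names(membership)
  H
}

#' Bootstrap test of the gradient structure
#'
#' The observed statistic is the Pearson correlation between the flattened
#' observed (z-scored) expression matrix and the flattened hypothesis
#' matrix.  The null distribution is built by permuting the ROI axis of
#' the expression matrix (`n_boot` times) and recomputing the correlation;
#' by default a single permutation is applied jointly to the whole matrix,
#' with `per_gene = TRUE` shuffling each gene's column independently.
#' One-sided p = fraction of null correlations >= the observed one,
#' displayed as "< 1/n_boot" when no null value reaches it.
#'
#' Modes: `"full"` uses the complete matrices; `"subsample"` restricts
#' both matrices to a random fraction of the ROIs on every null iteration
#' (robustness to individual regions); `"exclude_extrema"` drops the
#' configured extreme ROIs from the observed correlation while evaluating
#' it against the full-shuffle null.
#'
#' @param E ROI x gene observed matrix, gene columns z-scored across ROIs.
#' @param H Hypothesis matrix of the same shape (see
#'   [build_hypothesis_matrix()]).
#' @param n_boot Number of bootstrap iterations (default 1000).
#' @param mode "full", "subsample" or "exclude_extrema".
#' @param seed Integer seed for the permutation stream.
#' @param subsample_frac Fraction of ROIs retained per iteration in
#'   subsample mode (default 0.75).
#' @param exclude ROI labels dropped in exclude_extrema mode.
#' @param per_gene Permute each gene independently instead of jointly.
#' @return A `gradient_test`: list with `r`, `p`, `p_display`, `null`,
#'   `mode`, `n_boot`, `seed`.
#' @export
gradient_correlation_test <- function(E, H, n_boot = 1000L,
                                      mode = c("full", "subsample",
                                               "exclude_extrema"),
                                      seed = 1L,
                                      subsample_frac = 0.75,
                                      exclude = c("hOc1", "hOc2", "FG4"),
                                      per_gene = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(E), is.matrix(H), all(dim(E) == dim(H)))
  if (stats::sd(as.vector(E)) == 0)
    stop("constant expression matrix: correlation undefined", call. = FALSE)
  R <- nrow(E)
  obs_rows <- seq_len(R)
  if (mode == "exclude_extrema") {
    drop <- which(rownames(E) %in% exclude)
    if (length(drop) == 0L)
      stop("none of the excluded ROIs found in the matrix", call. = FALSE)
    obs_rows <- setdiff(obs_rows, drop)
  }
  r_obs <- stats::cor(as.vector(E[obs_rows, , drop = FALSE]),
                      as.vector(H[obs_rows, , drop = FALSE]))

  set.seed(.derive_seed(seed, 0L))
  null <- vapply(seq_len(n_boot), function(b) {
    rows <- if (mode == "subsample")
      sort(sample(R, max(2L, round(subsample_frac * R)))) else seq_len(R)
    Eb <- if (per_gene)
      apply(E, 2, sample) else E[sample(R), , drop = FALSE]
    stats::cor(as.vector(Eb[rows, , drop = FALSE]),
               as.vector(H[rows, , drop = FALSE]))
  }, numeric(1))
  count <- sum(null >= r_obs)
  p <- count / n_boot
  p_display <- if (count == 0L) sprintf("< %g", 1 / n_boot) else
    format(p, digits = 3)
  structure(list(r = r_obs, p = p, p_display = p_display, null = null,
                 mode = mode, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "gradient_test")
}

#' @export
print.gradient_test <- function(x, ...) {
  cat(sprintf("Gradient test (%s): r = %.3f, p %s (n_boot = %d)\n",
              x$mode, x$r,
              if (startsWith(x$p_display, "<")) x$p_display else
                paste("=", x$p_display),
              x$n_boot))
  invisible(x)
}
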