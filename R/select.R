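# Gene selection: one-way ANOVA ranking across the four cROI neighbourhood
# groups, plus the PCA-based alternative on the full ROI-mean matrix.

#' Rank genes by one-way ANOVA across cROI groups
#'
#' For every gene a classical one-way fixed-effects ANOVA with the cROI
#' neighbourhood group as the single factor:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`, with the upper-tail p-value
#' from the F distribution.  Genes are ranked by ascending p, ties broken
#' by descending F and then by gene ID.  Computation is vectorised over
#' genes; it agrees with `stats::aov` gene by gene.
#'
#' @param normalized_matrix Gene x sample matrix (donor z-scored).
#' @param groups Either the data frame from [group_crois()] (excluded
#'   samples are dropped) or a factor/vector of group labels per column of
#'   the matrix (NA = drop).
#' @return A `gene_selection` object: data frame with gene, F, p, rank
#'   (plus k and df stored as attributes).
#' @export
anova_rank_genes <- function(normalized_matrix, groups) {
  stopifnot(is.matrix(normalized_matrix))
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    g <- groups$group[match(colnames(normalized_matrix), groups$sample_id)]
  } else {
    stopifnot(length(groups) == ncol(normalized_matrix))
    g <- groups
  }
  keep <- !is.na(g)
  X <- normalized_matrix[, keep, drop = FALSE]
  g <- factor(g[keep])
  k <- nlevels(g)
  N <- ncol(X)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)

  grand <- rowMeans(X)
  group_means <- vapply(levels(g), function(l)
    rowMeans(X[, g == l, drop = FALSE]), numeric(nrow(X)))
  ssb <- as.vector(group_means^2 %*% as.vector(sizes)) -
    N * grand^2
  sst <- rowSums(X^2) - N * grand^2
  ssw <- sst - ssb
  # guard tiny negative rounding
  ssw[ssw < 0 & ssw > -1e-10] <- 0
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  # a gene constant everywhere carries no evidence: F = 0, p = 1
  flat <- sst == 0
  Fstat[flat] <- 0
  p[flat] <- 1
  degenerate <- ssw == 0 & !flat
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with zero within-group variance; F set to Inf, p to 0")
    Fstat[degenerate] <- Inf
    p[degenerate] <- 0
  }
  genes <- rownames(X)
  ord <- order(p, -Fstat, genes)
  rank <- integer(length(p))
  rank[ord] <- seq_along(ord)
  res <- data.frame(gene = genes, F = Fstat, p = p, rank = rank,
                    row.names = NULL)
  structure(res, class = c("gene_selection", "data.frame"),
            k = k, df = c(k - 1L, N - k))
}

#' Select the top (or bottom) n genes of an ANOVA ranking
#'
#' The top set contains the `n_select` genes with the smallest p-values
#' (ties broken by descending F then gene ID); the bottom set the least
#' significant genes, used as the control for the comparison dendrogram.
#'
#' @param selection A `gene_selection` from [anova_rank_genes()].
#' @param n_select Number of genes (default 200, about 1% of the genome).
#' @param bottom If TRUE, return the least significant genes instead.
#' @return Character vector of gene IDs in rank order.
#' @export
select_top <- function(selection, n_select = 200L, bottom = FALSE) {
  stopifnot(inherits(selection, "gene_selection"))
  n_select <- as.integer(n_select)
  if (n_select <= 0L) stop("n_select must be positive", call. = FALSE)
  usable <- selection[is.finite(selection$p), , drop = FALSE]
  usable <- usable[order(usable$rank), , drop = FALSE]
  n_select <- min(n_select, nrow(usable))
  if (bottom) utils::tail(usable$gene, n_select) else
    utils::head(usable$gene, n_select)
}

#' PCA-based gradient gene selection
#'
#' Alternative to the ANOVA ranking: principal components of the ROI-space
#' covariance of the full ROI x gene mean-expression matrix (each gene
#' centred), per-gene Pearson correlation of its ROI profile with the
#' first-component scores, and gene groups split by correlation sign at a
#' ladder of -log10 p thresholds.  The sign of the first component is
#' fixed so that the highest-rank ROI (most anterior) scores non-negative.
#'
#' @param croi_means ROI x gene matrix over all genes (rows in rank order).
#' @param thresholds -log10 p thresholds for the stepwise grouping
#'   (default 3:12).
#' @return A `pca_selection`: list with `scores` (ROI scores per retained
#'   component), `var_explained`, `gene_cor` (gene, r, p) and `groups`
#'   (per threshold: positive / negative gene sets).
#' @export
pca_gradient_selection <- function(croi_means, thresholds = 3:12) {
  stopifnot(is.matrix(croi_means))
  R <- nrow(croi_means)
  if (ncol(croi_means) < R)
    stop("need at least as many genes as ROIs", call. = FALSE)
  centred <- scale(croi_means, center = TRUE, scale = FALSE)
  if (all(abs(centred) < 1e-12))
    stop("zero-variance matrix", call. = FALSE)
  pc <- stats::prcomp(croi_means, center = TRUE, scale. = FALSE)
  scores <- pc$x
  if (scores[R, 1] < 0) scores[, 1] <- -scores[, 1]
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)

  s1 <- scores[, 1]
  r <- as.vector(stats::cor(croi_means, s1))
  # two-sided p via the t transform with R - 2 df
  tt <- r * sqrt((R - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), R - 2, lower.tail = FALSE)
  gene_cor <- data.frame(gene = colnames(croi_means), r = r, p = p,
                         row.names = NULL)
  groups <- lapply(thresholds, function(th) {
    sig <- gene_cor$p <= 10^(-th)
    list(threshold = th,
         positive = gene_cor$gene[sig & gene_cor$r > 0],
         negative = gene_cor$gene[sig & gene_cor$r < 0])
  })
  names(groups) <- paste0("logp", thresholds)
  structure(list(scores = scores, var_explained = var_explained,
                 gene_cor = gene_cor, groups = groups),
            class = "pca_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("Gene selection: %d genes, %d groups, df = (%d, %d)\n",
              nrow(x), attr(x, "k"), attr(x, "df")[1], attr(x, "df")[2]))
  print.data.frame(utils::head(x[order(x$rank), ], 5))
  invisible(x)
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf("PCA selection: PC1 explains %.1f%% of ROI-space variance\n",
              100 * x$var_explained[1]))
  invisible(x)
}
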