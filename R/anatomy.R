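# Anatomy: thickness / T1w-T2w summaries, metric x cROI ANOVA, gradient
# correlations, nested regressions, and the hypergeometric marker overlap.

#' Summarize anatomy measurements per subject and cROI
#'
#' Validates a subject x ROI table of mean cortical thickness (mm) and
#' mean T1w/T2w ratio.  When several rows exist per (subject, ROI) --
#' vertex-level input -- they are averaged; per-ROI input passes through.
#' Every subject must cover all ROIs.
#'
#' @param anatomy Data frame with subject, roi_label, thickness, t1t2
#'   (optionally rank).
#' @return Data frame with one row per subject x ROI.
#' @export
summarize_anatomy <- function(anatomy) {
  stopifnot(all(c("subject", "roi_label", "thickness", "t1t2") %in%
                  names(anatomy)))
  if (!all(is.finite(anatomy$thickness)) || !all(is.finite(anatomy$t1t2)))
    stop("non-finite anatomy values", call. = FALSE)
  if (any(anatomy$thickness <= 0))
    stop("non-positive cortical thickness", call. = FALSE)
  rois <- unique(anatomy$roi_label)
  agg <- stats::aggregate(cbind(thickness, t1t2) ~ subject + roi_label,
                          data = anatomy, FUN = mean)
  tab <- table(agg$subject)
  bad <- names(tab)[tab < length(rois)]
  if (length(bad) > 0L) {
    s <- bad[1]
    miss <- setdiff(rois, agg$roi_label[agg$subject == s])
    stop("subject ", s, " missing ROI(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("rank" %in% names(anatomy))
    agg$rank <- anatomy$rank[match(agg$roi_label, anatomy$roi_label)]
  agg[order(agg$subject, agg$roi_label), , drop = FALSE]
}

#' Two-way ANOVA of anatomical metric by cROI
#'
#' Balanced fixed-effects two-way ANOVA with factors metric (thickness vs
#' T1w/T2w) and cROI, including their interaction.  Because the two
#' metrics live on different scales (mm vs dimensionless), each metric is
#' z-scored across all subject x ROI cells before the analysis.
#'
#' @param summary Output of [summarize_anatomy()].
#' @return Data frame of effects (term, df, F, p).
#' @export
metric_croi_anova <- function(summary) {
  long <- rbind(
    data.frame(subject = summary$subject, roi = summary$roi_label,
               metric = "thickness", value = summary$thickness),
    data.frame(subject = summary$subject, roi = summary$roi_label,
               metric = "t1t2", value = summary$t1t2))
  tab <- table(long$metric, long$roi)
  if (length(unique(as.vector(tab))) != 1L)
    stop("unbalanced design: unequal cell counts", call. = FALSE)
  for (m in unique(long$metric)) {
    i <- long$metric == m
    long$value[i] <- as.vector(scale(long$value[i]))
  }
  long$metric <- factor(long$metric)
  long$roi <- factor(long$roi)
  fit <- stats::aov(value ~ metric * roi, data = long)
  an <- stats::anova(fit)
  data.frame(term = rownames(an)[1:3], df = an$Df[1:3],
             F = an$`F value`[1:3], p = an$`Pr(>F)`[1:3],
             row.names = NULL)
}

#' Correlate gradient expression with anatomy across cROIs
#'
#' Pearson correlation (two-sided p from the t transform with n - 2 df)
#' between each gradient's mean ROI expression profile and each per-ROI
#' anatomical mean, across the 13 cROIs.
#'
#' @param gradient_means ROI x 2 matrix from [mean_gradient_profiles()].
#' @param summary Output of [summarize_anatomy()] (averaged over subjects).
#' @return Data frame: gradient, metric, r, p, n.
#' @export
gradient_anatomy_correlation <- function(gradient_means, summary) {
  stopifnot(is.matrix(gradient_means))
  roi_means <- stats::aggregate(cbind(thickness, t1t2) ~ roi_label,
                                data = summary, FUN = mean)
  rois <- rownames(gradient_means)
  idx <- match(rois, roi_means$roi_label)
  if (anyNA(idx)) stop("ROIs missing from anatomy summary", call. = FALSE)
  out <- expand.grid(gradient = colnames(gradient_means),
                     metric = c("thickness", "t1t2"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_list <- lapply(seq_len(nrow(out)), function(i) {
    x <- gradient_means[, out$gradient[i]]
    y <- roi_means[[out$metric[i]]][idx]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance in correlation input", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  })
  cbind(out, do.call(rbind, stats_list))
}

.model_report <- function(fit, label) {
  s <- summary(fit)
  co <- s$coefficients
  data.frame(model = label, term = rownames(co),
             estimate = co[, 1], t = co[, 3], p = co[, 4],
             r_squared = s$r.squared, row.names = NULL)
}

#' Predict cortical thickness from T1w/T2w and ascending expression
#'
#' Ordinary least squares across the 13 cROIs: the full model uses both
#' the T1w/T2w ratio and the ascending-gradient mean expression as
#' predictors of mean cortical thickness; the two single-predictor models
#' are reported alongside for the nested comparison (a transparent
#' stand-in for stepwise selection, which is degenerate with only two
#' candidate predictors).  A warning is recorded when the predictors are
#' nearly collinear.
#'
#' @param thickness,t1t2,ascending Numeric vectors over the cROIs (same
#'   order).
#' @return A `regression_report`: data frame of per-model coefficients, t,
#'   p and R-squared, with attribute `condition_number`.
#' @export
thickness_two_predictor_regression <- function(thickness, t1t2, ascending) {
  stopifnot(length(thickness) == length(t1t2),
            length(thickness) == length(ascending))
  d <- data.frame(thickness = thickness, t1t2 = t1t2, ascending = ascending)
  Xs <- scale(cbind(d$t1t2, d$ascending))
  kappa_val <- kappa(crossprod(Xs) / (nrow(d) - 1), exact = TRUE)
  if (kappa_val > 1e6)
    warning("predictors nearly collinear (condition number ",
            format(kappa_val, digits = 3), ")")
  full <- stats::lm(thickness ~ t1t2 + ascending, data = d)
  m_t1t2 <- stats::lm(thickness ~ t1t2, data = d)
  m_asc <- stats::lm(thickness ~ ascending, data = d)
  out <- rbind(.model_report(full, "t1t2+ascending"),
               .model_report(m_t1t2, "t1t2_only"),
               .model_report(m_asc, "ascending_only"))
  structure(out, class = c("regression_report", "data.frame"),
            condition_number = kappa_val)
}

#' Inter-regional distance versus hierarchy regression
#'
#' Tests whether inter-regional differences in descending-gradient
#' expression are explained by hierarchy (ascending-gradient differences)
#' over and above macroanatomical proximity.  Builds the signed pairwise
#' difference matrices (row minus column) of the two gradient means and
#' the Euclidean distance matrix of the ROI centroids, takes the 78
#' unordered pairs (upper triangle) as observations, and fits (1)
#' descending differences ~ ascending differences and (2) the same plus
#' centroid distance.
#'
#' @param centroids ROI x 3 matrix of MNI centroid coordinates (mm).
#' @param descending,ascending Mean gradient expression per ROI (same row
#'   order as `centroids`).
#' @return A `regression_report` covering both models, with the pair data
#'   in attribute `pairs`.
#' @export
distance_vs_hierarchy_regression <- function(centroids, descending,
                                             ascending) {
  centroids <- as.matrix(centroids)
  R <- nrow(centroids)
  stopifnot(length(descending) == R, length(ascending) == R)
  D <- as.matrix(stats::dist(centroids))
  if (all(D == 0))
    stop("degenerate centroids: all identical", call. = FALSE)
  up <- upper.tri(D)
  diff_mat <- function(v) outer(v, v, "-")
  pairs <- data.frame(
    desc_diff = diff_mat(descending)[up],
    asc_diff = diff_mat(ascending)[up],
    distance = D[up])
  m1 <- stats::lm(desc_diff ~ asc_diff, data = pairs)
  m2 <- stats::lm(desc_diff ~ asc_diff + distance, data = pairs)
  out <- rbind(.model_report(m1, "ascending_only"),
               .model_report(m2, "ascending+distance"))
  structure(out, class = c("regression_report", "data.frame"),
            pairs = pairs)
}

#' Hypergeometric overlap of a selected gene set with a marker set
#'
#' Given a universe of N genes containing K markers, and a selection of n
#' genes of which k are markers, reports the expected overlap nK/N, the
#' hypergeometric standard deviation, the number of standard deviations
#' above chance z = (k - nK/N) / sd, the upper-tail hypergeometric
#' p-value P(X >= k), and the overlap percentage 100 k / n.
#'
#' @param selected Character vector of selected genes.
#' @param markers Character vector of marker genes.
#' @param universe_size Total number of genes N in the universe.
#' @return An `overlap_report` list: N, K, n, k, expected, sd, z, p,
#'   percent.
#' @export
hypergeometric_overlap <- function(selected, markers, universe_size) {
  N <- as.numeric(universe_size)
  selected <- unique(as.character(selected))
  markers <- unique(as.character(markers))
  n <- length(selected)
  K <- length(markers)
  if (n > N || K > N)
    stop("sets larger than the universe", call. = FALSE)
  if (K == 0 || K == N)
    stop("degenerate marker set (K = 0 or K = N): sd is 0", call. = FALSE)
  if (n == 0 || n == N)
    stop("degenerate selected set (n = 0 or n = N): sd is 0", call. = FALSE)
  k <- length(intersect(selected, markers))
  expected <- n * K / N
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  z <- (k - expected) / sqrt(v)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, expected = expected,
                 sd = sqrt(v), z = z, p = p, percent = 100 * k / n),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of n = %d (%.1f%%), expected %.2f\n",
    x$k, x$n, x$percent, x$expected))
  cat(sprintf("  z = %.1f sd above chance, p = %.3g\n", x$z, x$p))
  invisible(x)
}
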