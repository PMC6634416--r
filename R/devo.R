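# Developmental slope analysis (early vs late visual cortex across stages)
# and the cross-species macaque homolog slope analysis.

#' Developmental expression slopes per stage, donor and gradient
#'
#' The slope of a gradient at a developmental stage is the mean over its
#' genes of (late-region minus early-region expression), computed on
#' donor-level means: samples are first averaged per (stage, donor,
#' region, gene), then differenced, then averaged over the gradient's
#' genes.  Genes of the partition absent from the series are dropped with
#' a message; (stage, donor) pairs lacking one of the two regions are
#' excluded with a warning.
#'
#' @param series Long data frame with stage, stage_index, donor, region
#'   ("early"/"late"), gene, rpkm (see
#'   [generate_developmental_dataset()]).
#' @param partition A `gradient_partition` or named membership vector.
#' @return Data frame: stage, stage_index, donor, gradient, slope (RPKM).
#' @export
developmental_slopes <- function(series, partition) {
  membership <- if (inherits(partition, "gradient_partition"))
    partition$membership else partition
  membership <- membership[membership %in% c("ascending", "descending")]
  present <- names(membership) %in% unique(series$gene)
  if (any(!present))
    message(sum(!present), " partition gene(s) absent from the series")
  membership <- membership[present]
  if (length(membership) == 0L)
    stop("no partition genes present in the series", call. = FALSE)
  s <- series[series$gene %in% names(membership), , drop = FALSE]
  s$gradient <- membership[s$gene]
  # donor-level means per region and gene
  dm <- stats::aggregate(rpkm ~ stage + stage_index + donor + region +
                           gene + gradient, data = s, FUN = mean)
  wide <- stats::reshape(dm, direction = "wide",
                         idvar = c("stage", "stage_index", "donor",
                                   "gene", "gradient"),
                         timevar = "region")
  incomplete <- is.na(wide$rpkm.early) | is.na(wide$rpkm.late)
  if (any(incomplete)) {
    bad <- unique(wide[incomplete, c("stage", "donor")])
    warning(nrow(bad), " (stage, donor) pair(s) lacking a region excluded")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  wide$diff <- wide$rpkm.late - wide$rpkm.early
  out <- stats::aggregate(diff ~ stage + stage_index + donor + gradient,
                          data = wide, FUN = mean)
  names(out)[names(out) == "diff"] <- "slope"
  out[order(out$stage_index, out$donor, out$gradient), , drop = FALSE]
}

#' Two-way ANOVA of developmental slopes
#'
#' Fixed-effects two-way ANOVA of the donor-level slopes with gradient
#' (gene cluster) and developmental stage as factors, reporting both main
#' effects and the gradient x stage interaction.
#'
#' @param slope_table Output of [developmental_slopes()].
#' @return Data frame of effects (term, df, F, p).
#' @export
slope_interaction_anova <- function(slope_table) {
  st <- slope_table
  st$gradient <- factor(st$gradient)
  st$stage <- factor(st$stage, levels = unique(st$stage[order(st$stage_index)]))
  if (nlevels(st$stage) < 2L)
    stop("need at least 2 stages", call. = FALSE)
  cell <- table(st$gradient, st$stage)
  if (any(cell < 2L))
    stop("need at least 2 donors per gradient x stage cell", call. = FALSE)
  fit <- stats::aov(slope ~ gradient * stage, data = st)
  an <- stats::anova(fit)
  data.frame(term = rownames(an)[1:3], df = an$Df[1:3],
             F = an$`F value`[1:3], p = an$`Pr(>F)`[1:3],
             row.names = NULL)
}

#' Earliest stage at which the two gradients diverge in slope sign
#'
#' Scans the ordered stages for the first one whose mean descending slope
#' is negative while the mean ascending slope is positive.
#'
#' @param slope_table Output of [developmental_slopes()].
#' @return List with `stage` (label, or "none") and `index` (NA if none).
#' @export
crossover_stage <- function(slope_table) {
  means <- stats::aggregate(slope ~ stage + stage_index + gradient,
                            data = slope_table, FUN = mean)
  wide <- stats::reshape(means, direction = "wide",
                         idvar = c("stage", "stage_index"),
                         timevar = "gradient")
  wide <- wide[order(wide$stage_index), , drop = FALSE]
  hit <- which(wide$slope.descending < 0 & wide$slope.ascending > 0)
  if (length(hit) == 0L) return(list(stage = "none", index = NA_integer_))
  list(stage = wide$stage[hit[1]], index = wide$stage_index[hit[1]])
}

#' Macaque homolog expression slopes and group t-tests
#'
#' For every human gradient gene with a macaque homolog: expression is
#' averaged over the six cortical layers per tissue sample, the early
#' value is the mean over V1 and V2 samples, the late value the mean over
#' TE samples, and the normalized slope is late minus early (so the
#' normalized early value is 0 by construction).  For each human gradient
#' group, tissue-sample-level group means (mean over the group's genes
#' per sample) are compared early versus late with a pooled-variance
#' two-sample t-test; per-gene slope signs are tallied.
#'
#' @param macaque Output of [generate_macaque_dataset()]: list with
#'   `homolog_map` and long `expression`.
#' @param partition A `gradient_partition` or named membership vector for
#'   the human genes.
#' @return A `macaque_slopes` list: `gene_slopes` (gene, gradient, early,
#'   late, slope), `tests` (gradient, t, df, p, mean_early, mean_late,
#'   n_positive, n_negative).
#' @export
macaque_gradient_slopes <- function(macaque, partition) {
  membership <- if (inherits(partition, "gradient_partition"))
    partition$membership else partition
  membership <- membership[membership %in% c("ascending", "descending")]
  expr <- macaque$expression
  mapped <- intersect(names(membership),
                      intersect(macaque$homolog_map$human_gene,
                                unique(expr$gene)))
  for (gr in c("ascending", "descending")) {
    if (!any(membership[mapped] == gr))
      stop("no mapped genes for the ", gr, " gradient", call. = FALSE)
  }
  e <- expr[expr$gene %in% mapped, , drop = FALSE]
  e$phase <- ifelse(e$region %in% c("V1", "V2"), "early", "late")
  if (length(unique(e$sample_id[e$phase == "early"])) < 2L ||
      length(unique(e$sample_id[e$phase == "late"])) < 2L)
    stop("need at least 2 samples in each of early and late visual cortex",
         call. = FALSE)
  # layer-averaged sample-level values
  sl <- stats::aggregate(rpkm ~ sample_id + phase + gene, data = e,
                         FUN = mean)
  gene_phase <- stats::aggregate(rpkm ~ gene + phase, data = sl, FUN = mean)
  gw <- stats::reshape(gene_phase, direction = "wide", idvar = "gene",
                       timevar = "phase")
  gene_slopes <- data.frame(gene = gw$gene,
                            gradient = unname(membership[gw$gene]),
                            early = gw$rpkm.early, late = gw$rpkm.late,
                            slope = gw$rpkm.late - gw$rpkm.early,
                            row.names = NULL)

  tests <- do.call(rbind, lapply(c("ascending", "descending"), function(gr) {
    genes_gr <- names(membership)[membership == gr]
    slg <- sl[sl$gene %in% genes_gr, , drop = FALSE]
    per_sample <- stats::aggregate(rpkm ~ sample_id + phase, data = slg,
                                   FUN = mean)
    early <- per_sample$rpkm[per_sample$phase == "early"]
    late <- per_sample$rpkm[per_sample$phase == "late"]
    dfree <- length(early) + length(late) - 2L
    pooled_var <- ((length(early) - 1) * stats::var(early) +
                     (length(late) - 1) * stats::var(late)) / dfree
    if (pooled_var == 0) {
      # degenerate noiseless input: equal means carry no evidence
      delta <- mean(late) - mean(early)
      tval <- if (delta == 0) 0 else sign(delta) * Inf
      pval <- if (delta == 0) 1 else 0
    } else {
      tt <- stats::t.test(late, early, var.equal = TRUE)
      tval <- unname(tt$statistic)
      pval <- tt$p.value
    }
    gs <- gene_slopes[gene_slopes$gradient == gr, , drop = FALSE]
    data.frame(gradient = gr, t = tval,
               df = dfree, p = pval,
               mean_early = mean(early), mean_late = mean(late),
               n_positive = sum(gs$slope > 0), n_negative = sum(gs$slope < 0),
               row.names = NULL)
  }))
  structure(list(gene_slopes = gene_slopes, tests = tests),
            class = "macaque_slopes")
}

#' @export
print.macaque_slopes <- function(x, ...) {
  cat("Macaque homolog slope analysis\n")
  print.data.frame(x$tests, digits = 3)
  invisible(x)
}

#' Homolog map coverage per gradient
#'
#' Counts how many genes of each gradient have a macaque homolog and how
#' many are missing from the map.
#'
#' @param partition A `gradient_partition` or named membership vector.
#' @param homolog_map Data frame with human_gene, macaque_gene.
#' @return Data frame: gradient, mapped, missing.
#' @export
homolog_coverage <- function(partition, homolog_map) {
  membership <- if (inherits(partition, "gradient_partition"))
    partition$membership else partition
  membership <- membership[membership %in% c("ascending", "descending")]
  mapped <- names(membership) %in% homolog_map$human_gene
  out <- do.call(rbind, lapply(c("ascending", "descending"), function(gr) {
    i <- membership == gr
    data.frame(gradient = gr, mapped = sum(mapped & i),
               missing = sum(!mapped & i), row.names = NULL)
  }))
  rbind(out, data.frame(gradient = "total", mapped = sum(mapped),
                        missing = sum(!mapped)))
}
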