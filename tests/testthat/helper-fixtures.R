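# Shared fixtures and independent oracles for the test suite.

# desk-scale configuration: same 13-ROI structure (hOc5 keeps 2 samples),
# fewer genes and samples
small_config <- function(seed = 11L, ...) {
  args <- list(
    n_genes = 800L, n_ascending = 40L, n_descending = 20L,
    roi_sample_counts = c(12L, 10L, 8L, 8L, 6L, 6L, 5L, 5L, 2L,
                          6L, 6L, 5L, 5L),
    n_donors = 4L, probes_per_gene = c(1L, 2L), seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

# run generation + preprocessing + selection and return all intermediates
run_pipeline <- function(cfg, n_select = 60L) {
  atlas <- generate_atlas(cfg)
  sim <- generate_expression_dataset(cfg, atlas)
  expr <- filter_and_collapse_probes(sim$expression, sim$probes)
  zmat <- zscore_by_donor(expr, sim$samples$donor_id)
  asg <- assign_samples_to_crois(sim$samples, atlas)
  grp <- group_crois(asg)
  grp$group[grp$excluded] <- NA
  sel <- anova_rank_genes(zmat, grp)
  top <- select_top(sel, n_select)
  cm <- croi_mean_matrix(zmat, asg, gene_subset = top, atlas = atlas)
  list(cfg = cfg, atlas = atlas, sim = sim, expr = expr, zmat = zmat,
       asg = asg, grp = grp, sel = sel, top = top, cm = cm)
}

# brute-force WPGMA: returns merge heights in merge order
bf_wpgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  active <- as.list(seq_len(n))
  dm <- D
  heights <- numeric(0)
  while (length(active) > 1L) {
    m <- length(active)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      if (dm[i, j] < best[1]) best <- c(dm[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    newd <- (dm[i, ] + dm[j, ]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- matrix(0, m - 1L, m - 1L)
    if (length(keep) > 0L) {
      dm2[seq_along(keep), seq_along(keep)] <- dm[keep, keep]
      dm2[m - 1L, seq_along(keep)] <- newd[keep]
      dm2[seq_along(keep), m - 1L] <- newd[keep]
    }
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    dm <- dm2
  }
  heights
}

# brute-force group-by mean of matrix columns
bf_group_mean <- function(X, groups) {
  out <- sapply(sort(unique(groups)), function(g)
    apply(X[, groups == g, drop = FALSE], 1, mean))
  colnames(out) <- sort(unique(groups))
  out
}
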