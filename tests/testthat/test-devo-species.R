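# Developmental slope analysis and the macaque homolog analysis.

make_dev_fixture <- function() {
  # 2 stages x 2 donors x 2 regions x 3 genes, exact values
  grid <- expand.grid(gene = c("g1", "g2", "g3"),
                      region = c("early", "late"),
                      donor = c("d1", "d2"), stage_index = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$stage <- paste0("st", grid$stage_index)
  base <- c(g1 = 5, g2 = 3, g3 = 4)
  slope <- ifelse(grid$gene == "g3",
                  ifelse(grid$stage_index == 1, 1, -2), 2)
  grid$rpkm <- base[grid$gene] + (grid$region == "late") * slope
  grid
}

dev_membership <- c(g1 = "ascending", g2 = "ascending", g3 = "descending")

test_that("developmental slopes equal brute-force mean differences", {
  fx <- make_dev_fixture()
  st <- developmental_slopes(fx, dev_membership)
  # brute force: per (stage, donor, gradient) mean late - early over genes
  for (i in seq_len(nrow(st))) {
    genes <- names(dev_membership)[dev_membership == st$gradient[i]]
    sub <- fx[fx$stage == st$stage[i] & fx$donor == st$donor[i] &
                fx$gene %in% genes, ]
    bf <- mean(sub$rpkm[sub$region == "late"]) -
      mean(sub$rpkm[sub$region == "early"])
    expect_equal(st$slope[i], bf, tolerance = 1e-12)
  }
  # single ascending gene with late - early = 2 -> slope 2
  expect_true(all(st$slope[st$gradient == "ascending"] == 2))
  # late = early everywhere -> all slopes 0
  flat <- fx; flat$rpkm <- 1
  st0 <- developmental_slopes(flat, dev_membership)
  expect_true(all(st0$slope == 0))
  # genes absent from the series are dropped with a message
  expect_message(
    developmental_slopes(fx, c(dev_membership, gX = "ascending")),
    "absent")
  # a (stage, donor) lacking one region is excluded with a warning
  broken <- fx[!(fx$stage == "st1" & fx$donor == "d1" &
                   fx$region == "late"), ]
  expect_warning(stb <- developmental_slopes(broken, dev_membership),
                 "excluded")
  expect_false(any(stb$stage == "st1" & stb$donor == "d1"))
})

test_that("slope ANOVA matches hand sums of squares and detects the flip", {
  fx <- make_dev_fixture()
  # add donor-level jitter so the within-cell variance is nonzero
  set.seed(2)
  st <- developmental_slopes(fx, dev_membership)
  st$slope <- st$slope + rnorm(nrow(st), 0, 0.1)
  res <- slope_interaction_anova(st)
  # oracle: balanced two-way decomposition by hand
  g <- mean(st$slope)
  ss_a <- sum(tapply(st$slope, st$gradient,
                     function(x) length(x) * (mean(x) - g)^2))
  ss_b <- sum(tapply(st$slope, st$stage,
                     function(x) length(x) * (mean(x) - g)^2))
  cellm <- tapply(st$slope, list(st$gradient, st$stage), mean)
  ss_cells <- sum(2 * (cellm - g)^2)
  ss_int <- ss_cells - ss_a - ss_b
  ss_err <- sum((st$slope - g)^2) - ss_cells
  f_int <- (ss_int / 1) / (ss_err / (nrow(st) - 4))
  expect_equal(res$F[res$term == "gradient:stage"], f_int,
               tolerance = 1e-10)
  # identical trajectories for both gradients -> interaction ~ 0
  st_same <- st
  st_same$slope <- ave(st_same$slope, st_same$stage, st_same$donor)
  res_same <- slope_interaction_anova(st_same)
  expect_lt(res_same$F[res_same$term == "gradient:stage"], 1e-10)
  # synthetic flip-stage data: interaction detected at p < 0.01
  cfg <- small_config(seed = 6)
  dev <- generate_developmental_dataset(cfg)
  truth <- generate_expression_dataset(cfg, generate_atlas(cfg))$truth
  st_syn <- developmental_slopes(dev, truth$membership)
  res_syn <- slope_interaction_anova(st_syn)
  expect_lt(res_syn$p[res_syn$term == "gradient:stage"], 0.01)
})

test_that("crossover stage finds the earliest sign divergence", {
  fx <- make_dev_fixture()
  st <- developmental_slopes(fx, dev_membership)
  cs <- crossover_stage(st)
  expect_equal(cs$stage, "st2")
  expect_equal(cs$index, 2)
  # descending slope positive at all stages -> "none"
  pos <- st; pos$slope <- abs(pos$slope)
  expect_equal(crossover_stage(pos)$stage, "none")
  # reference synthetic series: flip at the configured stage and a
  # positive ascending slope at the first stage
  cfg <- small_config(seed = 4)
  dev <- generate_developmental_dataset(cfg)
  truth <- generate_expression_dataset(cfg, generate_atlas(cfg))$truth
  st_syn <- developmental_slopes(dev, truth$membership)
  cs_syn <- crossover_stage(st_syn)
  expect_equal(cs_syn$index, cfg$flip_stage)
  first_asc <- st_syn$slope[st_syn$stage_index == 1 &
                              st_syn$gradient == "ascending"]
  expect_gt(mean(first_asc), 0)
})

make_mac_fixture <- function() {
  # 2 early (V1, V2) + 2 late (TE) samples, 2 layers, exact values
  grid <- expand.grid(gene = c("g1", "g3"), layer = 1:2,
                      sample_id = c("m1", "m2", "m3", "m4"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$region <- c(m1 = "V1", m2 = "V2", m3 = "TE", m4 = "TE")[grid$sample_id]
  base <- c(g1 = 2, g3 = 1)
  bump <- ifelse(grid$region == "TE", ifelse(grid$gene == "g1", 3, 1), 0)
  # layer structure that averages out
  grid$rpkm <- base[grid$gene] + bump + ifelse(grid$layer == 1, 0.5, -0.5)
  samp_off <- c(m1 = 0.2, m2 = -0.2, m3 = 0.1, m4 = -0.1)
  grid$rpkm <- grid$rpkm + samp_off[grid$sample_id]
  list(homolog_map = data.frame(human_gene = c("g1", "g3"),
                                macaque_gene = c("q1", "q3")),
       expression = grid[, c("sample_id", "region", "layer", "gene", "rpkm")])
}

test_that("macaque slopes and t-tests match hand computation", {
  fx <- make_mac_fixture()
  mem <- c(g1 = "ascending", g3 = "descending")
  res <- macaque_gradient_slopes(fx, mem)
  gs <- res$gene_slopes
  # hand: layer-averaged sample values, early mean vs late mean
  # g1: early samples 2.2, 1.8 -> 2; late 5.1, 4.9 -> 5; slope 3
  expect_equal(gs$slope[gs$gene == "g1"], 3, tolerance = 1e-12)
  expect_equal(gs$slope[gs$gene == "g3"], 1, tolerance = 1e-12)
  expect_equal(gs$early[gs$gene == "g1"], 2, tolerance = 1e-12)
  # pooled t on sample-level group means, hand-computed
  tt <- res$tests[res$tests$gradient == "ascending", ]
  early <- c(2.2, 1.8); late <- c(5.1, 4.9)
  sp <- sqrt((var(early) + var(late)) / 2)
  t_hand <- (mean(late) - mean(early)) / (sp * sqrt(1 / 2 + 1 / 2))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 2)
  # all late = early (group means equal, sample noise balanced) ->
  # slope 0, t = 0
  flat <- fx
  e <- flat$expression
  bump <- ifelse(e$region == "TE", ifelse(e$gene == "g1", 3, 1), 0)
  flat$expression$rpkm <- e$rpkm - bump
  res0 <- macaque_gradient_slopes(flat, mem)
  expect_true(all(abs(res0$gene_slopes$slope) < 1e-12))
  expect_true(all(abs(res0$tests$t) < 1e-10))
  # normalized early value is 0 by construction for every gene
  expect_true(all(abs((res0$gene_slopes$late - res0$gene_slopes$early) -
                        res0$gene_slopes$slope) < 1e-12))
})

test_that("default macaque dataset gives t with df = 50 for both groups", {
  cfg <- small_config()
  truth <- generate_expression_dataset(cfg, generate_atlas(cfg))$truth
  mac <- generate_macaque_dataset(cfg, truth)
  res <- macaque_gradient_slopes(mac, truth$membership)
  expect_equal(res$tests$df, c(50, 50))
  expect_true(all(res$tests$t > 0))
})

test_that("homolog coverage counts mapped and missing genes", {
  mem <- c(g1 = "ascending", g2 = "ascending", g3 = "descending")
  full <- homolog_coverage(mem, data.frame(human_gene = c("g1", "g2", "g3"),
                                           macaque_gene = c("a", "b", "c")))
  expect_equal(full$missing, c(0, 0, 0))
  empty <- homolog_coverage(mem, data.frame(human_gene = character(0),
                                            macaque_gene = character(0)))
  expect_equal(empty$mapped, c(0, 0, 0))
  expect_equal(empty$missing[empty$gradient == "total"], 3)
  # default config: missing counts within the binomial 99% interval
  cfg <- small_config(seed = 12)
  truth <- generate_expression_dataset(cfg, generate_atlas(cfg))$truth
  mac <- generate_macaque_dataset(cfg, truth)
  cov <- homolog_coverage(truth$membership, mac$homolog_map)
  n_pl <- cfg$n_ascending + cfg$n_descending
  miss <- cov$missing[cov$gradient == "total"]
  q <- qbinom(c(0.005, 0.995), n_pl, 1 - cfg$mapped_fraction)
  expect_gte(miss, q[1])
  expect_lte(miss, q[2])
})
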