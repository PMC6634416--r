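# Anatomy summaries, ANOVA, correlations, regressions, and the
# hypergeometric marker overlap.

test_that("anatomy summary validates and averages vertex-level input", {
  cfg <- small_config()
  an <- generate_anatomy_dataset(cfg, n_subjects = 2)
  s <- summarize_anatomy(an)
  expect_equal(nrow(s), 2 * 13)
  # vertex-level duplication averages back to the same values
  dup <- rbind(an, transform(an, thickness = thickness + 0.2,
                             t1t2 = t1t2 + 0.02))
  s2 <- summarize_anatomy(dup)
  s2 <- s2[match(paste(s$subject, s$roi_label),
                 paste(s2$subject, s2$roi_label)), ]
  expect_equal(s2$thickness, s$thickness + 0.1, tolerance = 1e-12)
  # missing ROI is reported with subject and ROI
  expect_error(summarize_anatomy(an[-1, ]),
               an$roi_label[1])
  # noiseless config: thickness strictly increases with rank
  cfg0 <- small_config(thickness_sd = 0, t1t2_sd = 0)
  an0 <- summarize_anatomy(generate_anatomy_dataset(cfg0, n_subjects = 2))
  m <- aggregate(thickness ~ roi_label, data = an0, FUN = mean)
  rank <- cfg0$roi_labels
  ord <- match(rank, m$roi_label)
  expect_equal(cor(m$thickness[ord], 1:13, method = "spearman"), 1)
})

test_that("two-way metric x cROI ANOVA matches hand sums of squares", {
  # small balanced fixture: 2 metrics x 3 ROIs x 2 subjects
  vals <- c(1, 2, 4, 5, 2, 3,    # thickness: subj1/2 per roi
            5, 4, 2, 1, 3, 2)    # t1t2
  s <- data.frame(subject = rep(c("a", "b"), 3),
                  roi_label = rep(c("r1", "r2", "r3"), each = 2),
                  thickness = vals[1:6], t1t2 = vals[7:12])
  res <- metric_croi_anova(s)
  # oracle: explicit sums-of-squares decomposition on the z-scored data
  long <- rbind(data.frame(m = "thickness", roi = s$roi_label,
                           v = as.vector(scale(s$thickness))),
                data.frame(m = "t1t2", roi = s$roi_label,
                           v = as.vector(scale(s$t1t2))))
  N <- nrow(long); g <- mean(long$v)
  ss_m <- sum(tapply(long$v, long$m, function(x) length(x) * (mean(x) - g)^2))
  ss_r <- sum(tapply(long$v, long$roi, function(x) length(x) * (mean(x) - g)^2))
  cellm <- tapply(long$v, list(long$m, long$roi), mean)
  ss_cells <- sum(2 * (cellm - g)^2)
  ss_int <- ss_cells - ss_m - ss_r
  ss_tot <- sum((long$v - g)^2)
  ss_err <- ss_tot - ss_cells
  f_int <- (ss_int / 2) / (ss_err / (N - 6))
  expect_equal(res$F[res$term == "metric:roi"], f_int, tolerance = 1e-10)
  f_roi <- (ss_r / 2) / (ss_err / (N - 6))
  expect_equal(res$F[res$term == "roi"], f_roi, tolerance = 1e-10)
  # identical metric patterns -> interaction F ~ 0
  s_same <- s; s_same$t1t2 <- s_same$thickness
  res_same <- metric_croi_anova(s_same)
  expect_lt(res_same$F[res_same$term == "metric:roi"], 1e-10)
  # opposite noiseless ramps -> interaction dominates the metric effect
  cfg0 <- small_config(thickness_sd = 1e-6, t1t2_sd = 1e-6)
  s0 <- summarize_anatomy(generate_anatomy_dataset(cfg0, n_subjects = 3))
  r0 <- suppressWarnings(metric_croi_anova(s0))
  expect_gt(r0$F[r0$term == "metric:roi"], r0$F[r0$term == "metric"])
})

test_that("gradient-anatomy correlations match hand-computed Pearson", {
  set.seed(3)
  gm <- cbind(ascending = 1:13 + rnorm(13, 0, 0.5),
              descending = 13:1 + rnorm(13, 0, 0.5))
  rownames(gm) <- croi_labels()
  s <- data.frame(subject = "a", roi_label = croi_labels(),
                  thickness = 2 + 0.07 * (0:12) + rnorm(13, 0, 0.05),
                  t1t2 = 1.9 - 0.045 * (0:12) + rnorm(13, 0, 0.03))
  res <- gradient_anatomy_correlation(gm, s)
  row <- res[res$gradient == "ascending" & res$metric == "thickness", ]
  # hand Pearson and its t-transform p
  x <- gm[, "ascending"]; y <- s$thickness
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(11 / (1 - r_hand^2))
  expect_equal(row$r, r_hand, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(abs(t_hand), 11, lower.tail = FALSE),
               tolerance = 1e-12)
  # perfect linear / anti-linear pairings
  gm2 <- cbind(ascending = as.numeric(1:13), descending = as.numeric(13:1))
  rownames(gm2) <- croi_labels()
  s2 <- data.frame(subject = "a", roi_label = croi_labels(),
                   thickness = 1 + 0.1 * (1:13), t1t2 = 2 - 0.05 * (1:13))
  res2 <- gradient_anatomy_correlation(gm2, s2)
  expect_equal(res2$r[res2$gradient == "ascending" &
                        res2$metric == "thickness"], 1, tolerance = 1e-12)
  expect_equal(res2$r[res2$gradient == "ascending" &
                        res2$metric == "t1t2"], -1, tolerance = 1e-12)
  # Pearson p agrees with a permutation test within Monte-Carlo error
  set.seed(9)
  nperm <- 10000
  robs <- abs(r_hand)
  rperm <- replicate(nperm, abs(cor(x, sample(y))))
  p_perm <- mean(rperm >= robs)
  mc_se <- sqrt(max(p_perm, 1 / nperm) * (1 - p_perm) / nperm)
  expect_lt(abs(p_perm - row$p), max(3 * mc_se, 0.002))
})

test_that("thickness regression recovers planted coefficients", {
  set.seed(4)
  asc <- as.numeric(scale(1:13 + rnorm(13, 0, 0.3)))
  t1t2 <- as.numeric(scale(13:1 + rnorm(13, 0, 2)))
  # noiseless: thickness = 0.5 * ascending + 0 * t1t2
  th <- 0.5 * asc
  rep0 <- suppressWarnings(thickness_two_predictor_regression(th, t1t2, asc))
  full <- rep0[rep0$model == "t1t2+ascending", ]
  expect_equal(full$estimate[full$term == "ascending"], 0.5,
               tolerance = 1e-8)
  expect_equal(full$estimate[full$term == "t1t2"], 0, tolerance = 1e-8)
  expect_equal(full$r_squared[1], 1, tolerance = 1e-10)
  # irrelevant predictor leaves R^2 at 1 on noiseless data
  red <- rep0[rep0$model == "ascending_only", ]
  expect_equal(red$r_squared[1], 1, tolerance = 1e-10)
  # noisy recovery within 3 SEs
  set.seed(5)
  th_n <- 2 + 0.5 * asc + 0.2 * t1t2 + rnorm(13, 0, 0.05)
  rep1 <- thickness_two_predictor_regression(th_n, t1t2, asc)
  f1 <- rep1[rep1$model == "t1t2+ascending", ]
  se_asc <- abs(f1$estimate[f1$term == "ascending"] /
                  f1$t[f1$term == "ascending"])
  expect_lt(abs(f1$estimate[f1$term == "ascending"] - 0.5), 3 * se_asc)
})

test_that("distance-vs-hierarchy regression behaves like nested OLS", {
  set.seed(6)
  cent <- cbind(rnorm(13, 0, 2), seq(-95, -5, length.out = 13),
                rnorm(13, 0, 2))
  asc <- as.numeric(scale(1:13))
  desc <- 1.0 * asc                      # descending diffs = 1 x ascending
  rep0 <- suppressWarnings(distance_vs_hierarchy_regression(cent, desc, asc))
  m1 <- rep0[rep0$model == "ascending_only", ]
  expect_equal(m1$estimate[m1$term == "asc_diff"], 1, tolerance = 1e-8)
  expect_equal(m1$r_squared[1], 1, tolerance = 1e-10)
  # noisy case: the distance coefficient is within 3 SEs of 0 and adding
  # it never lowers R^2
  set.seed(7)
  desc_n <- asc + rnorm(13, 0, 0.2)
  rep1 <- distance_vs_hierarchy_regression(cent, desc_n, asc)
  m1n <- rep1[rep1$model == "ascending_only", ]
  m2n <- rep1[rep1$model == "ascending+distance", ]
  d_est <- m2n$estimate[m2n$term == "distance"]
  d_se <- abs(d_est / m2n$t[m2n$term == "distance"])
  expect_lt(abs(d_est), 3 * d_se)
  expect_gte(m2n$r_squared[1], m1n$r_squared[1])
  expect_error(distance_vs_hierarchy_regression(matrix(1, 13, 3),
                                                desc, asc),
               "degenerate")
})

test_that("hypergeometric overlap reproduces the closed form and symmetry", {
  universe <- sprintf("u%05d", 1:20737)
  markers <- universe[1:830]
  # selection with 43 marker genes among 200
  selected <- c(universe[1:43], universe[1000:1156])
  rep <- hypergeometric_overlap(selected, markers, 20737)
  expect_equal(rep$k, 43)
  expect_equal(rep$expected, 200 * 830 / 20737, tolerance = 1e-12)
  expect_equal(round(rep$z, 1), 12.7)
  expect_equal(rep$percent, 21.5, tolerance = 1e-12)
  expect_equal(rep$p, phyper(42, 830, 20737 - 830, 200,
                             lower.tail = FALSE), tolerance = 1e-15)
  # symmetric in the two sets for a fixed universe
  swap <- hypergeometric_overlap(markers, selected, 20737)
  expect_equal(swap$z, rep$z, tolerance = 1e-12)
  # near-expected overlap gives |z| < 0.2
  sel8 <- c(universe[1:8], universe[2000:2191])
  expect_lt(abs(hypergeometric_overlap(sel8, markers, 20737)$z), 0.2)
  expect_error(hypergeometric_overlap(selected, character(0), 20737),
               "degenerate")
})

test_that("hypergeometric z and p agree with Monte-Carlo sampling", {
  set.seed(10)
  N <- 2000; K <- 150; n <- 100
  universe <- sprintf("u%04d", 1:N)
  markers <- universe[1:K]
  selected <- universe[c(1:20, 500:579)]   # k = 20
  rep <- hypergeometric_overlap(selected, markers, N)
  draws <- rhyper(1e5, K, N - K, n)
  mc_mean <- mean(draws); mc_se_mean <- sd(draws) / sqrt(1e5)
  expect_lt(abs(rep$expected - mc_mean), 3 * mc_se_mean)
  p_mc <- mean(draws >= rep$k)
  mc_se_p <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(rep$p - p_mc), 3 * mc_se_p)
  z_mc <- (rep$k - mc_mean) / sd(draws)
  expect_lt(abs(rep$z - z_mc), 0.1)
})
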