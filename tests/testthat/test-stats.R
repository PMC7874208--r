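test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.2, -0.1)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_identical(q, oracle_bh(p))
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("group comparison separates phenotypes and respects its contracts", {
  p <- stimulus_protocol()
  tabs_wt <- lapply(simulate_cohort(phenotype_wildtype(), p, 4,
                                    base_seed = 60, genotype = "wt"),
                    cycle_metrics_table)
  tabs_nl <- lapply(simulate_cohort(phenotype_null(), p, 4,
                                    base_seed = 80, genotype = "mut"),
                    cycle_metrics_table)
  gt <- group_table(c(tabs_wt, tabs_nl), c(rep("wt", 4), rep("mut", 4)))
  s <- compare_groups(gt, "normalized_integral")
  expect_lt(s$omnibus$p[s$omnibus$term == "genotype"], 0.001)
  expect_gt(sum(s$per_cycle$q_bh < 0.05), 12)
  expect_true(all(s$per_cycle$q_bh >= s$per_cycle$p_raw - 1e-15))
  q <- s$per_cycle$q_bh
  expect_identical(s$per_cycle$stars,
                   ifelse(q < 0.001, "***",
                          ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", ""))))
  # identical groups (same values relabeled) -> nothing significant
  gt2 <- rbind(transform(gt[gt$genotype == "wt", ], genotype = "a"),
               transform(gt[gt$genotype == "wt", ],
                         genotype = "b", larva_id = paste0(larva_id, "b")))
  s2 <- compare_groups(gt2, "normalized_integral")
  expect_identical(sum(s2$per_cycle$q_bh < 0.05), 0L)
  # missing genotype x cycle cell is an explicit error
  gt3 <- gt[!(gt$genotype == "mut" & gt$cycle_index == 5), ]
  expect_error(compare_groups(gt3, "normalized_integral"), "missing cell")
  expect_error(compare_groups(gt, "nope"), "metric not found")
})

test_that("wild type vs depletion mutants separate late, not early", {
  p <- stimulus_protocol()
  tabs_wt <- lapply(simulate_cohort(phenotype_wildtype(), p, 8,
                                    base_seed = 100, genotype = "wt"),
                    cycle_metrics_table)
  tabs_sj <- lapply(simulate_cohort(phenotype_synj1(), p, 8,
                                    base_seed = 200, genotype = "synj1"),
                    cycle_metrics_table)
  gt <- group_table(c(tabs_wt, tabs_sj), c(rep("wt", 8), rep("synj1", 8)))
  s <- compare_groups(gt, "normalized_integral")
  pc <- s$per_cycle[order(s$per_cycle$cycle_index), ]
  expect_gt(pc$q_bh[1], 0.05)                       # first cycle comparable
  expect_true(all(pc$q_bh[10:21] < 0.05))           # late cycles separated
})

test_that("normality screening is calibrated and catches gross non-normality", {
  set.seed(42)
  x <- rnorm(200)
  sc <- normality_screen(x)
  expect_true(all(sc[, 3:6] > 0.1))
  # frozen oracle: scipy.stats.normaltest on this exact draw gives 0.6115904648
  expect_equal(sc$dagostino_pearson, 0.6115904648, tolerance = 1e-8)
  # per-test level-0.1 rejection rate stays near 0.1 under the null
  set.seed(7)
  pv <- t(replicate(200, unlist(normality_screen(rnorm(200))[, 3:6])))
  rates <- colMeans(pv <= 0.1)
  expect_true(all(rates >= 0.03 & rates <= 0.18))
  # a two-point mass distribution is flagged hard
  y <- rep(c(0, 1), each = 100)
  expect_lt(normality_screen(y)$shapiro_wilk, 0.01)
  expect_error(normality_screen(c(1, 2)), "insufficient")
  # small samples return NA for tests whose n requirement is unmet
  sc5 <- normality_screen(rnorm(5))
  expect_true(is.na(sc5$anderson_darling))
  expect_false(is.na(sc5$shapiro_wilk))
})
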