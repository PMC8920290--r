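test_that("abundance is the positive-cell percentage", {
  cells <- make_cells(runif_points(500), rep(0, 500))
  expect_equal(abundance(cells, "CD3"), 0)
  cells2 <- make_cells(runif_points(1000), c(rep(1, 30), rep(0, 970)))
  expect_equal(abundance(cells2, "CD3"), 3)
})

test_that("univariate groups follow the 5-level scheme with boundary-to-high", {
  cuts <- c(2, 500)
  g <- assign_group_univariate(c(0, 5, 5, 1, 1, 2), c(NA, 100, 900, 600, 100, 700), cuts)
  expect_equal(as.character(g), c("None", "HL", "HH", "LH", "LL", "HH"))
  # abundance exactly at the cut is High; zero is None regardless of degree
  expect_equal(as.character(assign_group_univariate(2, 0, cuts)), "HL")
  expect_equal(as.character(assign_group_univariate(0, 1e6, cuts)), "None")
  # positive abundance with undefined degree takes the Low clustering level
  expect_equal(as.character(assign_group_univariate(5, NA, cuts)), "HL")
  # labels partition the samples
  expect_equal(sum(table(g)), length(g))
})

test_that("bivariate groups encode absence/presence and co-occurrence level", {
  expect_equal(as.character(assign_group_bivariate(0, 0, NA, 100)), "AAN")
  expect_equal(as.character(assign_group_bivariate(0, 5, NA, 100)), "APN")
  expect_equal(as.character(assign_group_bivariate(3, 0, NA, 100)), "PAN")
  expect_equal(as.character(assign_group_bivariate(3, 4, 250, 100)), "PPH")
  expect_equal(as.character(assign_group_bivariate(1, 1, 50, 100)), "PPL")
})

test_that("coarsening merges clustering levels exactly", {
  g <- factor(c("None", "LL", "LH", "HL", "HH"),
              levels = c("None", "LL", "LH", "HL", "HH"))
  expect_equal(as.character(coarsen_groups(g)),
               c("None", "Low", "Low", "High", "High"))
  b <- factor(c("AAN", "PPL", "PPH"), levels = c("AAN", "APN", "PAN", "PPL", "PPH"))
  expect_equal(as.character(coarsen_groups(b)), c("AAN", "PP", "PP"))
})

test_that("candidate cut grids never admit an undersized group", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(60:140, 1)
    ab <- c(rep(0, sample(5:15, 1)), runif(n, 0.1, 10))
    dg <- c(rep(NA, sum(ab == 0)), rnorm(n, 300, 400))
    cand <- cutpoint_candidates(ab, dg, min_group = 10)
    if (nrow(cand) == 0) next
    keep <- ab > 0
    for (j in seq_len(nrow(cand))) {
      g <- assign_group_univariate(ab[keep], dg[keep],
                                   c(cand$a_cut[j], cand$d_cut[j]))
      expect_true(all(table(droplevels(g)) >= 10))
    }
  }
})

test_that("candidate grids are capped by quantile thinning", {
  set.seed(72)
  cand <- cutpoint_candidates(runif(500, 0.1, 20), rnorm(500), min_group = 1,
                              cap = 50)
  expect_lte(attr(cand, "n_candidates")["abundance"], 50)
  expect_lte(attr(cand, "n_candidates")["degree"], 50)
})

test_that("log-rank objective matches a hand-coded oracle on small cohorts", {
  set.seed(73)
  for (i in 1:5) {
    n <- 20
    time <- rexp(n, 0.05) + 0.5
    event <- c(1L, 1L, 1L, rbinom(n - 3, 1, 0.8))
    group <- c("A", "B", "C", sample(c("A", "B", "C"), n - 3, replace = TRUE))
    expect_equal(mifK:::logrank_chisq(time, event, group),
                 logrank_oracle(time, event, group), tolerance = 1e-8)
  }
})

test_that("cut-point search is deterministic and sample-order invariant", {
  sim <- simulate_cohort(n_subjects = 60, level = "summary", seed = 21)
  cohort <- sim$cohort
  c1 <- optimal_cutpoints(cohort, k_folds = 5, min_group = 10, cap = 15, seed = 9)
  c2 <- optimal_cutpoints(cohort, k_folds = 5, min_group = 10, cap = 15, seed = 9)
  expect_identical(c1$abundance_cut, c2$abundance_cut)
  expect_identical(c1$per_fold, c2$per_fold)
  shuffled <- cohort[sample(nrow(cohort)), ]
  c3 <- optimal_cutpoints(shuffled, k_folds = 5, min_group = 10, cap = 15, seed = 9)
  expect_equal(c3$abundance_cut, c1$abundance_cut)
  expect_equal(c3$degree_cut, c1$degree_cut)
  # folds partition subjects: every subject's samples share a fold, so the
  # medians come from k fold optima
  expect_equal(nrow(c1$per_fold), 5)
})

test_that("cut-point search recovers the generating partition", {
  # the identified quantity is the grouping the true cuts induce: recovered
  # cuts must reproduce it for nearly all samples
  hits <- 0L
  for (s in 1:5) {
    sim <- simulate_cohort(n_subjects = 80, level = "summary", seed = 100 + s)
    cuts <- optimal_cutpoints(sim$cohort, k_folds = 5, min_group = 10,
                              cap = 20, seed = s)
    g_hat <- assign_group_univariate(sim$cohort$abundance_pct,
                                     sim$cohort$degree, cuts)
    g_true <- assign_group_univariate(sim$cohort$abundance_pct,
                                      sim$cohort$degree, sim$truth$cuts)
    hits <- hits + (mean(g_hat == g_true) >= 0.9)
  }
  expect_gte(hits, 4)
})

test_that("infeasible constraints raise a clear error", {
  sim <- simulate_cohort(n_subjects = 12, samples_per_subject = 1,
                         level = "summary", seed = 22)
  expect_error(optimal_cutpoints(sim$cohort, min_group = 10),
               "infeasible")
})

test_that("Cox fit reports reference HR 1 and sensible group effects", {
  sim <- simulate_cohort(n_subjects = 90, level = "summary", seed = 23)
  g <- factor(sim$truth$sample_group[sim$cohort$sample_id],
              levels = c("None", "LL", "LH", "HL", "HH"))
  fit <- fit_cox_groups(sim$cohort, g, reference = "None")
  tab <- fit$table
  expect_equal(tab$hr[tab$group == "None"], 1)
  expect_true(all(tab$hr > 0))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  expect_equal(fit$overall_df, 4)
  # strongly protective HL group estimated smallest
  expect_equal(tab$group[which.min(tab$hr)], "HL")
  expect_error(fit_cox_groups(sim$cohort, factor(rep("HL", nrow(sim$cohort)))),
               "two populated groups")
  expect_error(fit_cox_groups(sim$cohort, g, reference = "Missing"),
               "empty")
})

test_that("LRT compares nested groupings and degenerates to p = 1", {
  sim <- simulate_cohort(n_subjects = 80, level = "summary", seed = 24)
  g <- assign_group_univariate(sim$cohort$abundance_pct, sim$cohort$degree,
                               c(2.5, 500))
  lrt <- lrt_spatial_vs_abundance(sim$cohort, g)
  expect_s3_class(lrt, "htest")
  expect_equal(unname(lrt$parameter), 2)
  expect_gte(unname(lrt$statistic), 0)
  # identical partitions carry no spatial information
  same <- lrt_spatial_vs_abundance(sim$cohort, coarsen_groups(g),
                                   coarsen_groups(g))
  expect_equal(same$p.value, 1)
  expect_equal(unname(same$statistic), 0)
  # non-nested labelings are rejected
  scrambled <- factor(sample(as.character(coarsen_groups(g))))
  expect_error(lrt_spatial_vs_abundance(sim$cohort, g, scrambled),
               "coarsening")
})

test_that("cohort join validates subjects and keeps per-sample rows", {
  sim <- simulate_cohort(n_subjects = 10, level = "summary", seed = 25)
  dt <- sim$cohort[, c("sample_id", "subject_id", "phenotype",
                       "abundance_pct", "degree", "estimable")]
  joined <- build_cohort(dt, sim$clinical)
  expect_equal(nrow(joined), nrow(dt))
  expect_true(all(c("time_months", "event", "age_dx", "stage") %in%
                  names(joined)))
  dt$subject_id[1] <- "GHOST"
  expect_error(build_cohort(dt, sim$clinical), "GHOST")
})
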