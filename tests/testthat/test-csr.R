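make_labelled_sample <- function(n = 300, p = 0.3, side = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_cells(runif_points(n, side), rbinom(n, 1, p))
}

test_that("permutation nulls are reproducible given a seed", {
  cells <- make_labelled_sample(seed = 61)
  n1 <- csr_permute(cells, "CD3", r = 30, n_perm = 25, seed = 7)
  n2 <- csr_permute(cells, "CD3", r = 30, n_perm = 25, seed = 7)
  expect_identical(n1$k_matrix, n2$k_matrix)
  n3 <- csr_permute(cells, "CD3", r = 30, n_perm = 25, seed = 8)
  expect_false(identical(n1$k_matrix, n3$k_matrix))
  # different seeds agree within the null spread
  se <- stats::sd(n1$k_matrix) / sqrt(n1$n_perm)
  expect_lt(abs(n1$mean - n3$mean), 6 * se)
  # mean_per_r is the column mean of the permutation matrix
  expect_equal(n1$mean, colMeans(n1$k_matrix))
})

test_that("the caller's RNG stream is not consumed by seeded permutations", {
  cells <- make_labelled_sample(seed = 62)
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(csr_permute(cells, "CD3", n_perm = 5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("an all-positive sample gives a degenerate null equal to observed K", {
  cells <- make_labelled_sample(n = 120, p = 1, seed = 63)
  w <- convex_hull_window(cells)
  k_obs <- ripley_k(cbind(cells$x, cells$y), w, 30)
  expect_warning(null <- csr_permute(cells, "CD3", w, 30, n_perm = 10, seed = 1),
                 "degenerate")
  expect_true(all(abs(null$k_matrix - k_obs$k) < 1e-9))
  expect_equal(degree_of_clustering(k_obs, null, 30)$degree, 0)
})

test_that("fewer than two positive cells is not estimable", {
  cells <- make_labelled_sample(n = 100, p = 0, seed = 64)
  cells$CD3[1] <- 1L
  null <- csr_permute(cells, "CD3", n_perm = 10, seed = 1)
  expect_false(null$estimable)
  d <- sample_degree(cells, "CD3", n_perm = 10, seed = 1)
  expect_false(d$estimable)
  expect_equal(d$n_pos, 1L)
  expect_gt(d$abundance_pct, 0)
})

test_that("degree is the observed-minus-null difference and is antisymmetric", {
  cells <- make_labelled_sample(seed = 65)
  w <- convex_hull_window(cells)
  pos <- phenotype_positive_cells(cells, "CD3")
  k_obs <- ripley_k(pos, w, 30)
  null <- csr_permute(cells, "CD3", w, 30, n_perm = 30, seed = 2)
  d <- degree_of_clustering(k_obs, null, 30)
  expect_equal(d$degree, k_obs$k - null$mean)
  # swapping the observed and null-mean roles flips the sign
  null_swapped <- null
  null_swapped$mean <- k_obs$k
  k_swapped <- k_obs
  k_swapped$k <- null$mean
  expect_equal(degree_of_clustering(k_swapped, null_swapped, 30)$degree,
               -d$degree)
  expect_error(degree_of_clustering(k_obs, null, 31), "grid")
})

test_that("null mean tracks pi r^2 for uniform labels in a known window", {
  set.seed(66)
  w <- square_window(1000)
  means <- replicate(6, {
    cells <- make_labelled_sample(n = 500, p = 0.5)
    csr_permute(cells, "CD3", w, 30, n_perm = 60, seed = sample.int(1e6, 1))$mean
  })
  expect_lt(abs(mean(means) - 900 * pi) / (900 * pi), 0.05)
})

test_that("bivariate permutation preserves counts and detects independence", {
  set.seed(67)
  n <- 400
  df <- data.frame(sample_id = "S1", subject_id = "P1",
                   x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                   CD3 = 1L,
                   CD8 = 0L, FOXP3 = 0L)
  type <- sample(c("cd8", "treg", "none"), n, replace = TRUE,
                 prob = c(0.15, 0.15, 0.7))
  df$CD8[type == "cd8"] <- 1L
  df$FOXP3[type == "treg"] <- 1L
  cells <- cell_table(df)
  d <- sample_degree_cross(cells, c("CD3", "FOXP3"), c("CD3", "CD8"),
                           r = 30, n_perm = 60, seed = 3)
  expect_true(d$estimable)
  null <- csr_permute_cross(cells, c("CD3", "FOXP3"), c("CD3", "CD8"),
                            r = 30, n_perm = 40, seed = 3)
  spread <- stats::sd(null$k_matrix)
  # independent uniform labels: co-occurrence degree sits inside the null
  expect_lt(abs(d$degree), 4 * spread)
})

test_that("cross degree is only estimable when both phenotypes are present", {
  cells <- make_labelled_sample(n = 80, p = 0.2, seed = 68)
  df <- as.data.frame(cells)
  df$CD8 <- 0L
  cells2 <- cell_table(df, markers = c("CD3", "CD8"))
  d <- sample_degree_cross(cells2, "CD3", c("CD3", "CD8"), n_perm = 5, seed = 1)
  expect_false(d$estimable)
  expect_equal(d$n2, 0L)
})

test_that("zero-positive samples report abundance 0 and no degree", {
  cells <- make_labelled_sample(n = 50, p = 0, seed = 69)
  d <- sample_degree(cells, "CD3", n_perm = 5, seed = 1)
  expect_equal(d$abundance_pct, 0)
  expect_equal(d$n_pos, 0L)
  expect_false(d$estimable)
  expect_true(is.na(d$degree))
})

test_that("punched holes push the permutation mean above pi r^2", {
  set.seed(70)
  samples <- lapply(1:6, function(i) {
    s <- simulate_points(c(1000, 1000), 8e-4,
                         list(model = "bernoulli", p = 0.3),
                         sample_id = paste0("S", i))
    punch_holes(s, 0.3, seed = i)
  })
  rep_ <- csr_bias_report(samples, "CD3", r = 30, n_perm = 40, seed = 4)
  expect_true(all(rep_$estimable))
  expect_lt(attr(rep_, "mean_difference"), 0)
  expect_equal(rep_$difference, rep_$theoretical - rep_$csr_mean)
})
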