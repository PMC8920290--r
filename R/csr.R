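#' Empirical CSR null for univariate K by label permutation
#'
#' The theoretical CSR value `pi r^2` assumes cells could have appeared
#' anywhere in the window, which fails when a TMA core has folds or tears —
#' regions where no cell could be measured. The permutation null instead
#' holds every measured cell location (and hence the "holes") fixed and
#' randomly reassigns the marker labels: each replicate draws `n_pos` of
#' the `n_total` cell locations without replacement and recomputes K on the
#' drawn set, with the window and edge-correction weights held fixed. The
#' mean over replicates estimates K under CSR *given the observed
#' locations*.
#'
#' @param cells a single-sample [cell_table()], already restricted to the
#'   compartment under analysis.
#' @param phenotype character vector of marker names (conjunction), as in
#'   [phenotype_positive_cells()].
#' @param window observation window; defaults to the convex hull of all
#'   cells in `cells`.
#' @param r radius grid (microns).
#' @param correction edge correction, as in [ripley_k()].
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed for the permutation draws; the caller's RNG
#'   stream is left untouched.
#' @return a `csr_null`: list with `k_matrix` (`n_perm` x `length(r)`),
#'   `mean` (per-radius column means), `r`, `n_perm`, `seed`, `correction`,
#'   `n_total`, `n_pos` (or `c(n1, n2)`), `type`, `estimable`.
#' @export
csr_permute <- function(cells, phenotype, window = NULL, r = 30,
                        correction = c("translation", "isotropic", "none"),
                        n_perm = 100, seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(cells, "cell_table"), n_perm >= 1)
  one_sample(cells)
  locs <- cbind(cells$x, cells$y)
  n_total <- nrow(locs)
  n_pos <- nrow(phenotype_positive_cells(cells, phenotype))
  if (is.null(window)) window <- convex_hull_window(locs)
  r <- as.numeric(r)

  if (n_pos < 2L) {
    return(new_csr_null(NULL, rep(NA_real_, length(r)), r, n_perm, seed,
                        correction, n_total, n_pos, "univariate",
                        estimable = FALSE))
  }
  if (n_pos == n_total) {
    warning("all cells carry the phenotype: permutation null is degenerate ",
            "(every replicate equals the observed K)", call. = FALSE)
  }
  km <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n_total, n_pos)
      ripley_k(locs[idx, , drop = FALSE], window, r, correction)$k
    }, numeric(length(r)))
  })
  km <- if (is.matrix(km)) t(km) else matrix(km, ncol = 1L)
  new_csr_null(km, colMeans(km), r, n_perm, seed, correction,
               n_total, n_pos, "univariate")
}

#' Empirical CSR null for bivariate (cross) K
#'
#' Each replicate reassigns both labels jointly: `n1 + n2` locations are
#' drawn without replacement from all cell locations, the first `n1`
#' becoming anchors and the next `n2` the second type (disjoint sets,
#' counts preserved), and the cross K is recomputed.
#'
#' @inheritParams csr_permute
#' @param anchor_phenotype,other_phenotype marker conjunctions for the
#'   anchor and second cell type.
#' @return a `csr_null` with `n_pos = c(n1, n2)`.
#' @export
csr_permute_cross <- function(cells, anchor_phenotype, other_phenotype,
                              window = NULL, r = 30,
                              correction = c("translation", "isotropic", "none"),
                              n_perm = 100, seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(cells, "cell_table"), n_perm >= 1)
  one_sample(cells)
  locs <- cbind(cells$x, cells$y)
  n_total <- nrow(locs)
  n1 <- nrow(phenotype_positive_cells(cells, anchor_phenotype))
  n2 <- nrow(phenotype_positive_cells(cells, other_phenotype))
  if (is.null(window)) window <- convex_hull_window(locs)
  r <- as.numeric(r)

  if (n1 < 1L || n2 < 1L || n1 + n2 > n_total) {
    return(new_csr_null(NULL, rep(NA_real_, length(r)), r, n_perm, seed,
                        correction, n_total, c(n1 = n1, n2 = n2), "cross",
                        estimable = FALSE))
  }
  km <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n_total, n1 + n2)
      ripley_k_cross(locs[idx[seq_len(n1)], , drop = FALSE],
                     locs[idx[n1 + seq_len(n2)], , drop = FALSE],
                     window, r, correction)$k
    }, numeric(length(r)))
  })
  km <- if (is.matrix(km)) t(km) else matrix(km, ncol = 1L)
  new_csr_null(km, colMeans(km), r, n_perm, seed, correction,
               n_total, c(n1 = n1, n2 = n2), "cross")
}

new_csr_null <- function(k_matrix, mean_per_r, r, n_perm, seed, correction,
                         n_total, n_pos, type, estimable = TRUE) {
  structure(list(k_matrix = k_matrix, mean = mean_per_r, r = r,
                 n_perm = n_perm, seed = seed, correction = correction,
                 n_total = n_total, n_pos = n_pos, type = type,
                 estimable = estimable),
            class = "csr_null")
}

#' @export
print.csr_null <- function(x, ...) {
  cat(sprintf("<csr_null> %s, %d permutations, n_total = %d, n_pos = %s\n",
              x$type, x$n_perm, x$n_total,
              paste(x$n_pos, collapse = "/")))
  if (x$estimable) {
    for (i in seq_along(x$r)) {
      cat(sprintf("  r = %g: mean K = %.2f (theoretical CSR %.2f)\n",
                  x$r[i], x$mean[i], theoretical_csr(x$r[i])))
    }
  } else {
    cat("  not estimable (phenotype too sparse)\n")
  }
  invisible(x)
}

#' Degree of spatial clustering (or co-occurrence)
#'
#' The per-sample summary statistic: observed K minus the mean of the
#' permutation-derived CSR distribution at the analysis radius. Positive
#' values indicate clustering beyond what the cell arrangement allows under
#' random labelling; negative values indicate spatial regularity.
#'
#' @param k_obs a `k_estimate` from [ripley_k()] or [ripley_k_cross()].
#' @param null a `csr_null` from [csr_permute()] / [csr_permute_cross()].
#' @param r analysis radius; must lie on the grid of both inputs. Default
#'   is the single shared radius when both grids have length one.
#' @return a `clustering_degree`: list with `r`, `k_observed`, `csr_mean`,
#'   `degree` and `estimable`.
#' @export
degree_of_clustering <- function(k_obs, null, r = NULL) {
  stopifnot(inherits(k_obs, "k_estimate"), inherits(null, "csr_null"))
  if (is.null(r)) {
    if (length(k_obs$r) == 1L && length(null$r) == 1L &&
        isTRUE(all.equal(k_obs$r, null$r))) {
      r <- k_obs$r
    } else {
      stop("specify r explicitly when the grids have more than one radius",
           call. = FALSE)
    }
  }
  io <- match_radius(r, k_obs$r)
  im <- match_radius(r, null$r)
  estimable <- k_obs$estimable && null$estimable
  k_observed <- if (estimable) k_obs$k[io] else NA_real_
  csr_mean <- if (estimable) null$mean[im] else NA_real_
  structure(list(r = r, k_observed = k_observed, csr_mean = csr_mean,
                 degree = k_observed - csr_mean, estimable = estimable),
            class = "clustering_degree")
}

match_radius <- function(r, grid) {
  i <- which(abs(grid - r) < 1e-8)
  if (length(i) != 1L) stop("radius ", r, " is not on the estimate's grid",
                            call. = FALSE)
  i
}

#' @export
print.clustering_degree <- function(x, ...) {
  if (!x$estimable) {
    cat("<clustering_degree> not estimable\n")
  } else {
    cat(sprintf(
      "<clustering_degree> r = %g: observed K = %.2f, CSR mean = %.2f, degree = %.2f\n",
      x$r, x$k_observed, x$csr_mean, x$degree))
  }
  invisible(x)
}

#' Per-sample degree of clustering, end to end
#'
#' Convenience wrapper running the full per-sample chain for one phenotype:
#' compartment filter, convex-hull window, observed K, permutation null,
#' degree. Samples where the chain cannot run (no cells after filtering,
#' fewer than 3 cells for the hull, fewer than 2 positive cells) are
#' returned flagged not estimable rather than erroring, so cohort runs skip
#' bad samples gracefully.
#'
#' @inheritParams csr_permute
#' @param compartment compartment restriction applied before anything else.
#' @return one-row data frame: `sample_id`, `subject_id`, `phenotype`, `r`,
#'   `n_total`, `n_pos`, `abundance_pct`, `k_observed`, `csr_mean`,
#'   `degree`, `n_perm`, `seed`, `estimable`.
#' @export
sample_degree <- function(cells, phenotype, r = 30,
                          correction = c("translation", "isotropic", "none"),
                          n_perm = 100, seed = NULL,
                          compartment = c("all", "tumor", "stroma")) {
  correction <- match.arg(correction)
  compartment <- match.arg(compartment)
  stopifnot(inherits(cells, "cell_table"))
  sid <- one_sample(cells)
  subj <- cells$subject_id[1L]
  cells <- filter_compartment(cells, compartment)
  row <- data.frame(sample_id = sid, subject_id = subj,
                    phenotype = paste(phenotype, collapse = "+"),
                    r = r[1L], n_total = nrow(cells), n_pos = NA_integer_,
                    abundance_pct = NA_real_, k_observed = NA_real_,
                    csr_mean = NA_real_, degree = NA_real_,
                    n_perm = n_perm,
                    seed = if (is.null(seed)) NA_integer_ else seed,
                    estimable = FALSE, stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) {
    row$n_pos <- 0L; row$abundance_pct <- NA_real_
    return(row)
  }
  pos <- phenotype_positive_cells(cells, phenotype)
  row$n_pos <- nrow(pos)
  row$abundance_pct <- 100 * nrow(pos) / nrow(cells)
  if (nrow(pos) < 2L || nrow(cells) < 3L) return(row)
  win <- tryCatch(convex_hull_window(cells), error = function(e) NULL)
  if (is.null(win)) return(row)
  k_obs <- ripley_k(pos, win, r, correction)
  null <- csr_permute(cells, phenotype, win, r, correction, n_perm, seed)
  d <- degree_of_clustering(k_obs, null, r[1L])
  row$k_observed <- d$k_observed
  row$csr_mean <- d$csr_mean
  row$degree <- d$degree
  row$estimable <- d$estimable
  row
}

#' @rdname sample_degree
#' @inheritParams csr_permute_cross
#' @return For the cross version, the row also carries `n1`, `n2` and the
#'   two phenotype labels; the degree is estimable only when both types are
#'   present (`n1 >= 1`, `n2 >= 1`).
#' @export
sample_degree_cross <- function(cells, anchor_phenotype, other_phenotype,
                                r = 30,
                                correction = c("translation", "isotropic", "none"),
                                n_perm = 100, seed = NULL,
                                compartment = c("all", "tumor", "stroma")) {
  correction <- match.arg(correction)
  compartment <- match.arg(compartment)
  stopifnot(inherits(cells, "cell_table"))
  sid <- one_sample(cells)
  subj <- cells$subject_id[1L]
  cells <- filter_compartment(cells, compartment)
  row <- data.frame(sample_id = sid, subject_id = subj,
                    anchor = paste(anchor_phenotype, collapse = "+"),
                    other = paste(other_phenotype, collapse = "+"),
                    r = r[1L], n_total = nrow(cells),
                    n1 = NA_integer_, n2 = NA_integer_,
                    k_observed = NA_real_, csr_mean = NA_real_,
                    degree = NA_real_, n_perm = n_perm,
                    seed = if (is.null(seed)) NA_integer_ else seed,
                    estimable = FALSE, stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) {
    row$n1 <- 0L; row$n2 <- 0L
    return(row)
  }
  a <- phenotype_positive_cells(cells, anchor_phenotype)
  b <- phenotype_positive_cells(cells, other_phenotype)
  row$n1 <- nrow(a); row$n2 <- nrow(b)
  if (nrow(a) < 1L || nrow(b) < 1L || nrow(cells) < 3L) return(row)
  win <- tryCatch(convex_hull_window(cells), error = function(e) NULL)
  if (is.null(win)) return(row)
  k_obs <- ripley_k_cross(a, b, win, r, correction)
  null <- csr_permute_cross(cells, anchor_phenotype, other_phenotype, win,
                            r, correction, n_perm, seed)
  d <- degree_of_clustering(k_obs, null, r[1L])
  row$k_observed <- d$k_observed
  row$csr_mean <- d$csr_mean
  row$degree <- d$degree
  row$estimable <- d$estimable
  row
}

#' Theoretical-vs-permutation CSR bias report
#'
#' For each sample, compares the theoretical CSR value `pi r^2` with the
#' permutation-null mean; `difference = pi r^2 - csr_mean`. In samples with
#' cell-free holes the permutation mean exceeds `pi r^2` (the remaining
#' cells are effectively packed into a smaller region), so the difference
#' is negative — using the theoretical value there understates K under CSR
#' and overstates the degree of clustering.
#'
#' @param samples list of single-sample [cell_table()]s (or one
#'   multi-sample table).
#' @inheritParams sample_degree
#' @return data frame with `sample_id`, `theoretical`, `csr_mean`,
#'   `difference` and `estimable`; the cohort mean difference over
#'   estimable samples is attached as attribute `"mean_difference"`.
#' @export
csr_bias_report <- function(samples, phenotype, r = 30,
                            correction = c("translation", "isotropic", "none"),
                            n_perm = 100, seed = NULL,
                            compartment = c("all", "tumor", "stroma")) {
  correction <- match.arg(correction)
  compartment <- match.arg(compartment)
  if (inherits(samples, "cell_table")) samples <- split_samples(samples)
  seeds <- derive_seeds(length(samples), seed)
  rows <- lapply(seq_along(samples), function(i) {
    d <- sample_degree(samples[[i]], phenotype, r, correction, n_perm,
                       seeds[[i]], compartment)
    data.frame(sample_id = d$sample_id,
               theoretical = theoretical_csr(r[1L]),
               csr_mean = d$csr_mean,
               difference = theoretical_csr(r[1L]) - d$csr_mean,
               estimable = d$estimable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_difference") <- mean(out$difference[out$estimable])
  out
}

#' Degree of clustering for a whole cohort
#'
#' Runs [sample_degree()] for every sample and phenotype, with
#' reproducible per-sample sub-seeds derived from one master seed. Bad
#' samples are flagged, never fatal.
#'
#' @param samples list of single-sample [cell_table()]s or one
#'   multi-sample table.
#' @param phenotypes list of marker conjunctions, e.g.
#'   `list("CD3", c("CD3", "CD8"))`.
#' @inheritParams sample_degree
#' @return data frame with one row per sample x phenotype (see
#'   [sample_degree()]).
#' @export
cohort_degree <- function(samples, phenotypes, r = 30,
                          correction = c("translation", "isotropic", "none"),
                          n_perm = 100, seed = NULL,
                          compartment = c("all", "tumor", "stroma")) {
  correction <- match.arg(correction)
  compartment <- match.arg(compartment)
  if (inherits(samples, "cell_table")) samples <- split_samples(samples)
  if (!is.list(phenotypes)) phenotypes <- list(phenotypes)
  seeds <- derive_seeds(length(samples) * length(phenotypes), seed)
  rows <- list()
  k <- 0L
  for (i in seq_along(samples)) {
    for (p in phenotypes) {
      k <- k + 1L
      rows[[k]] <- sample_degree(samples[[i]], p, r, correction, n_perm,
                                 seeds[[k]], compartment)
    }
  }
  do.call(rbind, rows)
}

#' @rdname cohort_degree
#' @inheritParams sample_degree_cross
#' @export
cohort_degree_cross <- function(samples, anchor_phenotype, other_phenotype,
                                r = 30,
                                correction = c("translation", "isotropic", "none"),
                                n_perm = 100, seed = NULL,
                                compartment = c("all", "tumor", "stroma")) {
  correction <- match.arg(correction)
  compartment <- match.arg(compartment)
  if (inherits(samples, "cell_table")) samples <- split_samples(samples)
  seeds <- derive_seeds(length(samples), seed)
  rows <- lapply(seq_along(samples), function(i) {
    sample_degree_cross(samples[[i]], anchor_phenotype, other_phenotype, r,
                        correction, n_perm, seeds[[i]], compartment)
  })
  do.call(rbind, rows)
}
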