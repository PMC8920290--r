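#' Write a per-sample degree table as TSV
#'
#' @param x data frame from [cohort_degree()], [cohort_degree_cross()] or
#'   [csr_bias_report()].
#' @param path output path.
#' @export
write_degree_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample degree table written by [write_degree_tsv()]
#' @param path TSV path.
#' @return data frame.
#' @export
read_degree_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character",
                                   subject_id = "character"))
}

#' Run the spatial degree stage over a directory of cell tables
#'
#' Reads every cell table, applies the conflicting-phenotype QC when the
#' CD3/CD8/FOXP3 trio is present, and computes the per-sample degree of
#' clustering for each phenotype. Samples that fail individually are
#' reported as not-estimable rows, not errors, so one bad core does not
#' abort a cohort run.
#'
#' @param paths character vector of cell-table files.
#' @param phenotypes list of marker conjunctions.
#' @param coord_units,mpp passed to [read_cell_table()].
#' @inheritParams cohort_degree
#' @param out optional output TSV path.
#' @return the degree table, invisibly when `out` is given.
#' @export
run_degree <- function(paths, phenotypes, coord_units = "microns",
                       mpp = 0.4977, r = 30, correction = "translation",
                       n_perm = 100, seed = NULL, compartment = "all",
                       out = NULL) {
  samples <- list()
  for (p in paths) {
    tab <- read_cell_table(p, coord_units = coord_units, mpp = mpp)
    if (all(c("CD3", "CD8", "FOXP3") %in% attr(tab, "markers"))) {
      tab <- resolve_conflicting_phenotypes(tab)$table
    }
    samples <- c(samples, split_samples(tab))
  }
  res <- cohort_degree(samples, phenotypes, r = r, correction = correction,
                       n_perm = n_perm, seed = seed,
                       compartment = compartment)
  if (!is.null(out)) {
    write_degree_tsv(res, out)
    return(invisible(res))
  }
  res
}

#' Run the survival stage and write its reports
#'
#' Joins a degree table to a clinical table, finds constrained CV
#' cut-points, assigns the five groups, and fits the Cox models and the
#' spatial-vs-abundance likelihood-ratio test; optionally writes the group
#' assignments and Cox coefficient table as TSV.
#'
#' @param degree_table data frame from [run_degree()] /
#'   [read_degree_tsv()].
#' @param clinical a [clinical_table()].
#' @inheritParams run_survival_analysis
#' @param out_prefix optional path prefix; writes
#'   `<prefix>_groups.tsv` and `<prefix>_cox.tsv`.
#' @return the `mif_survfit` object.
#' @export
run_survival <- function(degree_table, clinical, k_folds = 10L,
                         min_group = 10L, reference = "None", seed = NULL,
                         out_prefix = NULL) {
  cohort <- build_cohort(degree_table, clinical)
  fit <- run_survival_analysis(cohort, k_folds = k_folds,
                               min_group = min_group,
                               reference = reference, seed = seed)
  if (!is.null(out_prefix)) {
    ga <- data.frame(sample_id = cohort$sample_id,
                     subject_id = cohort$subject_id,
                     abundance_pct = cohort$abundance_pct,
                     degree = cohort$degree,
                     group = as.character(fit$groups),
                     stringsAsFactors = FALSE)
    utils::write.table(ga, paste0(out_prefix, "_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tab <- fit$cox$table
    tab$overall_p <- fit$cox$overall_p
    tab$lrt_p <- fit$lrt$p.value
    utils::write.table(tab, paste0(out_prefix, "_cox.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  fit
}

#' Predicted per-group survival curves from a group Cox fit
#'
#' Curve coordinates for plotting: expected survival per group at the
#' cohort-average covariates.
#'
#' @param fit a `cox_groups` object.
#' @return data frame with `group`, `time`, `survival`.
#' @export
predicted_survival_curves <- function(fit) {
  stopifnot(inherits(fit, "cox_groups"))
  model <- fit$fit_unclustered
  d <- model.frame(model)
  gl <- levels(d$group)
  nd <- data.frame(group = factor(gl, levels = gl),
                   age_dx = mean(d$age_dx))
  if ("stage" %in% names(d)) {
    tabs <- table(d$stage)
    nd$stage <- factor(names(tabs)[which.max(tabs)], levels = levels(d$stage))
  }
  sf <- survival::survfit(model, newdata = nd)
  sv <- if (is.matrix(sf$surv)) sf$surv else matrix(sf$surv, ncol = 1L)
  do.call(rbind, lapply(seq_along(gl), function(i) {
    data.frame(group = gl[i], time = sf$time, survival = sv[, i],
               stringsAsFactors = FALSE)
  }))
}
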