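#' Phenotype abundance in a sample
#'
#' @param cells a single-sample [cell_table()] (at least one cell).
#' @param phenotype marker conjunction.
#' @return percentage of cells positive for the full conjunction, in
#'   \[0, 100\].
#' @export
abundance <- function(cells, phenotype) {
  stopifnot(inherits(cells, "cell_table"), nrow(cells) >= 1L)
  100 * nrow(phenotype_positive_cells(cells, phenotype)) / nrow(cells)
}

#' Join per-sample spatial summaries to per-subject survival data
#'
#' @param degree_table output of [cohort_degree()] (or the cross variant).
#' @param clinical a [clinical_table()] data frame.
#' @return a `cohort_table` data frame: per-sample rows carrying
#'   `abundance_pct`, `degree`, `estimable` plus the subject's `time_months`,
#'   `event`, `age_dx`, `stage`. Errors if a sample's subject is missing
#'   from the clinical table.
#' @export
build_cohort <- function(degree_table, clinical) {
  miss <- setdiff(unique(degree_table$subject_id), clinical$subject_id)
  if (length(miss)) {
    stop("subjects missing from clinical table: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  out <- merge(degree_table, clinical, by = "subject_id", all.x = TRUE,
               sort = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

group_levels_uni <- c("None", "LL", "LH", "HL", "HH")
group_levels_biv <- c("AAN", "APN", "PAN", "PPL", "PPH")

#' Univariate abundance-by-clustering group labels
#'
#' Five groups: `None` (zero abundance — no positive cells, so clustering is
#' undefined), then the abundance level (Low/High) crossed with the
#' clustering level (Low/High). Values exactly at a cut go to High. Samples
#' with positive abundance whose degree is not estimable (a single positive
#' cell) take the Low clustering level: one cell cannot exhibit clustering.
#'
#' @param abundance_pct numeric vector of abundances (percent).
#' @param degree numeric vector of clustering degrees (`NA` when not
#'   estimable).
#' @param cuts length-2 numeric `c(abundance_cut, degree_cut)` (a
#'   [optimal_cutpoints()] result is also accepted).
#' @return factor with levels `None, LL, LH, HL, HH`.
#' @export
assign_group_univariate <- function(abundance_pct, degree, cuts) {
  if (inherits(cuts, "cutpoint_cv")) cuts <- c(cuts$abundance_cut, cuts$degree_cut)
  stopifnot(length(cuts) == 2L, all(is.finite(cuts)))
  a_lvl <- ifelse(abundance_pct >= cuts[1L], "H", "L")
  d_lvl <- ifelse(!is.na(degree) & degree >= cuts[2L], "H", "L")
  lab <- ifelse(abundance_pct == 0, "None", paste0(a_lvl, d_lvl))
  factor(lab, levels = group_levels_uni)
}

#' Bivariate presence-by-co-occurrence group labels
#'
#' `AAN`/`APN`/`PAN` encode absence/presence of the two cell types (a type
#' is present with at least one positive cell; cross K is estimable with
#' one of each); when both are present the third letter grades the
#' co-occurrence degree Low/High against the cut.
#'
#' @param n1,n2 integer counts of the anchor and second cell type.
#' @param degree co-occurrence degree (`NA` allowed when not estimable;
#'   treated as Low).
#' @param d_cut degree cut-point.
#' @return factor with levels `AAN, APN, PAN, PPL, PPH`.
#' @export
assign_group_bivariate <- function(n1, n2, degree, d_cut) {
  stopifnot(is.finite(d_cut))
  lab <- ifelse(n1 == 0 & n2 == 0, "AAN",
         ifelse(n1 == 0, "APN",
         ifelse(n2 == 0, "PAN",
         ifelse(!is.na(degree) & degree >= d_cut, "PPH", "PPL"))))
  factor(lab, levels = group_levels_biv)
}

#' Coarsen 5-level groups to abundance-only groups
#'
#' Drops the clustering letter: `LL`/`LH` become `Low`, `HL`/`HH` become
#' `High` (univariate); `PPL`/`PPH` become `PP` (bivariate). Used as the
#' reduced model in [lrt_spatial_vs_abundance()].
#'
#' @param groups factor of group labels.
#' @return factor of coarsened labels.
#' @export
coarsen_groups <- function(groups) {
  map <- c(None = "None", LL = "Low", LH = "Low", HL = "High", HH = "High",
           AAN = "AAN", APN = "APN", PAN = "PAN", PPL = "PP", PPH = "PP")
  lab <- map[as.character(groups)]
  lv <- if (all(levels(groups) %in% group_levels_uni)) {
    c("None", "Low", "High")
  } else {
    c("AAN", "APN", "PAN", "PP")
  }
  factor(unname(lab), levels = lv)
}

# Candidate cut values: midpoints between consecutive unique order
# statistics, thinned to at most `cap` by quantiles.
cut_candidates <- function(values, cap = 50L) {
  u <- sort(unique(values[is.finite(values)]))
  if (length(u) < 2L) return(numeric(0))
  mids <- (u[-1L] + u[-length(u)]) / 2
  if (length(mids) > cap) {
    mids <- unique(stats::quantile(mids, probs = seq(0, 1, length.out = cap),
                                   names = FALSE, type = 1))
  }
  mids
}

#' Feasible cut-point candidates under the minimum group-size constraint
#'
#' Enumerates candidate `(abundance_cut, degree_cut)` pairs — midpoints of
#' consecutive observed values, quantile-thinned to at most `cap` per
#' dimension — and keeps those for which each of the four nonzero-abundance
#' groups (LL, LH, HL, HH) contains at least `min_group` samples. Zero
#' abundance samples are excluded before counting, as they belong to `None`
#' regardless of the cuts.
#'
#' @param abundance_pct,degree per-sample values (samples with
#'   `abundance_pct > 0` are used; `NA` degree counts as Low clustering).
#' @param min_group minimum samples per group (default 10).
#' @param cap maximum candidates per dimension.
#' @return data frame of feasible `a_cut`, `d_cut` pairs (possibly empty),
#'   with the full candidate grid sizes as attributes.
#' @export
cutpoint_candidates <- function(abundance_pct, degree, min_group = 10L,
                                cap = 50L) {
  keep <- abundance_pct > 0
  ab <- abundance_pct[keep]
  dg <- degree[keep]
  a_cand <- cut_candidates(ab, cap)
  d_cand <- cut_candidates(dg, cap)
  grid <- expand.grid(a_cut = a_cand, d_cut = d_cand,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid)) {
    ok <- vapply(seq_len(nrow(grid)), function(i) {
      hi_a <- ab >= grid$a_cut[i]
      hi_d <- !is.na(dg) & dg >= grid$d_cut[i]
      min(sum(!hi_a & !hi_d), sum(!hi_a & hi_d),
          sum(hi_a & !hi_d), sum(hi_a & hi_d)) >= min_group
    }, logical(1L))
    grid <- grid[ok, , drop = FALSE]
  }
  attr(grid, "n_candidates") <- c(abundance = length(a_cand),
                                  degree = length(d_cand))
  grid
}

# Multi-group log-rank chi-square; the objective maximised by the
# cut-point search ("largest difference in the survival curves").
logrank_chisq <- function(time, event, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) return(0)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  unname(sd_$chisq)
}

#' Constrained optimal cut-points by cross-validated grid search
#'
#' Finds abundance and degree cut-points that maximise the separation of
#' the five groups' survival curves (multi-group log-rank chi-square),
#' constrained so every nonzero-abundance group keeps at least `min_group`
#' training samples, under k-fold cross-validation: folds partition
#' *subjects* (all samples of a subject share a fold, preventing leakage
#' across repeated samples), each fold's training portion yields one
#' optimal pair, and the final cuts are the per-dimension medians of the
#' fold optima.
#'
#' @param cohort a [build_cohort()] table (`abundance_pct`, `degree`,
#'   `time_months`, `event`, `subject_id` columns).
#' @param k_folds number of folds (default 10).
#' @param min_group minimum samples per nonzero-abundance group (default 10).
#' @param cap maximum candidate cuts per dimension (quantile thinning).
#' @param seed seed for the subject-fold assignment.
#' @return a `cutpoint_cv`: `abundance_cut`, `degree_cut`, `per_fold`
#'   (fold optima with objectives), `trace` (per-fold candidate grids with
#'   objectives), `k_folds`, `min_group`.
#' @export
optimal_cutpoints <- function(cohort, k_folds = 10L, min_group = 10L,
                              cap = 50L, seed = NULL) {
  stopifnot(k_folds >= 2L)
  nonzero <- sum(cohort$abundance_pct > 0, na.rm = TRUE)
  if (nonzero < 4L * min_group) {
    stop("infeasible: only ", nonzero, " nonzero-abundance samples; at least ",
         4L * min_group, " are needed for four groups of ", min_group,
         call. = FALSE)
  }
  subjects <- sort(unique(cohort$subject_id))  # sample-order invariance
  fold_of <- with_seed(seed, {
    setNames(sample(rep_len(seq_len(k_folds), length(subjects))), subjects)
  })
  per_fold <- vector("list", k_folds)
  trace <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- cohort[fold_of[cohort$subject_id] != f, , drop = FALSE]
    cand <- cutpoint_candidates(train$abundance_pct, train$degree,
                                min_group, cap)
    if (nrow(cand) == 0L) {
      stop("infeasible: fold ", f, " admits no cut-point pair with all four ",
           "nonzero-abundance groups >= ", min_group, " training samples",
           call. = FALSE)
    }
    obj <- vapply(seq_len(nrow(cand)), function(i) {
      g <- assign_group_univariate(train$abundance_pct, train$degree,
                                   c(cand$a_cut[i], cand$d_cut[i]))
      logrank_chisq(train$time_months, train$event, g)
    }, numeric(1L))
    best <- which.max(obj)
    per_fold[[f]] <- data.frame(fold = f, a_cut = cand$a_cut[best],
                                d_cut = cand$d_cut[best],
                                objective = obj[best])
    cand$objective <- obj
    trace[[f]] <- cand
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(abundance_cut = stats::median(per_fold$a_cut),
                 degree_cut = stats::median(per_fold$d_cut),
                 per_fold = per_fold, trace = trace,
                 k_folds = k_folds, min_group = min_group, seed = seed),
            class = "cutpoint_cv")
}

#' @export
print.cutpoint_cv <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_cv> %d-fold CV, min group size %d\n  abundance cut: %.4g%%\n  degree cut:    %.6g\n",
    x$k_folds, x$min_group, x$abundance_cut, x$degree_cut))
  invisible(x)
}

#' Cox proportional hazards fit for abundance/clustering groups
#'
#' Fits `Surv(time, event) ~ group + age + stage` on per-sample rows with a
#' cluster-robust (sandwich) variance by subject, accounting for repeated
#' samples per subject. Stage enters as indicators with stage I reference;
#' age is linear in years. Reports hazard ratios with 95% confidence
#' intervals against the reference group, and the overall robust Wald test
#' of all group terms (4 df for five populated groups). A parallel fit
#' without the cluster term supplies the partial log-likelihood used by
#' [lrt_spatial_vs_abundance()].
#'
#' @param cohort a [build_cohort()] table.
#' @param groups factor of per-sample group labels (e.g. from
#'   [assign_group_univariate()]).
#' @param reference reference group label (default `"None"`).
#' @return a `cox_groups`: coefficient table (`group`, `n`, `events`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `overall_p` and `overall_df`, `loglik`
#'   (unclustered), the underlying `coxph` fits.
#' @export
fit_cox_groups <- function(cohort, groups, reference = "None") {
  groups <- factor(groups)
  stopifnot(length(groups) == nrow(cohort))
  populated <- names(which(table(groups) > 0))
  if (length(populated) < 2L) {
    stop("need at least two populated groups", call. = FALSE)
  }
  if (!reference %in% populated) {
    stop("reference group '", reference, "' is empty", call. = FALSE)
  }
  d <- data.frame(time = cohort$time_months, event = cohort$event,
                  group = stats::relevel(droplevels(groups), ref = reference),
                  age_dx = cohort$age_dx,
                  stage = factor(cohort$stage, levels = c("I", "II", "III", "IV")),
                  subject_id = cohort$subject_id,
                  stringsAsFactors = FALSE)
  if (sum(d$event) == 0L) stop("no events in cohort", call. = FALSE)
  stage_term <- nlevels(droplevels(d$stage)) > 1L
  fml <- if (stage_term) {
    survival::Surv(time, event) ~ group + age_dx + stage
  } else {
    survival::Surv(time, event) ~ group + age_dx
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, cluster = subject_id),
    warning = function(w) {
      if (grepl("did not converge|infinite|out of iterations",
                conditionMessage(w))) {
        stop("coxph failed to converge: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  fit_plain <- survival::coxph(fml, data = d)

  gl <- levels(d$group)
  co <- coef(fit)
  rse <- sqrt(diag(fit$var))             # robust when cluster= is given
  names(rse) <- names(co)
  gterms <- paste0("group", gl[-1L])
  z <- co[gterms] / rse[gterms]
  tab <- data.frame(
    group = gl,
    n = as.integer(table(d$group)[gl]),
    events = as.integer(tapply(d$event, d$group, sum)[gl]),
    hr = c(1, exp(co[gterms])),
    ci_low = c(1, exp(co[gterms] - 1.96 * rse[gterms])),
    ci_high = c(1, exp(co[gterms] + 1.96 * rse[gterms])),
    p = c(NA_real_, 2 * pnorm(-abs(z))),
    row.names = NULL, stringsAsFactors = FALSE)

  V <- fit$var[seq_along(gterms), seq_along(gterms), drop = FALSE]
  b <- co[gterms]
  wald <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  overall_df <- length(gterms)
  overall_p <- pchisq(wald, df = overall_df, lower.tail = FALSE)

  structure(list(table = tab, reference = reference,
                 overall_p = overall_p, overall_df = overall_df,
                 overall_chisq = wald,
                 loglik = fit_plain$loglik[2L],
                 n = nrow(d), n_subjects = length(unique(d$subject_id)),
                 n_events = sum(d$event),
                 fit = fit, fit_unclustered = fit_plain),
            class = "cox_groups")
}

#' @export
print.cox_groups <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<cox_groups> %d samples, %d subjects, %d events; reference = %s\n",
    x$n, x$n_subjects, x$n_events, x$reference))
  tab <- x$table
  tab$hr <- signif(tab$hr, digits)
  tab$ci_low <- signif(tab$ci_low, digits)
  tab$ci_high <- signif(tab$ci_high, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("overall group test (robust Wald, %d df): p = %.4g\n",
              x$overall_df, x$overall_p))
  invisible(x)
}

#' @export
summary.cox_groups <- function(object, ...) {
  print(object, ...)
  cat("\nunderlying coxph fit (cluster-robust):\n")
  print(object$fit)
  invisible(object)
}

#' Likelihood-ratio test of spatial grouping vs abundance-only grouping
#'
#' Compares the Cox model with the full abundance-by-clustering groups
#' against the nested model whose groups carry abundance information only
#' ([coarsen_groups()] of the full labels). Both models use unclustered
#' partial likelihoods — likelihood ratios are undefined for
#' sandwich-variance fits — with the same age and stage adjustment. Twice
#' the log-likelihood difference is referred to a chi-square whose degrees
#' of freedom equal the difference in group indicator counts (2 for the
#' univariate five- vs three-group comparison).
#'
#' @param cohort a [build_cohort()] table.
#' @param groups_full factor of full group labels.
#' @param groups_reduced factor of coarsened labels; must be a coarsening
#'   of `groups_full` (each full label maps to exactly one reduced label).
#' @param reference_full,reference_reduced reference levels for the fits.
#' @return an object of class `htest` with the statistic, df and p-value.
#' @export
lrt_spatial_vs_abundance <- function(cohort, groups_full,
                                     groups_reduced = coarsen_groups(groups_full),
                                     reference_full = levels(factor(groups_full))[1L],
                                     reference_reduced = levels(factor(groups_reduced))[1L]) {
  groups_full <- droplevels(factor(groups_full))
  groups_reduced <- droplevels(factor(groups_reduced))
  nested <- all(vapply(split(as.character(groups_reduced),
                             as.character(groups_full)),
                       function(v) length(unique(v)) == 1L, logical(1L)))
  if (!nested) {
    stop("groups_reduced is not a coarsening of groups_full", call. = FALSE)
  }
  ref_f <- if (reference_full %in% levels(groups_full)) reference_full else
    levels(groups_full)[1L]
  ref_r <- if (reference_reduced %in% levels(groups_reduced)) reference_reduced else
    levels(groups_reduced)[1L]
  fit_full <- fit_cox_groups(cohort, groups_full, ref_f)
  fit_red <- fit_cox_groups(cohort, groups_reduced, ref_r)
  df <- (nlevels(groups_full) - 1L) - (nlevels(groups_reduced) - 1L)
  stat <- 2 * (fit_full$loglik - fit_red$loglik)
  stat <- max(stat, 0)
  # identical partitions (df 0): no spatial information was added
  p <- if (df == 0L) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = c(`X-squared` = stat),
                 parameter = c(df = df),
                 p.value = p,
                 method = "Likelihood ratio test: spatial vs abundance-only grouping",
                 data.name = "cohort"),
            class = "htest")
}

#' Survival analysis of a cohort, end to end
#'
#' Convenience wrapper for the downstream stage: constrained CV cut-points,
#' five-group assignment, cluster-robust Cox fit, abundance-only fit, and
#' the spatial-vs-abundance likelihood-ratio test.
#'
#' @inheritParams optimal_cutpoints
#' @param reference reference group for the Cox fits.
#' @return a `mif_survfit`: `cuts`, `groups`, `cox`, `cox_abundance`,
#'   `lrt`.
#' @export
run_survival_analysis <- function(cohort, k_folds = 10L, min_group = 10L,
                                  reference = "None", seed = NULL) {
  cuts <- optimal_cutpoints(cohort, k_folds = k_folds, min_group = min_group,
                            seed = seed)
  groups <- assign_group_univariate(cohort$abundance_pct, cohort$degree, cuts)
  cox <- fit_cox_groups(cohort, groups, reference)
  groups_ab <- coarsen_groups(groups)
  cox_ab <- fit_cox_groups(cohort, groups_ab, reference)
  lrt <- lrt_spatial_vs_abundance(cohort, groups, groups_ab,
                                  reference, reference)
  structure(list(cuts = cuts, groups = groups, cox = cox,
                 cox_abundance = cox_ab, lrt = lrt),
            class = "mif_survfit")
}

#' @export
print.mif_survfit <- function(x, ...) {
  print(x$cuts)
  cat("\n")
  print(x$cox)
  cat(sprintf("\nspatial vs abundance-only LRT: X2 = %.3f, df = %d, p = %.4g\n",
              x$lrt$statistic, x$lrt$parameter, x$lrt$p.value))
  invisible(x)
}
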