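#' Simulate an mIF-like cell sample
#'
#' Generates a homogeneous Poisson background of cells in a rectangular
#' region and labels positives either by independent Bernoulli thinning
#' (the CSR regime: positives are a random thinning of a homogeneous
#' process, so their K stays at `pi r^2`) or as a Thomas cluster process
#' superposed on uniform negatives (the clustered regime). The Thomas
#' process — Poisson parents, Poisson numbers of Gaussian-displaced
#' offspring — is used because its K has a closed form,
#' `K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa`,
#' giving an analytic oracle for the degree of clustering.
#'
#' @param window length-2 numeric: rectangle width and height in microns.
#' @param lambda background cell intensity (cells per square micron); the
#'   expected total background count is `lambda * width * height`.
#' @param positivity a list, either
#'   `list(model = "bernoulli", p = <rate>)` with `p` the marker positivity
#'   probability (typical mIF panels: 0.01--0.30), or
#'   `list(model = "thomas", kappa = <parents/um^2>, mu = <mean offspring>,
#'   sigma = <offspring sd, um>)`. Under the Thomas model positives are
#'   generated on top of the `lambda` background of negatives (parents are
#'   drawn in a window expanded by `4 sigma` so cluster edges are not
#'   thinned).
#' @param marker marker name for the positive label (default `"CD3"`).
#' @param extra_markers additional all-zero marker columns to carry.
#' @param sample_id,subject_id identifiers.
#' @param compartment compartment label given to every cell.
#' @param seed RNG seed.
#' @return a [cell_table()].
#' @export
simulate_points <- function(window = c(1000, 1000), lambda = 1e-3,
                            positivity = list(model = "bernoulli", p = 0.05),
                            marker = "CD3", extra_markers = character(0),
                            sample_id = "S1", subject_id = "P1",
                            compartment = "tumor", seed = NULL) {
  stopifnot(length(window) == 2L, all(window > 0), lambda >= 0)
  with_seed(seed, {
    A <- window[1L] * window[2L]
    n_bg <- rpois(1L, lambda * A)
    bg <- cbind(runif(n_bg, 0, window[1L]), runif(n_bg, 0, window[2L]))
    if (identical(positivity$model, "bernoulli")) {
      p <- positivity$p
      stopifnot(p >= 0, p <= 1)
      flag <- rbinom(n_bg, 1L, p)
      xy <- bg
    } else if (identical(positivity$model, "thomas")) {
      pos <- rthomas(window, positivity$kappa, positivity$mu, positivity$sigma)
      xy <- rbind(bg, pos)
      flag <- c(rep(0L, n_bg), rep(1L, nrow(pos)))
    } else {
      stop("unknown positivity model: ", positivity$model, call. = FALSE)
    }
    if (nrow(xy) == 0L) stop("simulated sample has zero cells; increase lambda",
                             call. = FALSE)
    df <- data.frame(sample_id = sample_id, subject_id = subject_id,
                     x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
    df[[marker]] <- as.integer(flag)
    for (m in extra_markers) df[[m]] <- 0L
    df$compartment <- compartment
    cell_table(df, markers = c(marker, extra_markers))
  })
}

# Thomas cluster process in [0,w1]x[0,w2]; parents simulated in a 4*sigma
# buffer so offspring intensity is homogeneous inside the window.
rthomas <- function(window, kappa, mu, sigma) {
  stopifnot(kappa > 0, mu > 0, sigma > 0)
  buf <- 4 * sigma
  n_par <- rpois(1L, kappa * (window[1L] + 2 * buf) * (window[2L] + 2 * buf))
  if (n_par == 0L) return(cbind(numeric(0), numeric(0)))
  px <- runif(n_par, -buf, window[1L] + buf)
  py <- runif(n_par, -buf, window[2L] + buf)
  n_off <- rpois(n_par, mu)
  ox <- rep(px, n_off) + rnorm(sum(n_off), 0, sigma)
  oy <- rep(py, n_off) + rnorm(sum(n_off), 0, sigma)
  keep <- ox >= 0 & ox <= window[1L] & oy >= 0 & oy <= window[2L]
  cbind(ox[keep], oy[keep])
}

#' Closed-form K of a Thomas cluster process
#'
#' `K(r) = pi r^2 + (1 - exp(-r^2 / (4 sigma^2))) / kappa`.
#'
#' @param r radius (microns).
#' @param kappa parent intensity (per square micron).
#' @param sigma offspring displacement sd (microns).
#' @return theoretical K value(s).
#' @export
thomas_k <- function(r, kappa, sigma) {
  pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa
}

#' Closed-form K of the superposition of two independent processes
#'
#' For independent processes with intensities `lambda1`, `lambda2` and K
#' functions `k1`, `k2`, the superposition has
#' `K = (lambda1^2 k1 + lambda2^2 k2 + 2 lambda1 lambda2 pi r^2) /
#' (lambda1 + lambda2)^2`. The permutation CSR null draws uniformly from
#' the superposed locations, so its mean converges to this value — the
#' analytic reference for the degree of clustering of Thomas positives
#' over a uniform background.
#'
#' @param r radius.
#' @param lambda1,lambda2 intensities of the two components.
#' @param k1,k2 their K values at `r` (defaults: CSR, `pi r^2`).
#' @return theoretical K of the superposition.
#' @export
superposition_k <- function(r, lambda1, lambda2, k1 = pi * r^2,
                            k2 = pi * r^2) {
  (lambda1^2 * k1 + lambda2^2 * k2 + 2 * lambda1 * lambda2 * pi * r^2) /
    (lambda1 + lambda2)^2
}

#' Punch cell-free holes into a sample
#'
#' Emulates TMA folds and tears: random discs are added until the target
#' fraction of the bounding region is covered (measured on a fixed 101 x
#' 101 evaluation grid), then every cell falling inside a disc is removed.
#' The surviving cells inherit the original table's attributes; the discs
#' are attached as attribute `"holes"`.
#'
#' @param cells a single-sample [cell_table()].
#' @param fraction target missing-area fraction in \[0, 1).
#' @param radius length-2 range of disc radii (microns).
#' @param seed RNG seed.
#' @return a `cell_table` with the covered cells removed.
#' @export
punch_holes <- function(cells, fraction, radius = c(50, 120), seed = NULL) {
  stopifnot(inherits(cells, "cell_table"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(cells)
  with_seed(seed, {
    xr <- range(cells$x); yr <- range(cells$y)
    gx <- seq(xr[1L], xr[2L], length.out = 101L)
    gy <- seq(yr[1L], yr[2L], length.out = 101L)
    grid <- cbind(rep(gx, times = 101L), rep(gy, each = 101L))
    covered <- rep(FALSE, nrow(grid))
    holes <- list()
    max_holes <- 10000L
    while (mean(covered) < fraction && length(holes) < max_holes) {
      cx <- runif(1L, xr[1L], xr[2L])
      cy <- runif(1L, yr[1L], yr[2L])
      rr <- runif(1L, radius[1L], radius[2L])
      holes[[length(holes) + 1L]] <- c(cx, cy, rr)
      covered <- covered | ((grid[, 1L] - cx)^2 + (grid[, 2L] - cy)^2 <= rr^2)
    }
    hmat <- do.call(rbind, holes)
    keep <- rep(TRUE, nrow(cells))
    for (i in seq_len(nrow(hmat))) {
      keep <- keep & ((cells$x - hmat[i, 1L])^2 +
                      (cells$y - hmat[i, 2L])^2 > hmat[i, 3L]^2)
    }
    out <- cells[keep, , drop = FALSE]
    for (a in c("markers", "has_compartment", "units")) {
      attr(out, a) <- attr(cells, a)
    }
    class(out) <- class(cells)
    attr(out, "holes") <- data.frame(x = hmat[, 1L], y = hmat[, 2L],
                                     r = hmat[, 3L])
    attr(out, "covered_fraction") <- mean(covered)
    out
  })
}

#' Simulate a survival cohort with known ground truth
#'
#' Emulates the shape of an ovarian-cancer mIF study: ~90 subjects with up
#' to 3 tissue samples each, a true abundance-by-clustering group per
#' subject, and exponential survival times whose log-hazard adds age,
#' stage and the group's log hazard ratio (proportional hazards hold by
#' construction, so Cox recovery is well posed). Censoring is independent
#' uniform.
#'
#' Two levels of fidelity:
#' * `level = "summary"` draws each sample's abundance and clustering
#'   degree directly from group-dependent distributions separated by the
#'   true cuts (`truth$cuts`), skipping point patterns — fast, for
#'   exercising the survival stage.
#' * `level = "cells"` generates an actual point pattern per sample
#'   (Bernoulli labels for Low clustering, Thomas positives for High), to
#'   be fed through [cohort_degree()].
#'
#' @param n_subjects number of subjects.
#' @param samples_per_subject samples (cores/ROIs) per subject.
#' @param group_probs named probabilities over
#'   `c("None","LL","LH","HL","HH")`.
#' @param log_hr named true log hazard ratios per group (reference `None`
#'   should be 0).
#' @param level `"summary"` or `"cells"` (see above).
#' @param abundance_low,abundance_high positivity rates of the Low/High
#'   abundance regimes (proportions).
#' @param degree_high true mean degree of the High clustering regime in
#'   summary mode (Low is centred at 0); the true degree cut is half this.
#' @param lambda,window background intensity and window for `"cells"` mode.
#' @param kappa,sigma Thomas parameters for the High clustering regime.
#' @param age_beta,stage_beta covariate effects on the log hazard
#'   (`stage_beta` has entries for stages II--IV against I).
#' @param baseline_hazard exponential baseline hazard per month.
#' @param censor_max administrative censoring horizon (months); censoring
#'   times are uniform on (0, `censor_max`).
#' @param seed RNG seed.
#' @return list with `clinical` (a [clinical_table()]), `truth` (per
#'   subject group, per sample regime, generating parameters, true cuts)
#'   and either `cohort` (summary mode: ready for [build_cohort()]
#'   consumers, with `abundance_pct`, `degree`, `estimable` joined to the
#'   clinical fields) or `cells` (cells mode: named list of `cell_table`s).
#' @export
simulate_cohort <- function(n_subjects = 90L, samples_per_subject = 3L,
                            group_probs = c(None = 0.2, LL = 0.2, LH = 0.2,
                                            HL = 0.2, HH = 0.2),
                            log_hr = c(None = 0, LL = -0.3, LH = -0.2,
                                       HL = -1.9, HH = -0.5),
                            level = c("summary", "cells"),
                            abundance_low = 0.01, abundance_high = 0.04,
                            degree_high = 1000,
                            lambda = 2.5e-4, window = c(1000, 1000),
                            kappa = 5e-5, sigma = 15,
                            age_beta = 0.02, stage_beta = c(0.2, 0.5, 0.8),
                            baseline_hazard = log(2) / 36,
                            censor_max = 120, seed = NULL) {
  level <- match.arg(level)
  groups <- group_levels_uni
  stopifnot(all(names(group_probs) == groups), all(names(log_hr) == groups))
  with_seed(seed, {
    subj <- sprintf("P%03d", seq_len(n_subjects))
    g <- sample(groups, n_subjects, replace = TRUE, prob = group_probs)
    age <- rnorm(n_subjects, 58, 10)
    stage <- sample(c("I", "II", "III", "IV"), n_subjects, replace = TRUE,
                    prob = c(0.1, 0.15, 0.45, 0.3))
    lp <- age_beta * (age - 58) +
      c(0, stage_beta)[match(stage, c("I", "II", "III", "IV"))] +
      log_hr[g]
    t_event <- rexp(n_subjects, rate = baseline_hazard * exp(lp))
    t_cens <- if (is.finite(censor_max)) runif(n_subjects, 0, censor_max) else
      rep(Inf, n_subjects)   # censor_max = Inf: every event observed
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(time, 1e-3)
    clinical <- clinical_table(data.frame(
      subject_id = subj, time_months = time, event = event,
      age_dx = age, stage = stage, stringsAsFactors = FALSE))

    n_samp <- n_subjects * samples_per_subject
    samp_subj <- rep(subj, each = samples_per_subject)
    samp_group <- rep(g, each = samples_per_subject)
    samp_id <- sprintf("%s_s%d", samp_subj,
                       rep(seq_len(samples_per_subject), n_subjects))
    truth <- list(group = setNames(g, subj),
                  sample_group = setNames(samp_group, samp_id),
                  cuts = c(abundance = 100 * (abundance_low + abundance_high) / 2,
                           degree = degree_high / 2),
                  log_hr = log_hr, group_probs = group_probs,
                  age_beta = age_beta, stage_beta = stage_beta,
                  baseline_hazard = baseline_hazard, seed = seed)

    if (level == "summary") {
      ab <- numeric(n_samp); dg <- numeric(n_samp)
      a_lo <- 100 * abundance_low; a_hi <- 100 * abundance_high
      for (i in seq_len(n_samp)) {
        gi <- samp_group[i]
        ab[i] <- switch(gi, None = 0,
                        LL = , LH = runif(1L, 0.25 * a_lo, 1.75 * a_lo),
                        HL = , HH = runif(1L, 1.25 * a_hi, 3 * a_hi))
        dg[i] <- switch(gi, None = NA_real_,
                        LL = , HL = rnorm(1L, 0, degree_high / 8),
                        LH = , HH = rnorm(1L, degree_high, degree_high / 8))
      }
      cohort <- data.frame(sample_id = samp_id, subject_id = samp_subj,
                           phenotype = "CD3", r = 30,
                           abundance_pct = ab, degree = dg,
                           estimable = !is.na(dg), stringsAsFactors = FALSE)
      cohort <- build_cohort(cohort, clinical)
      list(cohort = cohort, clinical = clinical, truth = truth)
    } else {
      A <- window[1L] * window[2L]
      n_parents <- kappa * A
      cells <- vector("list", n_samp)
      for (i in seq_len(n_samp)) {
        gi <- samp_group[i]
        pos_model <- switch(gi,
          None = list(model = "bernoulli", p = 0),
          LL = list(model = "bernoulli", p = abundance_low),
          HL = list(model = "bernoulli", p = abundance_high),
          LH = list(model = "thomas", kappa = kappa, sigma = sigma,
                    mu = abundance_low * lambda * A / n_parents),
          HH = list(model = "thomas", kappa = kappa, sigma = sigma,
                    mu = abundance_high * lambda * A / n_parents))
        cells[[i]] <- simulate_points(window, lambda, pos_model,
                                      marker = "CD3",
                                      sample_id = samp_id[i],
                                      subject_id = samp_subj[i])
      }
      names(cells) <- samp_id
      list(cells = cells, clinical = clinical, truth = truth)
    }
  })
}
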