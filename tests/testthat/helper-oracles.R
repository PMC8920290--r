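# Independent oracles and small fixtures used across the suite.

# Naive double-loop Ripley's K: same pair weights as the package (via the
# exported single-pair edge_weight), but the summation, indicator and
# normalisation are re-derived here from the estimator definition.
naive_k <- function(points, window, r, correction) {
  n <- nrow(points)
  acc <- numeric(length(r))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      hit <- d < r
      if (any(hit)) {
        w <- edge_weight(points[i, ], points[j, ], window, correction, cap = n)
        acc[hit] <- acc[hit] + w
      }
    }
  }
  window$area * acc / (n * (n - 1))
}

naive_k_cross <- function(anchors, others, window, r, correction) {
  n1 <- nrow(anchors); n2 <- nrow(others)
  acc <- numeric(length(r))
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      d <- sqrt(sum((anchors[i, ] - others[j, ])^2))
      hit <- d < r
      if (any(hit)) {
        w <- edge_weight(anchors[i, ], others[j, ], window, correction,
                         cap = n1 + n2)
        acc[hit] <- acc[hit] + w
      }
    }
  }
  window$area * acc / (n1 * n2)
}

# Hand-coded multi-group log-rank chi-square (observed vs expected events
# at each distinct event time, hypergeometric variance omitted in favour of
# the classical O-E form used by the score test).
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  g <- levels(group)
  times <- sort(unique(time[event == 1]))
  O <- setNames(numeric(length(g)), g)
  E <- setNames(numeric(length(g)), g)
  V <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    for (k in g) {
      n_k <- sum(at_risk & group == k)
      O[k] <- O[k] + sum(event == 1 & time == t & group == k)
      E[k] <- E[k] + d_t * n_k / n_t
    }
    if (n_t > 1) {
      for (k in g) for (l in g) {
        n_k <- sum(at_risk & group == k)
        n_l <- sum(at_risk & group == l)
        V[k, l] <- V[k, l] + d_t * (n_t - d_t) / (n_t - 1) *
          (n_k * ((k == l) * n_t - n_l)) / n_t^2
      }
    }
  }
  u <- (O - E)[-1L]
  Vr <- V[-1L, -1L, drop = FALSE]
  drop(t(u) %*% solve(Vr, u))
}

square_window <- function(side = 1000) {
  convex_hull_window(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)))
}

runif_points <- function(n, side = 1000) {
  cbind(runif(n, 0, side), runif(n, 0, side))
}

# minimal cell table around given coordinates / flags
make_cells <- function(xy, flags, sample_id = "S1", subject_id = "P1",
                       marker = "CD3", compartment = NULL) {
  df <- data.frame(sample_id = sample_id, subject_id = subject_id,
                   x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
  df[[marker]] <- as.integer(flags)
  if (!is.null(compartment)) df$compartment <- compartment
  cell_table(df, markers = marker)
}
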