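# Independent oracles used to validate the package's implementations.
# Each is a deliberately naive hand computation, sharing no code with R/.

# Naive unweighted cross-K double loop: exact match to cross_k expected on
# patterns whose points all lie >= r from every boundary (all weights 1).
naive_cross_k <- function(pattern, ref_type, target_type, r) {
  ref <- select_cells(pattern, ref_type)$cells
  tgt <- select_cells(pattern, target_type)$cells
  A <- (pattern$window$x_max - pattern$window$x_min) *
       (pattern$window$y_max - pattern$window$y_min)
  same <- identical(ref_type, target_type)
  denom <- if (same) nrow(ref) * (nrow(ref) - 1) else nrow(ref) * nrow(tgt)
  total <- 0
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(tgt))) {
      if (ref$.row[i] == tgt$.row[j]) next
      d <- sqrt((ref$x[i] - tgt$x[j])^2 + (ref$y[i] - tgt$y[j])^2)
      if (d <= r) total <- total + 1
    }
  }
  A / denom * total
}

# Two-group log-rank by direct O-E/V tabulation over the risk table.
hand_log_rank <- function(groups, times, events) {
  g <- as.integer(factor(groups)) == 1L
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Exhaustive cut-point scan built on survdiff (a different log-rank route
# than the vectorized tabulation inside optimal_cutpoint).
brute_cutpoint <- function(values, times, events, min_group_frac = 0.10,
                           min_group_size = 1L) {
  n <- length(values)
  min_size <- max(ceiling(min_group_frac * n), min_group_size)
  best <- list(p_value = Inf, cutpoint = NA_real_)
  for (cand in sort(unique(values))) {
    hi <- values > cand
    if (sum(hi) < min_size || n - sum(hi) < min_size) next
    sd1 <- survival::survdiff(survival::Surv(times, events) ~ hi)
    p <- pchisq(sd1$chisq, df = 1, lower.tail = FALSE)
    if (p < best$p_value) {
      best <- list(p_value = p, cutpoint = cand, chi2 = unname(sd1$chisq))
    }
  }
  best
}

# Exact two-sided paired Wilcoxon signed-rank p by full sign-flip
# enumeration (valid for nonzero differences without tied magnitudes).
permutation_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wperm <- as.vector(signs %*% rk)
  p_up <- mean(Wperm >= W)
  p_dn <- mean(Wperm <= W)
  min(1, 2 * min(p_up, p_dn))
}

# Spearman rho via explicit rank transform + product-moment on ranks.
hand_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Deterministic interior-only pattern builder for oracle-equivalence tests.
interior_pattern <- function(n_ref, n_tgt, r, window = pp_window(),
                             seed = 1) {
  set.seed(seed)
  pad <- r + 1
  cells <- data.frame(
    x = runif(n_ref + n_tgt, window$x_min + pad, window$x_max - pad),
    y = runif(n_ref + n_tgt, window$y_min + pad, window$y_max - pad),
    cell_class = rep(c("tumor", "other"), c(n_ref, n_tgt)),
    cd68 = rep(c(0L, 1L), c(n_ref, n_tgt)))
  marked_point_pattern(cells, window)
}
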