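# Fixture builders and independent oracles used across the suite.
# Oracles deliberately avoid the code paths (and where possible the
# primitives) of the implementation they check.

make_counts <- function(mat, condition = "tumor") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  expr_matrix(mat, condition = condition)
}

random_counts <- function(n_genes, n_samples, seed, lambda = 50) {
  set.seed(seed)
  make_counts(matrix(rpois(n_genes * n_samples, lambda), n_genes))
}

# 67-entry panel with the 14/15/38 family split
fixture_panel <- function() synthetic_panel()

# --- oracles ---------------------------------------------------------------

# median-of-ratios by direct enumeration (loops, no matrix tricks)
oracle_size_factors <- function(mat) {
  ref <- which(apply(mat, 1, function(r) all(r > 0)))
  geo <- sapply(ref, function(i) prod(mat[i, ])^(1 / ncol(mat)))
  sapply(seq_len(ncol(mat)), function(j) {
    ratios <- sapply(seq_along(ref), function(k) mat[ref[k], j] / geo[k])
    median(ratios)
  })
}

# average ranks then Pearson by the direct sum formula
oracle_spearman <- function(mat) {
  ranks <- t(apply(mat, 1, rank))  # average ranks for ties
  g <- nrow(mat)
  out <- diag(1, g)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      x <- ranks[i, ] - mean(ranks[i, ])
      y <- ranks[j, ] - mean(ranks[j, ])
      out[i, j] <- out[j, i] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# Eq.-style z-score composed from log-formula arctanh and the printed denominator
oracle_diff_z <- function(rho_t, rho_c, n_t, n_c) {
  zt <- 0.5 * log((1 + rho_t) / (1 - rho_t))
  zc <- 0.5 * log((1 + rho_c) / (1 - rho_c))
  (zt - zc) / sqrt(1 / (n_t - 3) + 1 / (n_c - 3))
}

# Benjamini-Hochberg by the step-up rule, enumerated
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, n * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# product-limit estimator by explicit looping over event times
oracle_km <- function(time, event) {
  times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (k in seq_along(times)) {
    at_risk <- sum(time >= times[k])
    d <- sum(time == times[k] & event)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# two-group log-rank by the observed-minus-expected formula
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}
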