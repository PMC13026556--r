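corr_from <- function(rho, n, cond = "x") {
  structure(rho, n_samples = as.integer(n), condition = cond,
            class = c("corr_mat", "matrix", "array"))
}

named_corr <- function(g, n, fill = 0) {
  rho <- matrix(fill, g, g, dimnames = list(paste0("G", 1:g), paste0("G", 1:g)))
  diag(rho) <- 1
  corr_from(rho, n)
}

test_that("Fisher transform matches its closed form, is odd, and clamps at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-15)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-15)
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
  expect_error(fisher_z(1.01), "exceed")
})

test_that("the differential z-score matches the arithmetic oracle and its symmetries", {
  # zero at equality, for any valid cohort sizes
  for (n in c(5, 50, 500)) expect_equal(differential_zscore(0.4, 0.4, n, n + 7), 0)
  # antisymmetry under swapping the two conditions (equal n)
  expect_equal(differential_zscore(0.7, 0.2, 100, 100),
               -differential_zscore(0.2, 0.7, 100, 100))
  # the glioblastoma-scale case, step by step
  expect_equal(differential_zscore(0.6, 0.1, 145, 255),
               oracle_diff_z(0.6, 0.1, 145, 255), tolerance = 1e-12)
  expect_error(differential_zscore(0.5, 0.1, 3, 100), "more than 3")

  # composition with fisher_z and the explicit denominator, random draws
  set.seed(99)
  for (i in 1:200) {
    rt <- runif(1, -0.98, 0.98); rc <- runif(1, -0.98, 0.98)
    nt <- sample(5:500, 1); nc <- sample(5:500, 1)
    expect_equal(differential_zscore(rt, rc, nt, nc),
                 oracle_diff_z(rt, rc, nt, nc), tolerance = 1e-12)
  }

  # |Z| grows with the smaller cohort at fixed correlations
  zs <- sapply(c(10, 30, 100, 300), function(n) abs(differential_zscore(0.5, 0.2, n, n)))
  expect_true(all(diff(zs) > 0))
})

test_that("differential networks threshold at Z >= cutoff over all pairs", {
  ct <- named_corr(4, 100)
  cc <- named_corr(4, 150)
  # identical correlation structure -> no differential edges
  expect_equal(nrow(build_differential_network(ct, cc)$edges), 0L)

  # single strong pair: retained iff its oracle Z clears the threshold
  ct2 <- named_corr(4, 100); ct2[1, 2] <- ct2[2, 1] <- 0.9
  z <- oracle_diff_z(0.9, 0, 100, 100)
  net <- build_differential_network(ct2, named_corr(4, 100), z_threshold = 3)
  expect_equal(nrow(net$edges), as.integer(z >= 3))
  expect_equal(net$edges$Z, z, tolerance = 1e-12)
  # boundary is inclusive
  at <- build_differential_network(ct2, named_corr(4, 100), z_threshold = z)
  expect_equal(nrow(at$edges), 1L)

  # threshold of -Inf gives the complete graph when the positive mask is off
  full <- build_differential_network(ct, cc, z_threshold = -Inf, positive_only = FALSE)
  expect_equal(nrow(full$edges), 4 * 3 / 2)
  expect_equal(full$density, 1)

  # mask keeps only pairs with positive tumor correlation
  ct3 <- named_corr(3, 50); ct3[1, 2] <- ct3[2, 1] <- -0.2
  ct3[1, 3] <- ct3[3, 1] <- 0.2
  cc3 <- named_corr(3, 50); cc3[1, 2] <- cc3[2, 1] <- -0.9; cc3[1, 3] <- cc3[3, 1] <- -0.9
  masked <- build_differential_network(ct3, cc3, z_threshold = 3)
  expect_equal(nrow(masked$edges), 1L)
  expect_true(all(masked$edges$rho_T > 0))
  unmasked <- build_differential_network(ct3, cc3, z_threshold = 3, positive_only = FALSE)
  expect_equal(nrow(unmasked$edges), 2L)

  bad <- named_corr(4, 100)
  rownames(bad) <- colnames(bad) <- paste0("H", 1:4)
  expect_error(build_differential_network(ct, bad), "same genes")
})

test_that("density matching scans all distinct Z values and prefers the stricter tie", {
  set.seed(31)
  mk <- function(n, seed) {
    set.seed(seed)
    m <- matrix(rnorm(10 * n), 10, dimnames = list(paste0("G", 1:10), NULL))
    colnames(m) <- paste0("S", seq_len(n))
    spearman_matrix(expr_matrix(m, "x", units = "normalized_log2"))
  }
  ref <- build_differential_network(mk(40, 1), mk(60, 2), z_threshold = 1)
  expect_gt(nrow(ref$edges), 0)

  # identical second comparison reproduces the reference density exactly
  same <- match_density_threshold(ref, mk(40, 1), mk(60, 2))
  expect_equal(same$network$density, ref$density)

  # chosen threshold equals an exhaustive scan with high-tie preference
  ct2 <- mk(35, 3); cc2 <- mk(55, 4)
  got <- match_density_threshold(ref, ct2, cc2)
  probe <- build_differential_network(ct2, cc2, z_threshold = -Inf)
  cand <- probe$pairs$Z[probe$pairs$rho_T > 0]
  n_pairs <- 10 * 9 / 2
  best <- Inf; best_t <- NA
  for (t in sort(unique(cand), decreasing = TRUE)) {
    d <- sum(cand >= t) / n_pairs
    if (abs(d - ref$density) < best) { best <- abs(d - ref$density); best_t <- t }
  }
  expect_equal(got$threshold, best_t)
  expect_equal(got$network$z_threshold, best_t)

  empty <- build_differential_network(mk(40, 1), mk(40, 1), z_threshold = 99)
  expect_error(match_density_threshold(empty, ct2, cc2), "no edges")
})

# build a diff_net directly from an edge list, for graph-shape tests
net_from_edges <- function(nodes, edges) {
  tbl <- tibble::tibble(gene_a = edges[, 1], gene_b = edges[, 2],
                        rho_T = 0.5, rho_C = 0, z_T = fisher_z(0.5), z_C = 0,
                        Z = 5)
  structure(list(nodes = nodes, edges = tbl, z_threshold = 3,
                 n_T = 100L, n_C = 100L,
                 density = nrow(tbl) / (length(nodes) * (length(nodes) - 1) / 2),
                 positive_only = TRUE, pairs = tbl),
            class = "diff_net")
}

test_that("degrees come from edge incidence, with optional isolated nodes", {
  tri <- net_from_edges(c("A", "B", "C"),
                        cbind(c("A", "B", "A"), c("B", "C", "C")))
  expect_equal(node_degrees(tri)$degree, c(2L, 2L, 2L))

  leaves <- paste0("L", 1:8)
  star <- net_from_edges(c("hub", leaves, "iso"), cbind("hub", leaves))
  deg <- node_degrees(star, include_isolated = TRUE)
  expect_equal(deg$degree[deg$gene == "hub"], 8L)
  expect_equal(deg$degree[deg$gene == "iso"], 0L)
  expect_false("iso" %in% node_degrees(star)$gene)

  # random graph: degrees equal adjacency row sums
  set.seed(5)
  nodes <- paste0("N", 1:12)
  pairs <- t(combn(nodes, 2))
  keep <- pairs[runif(nrow(pairs)) < 0.3, , drop = FALSE]
  net <- net_from_edges(nodes, keep)
  adj <- matrix(0L, 12, 12, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(keep))) {
    adj[keep[i, 1], keep[i, 2]] <- adj[keep[i, 2], keep[i, 1]] <- 1L
  }
  deg <- node_degrees(net, include_isolated = TRUE)
  expect_equal(deg$degree[match(nodes, deg$gene)], unname(rowSums(adj)))
})

test_that("hub calling follows the degree-percentile rule", {
  leaves <- paste0("L", 1:8)
  star <- net_from_edges(c("hub", leaves), cbind("hub", leaves))
  hr <- identify_hubs(star, percentile = 80)
  expect_equal(hr$hubs, "hub")
  expect_equal(hr$degree_cutoff, 8L)

  # degree-regular network: everyone is a hub
  tri <- net_from_edges(c("A", "B", "C"), cbind(c("A", "B", "A"), c("B", "C", "C")))
  expect_setequal(identify_hubs(tri, 80)$hubs, c("A", "B", "C"))

  # percentile 0: every connected node is a hub, isolated nodes are not
  star_iso <- net_from_edges(c("hub", leaves, "iso"), cbind("hub", leaves))
  h0 <- identify_hubs(star_iso, percentile = 0)
  expect_setequal(h0$hubs, c("hub", leaves))

  # invariant to node relabeling
  relabeled <- net_from_edges(c("x", paste0("y", 1:8)),
                              cbind("x", paste0("y", 1:8)))
  expect_equal(length(identify_hubs(relabeled, 80)$hubs), 1L)
  expect_equal(identify_hubs(relabeled, 80)$hubs, "x")

  empty <- net_from_edges(c("A", "B"), cbind(character(0), character(0)))
  expect_error(identify_hubs(empty), "no edges")
})

test_that("network comparison reports degree agreement and hub overlap", {
  leaves <- paste0("L", 1:8)
  net <- net_from_edges(c("hub", leaves), cbind("hub", leaves))
  # extra edges so several nodes clear the min_degree restriction
  extra <- net_from_edges(c("hub", leaves),
                          rbind(cbind("hub", leaves), t(combn(leaves[1:6], 2))))
  self_cmp <- compare_networks(extra, extra, min_degree = 5)
  expect_equal(self_cmp$degree_rank_correlation, 1)
  expect_length(self_cmp$hub_overlap$only_a, 0)
  expect_length(self_cmp$hub_overlap$only_b, 0)
  expect_setequal(self_cmp$hub_overlap$shared, identify_hubs(extra)$hubs)

  expect_error(compare_networks(net, net, min_degree = 50), "fewer than 3")
})
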