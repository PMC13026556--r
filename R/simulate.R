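#' Configure a two-condition synthetic study
#'
#' Defines the conditions of a simulated tumor-vs-healthy co-expression
#' study: a lectin-sized gene panel with a block of genes whose pairwise
#' correlation exists only in the tumor condition (planted differential
#' hubs), a set of lowly expressed genes destined for the count filter,
#' negative-binomial count marginals coupled through a Gaussian copula, and
#' survival outcomes whose hazard depends on a two-gene high/low grouping.
#'
#' Defaults mirror a glioblastoma-scale design: 39 well-expressed panel
#' genes plus 18 low-count genes (57 measured of a 67-gene panel), 145
#' tumor and 255 control samples, one planted hub with 8 neighbors at
#' latent correlation 0.7, and exponential survival with a hazard ratio of
#' 3 for the high-expression group against a median survival of about a
#' year, with 20% independent censoring.
#'
#' @param n_genes Number of well-expressed panel genes.
#' @param n_lowcount_genes Genes simulated at low abundance so their total
#'   count falls below the 500-count filter.
#' @param n_tumor,n_control Cohort sizes (each > 3).
#' @param hub_spec List of planted hubs, each `list(n_neighbors=, rho=)`
#'   with latent correlation in (0, 1); neighborhoods are disjoint.
#' @param background_rho Baseline latent correlation between all genes.
#' @param nb_mean Median negative-binomial mean of expressed genes
#'   (per-gene means are drawn log-normally around it).
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param n_de_genes,de_log2fc Number of genes given a true log2 mean shift
#'   in the tumor condition, and the shift.
#' @param survival List: `baseline_hazard` (events/month), `hazard_ratio`
#'   for the true high group, `censoring_rate` in \[0, 1\].
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 39,
                              n_lowcount_genes = 18,
                              n_tumor = 145,
                              n_control = 255,
                              hub_spec = list(list(n_neighbors = 8, rho = 0.7)),
                              background_rho = 0,
                              nb_mean = 100,
                              nb_dispersion = 0.5,
                              n_de_genes = 5,
                              de_log2fc = 2,
                              survival = list(baseline_hazard = 1 / 12,
                                              hazard_ratio = 3,
                                              censoring_rate = 0.2),
                              seed = 1L) {
  if (n_tumor <= 3 || n_control <= 3) stop("cohorts need more than 3 samples", call. = FALSE)
  for (h in hub_spec) {
    if (h$rho <= 0 || h$rho >= 1) stop("latent hub correlation must lie in (0, 1)", call. = FALSE)
  }
  needed <- sum(vapply(hub_spec, function(h) h$n_neighbors + 1, numeric(1)))
  if (needed > n_genes) {
    stop("hub neighborhoods overflow the expressed gene set (",
         needed, " > ", n_genes, ")", call. = FALSE)
  }
  if (n_genes + n_lowcount_genes > nrow(synthetic_panel())) {
    stop("gene count exceeds the synthetic panel size", call. = FALSE)
  }
  if (survival$baseline_hazard <= 0) stop("baseline hazard must be positive", call. = FALSE)
  structure(list(n_genes = n_genes, n_lowcount_genes = n_lowcount_genes,
                 n_tumor = n_tumor, n_control = n_control,
                 hub_spec = hub_spec, background_rho = background_rho,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 n_de_genes = n_de_genes, de_log2fc = de_log2fc,
                 survival = survival, seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic 67-gene lectin-style panel
#'
#' A fixed panel of 14 siglec-, 15 galectin- and 38 C-type-style synthetic
#' gene symbols (suffix `.S` marks them as synthetic), used to name
#' simulated genes and to exercise panel subsetting.
#'
#' @return A `lect_panel` of 67 entries.
#' @export
synthetic_panel <- function() {
  panel(c(sprintf("SIGLEC.S%02d", 1:14),
          sprintf("LGALS.S%02d", 1:15),
          sprintf("CLEC.S%02d", 1:38)),
        c(rep("siglec", 14), rep("galectin", 15), rep("ctype", 38)))
}

#' Simulate two-condition counts with planted differential hubs
#'
#' Draws a latent multivariate Gaussian per condition — hub-neighbor
#' correlation (one-factor structure: hub at `rho`, neighbor pairs at
#' `rho^2`) present only in the tumor condition, `background_rho` elsewhere
#' — and maps it through a Gaussian copula to negative-binomial count
#' marginals. Low-count genes get small means so their totals fall below
#' the 500-count filter; DE genes get a `de_log2fc` mean shift in the
#' tumor condition. Deterministic given the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `tumor` and `control` (`lect_expr`, raw counts) and
#'   `truth`, a `sim_truth` list with `planted_hubs`, `planted_edges`
#'   (tibble gene_a/gene_b, always hub-anchored), `block_genes`,
#'   `de_genes` (tibble gene, log2_shift), `lowcount_genes`, and
#'   `survival_groups` (tibble subject, group) for the tumor cohort based
#'   on the latent (noise-free) signal of the first two block genes.
#' @export
generate_two_condition_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g_total <- cfg$n_genes + cfg$n_lowcount_genes
  genes <- synthetic_panel()$gene[seq_len(g_total)]
  expressed <- genes[seq_len(cfg$n_genes)]
  lowcount <- if (cfg$n_lowcount_genes > 0) genes[(cfg$n_genes + 1):g_total] else character(0)

  # assign hub blocks from the front of the expressed genes, disjointly
  blocks <- list()
  cursor <- 1L
  for (h in cfg$hub_spec) {
    idx <- cursor:(cursor + h$n_neighbors)
    blocks[[length(blocks) + 1L]] <- list(hub = expressed[idx[1]],
                                          neighbors = expressed[idx[-1]],
                                          rho = h$rho)
    cursor <- cursor + h$n_neighbors + 1L
  }
  de_genes <- if (cfg$n_de_genes > 0) {
    utils::tail(expressed, cfg$n_de_genes)
  } else character(0)

  sig_t <- latent_sigma(genes, blocks, cfg$background_rho)
  sig_c <- latent_sigma(genes, list(), cfg$background_rho)

  draws <- with_seed(cfg$seed, {
    mu <- stats::rlnorm(cfg$n_genes, meanlog = log(cfg$nb_mean), sdlog = 1)
    mu_low <- stats::runif(cfg$n_lowcount_genes, 0.1, 1.0)
    z_t <- matrix(stats::rnorm(cfg$n_tumor * g_total), cfg$n_tumor) %*% chol(sig_t)
    z_c <- matrix(stats::rnorm(cfg$n_control * g_total), cfg$n_control) %*% chol(sig_c)
    list(mu = mu, mu_low = mu_low, z_t = z_t, z_c = z_c)
  })
  mu_all <- stats::setNames(c(draws$mu, draws$mu_low), genes)
  mu_tumor <- mu_all
  mu_tumor[de_genes] <- mu_tumor[de_genes] * 2^cfg$de_log2fc

  size <- 1 / cfg$nb_dispersion
  counts_t <- copula_counts(draws$z_t, mu_tumor, size)
  counts_c <- copula_counts(draws$z_c, mu_all, size)
  rownames(counts_t) <- rownames(counts_c) <- genes
  colnames(counts_t) <- sprintf("T%03d", seq_len(cfg$n_tumor))
  colnames(counts_c) <- sprintf("C%03d", seq_len(cfg$n_control))

  # true high/low grouping from the noise-free latent signal of two markers
  marker_idx <- match(marker_genes(blocks, expressed), genes)
  latent_sum <- rowSums(draws$z_t[, marker_idx, drop = FALSE])
  grp <- ifelse(latent_sum > stats::median(latent_sum), "high", "low")

  truth <- structure(list(
    planted_hubs = vapply(blocks, `[[`, character(1), "hub"),
    planted_edges = purrr::map_dfr(blocks, function(b) {
      tibble::tibble(gene_a = b$hub, gene_b = b$neighbors)
    }),
    block_genes = lapply(blocks, function(b) c(b$hub, b$neighbors)),
    de_genes = tibble::tibble(gene = de_genes,
                              log2_shift = rep(cfg$de_log2fc, length(de_genes))),
    lowcount_genes = lowcount,
    survival_groups = tibble::tibble(subject = colnames(counts_t), group = grp)
  ), class = "sim_truth")

  list(tumor = expr_matrix(counts_t, condition = "tumor"),
       control = expr_matrix(counts_c, condition = "control"),
       truth = truth)
}

marker_genes <- function(blocks, expressed) {
  if (length(blocks)) c(blocks[[1]]$hub, blocks[[1]]$neighbors[1])
  else expressed[1:2]
}

latent_sigma <- function(genes, blocks, background_rho) {
  g <- length(genes)
  sig <- matrix(background_rho, g, g, dimnames = list(genes, genes))
  diag(sig) <- 1
  for (b in blocks) {
    members <- c(b$hub, b$neighbors)
    sig[members, members] <- b$rho^2        # one-factor: neighbor pairs at rho^2
    sig[b$hub, members] <- b$rho
    sig[members, b$hub] <- b$rho
  }
  diag(sig) <- 1
  sig
}

copula_counts <- function(z, mu, size) {
  u <- stats::pnorm(z)
  counts <- vapply(seq_along(mu), function(j) {
    stats::qnbinom(u[, j], size = size, mu = mu[j])
  }, numeric(nrow(z)))
  t(counts)
}

#' Simulate survival outcomes linked to the true grouping
#'
#' Exponential event times with the configured baseline hazard, multiplied
#' by the hazard ratio for subjects in the true high group. Censoring is
#' independent: each subject is censored with probability
#' `censoring_rate`, at a time uniform on (0, event time), so a rate of 1
#' censors everyone. Deterministic given the config seed.
#'
#' @param truth A `sim_truth` from [generate_two_condition_counts()].
#' @param cfg The same [simulation_config()].
#' @return A [survival_table()] with the true group labels.
#' @export
generate_survival <- function(truth, cfg) {
  stopifnot(inherits(truth, "sim_truth"), inherits(cfg, "sim_config"))
  sv <- cfg$survival
  if (sv$baseline_hazard <= 0) stop("baseline hazard must be positive", call. = FALSE)
  grp <- truth$survival_groups
  n <- nrow(grp)
  with_seed(cfg$seed + 1000003L, {
    rate <- sv$baseline_hazard * ifelse(grp$group == "high", sv$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = rate)
    censored <- stats::runif(n) < sv$censoring_rate
    time <- ifelse(censored, t_event * stats::runif(n), t_event)
    survival_table(grp$subject, time, !censored, grp$group)
  })
}

#' Serialize / restore simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path JSON path.
#' @return For `write_truth`, `truth` invisibly; for `read_truth`, the
#'   restored `sim_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, dataframe = "columns", pretty = TRUE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    planted_hubs = as.character(raw$planted_hubs),
    planted_edges = tibble::as_tibble(raw$planted_edges),
    block_genes = lapply(raw$block_genes, as.character),
    de_genes = tibble::as_tibble(raw$de_genes),
    lowcount_genes = as.character(raw$lowcount_genes),
    survival_groups = tibble::as_tibble(raw$survival_groups)
  ), class = "sim_truth")
}
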