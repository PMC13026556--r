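# lectnet

Differential co-expression network analysis for gene panels, with
degree-percentile hub detection, cross-cohort validation and survival
stratification. Built for the tumor-vs-healthy setting where a receptor
panel (e.g. siglecs, galectins and C-type lectins in glioblastoma versus
healthy brain cortex) contains genes whose *co-expression partners* change
in the tumor even when their mean expression does not.

## The statistic

For every gene pair, the Spearman correlations in the tumor cohort
(ρ_T, n_T samples) and in the control cohort (ρ_C, n_C samples) are
Fisher-transformed, z = artanh(ρ), and compared:

    Z = (z_T − z_C) / sqrt( 1/(n_T − 3) + 1/(n_C − 3) )

Pairs with Z ≥ 3 (and positive tumor correlation) form the differential
network: co-expression that appears or strengthens specifically in the
tumor. Hubs are the nodes at or above the 80th percentile of the degree
distribution. A validation cohort is thresholded by matching the discovery
network's edge density rather than at a fixed Z, and agreement is read from
the degree rank correlation and the overlap of hub sets. Subjects are then
stratified on hub-gene expression — two fuzzy C-means clusters tagged
low/high, or four median-split groups — and compared by Kaplan–Meier /
log-rank with a Mantel–Haenszel hazard ratio.

The pipeline around the statistic: panel subsetting, a strict <500 total
count filter, median-of-ratios + log2(x+1) normalization, and per-gene
Welch t-tests with Benjamini–Hochberg correction (flag: |log2FC| ≥ 1.5 and
adjusted p < 0.05) to annotate hubs as upregulated or unchanged.

A Gaussian-copula negative-binomial simulator with planted differential
hubs, low-count genes and linked survival outcomes
(`simulation_config()`, `generate_two_condition_counts()`,
`generate_survival()`) makes every stage testable without external data.

## Worked example

```r
library(lectnet)

cfg <- simulation_config(seed = 1)          # 39 panel genes, n = 145 vs 255,
sim <- generate_two_condition_counts(cfg)   # one planted hub with 8 neighbors
surv <- generate_survival(sim$truth, cfg)
validation <- generate_two_condition_counts(
  simulation_config(n_tumor = 109, seed = 20001))$tumor

report <- run_discovery_validation(
  discovery = sim$tumor, control = sim$control, validation = validation,
  panel = synthetic_panel(),
  clinical = data.frame(subject_id = surv$subject,
                        os_months = surv$time, event = surv$event),
  seed = 1)
report
```

```
# Differential co-expression run
#  discovery: 57 -> 39 genes after count filter
#  control: 57 -> 39 genes after count filter
#  validation: 57 -> 39 genes after count filter
#  differential network: 23 edges (density 0.0310), hubs: SIGLEC.S01, SIGLEC.S09
#  DE-flagged genes: 5
#  validation: threshold 2.542, degree rank corr 0.833, shared hubs: SIGLEC.S01, SIGLEC.S09
#  survival (fcm on SIGLEC.S01+SIGLEC.S09): log-rank p = 0.01153, HR = 1.59 [1.102, 2.295]
```

Reading it: 57 of the 67 panel genes were measured and 39 survive the
count filter; 23 gene pairs gain significant co-expression in the tumor
cohort; the planted hub `SIGLEC.S01` is called in the discovery network
and confirmed in the density-matched validation network; and the
fuzzy-C-means high-expression group has significantly shorter survival
(log-rank p ≈ 0.012), with the hazard ratio attenuated from the simulated
3 because stratification works on noisy expression rather than the true
grouping. Results are tibble-friendly: `tidy()` on networks, hub reports
and test results; `glance()` for one-row summaries; `autoplot()` /
`plot_km()` for degree and survival figures.

A thin command-line wrapper over the same functions lives at
`inst/cli/lectnet.R` (`simulate` and `run` subcommands).

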