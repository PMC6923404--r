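# cytoda

Multiplexed mass-cytometry (CyTOF) analysis in R: preprocessing of pooled
barcoded acquisitions, two-level SOM/consensus clustering of PBMC
phenotypes, and differential cell-population abundance between subject
groups — with a synthetic-data generator carrying full ground truth so that
every stage of the pipeline is testable without access to patient data.

## The problem

In a multiplexed CyTOF experiment, PBMC samples from every subject are
mass-tag barcoded (unique on/off combinations of metal-conjugated CD45
antibodies), pooled, stained with a ~35-antibody panel and acquired in a
single run together with EQ calibration beads.  Turning the raw event
stream into per-group biology requires, in order:

1. **Bead normalization** — instrument sensitivity drifts over the run;
   per 100-second interval (minimum 50 beads) a correction factor
   `f = median_global(bead) / median_interval(bead)` is interpolated at
   interval midpoints and applied to all ion counts.
2. **Singlet gating** — nucleated intact single cells are kept by DNA
   intercalator (¹⁹¹Ir/¹⁹³Ir) intensity and event length (10–150 pushes).
3. **Debarcoding** — each event's barcode channels are binarized by
   per-channel 2-means thresholds and matched exactly against the sample
   code book (Boolean deconvolution); non-matching patterns, including
   all-on doublets, stay unassigned.
4. **Spillover compensation** — per event, solve
   `min ‖xS − y‖²  s.t.  x ≥ 0` (non-negative least squares), where `S` is
   the spillover matrix estimated from single-stained beads as
   `S[i,j] = median_j / median_i`.
5. **arcsinh transform** — `x ↦ asinh(x / 5)`.
6. **Two-level clustering** — a 10×10 batch self-organizing map on the
   lineage markers, consensus meta-clustering of the 100 node codebook
   (100 subsampled hierarchical clusterings, maxK 25), manual merging into
   lineages, then per-lineage re-clustering on all markers (7×7 grid,
   clusters below 0.1 % of parent merged into their nearest neighbour).
7. **Differential abundance** — per cluster `c` and sample `s` with
   `y_cs` cells of `n_s`, a binomial GLMM

   `logit P(cell ∈ c | s) = β₀ + β_g·group(s) + u_s,  u_s ~ N(0, σ²)`

   fitted by Laplace approximation; Wald test of `β_g` (t reference,
   df = n_samples − 2), Benjamini–Hochberg FDR at 10 %, with a cluster
   flagged *differential* only if `p < 0.05`, `p_adj ≤ 0.10` **and** it is
   present (≥ 3 cells) in ≥ 80 % of the samples of at least one group.
8. **Bin-wise DA on an embedding** — Barnes–Hut t-SNE (perplexity 30,
   theta 0.5, 1000 iterations per 100,000 cells) of the pooled events,
   partitioned into 2^depth equal-frequency bins by recursive median
   splits; per-bin counts are tested with a negative-binomial GLM (log
   library-size offset, common profile-likelihood dispersion,
   likelihood-ratio test) and BH-adjusted.

Because the emulated study deposits no data, the package ships a
generator (`default_truth()`, `simulate_experiment()`) producing a pooled
22-sample run — 14 populations, 6 barcode channels, beads, doublets,
spillover, sensitivity drift — together with per-event ground truth, plus
`spike_differential()` to plant known abundance shifts.

## Worked example

Simulate the default two-group design with an odds-ratio-2 spike in the
`NK_dim` population of the MS group, run the pipeline, and test:

```r
library(cytoda)
truth  <- default_truth(n_events = 2000, seed = 42)
truth  <- spike_differential(truth, "NK_dim", "MS", log(2))
sim    <- simulate_experiment(truth)
scheme <- default_barcode_scheme(vapply(truth$samples, `[[`, "", "sample_id"))
pp     <- preprocess_pipeline(sim$events, scheme, spillover = truth$spillover)
pp$counts
#>             input excluded_interval              bead         gated_out
#>             45760                 0               880                14
#>          assigned        unassigned
#>             44113               753
```

Every input event lands in exactly one of the five bins (conservation is
asserted in the test-suite).  Cluster and test:

```r
keep  <- !is.na(pp$sample_id)
lin   <- pp$events$channels$name[pp$events$channels$lineage]
model <- fit_som(pp$events$values[keep, lin], seed = 42)
model <- consensus_metacluster(model, maxK = 25, seed = 42)
asg   <- choose_k_and_merge(model, 14, setNames(paste0("pop", 1:14), 1:14),
                            pp$sample_id[keep])
md    <- data.frame(sample_id = vapply(truth$samples, `[[`, "", "sample_id"),
                    group     = vapply(truth$samples, `[[`, "", "group"))
freq  <- cluster_frequencies(asg, md)
cc    <- filter_clusters(counts_from_frequencies(freq, level = "lineage"))
res   <- presence_filter(cc, test_clusters_glmm(cc))
res[order(res$p), c("cluster","estimate","se","p","p_adj","differential")][1:4, ]
#>    cluster estimate     se        p    p_adj differential
#> 4    pop12    0.807 0.0631 4.41e-11 6.18e-10         TRUE
#> 8     pop3   -0.217 0.0742 8.35e-03 5.84e-02         TRUE
#> 11    pop6   -0.226 0.0892 1.98e-02 8.87e-02         TRUE
#> 5    pop13   -0.159 0.0660 2.53e-02 8.87e-02         TRUE
```

The spiked population (here relabelled `pop12`) is recovered with a
log-odds estimate of 0.81 (truth: log 2 ≈ 0.69 plus the compositional
push-down of the other populations, which also explains the small negative
effects elsewhere).  The meta-clustering matches the generating
populations exactly (adjusted Rand index 1.0 on this run).

Cohort-level descriptive statistics reproduce the published worked
example: `fisher_exact_2x2(matrix(c(10, 1, 8, 3), 2, byrow = TRUE))`
gives p = 0.5865, and the pooled two-sample t-test for 11 + 11 subjects
has df = 20.

## Command line

A thin CLI wraps the main stages (see `inst/cli/cytoda.R`):

```sh
Rscript inst/cli/cytoda.R simulate   --seed 17 --out sim/
Rscript inst/cli/cytoda.R preprocess --fcs sim/pooled.fcs --panel sim/panel.csv \
    --barcodes sim/barcodes.csv --spillover sim/spillover.csv --out samples/
Rscript inst/cli/cytoda.R cluster    --samples samples/ --panel sim/panel.csv --k 14 --out clusters/
Rscript inst/cli/cytoda.R da         --frequencies clusters/frequencies.csv --out da/
```

## Limitations

The generator states an idealized world — lognormal marker intensities,
scalar sensitivity drift, adjacent-channel spillover, strongly separated
lineage phenotypes — described in detail (with what a green test does and
does not establish) in the methods vignette, `vignettes/cytoda-methods.Rmd`.
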