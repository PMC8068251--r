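# tcellgater

Quantile-gated T-cell state calling and spatial proximity analysis for
tumour-immunology studies.

Landscape studies of tumour-infiltrating T-cells — pancreatic ductal
adenocarcinoma being the motivating case — routinely combine three bespoke
computational layers on top of off-the-shelf preprocessing:

1. **Cluster-state calling from scRNA-seq**: fine-grained T-cell clusters
   are annotated by positivity gates over cluster-level summary statistics.
   A gene *g* is called positive in cluster *c* when its 75th-percentile
   normalised expression `q75(c,g)` exceeds a threshold τ (default 0,
   strict), or — for poorly captured genes such as *CD4* and *B3GAT1* —
   when its mean exceeds τ_mean (default 0.05). On top of a CD3 gate
   (*CD3D*/*CD3E*/*CD3G* any-positive) and an ordered DN → DP → CD4 → CD8
   lineage assignment, functional states are flagged independently:
   Treg (*FOXP3*⁺), senescent (*CD27*⁻ *CD28*⁻ *KLRG1*⁺ *B3GAT1*⁺), and
   exhausted (≥ k of {*HAVCR2*, *PDCD1*, *TOX*, *LAG3*, *CTLA4*, *TIGIT*,
   *CD38*, *ENTPD1*} positive, with *TRDC*⁺ γδ clusters vetoed). k = 4 in
   the primary ruleset; a 3-of-6 variant is also packaged.
2. **CyTOF metacluster annotation** from per-marker 0–1 normalised
   heatmaps, via marker high/low definitions (senescent CD57⁺CD27⁻CD28⁻,
   naïve CCR7⁺CD45RA⁺, activated Treg TIGIT⁺ICOS⁺CD39⁺, ...), plus
   per-patient composition statistics (median, mean, sd, CV%).
3. **Spatial proximity analysis** of phenotyped multiplex-IF cell maps:
   per-source nearest-neighbour distances, 20-band histograms to a 50 µm
   cut-off, truncated-lognormal fits reporting the geometric mean e^µ and
   R², co-localisation fractions, and epithelium/stroma infiltration
   densities.

All rules live in JSON ruleset documents, every call carries full
provenance (each rule evaluated, the value compared and the threshold),
and a synthetic-data module plants ground-truth states and spatial
structure so the whole pipeline is testable end to end without any
external download.

## Worked example

```r
library(tcellgater)

# simulate five clusters with planted states, noise-free
cfg <- expression_sim_config(
  planted_states = c(k1 = "treg", k2 = "senescent", k3 = "exhausted",
                     k4 = "none", k5 = "non_t"),
  cells_per_cluster = 500, dropout_rate = 0, seed = 1)
sim <- simulate_expression(cfg)

profiles <- sim$expr |> normalize_counts() |> cluster_summaries()
call_clusters(profiles)[c("cluster", "lineage", "treg", "senescent", "exhausted")]
#> # A tibble: 5 × 5
#>   cluster lineage   treg  senescent exhausted
#>   <chr>   <chr>     <lgl> <lgl>     <lgl>
#> 1 k1      tcell_cd4 TRUE  FALSE     FALSE
#> 2 k2      tcell_cd8 FALSE TRUE      FALSE
#> 3 k3      tcell_cd8 FALSE FALSE     TRUE
#> 4 k4      tcell_cd8 FALSE FALSE     FALSE
#> 5 k5      non_t     FALSE FALSE     FALSE
```

Every planted state is recovered: the FOXP3⁺ cluster is called a CD4 Treg,
the CD27⁻CD28⁻KLRG1⁺ cluster senescent, the cluster co-expressing the
inhibitory-receptor signature exhausted, and the CD3-null cluster is
excluded as non-T.

```r
# banded truncated-lognormal fit of nearest-neighbour distances
d <- sample_truncated_lognormal(geo_mean = 17.21, log_sd = 0.5,
                                truncation = 50, n = 1e5, seed = 1)
fit <- fit_lognormal(band_histogram(d))
fit
#> <lognormal_fit> geometric mean 17.21 um, sigma 0.504 (log scale), R2 1 [binned_ls, n = 100000]
tidy(fit)
#> # A tibble: 1 × 4
#>      mu sigma geo_mean_um r_squared
#>   <dbl> <dbl>       <dbl>     <dbl>
#> 1  2.85 0.504        17.2     1.000
```

The fit recovers the generating geometric mean (17.21 µm) from the 20-band
histogram alone; `autoplot(band_histogram(d), fit)` overlays the fitted
curve on the bands.

```r
# planted co-localisation: 90% of Tregs within 50 um of a CD8 cell
m <- simulate_tissue(tissue_scenario("fig4f_cancer_demo", seed = 7))$map
fraction_within(m[m$phenotype == "treg", ], m[m$phenotype == "cd8", ], 50)
#> [1] 0.9
```

`run_pipeline()` chains the stages behind a JSON configuration (QC →
normalise → summarise → gate/lineage/state → composition → spatial) and
writes a combined report with assumption flags; `inst/exec/tcellgater` is
a thin command-line wrapper with `simulate`, `qc`, `call-states`,
`annotate-cytof`, `spatial`, `run` and `validate` subcommands.

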