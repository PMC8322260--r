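# ktrdyn

Single-cell analysis of ERK signaling inhibition and reactivation after
BRAF inhibition.

Melanoma cells carrying BRAF^V600E^ shut down MAPK signaling within
minutes of vemurafenib treatment, yet a small subpopulation reactivates
ERK signaling almost immediately and goes on to proliferate under drug.
`ktrdyn` is for researchers analyzing kinase-translocation-reporter (KTR)
time-lapse microscopy who want to detect and quantify that heterogeneity:
it segments nuclei and perinuclear cytoplasm rings, tracks cells across
frames with drift registration, reduces each cell's activity trace to a
two-phase linear model, tests slope distributions for bimodality, and
links early signaling class to long-term lineage size. A seedable
synthetic-data generator (traces, rendered two-channel movies, lineages,
in-cell-western plates) provides ground truth for every stage.

## The model at the core

Each cell's relative ERK activity trace *y(t)* ∈ [0, 1], sampled every
10 min over 4 h, is fitted with a continuous piecewise-linear curve

> y(t) = y₀ + s_inh · min(t, t_b) + s_rec · max(0, t − t_b)

with inhibition slope *s_inh* < 0, reactivation slope *s_rec*, and one
breakpoint *t_b* (y₀ anchored to the first observation). Across a treated
population the *s_inh* sample is homogeneous (a single Gaussian), while
the *s_rec* sample is a two-component Gaussian mixture: a flat component
near 0 and a reactivating component with positive mean. Modality is
decided by Kolmogorov–Smirnov goodness-of-fit tests with
parametric-bootstrap p-values (refitting per replicate, which accounts for
estimated parameters); when the verdict is bimodal, the weight of the
higher-mean component estimates the reactivating fraction (~15% under the
default study conditions), and posterior responsibilities classify
individual cells.

## Worked example

```r
library(ktrdyn)

cohort <- simulate_traces(population_params(), seed = 42)
cohort
#> <ktr_cohort> 1000 cells, 25 time points each (15% reactivating)

fits <- cohort$traces |> normalize_trace(method = "none") |> fit_two_phase()
glance(fits)
#> # A tibble: 1 x 5
#>   n_cells mean_s_inh mean_s_rec median_t_break total_rss
#>     <int>      <dbl>      <dbl>          <dbl>     <dbl>
#> 1    1000      -1.01     0.0223          0.833      21.0

slopes <- extract_slopes(fits)
mod <- decide_modality(slopes$reactivation, alpha = 0.05, seed = 43)
mod
#> <modality_result> verdict: bimodal (p_uni = 0, p_bi = 0.64, alpha = 0.05)
#>   reactivating fraction: 14.9% (component mean 0.152 vs -0.000489)
```

The mean inhibition slope of −1.01/h says signaling shuts down within
about an hour; the bimodal verdict with component means ≈ 0.15/h versus
≈ 0/h identifies a reactivating subpopulation, and its mixture weight —
14.9% of cells — recovers the 15% fraction the generator planted.
Following those same cells over a simulated week of drug treatment links
early signaling class to proliferation:

```r
labels <- assign_cells(slopes$reactivation, mod$mixture)
lin <- simulate_lineages(ifelse(labels == "recovering", "recovering", "flat"),
                         growth_params(), seed = 44)
recs <- count_descendants(lin$events,
                          tibble::tibble(ancestor_id = lin$records$ancestor_id,
                                         signaling_class = lin$records$signaling_class),
                          horizon_days = 7)
compare_groups(recs)
#> # A tibble: 1 x 7
#>   mean_recovering mean_non_recovering n_recovering n_non_recovering p_ranksum
#>             <dbl>               <dbl>        <int>            <int>     <dbl>
#> 1            8.21                2.80          149              851  5.82e-24
```

Reactivating ancestors found lineages of ~8 cells against ~2.8 for the
rest; the rank-sum p-value (~10⁻²⁴) rejects equal lineage sizes.
`autoplot()` methods on fits and modality results, plus
`plot_lineage_sizes()` and `plot_trace_groups()`, reproduce the standard
figures for these analyses. `run_end_to_end(run_config(...))` chains all
stages with one master seed and writes every intermediate table.

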