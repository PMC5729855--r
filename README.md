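# radscreen

Gene-expression screens for radiation biodosimetry.

After an uncontrolled radiation exposure most people are not wearing a
dosimeter, so absorbed dose must be inferred some other way. One candidate
is gene expression: if a gene's transcriptional response is *predictable in
dose*, measuring its expression estimates the dose. `radscreen` screens
bulk RNA-seq count data from an irradiated model organism — a dose ×
timepoint × replicate design with unirradiated controls — for exactly such
genes, and ships a synthetic-data generator with planted ground truth so
the entire screen is testable by parameter recovery.

## The method

Given a gene × sample count matrix and a sample table (timepoint in days,
dose in roentgen, replicate):

1. **Normalize** raw counts with the median-of-ratios size-factor
   estimator: sⱼ = medianᵍ kᵍⱼ / (∏ⱼ′ kᵍⱼ′)^(1/S) over genes with no zero
   count, rescaled to unit geometric mean.
2. **Average** replicates per (gene, timepoint, dose) condition.
3. **Fold changes** FC = mean(dose) / mean(0 R control, same timepoint),
   ignored when both means fall below a **bottom-quartile presence cutoff**
   (~18–20 counts at the default simulated expression scale).
4. **Linear screen:** per gene and timepoint, OLS of fold change on dose
   (linear roentgen scale, control point excluded); select genes with
   R² > 0.9 (strict) and ≥ 4 doses passing the cutoff. A secondary analysis
   drops the lowest dose (10 R, negligible for flies) and reruns the fit on
   the four remaining doses.
5. **Spike screen:** flag genes whose largest fold change is ≥ 5× the
   second largest and > 1 — an expression burst at a single dose. Spikes at
   the highest analyzed dose are excluded from the by-dose report (they
   look like monotone increases) but kept in the gene sets.
6. **Overlaps:** intersections of the selected sets across every
   combination of timepoints. Genes selected at *all* timepoints are the
   dosimeter candidates.

The simulator plants dose-linear genes (expected FC = 1 + slope·dose),
spike genes, and nulls in the study's own design — 3 timepoints × 6 doses ×
3 replicates with one dropped control replicate — under negative-binomial
noise (variance = μ + αμ²), and `recovery_metrics()` scores any screen
result against the planted truth.

## Worked example

```r
library(radscreen)
cfg <- sim_config(n_genes = 1000, nb_dispersion = 0.05, seed = 42)
res <- run_pipeline(pipeline_config(simulate = cfg))
#> input: 1000 genes, 53 samples
#> cutoff day 2: 19.19; cutoff day 10: 18.97; cutoff day 20: 19.30
#> fold changes: 11594 defined of 15000
#> linear: 44/43/52 selected
#> linear_no_low: 65/69/79 selected
#> spike: 10/10/10 selected
#> spike_no_low: 10/10/10 selected
```

The log shows the cascade: per-timepoint presence cutoffs near 19 counts,
11,594 of 15,000 gene × timepoint × dose fold changes defined (the rest
fall below the cutoff), then the four analyses (linear and spike, each with
and without the 10 R dose). Against the planted truth:

```r
res$recovery$linear$per_timepoint
#>   timepoint_days sensitivity    null_fpr spike_in_linear
#> 1              2        0.72 0.008510638               0
#> 2             10        0.72 0.007446809               0
#> 3             20        0.82 0.011702128               0
```

At dispersion 0.05 the screen recovers 72–82 % of the 50 planted linear
genes per timepoint; roughly 1 % of the 940 null genes slip past the
R² > 0.9 gate per timepoint (the analytic null rate at five doses is
0.0138), and no spike gene leaks into the linear sets. The overlap table is
the package's Venn-diagram summary:

```r
overlap_summary(res$analyses$linear$overlaps)[, 1:3]
#>       subset n_intersection n_exclusive
#> 1         d2             44           8
#> 2        d10             43           9
#> 3        d20             52          16
#> 4     d2&d10             30           4
#> 5     d2&d20             32           6
#> 6    d10&d20             30           4
#> 7 d2&d10&d20             26          26
```

26 genes respond linearly at all three timepoints — the dosimeter
candidates of this simulated experiment. With `zero_noise = TRUE` recovery
is exact: the triple overlap is precisely the planted linear set.

File-based inputs work the same way
(`pipeline_config(counts_path = ..., samples_path = ...)`, TSV formats
documented in `?read_count_matrix` and `?read_sample_table`), and a thin
command-line wrapper with `simulate` / `normalize` / `screen` / `report` /
`all` subcommands lives at `inst/scripts/radscreen-cli.R`.

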