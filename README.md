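# methylmetrics

Tools for quantifying DNA methylation from Illumina Infinium-style
two-channel microarray intensities, and for deciding — with evidence —
which of the two standard metrics to run differential analysis on.

Each CpG site on these arrays is measured by a methylated/unmethylated
probe pair. Two summaries of the pair are in common use:

* the **Beta-value**
  `β = max(y_meth, 0) / (max(y_unmeth, 0) + max(y_meth, 0) + α)`
  (offset `α = 100`), bounded in `[0, 1)` and readable as percent
  methylation;
* the **M-value**
  `M = log2((max(y_meth, 0) + α) / (max(y_unmeth, 0) + α))`
  (offset `α = 1`), the unbounded log2 channel ratio.

At the high intensities typical of these arrays the two are linked by a
base-2 logit, `M = log2(β / (1 − β))`, with `β = 0.2, 0.5, 0.8`
corresponding to `M = −2, 0, 2`. The Beta-value is the natural
reporting scale but is **heteroscedastic**: its technical variance
collapses near 0 and 1, so fixed difference thresholds and
normal-theory tests misbehave exactly where hyper- and hypomethylated
sites live. The M-value is approximately homoscedastic. This package
implements both metrics and their interconversion, the mean–SD
diagnostic that exposes the problem, and a titration-based benchmark
that quantifies its consequences for differential methylation calling:

* a synthetic titration-experiment simulator (two samples mixed at
  100:0, 90:10, 75:25, 50:50, 0:100 across 8 arrays, Gamma-distributed
  channel intensities, bimodal methylation, known per-site truth);
* GenomeStudio-style TSV input/output, detection-p prefiltering, and
  simple scaling normalization;
* Welch's t-test differential calling with low/middle/high range
  grouping and difference thresholds;
* correlation-defined True Positives (`|r| > 0.8` against the titration
  profile on both scales), top-N TPR/DR curves, difference-threshold
  sweeps, and turning-point threshold guidance.

## Worked example

Simulate a 10,000-site titration experiment with 30% truly differential
sites, define True Positives, and score M-value-based detection:

```r
library(methylmetrics)

sim  <- simulate_titration(10000, diff_fraction = 0.3, seed = 1)
beta <- compute_beta(sim$intensities)   # scale = "beta", alpha = 100
m    <- compute_m(sim$intensities)      # scale = "m",    alpha = 1

tp <- define_true_positives(beta, m, default_design())
tp
#> True-positive set: 2181 of 10000 sites with |r| > 0.8 (scales: both)

diff_m <- diff_methylation(m, c("Array1", "Array2"), c("Array7", "Array8"))
glance(diff_m)
#> # A tibble: 1 × 6
#>   scale n_sites n_p_lt_0.05 n_low n_middle n_high
#>   <chr>   <int>       <int> <int>    <int>  <int>
#> 1 m       10000        1775  3582     2772   3646

head(top_n_curve(select_candidates(diff_m), tp), 3)
#> # A tibble: 3 × 5
#>       x n_detected   tpr     dr one_minus_dr
#>   <dbl>      <dbl> <dbl>  <dbl>        <dbl>
#> 1    50         50     1 0.0229        0.977
#> 2   100        100     1 0.0459        0.954
#> 3   150        150     1 0.0688        0.931
```

2,181 of the 10,000 sites correlate strongly enough with the mixing
profile on both scales to count as True Positives. The 2-vs-2 Welch
gate at p < 0.05 passes 1,775 sites, and every one of the top 150
difference-ranked candidates is a True Positive (TPR = 1), jointly
covering 6.9% of the TP set (DR = 0.069) by N = 150.

The heteroscedasticity contrast that motivates the M-value, on the same
simulation (per-bin median SDs over technical replicates, 20 rank bins):

```r
groups <- split(default_design()$array_id, default_design()$mix_label)
glance(bin_mean_sd(replicate_mean_sd(beta, groups)))
#>   n_bins n_sites extreme_to_middle_ratio max_to_min_ratio
#> 1     20   10000                   0.333             10.0
glance(bin_mean_sd(replicate_mean_sd(m, groups)))
#>   n_bins n_sites extreme_to_middle_ratio max_to_min_ratio
#> 1     20   10000                    1.02             1.10
```

The Beta-value's extreme-range noise is a third of its mid-range level
(a 10-fold swing across bins); the M-value's bin medians vary by about
10% in total. `autoplot()` on either bin table draws the mean–SD panel.

A command-line front-end over the same pipeline lives at
`inst/cli/methylmetrics.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "methylmetrics.R", package = "methylmetrics"))')" \
  simulate --seed 1 --out-dir out n_sites=10000
```

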