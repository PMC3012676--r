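---
title: "Beta-values, M-values, and titration-based evaluation of differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-values, M-values, and titration-based evaluation of differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmetrics)
library(ggplot2)
```

## The two metrics and why both exist

Infinium-style methylation arrays interrogate each CpG site with a pair
of probes and report two fluorescence intensities: one for the
methylated allele ($y_{meth}$) and one for the unmethylated allele
($y_{unmeth}$). Two summary statistics are in common use.

The **Beta-value**,

$$\beta = \frac{\max(y_{meth}, 0)}{\max(y_{unmeth}, 0) + \max(y_{meth}, 0) + \alpha},
\qquad \alpha = 100 \text{ by default},$$

is the methylated fraction of the total signal. It lives in $[0, 1)$
and reads directly as "percent methylation", which makes it the
reporting scale biologists expect. Negative intensities (a background
correction can overshoot) are clamped to zero, and the offset $\alpha$
keeps the ratio stable when both channels are dim.

The **M-value**,

$$M = \log_2\frac{\max(y_{meth}, 0) + \alpha}{\max(y_{unmeth}, 0) + \alpha},
\qquad \alpha = 1 \text{ by default},$$

is the log2 ratio familiar from two-colour expression arrays: unbounded,
zero at half-methylation, positive when the methylated allele dominates.

When total intensity is high — which it is for the overwhelming majority
of probes on these arrays — the offsets are negligible and the two
scales are linked by a base-2 logit:

$$M = \log_2\frac{\beta}{1-\beta}, \qquad
\beta = \frac{2^M}{2^M + 1}.$$

Beta-values 0.2, 0.5 and 0.8 correspond to M-values $-2$, $0$ and $2$;
the relationship is close to linear between those anchors and strongly
compressive outside them.

```{r anchors}
beta_to_m(c(0.2, 0.5, 0.8))
m_to_beta(c(-2, 0, 2))
```

The statistical consequence of the compression is the package's central
concern: on the Beta scale the technical variance of a site depends on
its mean. Sites near 0 or 1 have artificially small standard deviations,
so a fixed effect-size threshold or any homoscedasticity-assuming model
treats them inconsistently. The logit transform removes most of this
mean–variance dependence, which is why differential analysis is better
conducted on M-values even if results are reported as Beta-values.

## The synthetic titration experiment

The package evaluates the two metrics the way a wet-lab titration
benchmark would, but with simulated arrays whose ground truth is known.
`default_design()` encodes the design: two base samples A and B mixed
at 100:0, 90:10, 75:25, 50:50 and 0:100 (percent A), measured with
2, 2, 1, 1 and 2 technical replicates — eight arrays in total. A site
that genuinely differs between A and B must track the mixing fraction
across arrays; one that does not is noise.

`simulate_titration()` draws data with this structure:

* **Methylation prior.** Per-site true fractions come from a bimodal
  mixture — weight 0.4 on Beta(2, 20) (unmethylated sites), 0.4 on
  Beta(20, 2) (methylated sites), 0.2 uniform — because genome-wide
  methylation on promoter-focused arrays is strongly bimodal. The
  weights and components are exposed as parameters.
* **Differential sites.** An exact count, `round(diff_fraction *
  n_sites)` chosen without replacement, redraws `p_B` independently of
  `p_A`; the rest have `p_B = p_A` exactly. The exact count (rather
  than per-site coin flips) keeps expectation denominators in recovery
  tests deterministic.
* **Mixing.** An array with sample-A fraction $f$ sees site-level
  methylation $f\,p_A + (1-f)\,p_B$ — mixing acts on methylation
  fractions, which is what equal-concentration DNA mixing does.
* **Intensities.** Channels are independent Gamma draws with common
  shape (default 16, i.e. 25% CV per channel) around means
  $T_i \, p \, s_a$ and $T_i (1-p) s_a$, where $T_i$ is a per-site
  log-normal total-intensity level (mean 3000 fluorescence units, 30%
  CV across sites) and $s_a$ a per-array log-normal technical factor
  (5% CV). Gamma intensities are the standard distributional assumption
  under which the Beta-value is literally Beta-distributed. With these
  defaults more than 95% of sites exceed a total intensity of 1000,
  matching what these arrays deliver in practice.
* **Detection p-values** are fixed at $10^{-6}$: every simulated probe
  is real signal. The detection filter is exercised with crafted
  fixtures instead, so the two concerns stay independent.

What the generator does **not** emulate: probe-chemistry differences,
cross-hybridisation, SNP-affected probes, dye or batch effects beyond
the per-array scale factor, or spatial artefacts. Passing the package's
comparative tests therefore shows that the metric-level claims follow
from the mean–variance structure of two-channel ratio data, not that
any particular real dataset is free of those other artefacts.

## The evaluation pipeline

1. **Prefilter.** `detection_filter()` removes sites whose detection
   p-value is worse than $10^{-4}$ on more than 50% of arrays. Both
   comparisons are strict: "worse than" means strictly larger (Illumina
   detection p-values are small-is-good), and a site failing on exactly
   half its arrays is kept. The removed site ids and the rule applied
   are kept in a report attached to the result.
2. **Normalization.** `scaling_normalize()` rescales each array so its
   pooled mean intensity (both channels, negatives clamped) equals the
   across-array grand mean. One factor per array multiplies both
   channels, so within-array ratios — and hence zero-offset M-values —
   are untouched. No background correction or colour balancing is
   attempted; this is scale-to-common-mean only.
3. **True positives.** `define_true_positives()` computes, per site,
   the Pearson correlation between the methylation profile and the
   titration profile (each replicate carries its mix's fraction, so the
   correlation runs over all 8 arrays). A site is a True Positive when
   $|r| > 0.8$ on **both** scales; zero-variance sites are excluded
   because their correlation is undefined. A per-scale-only mode exists
   for sensitivity analysis but is not the default.
4. **Detection.** `diff_methylation()` runs Welch's unequal-variance
   t-test comparing the two pure-A replicates against the two pure-B
   replicates, computes $|\bar{A} - \bar{B}|$ per site, and assigns
   each site to a methylation range group from its mean over the
   compared arrays: Beta low $(0, 0.2)$, middle $[0.2, 0.8]$, high
   $(0.8, 1)$; M low $(-\infty, -2)$, middle $[-2, 2]$, high
   $(2, \infty)$. The middle interval is closed on both ends. Analysing
   the nonlinear (low/high) ranges separately from the near-linear
   middle is what makes the metric comparison legible.
5. **Scoring.** Candidates are gated at $p < 0.05$ (strict, no
   multiple-testing correction — deliberately mirroring the
   fold-change-ranking-with-loose-p paradigm) and ranked by absolute
   difference, ties broken by site id. `top_n_curve()` scores the top
   $N = 50, 100, \ldots$ (plus a terminal point at the full list)
   against the TP set by
   $TPR = |TP \cap detected| / |detected|$ and
   $DR = |TP \cap detected| / |TP|$.
   `threshold_sweep()` instead fixes the p-gate and raises a minimum
   difference threshold, recording both rates at each step.
6. **Threshold guidance.** `suggest_thresholds()` operationalises the
   visual "turning point" reading of a sweep: the lower suggested
   threshold is the largest one at which DR is still within a plateau
   tolerance (default 2%, relative) of its zero-threshold value, and
   the upper is the smallest at which TPR reaches its plateau. The
   tolerance is reported with the result; if the two cross (possible on
   pathological, non-monotone sweeps) both are returned with a warning
   flag rather than silently reordered.

## Numerical and design choices

* **Boundary Beta-values.** The logit is undefined at exactly 0 or 1.
  `compute_beta()` with a positive offset never produces them, but
  user-supplied tables can, so `beta_to_m()` clips inputs into
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ by
  default; passing `clip = NULL` makes boundary values an error
  instead.
* **Stable inverse.** `m_to_beta()` evaluates $1/(1 + 2^{-M})$ for
  positive $M$ and $2^M/(2^M+1)$ otherwise, so large magnitudes cannot
  overflow. The forward direction uses a single `log2` of the odds
  ratio, which is exact at the 0.2/0.5/0.8 anchors. Round-trips are
  accurate to $10^{-12}$ on the Beta side; on the M side the Beta
  representation saturates near $|M| \approx 30$ (double-precision
  limit of $1 - \beta$), which the tests document.
* **Degenerate Welch sites.** Zero variance in both groups leaves the
  t-statistic undefined. With equal means the package defines $p = 1$;
  with unequal means it takes the zero-noise limit $p = 0$ and warns,
  rather than dropping the site silently.
* **Replicate pooling.** The mean–SD diagnostic pools technical
  replicate groups per site: pooled SD is the
  degrees-of-freedom-weighted root mean square of within-group SDs,
  pooled mean the unweighted mean of group means, with sample ($n-1$)
  SDs throughout. Sites missing a value in one group drop out of that
  group only.
* **Rank binning.** Mean–SD pairs are ranked by mean and cut into 20
  contiguous blocks of near-equal occupancy (5% of sites each); when
  the count is not divisible, earlier bins take the extra site, and
  ties in the mean break by site id. Because the binning is by rank,
  Beta-values and their logit give the identical site-to-bin
  assignment, which is what makes the two diagnostic panels
  comparable.
* **Mode counting.** The histogram bimodality indicator counts local
  maxima after a 3-cell moving-average smooth, ignoring maxima below
  5% of the tallest cell so that sampling jitter in thin tails does not
  register. It is a descriptive device, not a dip test.
* **Reproducibility.** Every simulation takes an explicit seed and
  restores the caller's RNG state; all TSV output uses fixed
  9-significant-digit formatting so identical configurations produce
  byte-identical files; every pipeline run writes its fully resolved
  configuration as JSON next to its outputs.

## What the checks compute, at what size

The package's own test suite exercises the mean–SD diagnostic on a
simulated experiment of 27,578 sites (the size of a
HumanMethylation27-class array) and the comparative evaluation on
10,000 sites with 30% truly differential — sizes chosen so each claim
is tested at realistic scale while the whole suite stays quick. On
those conditions the Beta-value's extreme-range bin SDs fall below half
its mid-range level while the M-value's bin medians stay within a
factor of about 1.1; M-value top-$N$ curves dominate Beta-value curves
in the low and high groups; and sweeping a difference threshold over
the matched ranges (Beta $0$–$0.25$ versus M $0$–$2.0$) collapses the
Beta-value's detection rate in the extreme groups to a few percent of
its starting value while the M-value retains over 80%. The
`scripts/acceptance.R` script recomputes exactly these quantities from
a fresh seed.

```{r example, fig.width = 6, fig.height = 3.5}
sim <- simulate_titration(3000, seed = 1)
beta <- compute_beta(sim$intensities)
groups <- split(default_design()$array_id, default_design()$mix_label)
autoplot(bin_mean_sd(replicate_mean_sd(beta, groups)))
```

## Limitations

* Correlation-defined True Positives are themselves an imperfect
  reference: a site can be genuinely differential yet fail the $|r| >
  0.8$ double gate, and occasional null sites slip in. This blurs
  absolute TPR/DR values but largely cancels when comparing the two
  metrics on the same TP set.
* The 2-vs-2 Welch test is strongly conservative (its
  Satterthwaite degrees of freedom are noisy at $n = 2$); empirical
  type-I rates near 0.02 at a nominal 0.05 are expected and documented
  in the tests. Real studies should use more replicates or a
  moderated-variance test; neither changes the metric comparison this
  package is about.
* Suggested difference thresholds depend on the intensity distribution
  of the dataset at hand; the defaults and the published-style ranges
  (M-value roughly 0.4–1.4, i.e. fold changes 1.32–2.64; Beta-value
  about 0.05–0.15, and only in the middle range) should be recomputed
  per dataset with `threshold_sweep()` and `suggest_thresholds()`.
* No IDAT parsing, colour-channel processing, quantile normalization
  or multiple-testing correction is provided; those belong to the
  established preprocessing stacks this package sits beside.
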