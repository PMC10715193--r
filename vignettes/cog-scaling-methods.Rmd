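---
title: "Methods: power-law and breakpoint scaling of COG categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power-law and breakpoint scaling of COG categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the estimation procedures,
the synthetic-data generator, and the numerical and design decisions behind
`cogscaling`.

## The model

For each organism let $x$ be its total number of COG functional annotations
and $y_c$ its count in category $c$. The working model is a power law,

$$ y_c = c_c \, x^{\beta_c}, $$

estimated on the log scale: $\log_{10} y = \log_{10} c + \beta \log_{10} x$
by ordinary least squares. The totals are defined as row sums of the count
matrix, so the matrix invariant `total == rowSums(counts)` holds exactly by
construction everywhere in the package.

### Counting rule

A protein annotated with a multi-letter category string contributes one
count to **each** letter: `"KT"` adds one to K, one to T, and two to the
organism's total. Duplicate letters inside one string each count
(`"CC"` adds two to C). Rows with an empty or `"-"` category field are
skipped and tallied, not errors.

### Confidence intervals

Reported 95% intervals are $t_{0.975,\,n-2} \cdot \mathrm{SE}$ half-widths
from the standard OLS theory. These half-widths — not raw standard errors —
are the "error bars" consumed by the Z-statistics below, so the two usages
stay consistent.

## Breakpoint model and selection

The two-regime alternative is the continuous segmented model

$$ y = b_0 + b_1 x + b_2 (x - \psi)_+ , $$

with slopes $b_1$ below and $b_1 + b_2$ above the breakpoint $\psi$. It is
fit by iterative linearization (refitting $y \sim x + (x-\psi)_+$ and
updating $\psi$ from the gap coefficient), with these safeguards:

* **Multi-start**: a coarse RSS profile over at least 30 candidate
  positions seeds `n_starts = 10` iterations from the best candidates.
* **Cycle detection**: an iteration stops when $\psi$ stalls or revisits
  any previously visited value (cycles of any period).
* **Polish**: each converged candidate is refined by a bounded 1-D
  optimization within one coarse-grid spacing.
* **Fallback**: if no start converges, the exhaustive grid search is used
  (with a warning).

`grid_oracle()` evaluates the profile RSS at every midpoint between
consecutive distinct $x$ values and is the independent reference the
iterative fit is tested against (agreement within 1% RSS on random
instances).

**Segment size.** Each segment must contain at least
`max(10, ceiling(0.05 n))` points by default. This prevents the segmented
model from chasing a handful of extreme genomes at either end of the range;
it can be relaxed explicitly for small inputs.

**Selection rule.** The segmented model is adopted only when
$\mathrm{RSS}_{seg} / \mathrm{RSS}_{single} \le 1 - \text{threshold}$ with
`threshold = 0.05`: a breakpoint must buy at least a 5% RSS reduction. A
noiseless single line (RSS $\approx 0$) short-circuits to the single model
to avoid a 0/0 ratio. Reported alongside the break position (in
$\log_{10}$ units) is the percentile of organisms below it, which is how
break locations are compared across groups with different size ranges.

## Group scaling and Z-statistics

Fits are computed per domain and per phylum. For a phylum with slope
$\beta_p$ and error $e_p$ (the CI half-width) against its domain's
$\beta_d, e_d$:

* `mode = "as_printed"`: $z = (\beta_p - \beta_d) / \sqrt{e_p^2 - e_d^2}$.
  The difference under the radical makes the statistic undefined when the
  phylum error does not exceed the domain error; such cells are NA with an
  explanatory reason rather than silently dropped.
* `mode = "sum_of_squares"`: $z = (\beta_p - \beta_d) / \sqrt{e_p^2 + e_d^2}$,
  the conventional form, always defined when either error is positive.

Both modes return exactly 0 when the slopes are equal. The two denominators
reflect a genuine ambiguity in how such scores are printed in the
literature; both are implemented, the mode is always explicit, and the
calibration guarantee (|z| ≤ 2 for phyla subsampled from one law) is stated
for `sum_of_squares`.

## Shuffle null

`shuffle_categories()` pools every category letter across all records,
permutes the pool uniformly, and re-deals letters to the same
(organism, protein) slots with each record keeping its letter count. Per-
organism totals and global per-category totals are therefore conserved
*exactly* — not in expectation — while per-organism category abundances are
randomized. Under this null every category's fitted exponent collapses
toward the exponent of the total itself (≈ 1), so the spread of null-mean
slopes across categories is a small fraction of the observed spread.
Permutation seeds derive deterministically from a master seed; unfittable
permutations are recorded as NA, not dropped.

## Phylogenetic distance

Patristic distances (sum of branch lengths between tips) come from
`stats::cophenetic` on an `ape` tree and are averaged over cross-phylum tip
pairs to a phylum-level matrix. Exponent divergence between phyla is
either `|Δβ|` or the larger-over-smaller quotient (NA for mixed-sign
pairs). The association between the two matrices is a Pearson or Spearman
correlation over upper-triangle entries, with an optional label-permutation
(Mantel) p-value; pairs sharing a phylum are not independent, and the
result carries `independent_pairs = FALSE` to say so.

## Synthetic generator: scope and limits

`simulate_matrix()` draws totals log-uniformly over a configured range,
evaluates each category's (phylum-adjusted) law at the drawn total, adds
Gaussian noise on the log10 scale (log-normal counts), rounds to
non-negative integers, and then **recomputes the total as the row sum** so
the matrix invariant holds. The drawn total is kept as `total_target`.

Consequences to be aware of:

* The realized total is a noisy proxy for the generative target. Fitting
  against realized totals (the study condition) attenuates recovered
  exponents slightly; `make_fit_input(x_source = "target")` fits against
  the generative target for clean parameter-recovery experiments.
* Designs should keep one dominant near-isometric category (like S) so the
  realized total tracks the target; a minor category offset so large that
  the category overtakes the total breaks the power-law relation to the
  total by construction.
* Rounding to integers breaks exactness at low counts; exactness guarantees
  are therefore stated on the continuous law scale (`law_mean_log10()`)
  and for noiseless OLS inputs, not through the integer matrix.

`simulate_tree()` generates a random coalescent (ultrametric) phylum tree.
At `coupling = 1` the exponent offsets come from a monotone line embedding
of the tree: merges are processed in height order and each merged pair of
clusters is separated by a gap larger than every existing within-cluster
span, so |offset difference| is rank-monotone in patristic distance for
every tree (classical 1-D MDS, tried first, can fail badly on trees that
embed poorly on a line). At `coupling = 0` offsets are independent
Gaussians; intermediate couplings blend the standardized components.

## Fitting options and defaults

* `zero_policy = "drop"` (default): organisms with zero counts in the
  category are dropped and tallied (`n_dropped_zero`); `"pseudocount"` uses
  $\log_{10}(y + 1)$ instead. Dropping is the default because the
  pseudocount biases low-count categories' slopes.
* `min_n = 3`: fewer than 3 usable points is an insufficient-data error —
  this is how NA cells in group tables arise.
* `bin_points(n_bins = 20)`: equal-width bins on the log10 x axis; each
  non-empty bin contributes (mean x in bin, mean y in bin). Using the
  within-bin mean of x (not the geometric bin center) keeps points that lie
  exactly on a line exactly collinear after binning, so a binned fit of
  perfect data equals the unbinned fit. At least 3 non-empty bins are
  required.
* Problem sizes in examples and tests (hundreds of organisms, totals
  spanning 2–4 decades) are package choices for fast, well-conditioned
  demonstrations; all sizes are configurable.

## Pipeline

`run_pipeline()` takes a validated `pipeline_config()` (or YAML via
`read_pipeline_config()`), requires exactly one of {real annotation +
taxon-map inputs, a simulation block}, derives per-stage seeds from the
master seed, and writes `count_matrix.tsv`, per-level fit tables, scaling
model selections, Z-scores, breakpoint spans, the null summary, the
distance association, and a `manifest.json` recording versions, seeds and
the configuration. Reruns with the same seed are byte-identical.

## Limitations

* Breakpoint inference assumes a single break; multi-break structure is
  detected only as a poorer single-break fit.
* The breakpoint standard error uses the delta method and is optimistic
  when segment slopes are nearly equal.
* Phylum-pair association tests share tips between pairs; the Mantel
  permutation option is the principled significance test.
* The generator does not model overdispersion beyond log-normal noise, nor
  correlated categories.
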