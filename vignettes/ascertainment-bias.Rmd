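---
title: "How SNP ascertainment distorts population-genetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How SNP ascertainment distorts population-genetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genotyping arrays interrogate a fixed set of SNP markers. Those markers
were *discovered* in a small panel of haplotypes and then filtered —
typically by a minor-allele-frequency (MAF) cutoff — before being typed in
the samples of interest. Every downstream quantity computed from the
typed genotypes (site-frequency spectra, heterozygosity, FST, principal
components) is therefore conditioned on the discovery process. This
conditioning, *ascertainment bias*, is not a nuisance constant: its
direction and size depend jointly on how the panel was chosen and on the
demographic history relating the populations.

`ascbias` rebuilds this genotyping pipeline end to end on simulated data,
where the unbiased answer is known, so that the bias of any
panel-design choice can be measured directly.

## The simulation model

Replicates are neutral coalescent samples with recombination
(infinite-sites mutation, 0/1 ancestral/derived coding) generated by the
msprime engine behind `simulate_replicates()`; any ms-compatible
simulator output can be substituted via `parse_ms_output()`. One
replicate emulates an unlinked ~50 kb region with

* `theta = 4 N0 mu l = 20` and `rho = 4 N0 r l = 20` (per-site rates of
  `1e-8` with reference deme size `N0 = 1e4`),
* 100 discovery + 100 typing haplotypes per population, disjoint by
  default (`sampling_design()`).

Four demographic histories are built in:

* **two-island** and **three-island** models — constant equal-size demes
  with symmetric migration. `island_model(n, M)` interprets `M = 4*N0*m`
  by the ms `-I` convention (total immigration per deme, split equally
  over sources), the convention under which the stated rates were used;
  `convention = "pairwise"` switches to per-pair rates. The study's rates
  are `4Nm = 0.1, 0.3, 0.5` (two-island) and `0.3` (three-island).
* **stepping-stone** — three demes on a line, migration only between
  adjacent demes (`4Nm = 0.3` per adjacent pair).
* **serial split** — population II founded from I at `t1 = 0.3` (units of
  `4*N0` generations), III from II at `t2 = 0.2`, founder fractions
  `f1 = 0.2`, `f2 = 0.1`, no migration. Each founding is modelled
  literally as a one-generation bottleneck (duration `1/(4*N0)` in scaled
  time) at size `f*N0`; at these parameters its coalescent effect is
  negligible but it is retained for fidelity.

## The three ascertainment schemes

Given a replicate, `candidate_sites()` applies one of three discovery
rules at a MAF threshold `t` (sites with panel MAF *below* `t` are
eliminated; ties kept — the strictness is switchable):

* `single_population` — discovery in one population's panel (default
  population I). Produces an asymmetric distortion: the ascertained
  population's spectrum is truncated at both ends, the others' only
  indirectly.
* `merged_panel` — all panels pooled; only variants rare in the pooled
  sample are lost, so diverged variants survive.
* `independent_panel` — a site must be segregating and at MAF `>= t` in
  *every* population's panel; population-specific variants are all lost.

A site invisible to the consulted panel(s) cannot be discovered, so
segregation in the panel is required even at `t = 0`. From the
candidates, `select_markers()` draws 50 markers uniformly; a replicate
with fewer than 50 candidates is *excluded* from that cell, and
exclusion fractions are reported so conditioning-induced bias stays
visible.

One practical consequence the pipeline makes explicit: under the
independent-panel rule, three-population histories at the study's
divergence levels leave only a handful of sites polymorphic in all three
panels, so the 50-marker requirement excludes essentially every
replicate once `t > 0`. The per-cell `n_excluded` column is the honest
record of this; interpreting a mean over a cell with heavy exclusion is
the user's responsibility.

## Statistics

For a site set, diversity is measured as mean pairwise differences
(totals over the site set, not per bp):

* within a population: `pi_w = sum_j d_j (n - d_j) / choose(n, 2)`,
* between populations:
  `pi_b = sum_j [dA_j (nB - dB_j) + dB_j (nA - dA_j)] / (nA nB)`,
* Hudson-style differentiation: `FST = 1 - pi_w / pi_b` with `pi_w` the
  unweighted mean of the two within-population values (deme sizes are
  equal throughout; the weighting would matter for unequal designs).
  `pi_b = 0` makes FST undefined; such replicates are dropped from the
  cell mean with a logged count.

These frequency formulas equal brute-force enumeration over haplotype
pairs exactly (tested). A subtlety worth knowing: because `pi_b` averages
over all `nA * nB` cross pairs, two *identical* finite samples give
`FST = -1/(n-1)`, not 0 — the estimator is asymptotically, not exactly,
centred.

Two baselines anchor every comparison, computed on the same typing
haplotypes as the schemes so that only the site selection differs:

* **re-sequencing** — all segregating sites of the replicate (the
  unbiased truth);
* **random markers** — 50 sites drawn uniformly from all segregating
  sites, the no-ascertainment analogue of a 50-marker array. Uniform
  subsampling is unbiased for per-site averages, so relative diversities
  (`relative_pi_*`) isolate the effect of the discovery rules from the
  effect of using 50 markers.

`aggregate_deviations()` reports, per (scheme, threshold, pair) cell, the
difference of replicate means between typing FST and re-sequencing FST —
the headline quantity — alongside the mean of per-replicate differences
(the two need not agree; both are stored), paired Monte-Carlo standard
errors, delta-method standard errors for the diversity ratios, and
exclusion counts.

## PCA

`run_pca_experiment()` mirrors array-based structure inference: per
replicate, *all* candidate sites at a 5% panel-MAF threshold (no
50-marker subsampling), typing haplotypes pooled over `R` replicates,
EIGENSTRAT-style normalization `(g - p) / sqrt(p (1 - p))` per site, and
eigendecomposition of the sample covariance. Haplotypes are the analysis
units (coalescent samples are haploid), so no diploid factor-of-2
rescaling is applied. Columns fixed among typing haplotypes are dropped
and counted — ascertained markers can be monomorphic after typing.
Component signs are fixed by making each score column's
largest-magnitude entry positive.

Because "three distinct clusters" is a visual claim, it is quantified by
`cluster_separation()`: centroid distance between two populations in the
first two components divided by their mean within-population RMS spread.
Ratios above 1 mean distinct clusters. The number of replicates pooled
is configurable (the assertions are ratio-based and robust to it);
`R = 100` is the default.

## Numerical and design choices

* **Determinism.** Every run derives all randomness from one master
  seed: per-replicate engine seeds via `replicate_seeds()` (a fixed
  sample drawn under the master seed, so replicate *i* is individually
  reproducible and independent of scheduling), and marker-selection
  seeds per replicate from a second stream. The caller's RNG state is
  never disturbed.
* **Paired design.** One simulation pass is shared by all (scheme,
  threshold) cells of a replicate, so scheme contrasts are paired and
  much lower-variance than independent runs.
* **Degenerate inputs.** A replicate with zero segregating sites is a
  valid empty dataset, excluded from cells with a count; `pi_b = 0`
  flags FST as undefined; a PCA input in which every site is fixed
  yields an empty normalized matrix with a warning; zero within-cluster
  spread returns an infinite separation with a warning.
* **Tie-breaks.** MAF ties at the threshold are kept (the rule
  eliminates sites strictly below threshold); `strict = TRUE` inverts
  this for sensitivity analysis. Tied positions in low-precision
  ms-format input are nudged apart deterministically.
* **Problem sizes.** The package defaults to 1,000 replicates per
  parameter set (the reference analysis used 10,000); the test suite
  checks the two-island baselines at 1,000 replicates, the
  three-population contrasts at 400, the neutral-theory calibration at
  10,000 small replicates, and PCA at `R = 100`, with all tolerances
  expressed in Monte-Carlo standard errors computed from the runs
  themselves.

## What the synthetic data does and does not capture

The generator reproduces the study conditions exactly: neutral,
equilibrium or piecewise-constant demographies, free recombination
between replicates, infinite-sites mutation, haploid genotypes without
error. Real SNP-array data additionally involve genotyping error,
linkage between markers on a chromosome, selection, and panel sizes far
from 100 haplotypes. Passing tests therefore validate the *logic* of the
ascertainment pipeline and the direction/size of bias under these
idealized conditions, not a calibration for any particular real dataset.

## Worked example

```{r}
library(ascbias)

cfg <- experiment_config(island_model(2, 0.1),
                         thresholds = c(0, 0.05, 0.1),
                         n_replicates = 200, master_seed = 1)
ex <- run_experiment(cfg)
tidy(ex)          # one row per (scheme, threshold, pair) cell
autoplot(ex)      # FST deviation against threshold
plot_relative_pi(ex)

pca <- run_pca_experiment(island_model(3, 0.3), n_replicates = 100,
                          master_seed = 1)
tidy(pca)         # pairwise cluster separations per scheme
autoplot(pca)
```

## Known limitations

* The independent-panel scheme with 50-marker selection is effectively
  infeasible for three-population histories at any positive threshold
  (see above); the package reports the empty cells rather than silently
  re-interpreting the rule.
* Single-population ascertainment does not erase the differentiation
  between the two unascertained populations in the three-island model:
  restricted to population I's candidate sites, Hudson FST between
  populations II and III stays close to its unascertained value, so with
  enough pooled markers PCA keeps them distinguishable at any pooling
  depth — the ascertained population's cluster inflates (its
  within-cluster spread roughly doubles) but the other two do not merge.
  Claims of a complete II/III collapse under this scheme should be read
  as statements about low-marker-count analyses.
* FST deviations are differences of means across replicates; with heavy
  exclusion the surviving replicates are a biased subset of all
  replicates, which is precisely the conditioning the exclusion counts
  are meant to expose.
* The PCA module extracts components by exact eigendecomposition of the
  sample covariance; for sample sizes far beyond a few thousand
  haplotypes a truncated solver would be preferable.
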