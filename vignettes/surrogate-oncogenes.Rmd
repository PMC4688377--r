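---
title: "Surrogate oncogenes: model, synthetic cohorts, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate oncogenes: model, synthetic cohorts, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosurrogate)
```

## The model

A surrogate oncogene is a gene whose immediate protein–protein interaction
(PPI) neighborhood is altered, within a single sample, more heavily than
random placement of that sample's alterations would explain. The intuition
is oncogenic collaboration: mutations in a protein's interaction partners
can perturb the protein's function or regulation even when the protein
itself is wild type, and most such partner mutations are individually rare
("long-tail") and invisible to cohort-frequency driver statistics.

The test operates per `(sample, gene)` pair on a simple undirected gene
graph with `N` nodes:

* `M` — the number of *distinct* altered genes in the sample. Point
  mutations and high-level copy-number gains/losses are pooled into one
  altered set; a gene that is both mutated and amplified counts once. This
  matches the gene-level (not event-level) view of the null: we ask where
  alterations *land*, not how many events hit one gene.
* `k` — the degree of the tested gene.
* `x_obs` — the number of altered genes among the `k` neighbors. The
  tested gene's own alteration is reported (`self_altered`) but never
  counted: the statistic is about the neighborhood, not the gene.

The null randomly "mutates the entire network": `M` distinct genes drawn
uniformly without replacement from all `N` nodes. The number landing in a
fixed `k`-neighborhood is then `Hypergeometric(N, k, M)`, so the
permutation p-value

> p = #\{permutations with count ≥ x_obs\} / n_perm

converges to the closed-form tail `P(X >= x_obs)`. `call_surrogates()`
offers both routes: `mode = "exact"` (default; fast, continuous in neither
sense — the null is discrete either way) and `mode = "perm"`, which
simulates the draws sequentially without replacement, vectorised across
permutations, and is the procedure the exact mode is cross-checked
against (and vice versa) in the test suite, alongside brute-force subset
enumeration on all networks with `N ≤ 12`.

Assumptions worth keeping in mind: the graph is binary and unweighted
(complex/multi-protein records must be pre-expanded to pairwise edges);
alterations are exchangeable across genes under the null, i.e. gene
length, mutability and copy-number segment structure are ignored; and the
per-sample tests share neighborhoods, so calls for overlapping hubs are
dependent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-test significance level; `significant` means `p < alpha` strictly |
| `n_perm` | 10000 | permutations per null (perm mode) |
| `min_connections` | 2 | seed-expansion threshold: a non-seed gene joins the surrogate set with at least this many seed neighbors |
| `amp_threshold`, `del_threshold` | 2, −2 | GISTIC calls treated as gain/loss (high-level only) |
| `exclude_classes` | `"Silent"` | MAF variant classes dropped at ingest |
| `refine_fraction` | 0.10 | fraction of features kept after Gini-importance ranking in the drug classifier (never fewer than 1) |
| `ntree` | 500 | trees per random forest |
| `max_leaves`, `min_leaf` | 4, 10 | survival-tree size limits |
| `split_threshold` | 3.84 | minimum two-sample log-rank chi-square for a split; 3.84 is the 0.05 critical value of chi-square with 1 df, acting as the complexity criterion |

No multiple-testing adjustment is applied by default: surrogate calls over
a shared network are nested, dependent tests for which standard
corrections (including Benjamini–Yekutieli) are not well calibrated, so
the raw per-test `alpha` is reported and Benjamini–Hochberg is available
via `p_adjust = "BH"` with that caveat. Permutation p-values are plain
proportions, so `p = 0` is possible; the print method flags such calls as
`p < 1/n_perm`, and `add_one = TRUE` switches to `(r + 1)/(n_perm + 1)`.

## The synthetic cohort generator

`generate_network()` (preferential attachment, `m = 3`) reproduces the one
property of curated PPI databases the statistic is sensitive to: a
heavy-tailed degree distribution in which oncogene-like genes are hubs.
`generate_cohort()` then plants precisely the structure the test detects —
*neighborhood* enrichment. Each gene is altered independently at
`background_rate` (default 0.02), except neighbors of each planted target,
altered at `min(1, enrichment × background_rate)` in exposed samples;
targets themselves stay at background rate, so recovery cannot come from
self-alteration. By default targets are the five highest-degree nodes with
degree ≥ 20, and about 30% of alterations are labelled copy-number
changes (split evenly between gain and loss), echoing the CNA share seen
in cell-line data. `exposed_fraction` (default 1) controls how many
samples carry the signal; phenotype association tests need contrast, so
they use cohorts with partial exposure. `generate_phenotypes()` drives
GI50 (exposed samples shifted toward sensitivity, i.e. lower GI50),
subtype labels (exposed samples get the first label with probability
0.9), and exponential survival with a configurable exposed-vs-baseline
hazard ratio and uniform censoring.

What the generator does **not** emulate: mutational signatures, gene
length and replication-timing effects, chromosome-arm-level CNA structure,
clonal heterogeneity, or correlated alteration of pathway modules beyond
the planted neighborhoods. Passing tests on these cohorts therefore
demonstrate that the statistic, parsers, and downstream models behave as
specified — not that surrogate calls on real tumors are biologically
validated.

### Power, and a self-masking property of the statistic

Planting enrichment raises not only `x_obs` around the targets but also
each sample's total burden `M` (in the default conditions, from ~10 to
~35 of 500 genes), which raises the null mean `kM/N` for *every* test in
that sample. Detection power is therefore governed by the gap between the
alternative neighbor-alteration rate (0.16 under enrichment 8) and the
*realized* `M/N`, not the background rate; with five enriched hub
neighborhoods, per-target detection at `alpha = 0.05` sits near 60%
rather than the ~95%+ a background-only `M` would suggest. The test suite
verifies this quantitatively: the measured detection fraction matches the
power predicted from the hypergeometric critical value at each sample's
realized `M` with a `Binomial(k, 0.16)` alternative. The same property
applies to real data — heavily altered samples need proportionally
stronger neighborhood clustering to reach significance, which is exactly
the intended behavior of a per-sample null conditioned on `M`.

## Numerical and design choices

* **Without-replacement null.** `M` is defined from distinct altered
  genes, so the null draws distinct genes; this makes the null exactly
  hypergeometric and gives the permutation route an independent
  closed-form oracle. An event-level null (placing mutation events with
  replacement) would need gene-level collapse rules the gene-level data
  no longer carry.
* **Focal gene in the permutation pool.** The null permutes the entire
  network, including the tested gene; the gene's own alteration simply
  never contributes to `x_obs`. (Excluding it would change `N` by one —
  negligible at network scale, but the convention is fixed for
  reproducibility.)
* **Null caching.** In perm mode, null count vectors are cached per
  `(k, M)` within a run under a single seeded RNG stream. Besides speed,
  caching makes p-values monotone in `x_obs` by construction.
* **Discrete calibration.** Both nulls are discrete, so the significant-
  call rate under a pure null is *at most* `alpha` and typically well
  below it for low-degree genes (the attainable p-values near 0.05 are
  sparse). Calibration is asserted as bounded above, not equal to
  `alpha`. The same conservatism applies to Fisher's exact test in the
  subtype association, whose empirical rejection rate under independence
  sits a little under the nominal level at cohort-scale counts.
* **GI50 orientation and binning.** Low GI50 (less drug needed for 50%
  growth inhibition) means sensitive; the flag `low_is_sensitive` flips
  the convention. Binning is an equal-occupancy median split — chosen to
  avoid the random forest's bias toward the majority class — with ties
  resolved by stable input order and bin sizes differing by at most one
  (the lower bin takes the extra element for odd counts).
* **Survival tree.** Implemented directly as greedy best-first log-rank
  partitioning rather than wrapping a generic recursive-partitioning
  package, so the split criterion, stopping rules (chi-square ≥ 3.84,
  `min_leaf`, `max_leaves`), and tie-breaking (first feature in column
  order wins equal statistics) are fully specified and testable.
  "Pruned to four nodes" is read as four terminal groups; `max_leaves`
  accommodates either reading. A root with no admissible split returns a
  single-leaf tree with a warning, not an error, so pipelines degrade
  gracefully on cohorts without survival structure.
* **Degenerate inputs.** A sample with `M = 0` yields `p = 1` everywhere;
  `alpha = 0` yields no calls; genes never significant in any sample are
  skipped by the subtype association (their Fisher tables are degenerate
  by construction); constant classifier features are tolerated by the
  forest and dropped from `surrogate_features()` by default.
* **Determinism.** Every stochastic component takes an explicit seed, and
  `run_pipeline()` writes a manifest (config echo, seed, package version,
  input MD5 checksums) with no timestamps, so a rerun with identical
  inputs is byte-identical.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run on sizes chosen to give
stable statistics at interactive speed: exhaustive enumeration up to
`N = 12`; Monte-Carlo oracle comparisons at 10^5 permutations; cohorts of
40 samples on 500-node networks (≥ 2000 null tests for calibration);
classifier contracts at 60–200 samples; survival simulations at 100–200
subjects per arm. These are the package's reference conditions, and the
seeds used are recorded in the tests themselves.

## Known limitations

* Symbol-level gene identity with no alias resolution: inputs must share
  the network's symbol vocabulary, or genes silently drop (counts are
  logged).
* The null ignores per-gene mutability covariates; highly mutable long
  genes in a neighborhood inflate `x_obs` on real data in a way the
  synthetic cohorts do not model.
* Surrogate calls for overlapping hubs are statistically dependent;
  per-gene prevalence tables should be read as descriptive, and any
  formal multiplicity control over the surrogate set remains an open
  methodological question.
* The drug classifier reports OOB error only; there is no nested
  cross-validation around the importance-based refinement step, so the
  refined error can be optimistic when the initial feature pool is huge.
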