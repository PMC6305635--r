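---
title: "Restriction-site haplotype networks and rho-statistic dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction-site haplotype networks and rho-statistic dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapnet)
```

## The data and the questions

A classical way to survey variation across the human &beta;-globin gene
cluster is to score seven polymorphic restriction sites (HincII 5' to
&epsilon;, HindIII at ^G^&gamma; and ^A^&gamma;, HincII in and 3' to
&psi;&beta;, AvaII in &beta;, HinfI 3' to &beta;). Each chromosome then
carries a binary seven-site haplotype, written `+ - - - - + +` and the
like, where `+` means the enzyme cuts. Surveys of carriers of the
hemoglobin variant Hb D-Los Angeles (&beta;121 Glu&rarr;Gln) report such
haplotype frequencies for populations from Turkey, Iran, India, Thailand
and western Europe and Mexico; `table1_fixture()` ships a published
21-haplotype, 8-population survey of this kind, and `table2_fixture()`
the corresponding published age table.

Three questions drive the toolkit:

1. **What are the haplotype frequencies?** Laboratory typing yields
   unphased diploid genotypes (how many `+` alleles at each site), not
   chromosomes; frequencies must be estimated through the phase
   ambiguity (`em_estimate()`).
2. **How are the haplotypes related?** A median-joining network
   (`mj_construct()`) displays the mutational paths connecting them,
   including inferred unsampled intermediates.
3. **How old are they?** Rooting the network at a designated ancestral
   haplotype, the rho statistic (`rho_estimate()`, `date_all_nodes()`)
   estimates each node's age in mutational units, converted to years by
   a calibration rate.

`run_pipeline()` chains the stages; every stage is also exposed on its
own.

## Haplotype frequencies with unknown gametic phase

Under Hardy-Weinberg equilibrium (HWE) a diploid individual is an
unordered pair of independent haplotype draws. Writing $p_h$ for the
frequency of haplotype $h$, the probability of an unphased genotype $g$
is

$$P(g \mid p) \;=\; \sum_{\{h_1,h_2\}\,\sim\,g} (2 - \delta_{h_1 h_2})\,
p_{h_1} p_{h_2},$$

the sum running over the unordered haplotype pairs whose site-wise
allele counts reproduce $g$ (a genotype heterozygous at $k$ sites admits
$\max(1, 2^{k-1})$ pairs; a missing site is summed over both alleles
rather than the individual being discarded). `em_estimate()` maximises
the product of these terms by expectation-maximisation: the E-step
weights each compatible pair by $(2-\delta)p_{h_1}p_{h_2}$, the M-step
sets each $p_h$ to its expected chromosome count over $2n$. The
log-likelihood is non-decreasing along iterations — the test suite
asserts this on every run — and the support is restricted to haplotypes
compatible with at least one sampled individual, which keeps it at no
more than $2^7$ patterns.

Tunables (`phase_config()`): convergence tolerance `1e-8` on the
absolute log-likelihood change; cap of 10,000 iterations; 20 starts.
The first start is the deterministic uniform distribution over the
support, the rest are Dirichlet(1) draws under the stated seed.
Multiple starts matter because symmetric configurations are genuine
fixed points: a single individual heterozygous at two sites sits
exactly at the uniform quarter-weights saddle, while the global optima
put half weight on each haplotype of one phase pair. Ties between
restarts go to the first occurrence, so results are reproducible.
Frequencies below $10^{-12}$ are dropped and the rest renormalised.

The estimator is validated three ways: exact hand-computed fixed
points; agreement within $10^{-4}$ log units with a direct multi-start
BFGS search over the softmax-parameterised simplex on small supports;
and parameter recovery from data simulated under HWE from the packaged
Turkish frequency vector (20 replicates of $n = 500$ individuals, mean
$L_\infty$ error below 0.05). The recovery runs use 3 starts rather
than 20: with hundreds of individuals the likelihood surface over this
support is effectively unimodal from the uniform start, and the
replication budget is better spent on replicates than on restarts.

## Median-joining networks

Intraspecific haplotype data rarely fit a strictly bifurcating tree:
ancestral haplotypes persist alongside descendants and alternative
single-step paths coexist. The median-joining construction displays
this as a network. `mj_construct()` iterates two steps until stable:

- **Backbone.** The minimum spanning network (MSN): processing weighted
  Hamming-distance classes in increasing order, a link of length $d$ is
  kept when its endpoints are not yet connected by links of length
  $< d - \varepsilon$. At $\varepsilon = 0$ this is exactly the union
  of all minimum spanning trees, which the tests verify against an
  independent igraph-based oracle (an edge belongs to some MST iff
  shrinking it by $10^{-6}$ lowers the MST weight by that amount).
- **Median insertion.** For every mutually linked node triple the
  quasi-median — for binary characters simply the site-wise majority —
  is a candidate Steiner point. Among candidates not already present,
  all whose connection cost (summed distance to the defining triple)
  lies within $\varepsilon$ of the round's minimum are added as
  unsampled "median vectors".

Afterwards, obsolete median vectors are pruned: any unsampled node of
degree $\le 2$ that lies on no shortest path between sampled nodes is
deleted (lexicographically first, links rebuilt after each deletion).
Keeping degree-2 medians that do carry a sampled-to-sampled geodesic is
deliberately conservative — deleting them can lengthen displayed
geodesics — so the guarantee checked by the tests is "degree $\ge 3$
or on a sampled geodesic" rather than degree $\ge 3$ alone.

Numerical and determinism choices, in one place:

- $\varepsilon$ defaults to 0 and site weights to 1. Reference
  implementations often use weight 10 per site, which differs only by a
  common scale; unit weights keep edge lengths equal to mutation
  counts.
- All tie-prone orderings (node sets, median insertion, pruning) sort
  patterns by a locale-independent byte key, so output files are
  identical across machines without any seed.
- Frequency weights never influence topology; they only size nodes in
  the DOT export (diameter proportional to frequency) and provide
  dating multiplicities downstream.
- Monotonicity in $\varepsilon$ holds for the backbone (every
  $\varepsilon = 0$ link is admitted at $\varepsilon = 1$), and the
  tests assert it there; the full construction does not inherit a
  subgraph guarantee because added medians change the node set.

On the classic `{000, 011, 110}` triangle the construction recovers the
central median with total length 3, which exhaustive Steiner search
certifies as optimal (the MST costs 4). The network always remains
connected, and connecting the sampled haplotypes inside it never costs
more than their MST; note that a spanning tree of the *augmented* node
set may legitimately cost more than the input MST once reticulations
are displayed.

## Rho dating

Given a genealogy rooted at an ancestral haplotype, the rho statistic
estimates the root's age as the multiplicity-weighted mean mutational
distance from the root to its sampled descendant chromosomes:
$\rho = \frac{1}{n}\sum_i m_i d_i$. Its standard error follows the
branch decomposition $\sigma^2 = n^{-2} \sum_b n_b^2 l_b$, with $n_b$
the sampled chromosomes below branch $b$ and $l_b$ its length; on a
star genealogy this collapses to $\sigma^2 = \rho / n$, which the tests
assert exactly. Ages in years are $\rho \times$ `calibration_rate()`.
The default rate, 20,180 years per mutation, is the mtDNA
control-region calibration traditionally used with this estimator; it
is a command-level parameter precisely because applying an mtDNA rate
to nuclear restriction-site data is a strong assumption — substitute a
locus-appropriate rate for absolute ages to be meaningful.

`extract_tree()` roots a network by its shortest-path tree with
deterministic parent choice (higher sampled frequency, then pattern
order). The alternative `all-shortest-paths-average` bookkeeping mode
records the mean root distance over all shortest paths; since all
shortest paths have the same length, depths coincide between modes and
only the recorded parents differ.

`date_all_nodes()` offers two readings of "the age of haplotype X",
because published per-haplotype tables are often ambiguous about which
genealogy each row was computed on:

- `descendant-rho` (default): apply the rho estimator at each node over
  its own clade. Leaves date to 0 — the age of a node *as an ancestor*.
- `root-path`: report each node's mutational distance from the root,
  with $\sigma = \sqrt{\text{depth}}$ (the branch formula along a
  single lineage) — the *formation time* reading.

Neither mode should be expected to reproduce every value of a published
age table computed interactively in a network GUI: per-haplotype rho
values depend on the exact displayed topology and on node-selection
choices that such tables do not record (the packaged age table, for
instance, contains rho values that differ from the haplotype's plain
root distance). What the package guarantees, and tests, is the
estimator itself — exact on constructed genealogies, unbiased on
simulated ones — and the exact rate conversion $\text{years} = \rho
\times \text{rate}$, reported at 0.1-year precision with rho and sigma
at three decimals. Emitted tables derive years from the
printed-precision rho so that every row is internally consistent.

The $\tau$-based expansion-time conversion $t = \tau / 2u$
(`expansion_time()`) is included as a convenience; estimating $\tau$
from mismatch distributions needs sequence-level data and is out of
scope.

## What the simulators emulate — and what they do not

`simulate_genotypes()` draws $2n$ chromosomes from a frequency vector
and pairs them at random (HWE), then erases phase. It emulates exactly
the sampling model the EM estimator assumes: no inbreeding, no
population structure, no genotyping error, sites in full linkage on
each chromosome. `simulate_star()` gives each of $n$ lineages a
Poisson($\lambda$) mutation count; sites are drawn without replacement
within a lineage (infinite-sites approximation) so the observed Hamming
distance equals the true count and rho validation is exact; recurrent
hits — possible in a real seven-site system — are available behind
`recurrent = TRUE`, where repeated hits toggle and a back-mutation
warning is raised. Passing tests under these generators shows the
estimators are correct under their own assumptions; it does not show
robustness to admixture, selection, recombination across the cluster,
or rate heterogeneity among sites, none of which the generators
produce.

Validation problem sizes, chosen to give stable Monte-Carlo bounds at
desk scale: EM recovery uses 20 replicates of 500 individuals; rho
unbiasedness uses 1,000 star genealogies of 20 chromosomes at
$\lambda = 3$ (replicate mean within $3 \pm 0.1$); the network
invariants run on 200 random instances of up to 8 haplotypes and 7
sites against exhaustive oracles.

## Pipeline conventions

`run_pipeline()` accepts either a frequency table (skipping EM, the
published-survey path) or raw genotypes. Populations are pooled by
$\text{count}_h = \sum_p f_{hp} s_p$ with user-supplied chromosome
counts $s_p$; when counts are unknown they default to equal — an
assumption the manifest records. On the genotype path, EM frequencies
are scaled to a nominal 100 chromosomes for dating multiplicities. The
default root is the all-minus haplotype, following the classical
inference that it is ancestral in this system; it is overridable. All
outputs (frequency TSV, edge list, DOT, GraphML, age TSV, JSON
manifest) are plain text, contain no timestamps, and are byte-identical
across runs with the same configuration and seed.

## Known limitations

- Median-joining is a heuristic: it need not find a minimum Steiner
  tree in general, and $\varepsilon > 0$ can add many medians on
  larger instances.
- The rho clock ignores lineage-specific rate variation, and its
  calibration here is borrowed from mtDNA unless the user supplies a
  locus-specific rate.
- EM standard errors are not computed; frequencies are point estimates.
- Per-haplotype ages from `date_all_nodes()` depend on the chosen mode
  and on the extracted tree; reticulate regions of the network admit
  several defensible genealogies.
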