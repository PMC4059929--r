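---
title: "Methods: case/control CNV association and gene-family network enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control CNV association and gene-family network enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the models and tests, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open. It states no empirical result that the package's tests do not
themselves compute.

## The scientific setting

Rare copy-number variants (CNVs) — deletions and duplications of genomic
segments — contribute to neurodevelopmental disease risk, but individual
variants are so rare (per-gene carrier frequencies well under 1%) that
single-locus tests are underpowered. Two complementary strategies are
implemented here:

1. **Region-level association.** Individual CNV calls are aggregated into
   copy-number variable regions (CNVRs), and each region's carrier
   frequency is compared between cases and controls.
2. **Network-level aggregation.** Genes are grouped into nomenclature
   families (e.g. `GRM1`–`GRM8` share the root `GRM`), each family's
   members seed a directed interaction network in a protein-interaction
   graph, and the *cumulative* CNV carrier frequency across the whole
   network is compared between cohorts. Aggregating over a pathway-sized
   gene set turns many individually untestable rare events into one
   testable common signal.

The catch with strategy 2 is that large families spawn large networks, and
a larger network accrues carriers by size alone — especially when cases
carry an overall excess CNV burden. The package therefore calibrates every
network's enrichment against an empirical null built from networks grown
from *random seed sets of the same size* in the same interactome, scored
against the same carrier data. That permutation null inherits the
network-size effect, the cohort imbalance, and any topological bias of the
interactome, so surviving it means the family's signal exceeds what its
size and the data's structure already explain.

## Statistical components

### One-sided Fisher's exact test

Every carrier comparison reduces to a 2x2 table (carrier/non-carrier by
case/control). With margins fixed, the number of case carriers is
hypergeometric; `fisher_one_sided()` reports the upper tail
$P(X \ge a)$. The one-sided upper-tail orientation is deliberate: the
hypothesis of interest is case enrichment, and deficits of carriers in
cases are not evidence for it. The effect size is the unconditional
cross-product odds ratio $(ad)/(bc)$, reported as `Inf` when $bc = 0$ with
$ad > 0$ — a convention that keeps zero-control-carrier networks rankable
— and `NaN` when both products vanish. Note this is not the conditional
maximum-likelihood estimate that `stats::fisher.test()` prints; for the
rare-carrier tables this package deals in, the cross-product is the
conventional summary. `stats::phyper()` supplies the tail probability; the
test suite verifies it against an independent binomial-coefficient tail
sum on every table with margins up to 30 (relative error below 1e-12) and
against `stats::fisher.test(alternative = "greater")` on random tables.

Cohort denominators are explicit parameters everywhere
(`n_case`, `n_control`) rather than being inferred from carrier tables,
because published cohort summaries frequently use slightly different
post-QC totals for different analyses; the caller decides.

### CNVR construction

`build_cnvrs()` segments each (chromosome, CNV type) track separately —
deletions and duplications are never merged, since they are biologically
distinct lesions. Two segmentation modes exist:

* **breakpoint** (default): the union of call footprints is partitioned at
  every distinct call boundary; each elementary segment's carrier set is
  computed; adjacent segments with *identical* carrier sets are merged
  back. This preserves frequency differences inside stacks of partially
  overlapping calls — the region where ten cases and one control overlap
  stays distinct from the flank carried by one sample.
* **union**: plain interval union, the coarser alternative, for
  sensitivity analysis.

Breakpoint partitioning is the default because carrier-frequency contrast
is exactly what downstream association consumes; a union region dilutes a
sharp internal signal with low-frequency flanks. The implementation uses
`IRanges::disjoin()`/`findOverlaps()`; the tests compare it against a
per-base-pair carrier-profile oracle on random call sets.

Coordinates are 0-based half-open internally. Call tables on disk default
to the 1-based inclusive convention CNV callers emit (`coords =
"onebased"`), gene models are standard BED; readers convert at the
boundary, and abutting intervals (`[100,200)` vs `[200,300)`) never count
as overlapping.

### Burden testing

Per-sample CNV burden is the *total* span of a sample's calls in kb
(call-free samples contribute 0), averaged within each cohort. The
per-sample-total definition (rather than mean span per call) is used
because it reflects how much of each genome is copy-number perturbed and
does not discard call counts. Significance of the cohort difference comes
from case/control label permutation of the absolute mean difference, with
the plus-one estimator $(r+1)/(n_{perm}+1)$, which is never exactly zero
and is uniformly distributed under the null up to discreteness.
Permutation draws use per-iteration seeds derived from the master seed by
a counter scheme, so the result is independent of evaluation order.

### Network expansion and enrichment

`expand_network()` grows a network from seed genes by breadth-first
traversal: first-degree = seeds plus their interaction partners,
second-degree = one further step. Traversal follows *outgoing* edges by
default; the interactome is directed (bait-to-prey in two-hybrid data) and
no canonical traversal direction exists, so the direction is a parameter
(`"out"`, `"in"`, `"all"`). Seeds absent from the interactome contribute
only themselves; a family whose members are all absent yields a seed-only
network.

`network_association()` counts each sample once per network however many
member genes its CNVs hit (the distinct-carrier contract), tests the
resulting 2x2 table one-sided, and tallies *informative* genes (at least
one carrier in either cohort) and *enriched* genes (case carrier frequency
strictly above control). A network with zero informative genes is flagged
untestable and excluded from ranking rather than given a fake p-value.

Gene carrier status uses whole-gene-interval overlap by default; an
exon-restricted mode exists, but exon disruption is treated as an
annotation rather than a filter, since regulatory and intronic CNVs can
still be functional. Carrier status is type-blind (del and dup both
count), which the tests verify via a label-swap invariance.

### The random-gene-set permutation test

For an observed family of $N$ members, `permutation_test()` draws $N$
distinct symbols uniformly from the seed universe (default: all
interactome symbols), expands them with the same degree and direction, and
recomputes the enrichment statistic against the same carrier sets. The
permutation statistic is the enrichment odds ratio by default; a
case-carrier-count alternative (`stat = "carriers"`) is provided for
sensitivity analysis. Null draws with no informative gene count as
non-exceeding — they are evidence that a random network of that size shows
*less* signal, not missing data. Two estimators are reported: the primary
plus-one $(r+1)/(n_{perm}+1)$, which cannot be zero and keeps the ranking
honest at finite $n_{perm}$, and the raw $r/n_{perm}$ for comparability
with conventions that report it. Draws sample seeds without replacement
within a draw and independently across draws; the observed family's
members are *not* excluded from the universe (excluding them would shift
the null toward easier comparisons for large families). Per-draw seeds
are counter-derived, and each family's stream in `rank_gfins()` is
derived from the master seed and the family root, so any single family
can be re-run in isolation with identical results.

## Sample quality control

`filter_samples()` applies the four standard array-CNV QC thresholds —
SNP call rate ≥ 0.95, standard deviation of normalised intensity ≤ 0.3,
absolute genomic wave factor ≤ 0.02, and ≤ 100 CNV calls — all
inclusively, matching their printed operators. Duplicate removal
(`dedupe_samples()`) forms single-linkage clusters over sample pairs with
identity-by-state ≥ 0.9 (inclusive) and keeps the highest
`quality_score` sample per cluster, ties broken by smallest sample id;
the quality score itself is an input, computed upstream from genotyping
statistics. Ancestry classification (`classify_ancestry()`) operates in
the supervised k-means setting on the first 10 principal-component
eigenvectors: with training labels fixed, the centroids are per-label
training means and assignment is nearest-centroid — the assignment step
alone, with no iterative refinement, is the deterministic interpretation
of supervised k-means, and distance ties break to the lexicographically
first label. The label set and k are arbitrary; nothing hard-codes three
continents.

## The synthetic cohort generator

No individual-level cohort data ships with the package, so every stage is
exercised against `simulation_config()` / `make_genome()` /
`make_interactome()` / `simulate_cohort()`, which plant known structure
and record it in a truth object.

**What it emulates.** Rare gene-anchored CNVs: for each (sample, gene)
pair a carrier event is drawn at the gene's configured rate; each event
becomes a del/dup call covering the gene with random flanks of up to one
gene length, so call-to-gene overlap mapping is non-trivial. Case rates
are the background rate times a genome-wide `case_burden_multiplier`
(excess case burden), times an `effect_multiplier` on the expanded
network of one designated family (`effect_target`) — the planted signal
the enrichment machinery must recover. QC metrics are drawn inside the
standard thresholds except for exactly `ceiling(qc_fail_fraction * n)`
samples, each violating at least one threshold; injected duplicate pairs
get IBS on [0.9, 1.0] and background pairs on [0.6, 0.85], cleanly
separated so dedupe behaviour is unambiguous. Ancestry eigenvectors
(`ancestry_fixture()`) are isotropic Gaussian clusters in 10 dimensions.

**Reference conditions.** The defaults are the package's reference
simulation, chosen once as a realistic scaled-down rare-variant study:
500 cases / 500 controls, 200 genes on 5 chromosomes (mean gene length
20 kb), background carrier rate 0.002 per gene per sample, a Poisson
out-degree-2 interactome, one 10-member target family among 20 families,
and an 8-fold planted case excess on the target family's second-degree
network. Intergenic gaps are kept at least two mean gene lengths so
flank spillover onto neighbouring genes is rare and realised carrier
rates track the configured ones. Test and acceptance runs use these
conditions directly, with 20 replicates and 200 permutation draws per
test — sizes at which the planted effect is recovered essentially always
while a full run stays in the tens of seconds.

**What it does not emulate** — and therefore what passing tests do not
show about real data: raw intensity/B-allele signals and the CNV-calling
step (calls are consumed as given), linkage disequilibrium and realistic
population structure, locus-specific mutation hotspots, gene-length and
degree correlations (real hub genes are not random), and shared calls
between injected duplicate samples. Recovery of the planted effect
demonstrates the statistical machinery is correct and calibrated, not
that any particular real cohort would yield the same power.

## Numerical choices and degenerate inputs

* Fisher p-values are clamped to $(0, 1]$; the all-zero 2x2 table is an
  error, not a number.
* Undefined ratios (PPV with no positive predictions; odds ratio 0/0)
  are `NA`/`NaN`, never silently 0 or 1.
* `derive_seed()` folds a text label into a master seed with a
  polynomial hash modulo $2^{31}-1$, so every stage, family and
  permutation draw has a reproducible, order-independent stream and all
  seeds remain valid 32-bit integers.
* Generators restore the caller's RNG state (`with_seed()`), so library
  calls never perturb user-level reproducibility.
* Empty inputs degrade to empty outputs (zero-row tables) wherever the
  operation is meaningfully vacuous — no region replicating, a family
  with no informative genes — and to errors where they are not (no
  training labels, inverted coordinates, unknown effect target).

## Known limitations

* The permutation null is conditional on the supplied interactome; a
  biased or sparsely covered graph biases both observed and null networks
  in the same direction, which controls ranking but not absolute
  interpretation.
* Second-degree expansion in dense graphs saturates (most networks reach
  most of the graph), compressing enrichment contrast; the degree
  parameter exists precisely because no single depth suits all graphs.
* `discovery_replication()` matches regions by same-type overlap and
  pools counts; it does not meta-analyse effect sizes.
* No multiple-testing correction is applied across CNVRs or networks by
  default (selection uses raw thresholds); `adjust_bh()` is available
  when FDR control across a report is wanted.
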