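---
title: "Category-level divergence testing: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-level divergence testing: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own science: the model
behind each stage, the parameters that matter, what the simulator does
and does not emulate, and the numerical and design choices a maintainer
should know about.

## 1. The model

### Counting substrate

The unit of observation is a pairwise in-frame codon alignment of a
one-to-one ortholog pair.  For gene $i$ we count non-synonymous
substitutions and sites ($a_i$, $A_i$) and synonymous substitutions and
sites ($s_i$, $S_i$) with equal-weight pathway counting:

* **Sites.**  Each codon position contributes the fraction of its three
  single-base mutants that preserve the amino acid; mutations creating a
  stop codon are charged to the non-synonymous side.  Site counts per
  codon always sum to 3 and are averaged between the two aligned
  sequences (a symmetric choice; the two sequences' site structures
  differ only at diverged codons).
* **Substitutions.**  Codon pairs differing at $d$ positions are scored
  by averaging the synonymous/non-synonymous step classification over
  all $d!$ orderings of single-base steps.  Orderings that pass through
  a stop codon are excluded (if all do, all are used, steps touching a
  stop classed non-synonymous).  This yields fractional counts, which
  are carried unrounded through every later stage.
* **Column filter.**  Codon columns containing a gap, an ambiguous base
  or a stop codon in either sequence are skipped, and gaps must fill
  whole codons (enforced when alignments are read).  A gene with no
  usable column is excluded with a log message.

This counting estimator deliberately replaces the codon
maximum-likelihood machinery often used to produce such counts: the
category statistic consumes only $(a, A, s, S)$, so the estimator is
swappable, and `read_counts_table()` imports externally estimated
counts verbatim when a likelihood-based run is available.  Pairwise
counts (not branch-specific ones) are computed; with an outgroup-based
external run, branch counts can be imported through the same table.

### The category statistic

Genome-wide rates pool by ratio of sums over the whole ortholog
universe $T$, which is equivalent to concatenating all genes:
$k_a = \sum_T a_i / \sum_T A_i$, $k_s = \sum_T s_i / \sum_T S_i$.
A category $C$ then has expected non-synonymous proportion

$$P_A = \frac{k_a \sum_C A_i}{k_a \sum_C A_i + k_s \sum_C S_i}$$

and its observed counts are scored by both binomial tails of
$\mathrm{Binomial}(a_C + s_C,\; P_A)$, each including the observed
value.  One wording in the source literature attaches the $k_a, k_s$
averages to "genes annotated to a given GO term"; taken literally that
would make $P_A$ a function of the category's own rates and the test
vacuous.  The comparison is explicitly against "the average across all
orthologs", so genome-wide rates enter $P_A$ and only site totals are
category-specific.  This is the single most consequential reading in
the package and is pinned by the whole-universe identity test
($C = T \Rightarrow P_A = \sum a / (\sum a + \sum s)$).

### The permutation null

Per-category tail probabilities are not corrected for multiple testing;
instead the *count* of categories below each threshold (0.05, 0.01,
0.001, 0.0001 by default) is compared with its distribution under
annotation permutation.  Each gene's complete term set moves to another
gene as an atomic unit, so term sizes — and hence the set of categories
passing the $\ge 20$-gene filter — are invariant; only memberships
change.  The mean permuted count is the expected number of false
positives, and the global p-value for an excess uses the add-one
estimator $(1 + \#\{c_\pi \ge c_{obs}\})/(1 + n_\pi)$, with the plain
proportion reported alongside for comparison with literature that
quotes it.

Two open choices were resolved as follows:

* **Permutation universe.**  All orthologs, including unannotated genes
  (carried with empty term sets), participate: annotation can land on a
  gene of any substitution profile, which is what "randomly composed
  categories" should mean.  Genes without a usable counts record are
  removed from the universe *before* permuting so that category sizes
  stay fixed across permutations; this is also what makes the
  sparse-matrix fast path exact (category sums under a permutation are
  one matrix product through the inverse gene reassignment).
* **Global test form.**  The implemented global test counts permuted
  datasets whose outlier count reaches the observed one, following the
  stated null that the number of meaningful categories below the
  threshold is no more than expected.  An alternative reading — a
  per-category empirical p-value against the permuted $P_C$
  distribution — is noted here but not implemented.
* **Genome-wide rates under permutation.**  They are sums over all
  genes and therefore permutation-invariant; they are computed once.

## 2. Parameters that matter

| Parameter | Where | Default | Meaning / rationale |
|---|---|---|---|
| `min_genes` | `build_categories`, `permutation_null` | 20 | smallest category tested; below this the binomial has little resolution and term counts explode |
| `thresholds` | `permutation_null`, `run_pipeline` | 0.05, 0.01, 0.001, 0.0001 | the scanned outlier thresholds (strict `<`) |
| `n_permutations` | `permutation_null` | 10 000 | permutation replicates; the add-one global p cannot drop below $1/(n+1)$ |
| `min_coverage` | `check_mapping` | 0.80 | criterion (a), inclusive |
| `max_lowqual` | `check_mapping` | 0.10 | criterion (b), inclusive |
| `window` | `cluster_indels` | 15 bases | frameshift-compensation window, start-to-start, merged transitively |
| `df` | `lrt`, `batch_lrt` | none | degrees of freedom depend on which nested codon models were fitted; deliberately never defaulted |

Boundary conventions: coverage exactly 0.80 and low-quality exactly
0.10 pass; an indel cluster is compensated when its *net* signed length
is a multiple of 3; transcript-length ties break to the
lexicographically smallest transcript id so ortholog sets are
reproducible.

## 3. What the simulator emulates — and what it does not

`simulate_gene_pair()` draws a uniform-random sense-codon ancestor and
evolves two lineages independently by single-base proposals: position
uniform, alternative base weighted $\kappa : 1$ for transitions over
transversions, synonymous proposals always accepted, non-synonymous
accepted with probability $\min(1, \omega)$, stop-creating proposals
rejected.  The stopping rule is explicit: each lineage draws
$n \sim \mathrm{Poisson}(d_S^{target} \cdot S_{anc})$ and evolves until
$n$ synonymous substitutions have been accepted, which targets the
requested synonymous divergence per synonymous site per lineage.

Defaults describe a songbird-scale comparison and are fixed once: gene
lengths uniform on 100–500 codons (typical vertebrate CDS lengths),
`dS_target = 0.1` per lineage (a passerine-level divergence),
`omega0 = 0.15` (a typical genome-wide mammal/bird dN/dS) and
`kappa = 2` (a common transition bias).  `simulate_dataset()` plants
category effects multiplicatively: a gene's $\omega$ is `omega0` times
the product of its categories' multipliers, memberships drawn disjointly
by default (overlapping when `disjoint = FALSE`), with optional
unannotated filler genes so the permutation-universe choice is
exercised.

Deliberate non-realism, and what that means for the tests: uniform
codon frequencies (no F3×4-style composition), no indels, no rate
variation along the gene, no CpG or context effects, two lineages with
no outgroup.  Passing tests therefore demonstrate the *statistical
contract* of the pipeline — calibration under a shared $\omega$,
recovery of planted category effects, permutation exactness — not
robustness to alignment error or compositional bias in real genomes.

Two second-order properties of the counting-plus-simulation pair are
worth knowing.  Under $\omega = 1$ the pooled $(a/A)/(s/S)$ converges
not to 1 but to the fraction of non-synonymous mutational opportunity
that avoids stop codons ($\approx 0.945$ under uniform codon usage),
because site counting charges stop mutations to the non-synonymous side
while the simulator (like selection) never fixes them.  And under
$\omega = 0$ the protein never changes, yet pathway-averaged counting
can attribute small fractional non-synonymous counts when both lineages
hit the same codon with different synonymous changes.  Both effects are
asserted at their true values in the test suite; neither affects
category-level calibration, because every gene is scored by the same
conventions and the genome-wide rates absorb the shared bias.

## 4. Numerical choices

* **Fractional counts and tails.**  Tail probabilities are evaluated
  with the regularized incomplete beta function:
  $P(j \ge a) = I_p(a, s + 1)$ and $P(j \le a) = I_{1-p}(s, a + 1)$,
  which coincide with the direct binomial sums at integer counts
  (checked against an explicit-summation oracle to $10^{-10}$) and
  extend them continuously to fractional ones — preferable to rounding,
  which would discard information the pathway average carries.
  $a = 0$ (upper) and $s = 0$ (lower) return exactly 1; degenerate
  $P_A \in \{0, 1\}$ yields 0/1 with a warning.
* **Both tails include the observed value**, mirroring "equal or more"
  on the rapid side; consequently $p_{rapid} + p_{slow} \ge 1$ at
  integer counts.
* **Outlier counting is strictly below** the threshold.
* **Determinism.**  Every stochastic entry point takes or requires an
  explicit seed; permutation replays are bit-reproducible, and the
  pipeline writes counts with 17 significant digits so staged runs
  reproduce monolithic runs exactly.
* **Degenerate inputs.**  Zero-usable-codon genes are flagged and
  dropped; $\sum S = 0$ aborts (the statistic is undefined); categories
  losing members below `min_genes` after the counts join are dropped
  with a message; negative LRT differences are clamped to 0 with a
  warning flag.

## 5. Problem sizes used by the test suite

The calibration test simulates 2,200 genes (100 disjoint 20-gene null
categories plus unannotated filler) and a 1,000-replicate permutation
null; the recovery test runs 20 replicates of 1,100 genes with five
planted rapid categories (multiplier 3) among 50 and 300 permutations
each.  These sizes give the binomial comparisons enough resolution
(category substitution totals in the hundreds) while keeping a full
suite run around two minutes; the acceptance script uses the same
scales.

## 6. Known limitations

* Pairwise counting cannot attribute substitutions to a lineage; claims
  about *which* species accelerated require branch counts from an
  outgroup-aware external run, imported via `read_counts_table()`.
* The counting estimator ignores transition/transversion bias in its
  site definitions; with strong bias it shifts all genes coherently,
  which cancels in the category test but biases absolute Ka/Ks.
* Jukes–Cantor correction is provided for reporting per-gene distances
  but is deliberately not applied inside the category statistic, which
  models raw counts.
* The GO DAG is not consumed: term sets are expected to be
  ancestor-propagated upstream, and hierarchy preservation under
  permutation is purely structural (sets move atomically).
* The global permutation test controls the expected *count* of false
  positives; it does not name which observed categories are the true
  ones.
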