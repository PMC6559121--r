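---
title: "Methods: network statistics for interactor-set analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network statistics for interactor-set analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbridge)
library(igraph)
```

## The scientific problem

A membrane protein such as the CFTR chloride channel is stabilised at the
plasma membrane by a web of protein–protein interactions. Co-precipitation
experiments under different stabilisation conditions yield several
*interactor sets* — lists of proteins pulled down with the channel when one
or another stability pathway is engaged. The analytic question is: which
*other* proteins in the interactome, never themselves detected in the
pull-downs, are so entangled with these sets that perturbing them should
move the channel's surface stability? `netbridge` implements the complete
chain of statistics for that question: set connectivity against a matched
null, neighbour-enrichment selection, short-path bridge scoring,
annotation-driven hit filtering, and the deviation-score statistics of an
image-based siRNA trafficking screen used to validate hits.

## The operational network

The substrate is an undirected, unweighted, simple, connected graph of
protein identifiers. `build_network()` fixes the cleaning order: self-loops
and duplicate/reciprocal pairs are removed first; then the
exclusive-location filter removes proteins whose *every* compartment
annotation is in the excluded set (default nucleus, mitochondrion,
peroxisome — compartments where interactions relevant to plasma-membrane
stability cannot take place); finally the largest connected component is
kept. The source databases do not dictate whether the location filter runs
before or after component extraction, and the two orders can give different
node counts; we filter first so the result is connected by construction,
and declare that choice here rather than infer it. Unannotated proteins
are never removed — absence of annotation is not evidence of exclusive
nuclear residence. A tie between equally large components is broken toward
the component containing the lexicographically smallest identifier, for
determinism. Identifiers are opaque, case-sensitive strings: any mapping
between accession systems is the user's responsibility.

## Connectivity between interactor sets and its null model

Three statistics measure how strongly two sets are wired together
(`connectivity_stats()`): member overlap, direct interactions (edges with
one endpoint in each set, an edge inside the overlap counted once — edge-set
cardinality, hence symmetric), and common neighbours (proteins adjacent to
at least one member of each set; the neighbour's own membership is
irrelevant, and a flag exists to exclude set members from the count).

Because the sets were selected by co-precipitation with the anchor protein,
random sets of equal *size* would be the wrong null: proximity to the
anchor must be preserved. `sample_matched_set()` therefore draws random
sets with exactly the observed number of proteins at each shortest-path
distance from the anchor, uniformly without replacement within each
distance stratum, never sampling the anchor itself.
`connectivity_significance()` repeats this for both sets (a flag fixes one
set instead), recomputes the three statistics for `n_random` pairs (default
500) and reports the empirical p as the fraction of random pairs with a
value **greater than or equal to** the observed one. Counting ties as
exceeding makes p conservative — it is never understated. A zero exceedance
count is reported as `<1/n_random` (e.g. `<0.002` at the default), the
resolution floor of the randomisation; the raw fraction is kept alongside
for calibration work.

## Specific common neighbours

For every protein with at least one neighbour in a set,
`neighbor_enrichment_p()` asks whether its neighbourhood is enriched in set
members: an upper-tail hypergeometric test with population $N-1$ (the
candidate is not its own neighbour and is excluded from the universe and
from the success count), successes $|S \setminus \{c\}|$, draws equal to the
candidate's degree, $p = P(X \ge \text{overlap})$.

Testing every protein against every set invites a multiple-testing problem;
instead of a p cutoff, the procedure qualifies, per set, the fraction
`top_fraction` (default 5%) of tested candidates with the smallest p
(the first $\lceil 0.05\,n \rceil$; boundary ties all qualify). Selection
then additionally requires at least `min_cross_interactions` (default 3)
direct interactions with each of at least `min_sets` (default 2) sets. No
FDR or Bonferroni correction is applied anywhere in this stage — the
top-fraction device replaces it deliberately, and users should not add one
on top. Two points were genuinely open and are resolved here as package
choices, each behind a flag:

* **Rank convention.** Selected proteins are ordered by a rank sum over
  their qualified sets only. We give the smallest p the *largest* rank
  ($n_\text{tested}$, mid-ranks on ties), so that the sum rewards both
  significance and breadth across sets and "higher rank sum = better".
  The opposite convention (smallest p = rank 1) would perversely reward
  candidates qualified in fewer sets once unqualified sets are discarded;
  `rank_direction = "low_best"` provides it anyway.
* **Qualification breadth.** The default selects proteins qualified in at
  least one set that also meet the cross-interaction rule;
  `require_min_sets_qualified = TRUE` demands qualification in `min_sets`
  sets.

## Bridge scores

To find mediators between the anchor and a known stability factor,
`assemble_subnetwork()` induces the subgraph on the anchors plus the
selected candidates and keeps the component of the first anchor. For an
anchor pair $(a,b)$, `count_paths()` enumerates **simple** paths (no node
revisited) of exactly 2, 3 and 4 edges; walks are rejected because
back-and-forth traversals would let length-4 counts explode and degrade
the fractions to noise. The bridge score of candidate $c$ is

$$\mathrm{BS}(c) = 1 \cdot f_2(c) + 0.5 \cdot f_3(c) + 0.25 \cdot f_4(c),$$

where $f_L(c)$ is the fraction of length-$L$ paths containing $c$, and a
length with no paths contributes 0 so scores stay totally ordered. The
endpoints are never intermediates; other anchors may be. The
implementation counts by adjacency enumeration (common neighbours for
$L=2$; one and two interior loops for $L=3,4$), and the test suite holds it
exactly equal to an independent exhaustive depth-first path enumerator on
random graphs.

A candidate is a **strong mediator** for a pair if its score is in the top
`top_fraction` (default 25%) of that pair's candidate scores: threshold =
the $\lceil 0.25\,n \rceil$-th largest score, boundary ties included, so a
degenerate all-equal distribution makes every candidate strong. (A
percentile-of-sorted-values rule was considered and rejected: on
`{0,0,0,1}` it would call everything strong, which contradicts any sensible
reading of "top 25%".)

## Hit filtering

`apply_filters()` turns the ranked candidate list into a testable hit list
through an ordered, fully audited cascade: exclusion of proteins present in
the experimentally derived sets, a top-25% rank cut, exclusion by tissue
expression level (`low` dropped; `not_available` *kept* — missing evidence
is not low expression), case-insensitive exact keyword exclusion
(ribosomal/elongation/transcription factor/HNRNP/RNA processing/nuclear by
default; exact label matching keeps every removal auditable), exclusion of
previously known anchor interactors, and finally an explicit manual keep
list standing in for literature-mining steps that are not reproducible
computation — it can only remove, never add. Every removal is attributed
to exactly one filter, so per-filter removals plus survivors always equal
the input count.

## Trafficking-screen statistics

Per cell, traffic efficiency is surface signal over total signal; per
image, the median over cells (robust to segmentation outliers); images
with fewer than 20 cells are excluded, and any upstream per-cell QC flag is
honoured but never computed here. Per well, the mean over passing images.
The deviation score normalises a test traffic efficiency to the same
plate's negative controls:

$$\mathrm{DS} = \frac{TE_\text{test} - TE_\text{control}}{2 \times \mathrm{SEM}_\text{control}},$$

so DS = 1 means double the control SEM, positive scores are traffic
enhancers and negative scores inhibitors. The SEM's unit of replication is
the control *well* within the plate (sample SD of per-well means over
√n wells) — the natural reading of same-plate control normalisation.

The global effect of an siRNA over the three CFTR types (wild type,
mutant, corrector-rescued mutant) is $\Sigma_i |\langle DS_i \rangle|$, the
sum of absolute per-type replicate means; absolute values capture siRNAs
that push different CFTR types in opposite directions. Significance comes
from a **full-matrix permutation test**: all individual DS values across
every siRNA, type and replicate are shuffled together (legitimate exactly
because every value is control-normalised), the per-siRNA statistic is
recomputed for each of 10,000 shuffles by default, and p is the fraction
of shuffles at or above the observed value, floored at 1/n_perm so it is
never zero; effects with p < 0.05 are called significant.

For the halide-quenching functional assay, `fit_decay()` normalises the
fluorescence trace to its pre-addition baseline mean and fits
$F/F_0(t) = \text{offset} + A e^{-kt}$ on the post-addition samples
(Levenberg–Marquardt least squares; `offset_term = FALSE` gives the
two-parameter variant), reporting the initial slope $-Ak$ at $t=0$, the
quantity proportional to the initial anion influx rate. A flat trace
short-circuits to amplitude 0 rather than a degenerate fit.
`surface_retention()` expresses surface/total ratios as percentages of a
reference condition.

## Synthetic data and what it does (not) show

The generators exist so every stage is testable without any database
download, with known ground truth:

* `generate_network()` — Erdős–Rényi base graph (default 1,000 nodes, mean
  degree 8) made connected by attaching stray components to the anchor's
  component; five interactor sets of 80 by default (≈400 candidates in
  all, the scale of the motivating screens), half of each set drawn from
  within distance 2 of the anchor to mimic co-precipitation selection;
  optional extra within-set and cross-set edges plant the connectivity
  signal; each requested stability factor is attached to the network
  exclusively through a dedicated bridge node, so that node provably
  carries every anchor–factor path and must attain the maximal bridge
  score — a construction guarantee, not a statistical hope.
* `generate_screen()` — 12 siRNAs × 3 CFTR types × 3 replicates by
  default, unit-variance Gaussian null deviation scores, planted per-type
  mean effects for chosen siRNAs.
* `generate_annotations()` — random expression levels, keywords and flags
  at chosen rates.

The base graph is deliberately *not* scale-free and makes no attempt to
mimic the degree distribution, clustering or annotation biases of curated
interactomes. Passing the planted-recovery and calibration tests therefore
demonstrates algorithmic correctness and statistical calibration under the
stated generative model — not that any particular biological dataset will
yield well-calibrated p-values, which also depends on database completeness
and ascertainment bias that no synthetic null reproduces.

## Numerical choices and problem sizes

* Empirical p-values use ≥ (ties exceed) and are floored at one over the
  randomisation count; raw fractions are retained where calibration needs
  them.
* Hypergeometric tails come from `phyper` on a log-safe scale; the suite
  pins them to exhaustive subset enumeration for populations ≤ 12.
* Top-fraction cuts use ceiling counts with inclusive boundary ties
  everywhere (enrichment qualification, mediator selection, hit-list rank
  cut), so results are deterministic under reordering of tied items.
* The decay fit starts from a crude 1/e-crossing rate estimate and bounds
  the rate at zero; convergence failures are errors, not silent NAs.
* The test suite runs its statistical checks at deliberately modest sizes
  chosen once: 300-node networks and sets of 20–30 for calibration
  (1,000 replicates at 200 randomisations) and recovery (20 seeds),
  1,000-permutation screens (1,000 null replicates, 100 power seeds), and
  100 random graphs of ≤ 30 nodes for the exact path-enumeration oracle.
  Null calibration of the connectivity test is checked on the
  common-neighbour statistic: the overlap statistic between 20-member sets
  is so discrete (usually 0) that its conservative empirical p cannot be
  near-uniform — a property of the statistic, not a defect of the test.
* Determinism: every stochastic function takes an optional seed;
  `run_pipeline()` threads one seed through all stages and hashes every
  stage output into a manifest, and the suite asserts byte-identical
  reruns.

## Known limitations

Calibration and recovery results are under the synthetic model above.
The headline counts of any particular interactome snapshot (network size
after filtering, number of selected neighbours, mediator counts) depend on
the snapshot and the unpublished experimental sets and are not reproducible
quantities of this package; what the package guarantees is the procedure.
GO-term enrichment of candidate lists, identifier mapping, and expression
retrieval are outside scope: annotation and expression arrive as
user-prepared tables. Path lengths beyond 4 are excluded by design — the
weights halve per extra edge, and length-5 fractions on dense subnetworks
are numerically meaningless.
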