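---
title: "Models and methods behind linfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind linfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

linfam reconstructs the history of a gene family from four sources of
evidence: the topology and supports of the gene tree, its
reconciliation with the species tree, the chromosomal arrangement of
the genes, and their sequence divergence.  This vignette states each
model precisely, explains the parameters and the choices made where the
underlying procedure is under-determined, and describes what the
simulator does and does not emulate.

## Lineage delineation

The unit of analysis is the *ancestral homolog lineage*: a clade of the
gene tree hypothesised to descend from one gene copy in the last common
ancestor of the ingroup clades (A, B and D in the default Brassicaceae
setting; clade F is the outgroup).  `delineate_lineages()` anchors a
lineage at every node that is

* **well supported** — internal support (ultrafast-bootstrap percent)
  at least `support_min` (default 60); the whole-ingroup node passes
  unconditionally so a family that never qualifies still yields one
  lineage, and leaves always pass because terminal branches carry no
  bootstrap;
* **criterion-satisfying** — its species content includes the deep
  clade D *and* at least one crown clade A/B (criterion 1), or its
  sister satisfies criterion 1 (criterion 2); and
* **minimal** — its leaf set admits no exact partition into two or more
  smaller well-supported criterion-satisfying clades.  Minimality is
  decided bottom-up: a node is *coverable* when it qualifies or all its
  children are coverable, and a qualifying node is split exactly when
  all its children are coverable.

Because qualifying clades are nested inside the tree, the exact-cover
formulation and the recursive one coincide; the test suite checks the
implementation against an independent exhaustive exact-cover search
over all qualifying clades on seeded random trees.

Two aspects are genuinely open and therefore exposed as configuration
and echoed in the run report:

* **Stray leaves.**  Ingroup leaves under no qualifying clade (e.g. a
  crown-only subtree hanging off the backbone) are absorbed into the
  anchored lineage that shares their most recent ancestor, walking
  upward from the leaf and picking the shallowest anchor below the
  first ancestor that contains one (ties broken by node id).  This
  nearest-anchor rule is the most conservative reading of "assign every
  gene to a lineage"; `unassigned_policy = "own_lineage"` instead
  promotes each maximal stray clade to its own lineage.
* **Support-absent nodes** fail the support test by default
  (`support_absent = "fail"`, absence of evidence); `"pass"` treats
  them as supported.  A tree with no supports at all is an error unless
  the policy is `"pass"`.

Lineages are numbered in cladewise (parent-before-child, left-to-right)
traversal order, with the outgroup lineage last; this makes numbering
stable under leaf-order permutations up to the arbitrary orientation of
the input tree, which property tests confirm by comparing partition
*contents* after rotation.

## Reconciliation and gain/loss counting

`lca_reconcile()` is standard LCA mapping: every gene-tree node maps to
the species-tree LCA of its descendant species, and a node is a
duplication when two children map to comparable (ancestor-or-equal)
species-tree nodes.  A quadratic brute force (scan all species-tree
nodes for minimal common ancestry) backs this in the tests.

Counting gains between the family origin and the clade ancestors is
under-determined by a tree alone, so `tally_gains_losses()` states its
rule explicitly:

* the expansion from one ancestral copy to one copy per lineage
  contributes `ingroup lineages − 1` *founding* gains;
* a within-lineage duplication node contributes one gain toward clade
  ancestor X iff its mapping is at-or-above `LCA_X` and at least one
  descendant gene belongs to clade X.  Both the pooled tally (each node
  once) and the per-clade tally (a node counted toward every clade it
  predates) are reported, since a duplication that precedes the A/B
  split predates two clade ancestors at once.
* losses are Dollo-style clade-stem absences: one loss per (ingroup
  lineage, clade) pair with no sampled gene from that clade.  Losses
  below the clade ancestors are deliberately excluded from the headline
  tally; with extant-only sampling the Dollo count is a lower bound,
  and the simulator-based tests verify the masking direction (tallied ≤
  simulated) rather than equality.

`copy_number_at()` reports per-lineage copies surviving to a named
ancestor as 1 + the number of within-lineage duplication nodes mapped
at-or-above it, counting a lineage only when it retains at least one
gene from species descending from that ancestor.

## Tandem arrays and collinear blocks

Gene order is reduced to integer ranks per chromosome.  A tandem array
is a maximal group of transitively homologous genes on one chromosome
whose consecutive members are within `max_intervening` ranks (default
5).  The field's tools count a size-k array as k − 1 duplication
events; both the array count and the event count are returned.  The
bound is a parameter because no single convention exists; 5 mirrors
common collinearity-tool defaults.

Collinear blocks are chained by dynamic programming over anchors
(homolog pairs admitted at E-value ≤ 1e−10):
`score(i) = match_score + max_j(score(j) + gap_penalty · gap(i, j))`
over predecessors with both rank increments in `[1, max_gaps + 1]`,
`gap(i, j) = (Δrank_a − 1) + (Δrank_b − 1)`; both orientations are
searched, the best chain is extracted, anchors within `overlap_window`
ranks of an accepted block are suppressed, and chaining repeats until
no chain reaches `match_size` anchors.  The DP is proven equal to
exhaustive best-chain enumeration on all anchor sets of up to 8 anchors
over hundreds of seeded layouts.  The E-value threshold gates anchor
admission only; no block-level significance statistic is computed,
because such statistics are tool- and version-specific while anchor
gating is deterministic.

A homolog pair is *syntenic* when both genes are anchors of a shared
block or (by default, `span_membership = TRUE`) fall inside its rank
spans — genes can sit inside a conserved segment without being anchors;
the stricter anchors-only count is also reported.

## Sequence statistics

* **Trimming** keeps exactly the columns with non-gap fraction ≥
  `gap_threshold` (default 0.3, trimAl `-gt` semantics); the boundary
  is inclusive and tested exactly.
* **Similarity** is percent identity over mutually ungapped columns.
  "Similarity" sometimes means substitution-matrix positivity, but
  identity is the only parameter-free reading, so it is the definition
  used throughout.
* **Ka/Ks** uses Nei–Gojobori (1986) counting: per-codon
  synonymous-site fractions (changes to stop codons count as
  nonsynonymous), pathway-averaged substitution counts for multi-hit
  codons (pathways through stop codons are excluded; if every pathway
  is blocked, all are averaged), and the Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3) with p ≥ 3/4 flagged as saturated.  NG86 is
  the simplest standard estimator and the one whose counts can be
  verified against exhaustive pathway enumeration, which the tests do
  codon by codon.  Terminal stop codons are dropped; internal stops are
  an error naming the codon.
* **Medians** use the mean-of-central-pair convention for even n
  (`stats::median`), stated here because published summaries do not
  always say which convention they used.

## The simulator

`simulate_family()` runs a Gillespie birth–death process (duplication
rate λ, loss rate μ per copy) along every branch of a clade-structured
species tree, starting from one copy at the root.  Design choices:

* **Exact event times**, not discretised steps, so counts are unbiased
  at any rate.
* **Bursty rates.**  Each species-tree branch receives a lognormal
  duplication-rate multiplier (mean 1, log-sd `lambda_sigma`, default
  0.6), and the stem branches between the family origin and the
  ingroup crown ancestor are further multiplied by `stem_boost`
  (default 3).  This reproduces the empirical signature of such
  families: expansion concentrated early (one ancestral copy becoming
  many founders before the crown radiation) with wide variation in
  per-species family size — runs under the default regime span from a
  handful to on the order of a hundred copies per genome.  Runaway
  bursts beyond `max_genes` (default 1500) are resampled with a logged
  count, as are families extinct before reaching two genes.
* **Placement.**  A duplicate inserts adjacent to its parent with
  probability `p_tandem` (default 0.3, implemented as parent key plus a
  sub-rank offset so the tandem-adjacency signal survives later
  insertions) or at a uniform-random chromosome position; placements
  are inherited through speciations, so pre-speciation duplicates are
  syntenic between the daughter genomes, exactly the signal the
  synteny stage detects.  Emitted genomes carry `n_bg` background gene
  slots per chromosome in a common ancestral order, each relocated
  with probability `p_relocate` per species (default 0.05) — the
  background orthologs are the collinearity signal, the relocations
  the noise.
* **Sequences** evolve at the codon level: nucleotide mutation events
  arrive at `substitution_rate` per site, synonymous changes are always
  accepted, nonsynonymous ones with probability ω, and changes to stop
  codons are rejected.  The default rate 0.016/site/unit was chosen
  once so that within-lineage conserved-region identity falls in the
  empirically observed 40–72% band (measured medians ≈ 55–73% across
  seeds); ω defaults to 0.3, a typical purifying regime.
* **Supports**: each internal node gets the full value (100) with
  probability `support_q`, else an integer uniform on [30, 100) — a
  deliberately simple two-component model whose mixture weight and
  uniformity the tests check distributionally.
* **Ground truth**: every duplication (time, species branch,
  tandem/dispersed, placement) and loss is logged with stable copy ids
  that persist through speciations, so the extant gene set of any
  species can be replayed from the log alone; founder identities are
  recorded when copies cross the `founder_node` speciation
  (`LCA_ABD`).  The default 23-species tree is synthetic — clade
  sizes 9/7/6/1 (A/B/D/F), ladderised crowns, root age 54 time
  units — because only its clade structure, not its exact species
  composition, matters to the methods.

What the simulator does **not** emulate: whole-genome duplication or
triplication (no coordinated multi-gene events), gene conversion,
inference error in the gene-tree topology (supports vary but the
topology is always true), alignment error or indels (simulated
sequences are gap-free codon alignments), and transposable-element
annotation.  Passing recovery tests therefore demonstrates the
correctness of the algorithms under the stated generative model, not
robustness to tree-estimation artefacts in real data.

## Parameter recovery and problem sizes

With μ = 0 and all supports at 100, delineation recovers the simulated
founder count exactly and the gain tallies equal the event-log truth on
every seed — the core acceptance property, run over 100 seeded
families.  With μ > 0, extant-only Dollo counting can only undercount,
and the suite asserts that direction on every run.  The remaining
standing checks use 200 random trees (≤ 24 leaves) against the
exhaustive lineage oracle, brute-force reconciliation on trees up to 50
leaves, 500 chaining layouts of ≤ 8 anchors, 200 neutral sequence pairs
of 300 codons (median Ka/Ks required in [0.8, 1.25]), and
threshold-boundary trimming fixtures.  These sizes keep the full suite
within a desk-scale run while exercising every code path; the
acceptance script (`scripts/acceptance.R`) uses one full-regime family
plus 30 loss-free and 15 lossy recovery runs and 100 neutral pairs.

## Known limitations

* Delineation assumes the outgroup clade is monophyletic in the rooted
  tree; reticulate histories and horizontal transfer are out of scope.
* The gain rule attributes each duplication node from its LCA mapping;
  unsampled species can make a late duplication look earlier
  (at-or-above an ancestor) than it was.
* Dollo losses are lower bounds under extant-only sampling, and a
  lineage extinct in *all* clades leaves no trace at all.
* NG86 with Jukes–Cantor saturates near p = 3/4; deeply diverged pairs
  are flagged rather than extrapolated.  Codon-model (ML) estimators
  are deliberately out of scope.
* Polytomies are retained, with each polytomy child treated as a
  candidate clade; ties between identical candidate leaf sets go to
  the shallower node.
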