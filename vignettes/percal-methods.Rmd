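---
title: "Methods: motif scanning, enrichment and domain phylogenetics in percal"
author: "percal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scanning, enrichment and domain phylogenetics in percal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percal)
```

## The problem

Bacterial proteins of the animal-heme-peroxidase superfamily carry one or
two catalytic "ANP-like" domains (delimited by the PROSITE profile
PS50292). Alignments of these domains reveal short, lineage-specific
insertions of eleven residues that are rich in glycine and aspartate and
that share the consensus `G-x-D-G-x-x-[GN]-[TN]-x-D-D` — the PERCAL
calcium-binding motif. Establishing that such a motif is real rather than
compositional noise requires a pipeline of small, well-defined steps:
scanning sequences for PROSITE-syntax patterns, classifying occurrences
against annotated domain intervals, summarising the insert alignment as a
consensus and a sequence logo, comparing observed counts with the number
expected by chance under a residue-composition background, and placing the
motif-bearing domains on a bootstrap phylogeny to ask whether two-domain
proteins arose by duplication or by recruitment. `percal` implements each
of these steps as a tested, seeded, reusable unit. Domain boundaries and
multiple sequence alignments are *inputs*: the package does not rerun
profile scans or alignment programs.

## Pattern grammar and matching conventions

`parse_prosite()` accepts the PROSITE pattern grammar: residue letters,
classes `[GN]`, negations `{G}` (any residue except those listed), the
wildcard `x`, repeat suffixes `(n)` and `(n,m)`, terminal anchors `<` and
`>`, and the slash shorthand `T/N` as a synonym of `[TN]`. Elements are
separated by `-`; whitespace and a trailing period are ignored.

Matching conventions are fixed once and used everywhere:

* **Coordinates** are 0-based, half-open, in every data frame and file.
  Human-readable reports may additionally print 1-based positions.
* **Overlap policy.** The default `all-starts` policy reports one hit per
  start position that admits a match; `non-overlapping-leftmost` keeps a
  greedy left-to-right subset. Published motif scans rarely state their
  overlap convention, and for 11-residue motifs overlapping self-matches
  are rare, so the simplest deterministic convention is the default.
* **Variable wildcards** are expanded leftmost-shortest: at each start the
  reported span is the first success when repeat counts are tried in
  ascending order, element by element. The matcher compiles patterns to
  lazy-quantifier regular expressions; an independent brute-force oracle
  that enumerates every (start, expansion) combination confirms exact
  agreement on randomized cases in the test suite.
* **Non-standard letters** (B, J, O, U, X, Z) are matched by wildcards and
  negated sets, never by fixed residue sets — the conservative choice for
  motif counting. Sequences are uppercased on ingest.

```{r}
percal <- parse_prosite("G-x-D-G-x(2)-[GN]-[TN]-x-D-D", name = "PERCAL")
find_matches(percal, "PGPDGVPNTEDD")
```

## Expected random occurrence and enrichment

The null model is an order-0 (Bernoulli) background: residues i.i.d. with
frequencies $f_a$, either estimated from the scanned collection itself
(maximum-likelihood proportions over standard residues) or supplied as a
composition table, since enrichment ratios depend on the composition used.

For a fixed-span pattern the per-site match probability is
$p = \prod_j q_j$ with $q_j = \sum_{a \in A_j} f_a$ for a residue class,
$1 - \sum_{a} f_a$ for a negation and $1$ for a wildcard. The expected
number of matching windows in a sequence of length $L_i$ is
$\sum_s \max(0, L_i - s + 1)\, p_s$, summed over realized spans $s$ and
over sequences. Variable-span patterns are expanded over their repeat
ranges; the per-span probabilities are accumulated by polynomial
convolution, so cost grows with the span range, not exponentially with the
number of variable elements.

Two approximations are deliberate and documented:

* window overlap is ignored — exact for the *expectation* of fixed-span
  window counts (linearity), and only the variance is affected;
* for variable spans the expansions at one window are summed although the
  all-starts count realizes at most one of them, making the analytic value
  a slight upper bound.

`monte_carlo_expectation()` is the built-in simulation oracle: it draws
collections from the background, counts matches with the real matcher and
returns mean ± SE. The test suite requires 3-SE agreement for fixed-span
patterns across randomized configurations (the sample SE is floored by the
model-based Poisson value $\sqrt{E/n}$, since it degenerates to zero when
every replicate count is equal) and the upper-bound property for
variable-span patterns. Exact occurrence distributions, compound-Poisson
corrections and higher-order Markov backgrounds are out of scope.
Enrichment ratios published from database screens depend on the database
release and the composition table used there, so they are not
digit-reproducible quantities; the package reproduces the *method* and
reports the same motif/observed/expected/ratio table shape.

## Intra-domain classification, flanked inserts, consensus and logo heights

A hit is **intra-domain** iff its interval is fully contained in one of
its protein's annotated domain intervals; hits straddling a boundary count
as extra-domain. Containment is the stricter, reproducible choice where
published counts do not state how edge-straddling occurrences were
handled. `classify_hits()` also reports the number of domains and proteins
carrying at least one intra-domain hit.

`extract_flanked_inserts()` pads each matched core with up to three
residues of context per side, filling positions beyond the sequence ends
with `-` so that equal-span records align column-wise (the
`x-x-x-core-x-x-x` records behind a sequence logo).

`build_consensus()` turns aligned cores into a PROSITE-style string, one
column at a time: a single residue if the top frequency reaches
`single_threshold` (default 0.5) while the runner-up stays below
`1 - single_threshold`; a two-letter class `[XY]` if the top two jointly
reach `pair_threshold` (default 0.75); otherwise `x`. The defaults are
chosen so that a clear majority stays a single letter while a column that
splits evenly between two residues — as the ninth position of the insert
consensus does between Ala and Thr once the less stringent insert set is
included — emerges as a class. Note the rule's knife edge at an exact tie:
a 101/99 split in 200 records still emits the single majority letter.
Both thresholds are exposed as parameters.

Logo column heights are $IC_j = \log_2 20 - H_j$ bits, with $H_j$ the
plug-in Shannon entropy of the column's residue frequencies. No
small-sample correction is applied by default; common logo renderers apply
the first-order Miller–Madow bias correction $(k-1)/(2 n \ln 2)$, which is
available as `correction = "miller-madow"` and *lowers* the IC of sparse
columns.

`detect_msa_insertions()` finds insertion segments in an alignment by the
gap structure alone: a column is an insert column when its gap fraction
reaches the threshold (default 0.5), maximal runs of at least `min_run`
(default 4) insert columns are reported, and the rows carrying at least
50% residues within the run are the insertion's members. Gap characters
are `-` in all I/O; `.` is accepted on read and normalized.

## Distances, neighbor joining and bootstrap supports

`pairwise_distance()` computes the p-distance (mismatches over compared
sites) under pairwise or complete gap deletion, optionally
Poisson-corrected as $d = -\ln(1 - p)$; a saturated pair ($p = 1$) is an
error rather than a silent infinity. The original domain trees were built
with alignment and tree programs run at default parameters whose exact
distance settings are not recoverable, so the test surface is
topology-level behaviour on synthetic data rather than a published tree.

`neighbor_joining()` is the classic agglomerative algorithm: join the pair
minimizing $Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$,
assign branch lengths by the standard formulas, reduce the matrix. Two
rules make it deterministic across platforms: ties in $Q$ break to the
smallest (row, column) index pair in the current label order, and a
negative branch length is clamped to zero with the deficit moved to its
sister branch. On additive matrices the algorithm provably recovers the
generating tree; the suite checks exact topology and path-length recovery
on 100 random 6–10-leaf trees and agreement with an independent NJ
implementation.

`bootstrap_consensus()` resamples alignment columns with replacement,
rebuilds a tree per replicate and reports either the ≥50% majority-rule
consensus (default) or the full-alignment tree, decorated with supports:
the percentage of replicates containing each internal bipartition,
counted on canonical split identities so the result is invariant to leaf
order and rooting. "Average bootstrap tree" is ambiguous between these
two conventions in older software, which is why both are provided.
Replicates with undefined distances are dropped with a warning; more than
10% dropped aborts the run. `are_sister()` answers the duplication
question: two leaves are sisters iff they form a cherry on the unrooted
tree; in degenerate trees of three or fewer leaves every pair is reported
as sisters.

## What the synthetic data emulate — and what they do not

The generators provide seeded, manifest-carrying inputs with the
statistical structure the analysis assumes:

* `generate_background_sequences()`: i.i.d. draws from a composition —
  the enrichment null.
* `plant_insertions()`: designates non-overlapping domain intervals
  (lengths drawn from a range, at least one residue between domains) and
  *splices* motif cores sampled from a per-column profile at uniform
  positions inside each domain, plus optional extra-domain inserts at a
  Poisson rate. Splicing (not overwriting) mirrors the interpretation of
  the motifs as insertions interrupting the domain alignment. Domain
  coordinates are updated for every length change, so ground truth is
  exact by construction; on backgrounds restricted to residues absent
  from the motif, pipeline recovery must equal ground truth exactly.
* `evolve_alignment()`: a root sequence drawn uniformly evolves along a
  tree; each site substitutes with probability $1 - e^{-b}$ on a branch of
  length $b$, to a uniformly chosen different residue. This
  exchangeability-free Poisson model is the simplest that makes corrected
  distances consistent estimators of path lengths, which is all the
  topology-recovery tests require.

Real protein data differ in ways these generators do not emulate:
compositional heterogeneity along sequences, insertion/deletion evolution,
rate variation across sites and residues, and domain architectures beyond
plain intervals. Passing tests therefore demonstrate correctness of the
*algorithms* under their stated models, not performance guarantees on
arbitrary proteomes.

## Defaults, problem sizes and numerical choices

| Parameter | Default | Where |
|---|---|---|
| overlap policy | all-starts | `find_matches()` |
| flank width | 3 residues | `extract_flanked_inserts()` |
| consensus thresholds | 0.5 / 0.75 | `build_consensus()` |
| gap fraction / min run | 0.5 / 4 columns | `detect_msa_insertions()` |
| distance model | p or Poisson-corrected | `pairwise_distance()` |
| bootstrap replicates | 500 | `bootstrap_consensus()` |
| background | estimated from the collection | `enrichment_report()` |

The test and acceptance workloads are sized so the whole suite runs in a
few minutes on one CPU while keeping each statistical check
well-powered: 1000+ random matcher/oracle cases, 20 Monte-Carlo
calibration configurations at 300–400 replicates, 100 random additive
trees, one 6-leaf long-branch simulation of 2000 columns with 500
bootstrap replicates, and planted-insertion runs of a few thousand
residues. Every stochastic step takes an explicit seed and restores the
caller's RNG state; generators attach a JSON-serializable manifest of
their parameters.

## Known limitations

* PROSITE *profiles* (position-weight matrices with gap penalties) are
  not implemented; domain boundaries must be supplied.
* The enrichment model is order-0; compositional clustering (e.g.
  low-complexity regions) inflates both observed and expected counts in
  ways the model cannot separate.
* The published domain-scan counts and insert-coverage percentages can be
  recomputed only when the corresponding domain-sequence and insert-record
  files are supplied by the user; they are journal supplementary data that
  the package does not redistribute.
* Bootstrap supports on short alignments are themselves noisy; the
  package reports them as computed and leaves interpretation to the user.
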