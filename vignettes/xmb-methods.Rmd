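---
title: "Repeat-aware assembly of noisy shotgun reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware assembly of noisy shotgun reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xmb)
```

## The problem

Shotgun sequencing samples `N` reads of length `L` uniformly from an unknown
genome of length `G`; each read base is corrupted, either by substitutions
(probability `p`, uniform over the three other bases) or by insertions and
deletions (`p_i`, `p_d`). *Genome finishing* asks for a single contig within
edit distance `delta` of the truth, with probability at least `1 - epsilon`;
`delta = 2 p G` is used throughout, the noise floor of an assembly that
spells reads without a final polishing pass.

What makes finishing hard is not noise per se but *repeats*. Three exact
statistics of the genome govern reconstructibility: the longest exact repeat
`l_max`, the longest pair of interleaved exact repeats `l_int` (two repeats
whose copies alternate, `-X-Y-X-Y-`), and the longest exact triple repeat
`l_tri`. With noiseless reads, reconstruction is possible essentially iff
`L` exceeds `l_crit = max(l_int, l_tri)`. Real long repeats are *flanked*:
terminated by statistically uncorrelated sequence in which two copies
mismatch at a density near 0.75 (the rate of independent uniform bases).
When the repeat interior carries sparse polymorphism, the *flanked* length
`~l` can greatly exceed the longest enclosed *exact* repeat, and naive
noisy-read assembly needs `L` above the flanked scale. The X-phased
multibridging algorithm implemented here closes that gap: its read-length
requirement returns to (nearly) the noiseless `l_crit`.

## Genome model

`genome_spec()` / `simulate_genome()` build genomes with exactly the
structure that drives the theory: an i.i.d. uniform ACGT background; a
planted longest flanked repeat (length `flanked_max`), a partner repeat
(length `flanked_int`) interleaving it in `-X-Y-X-Y-` order, and optionally
a flanked triple repeat; and polymorphic edits inside each repeat interior
placed so the longest exact run equals a prescribed target. Placement uses
rejection sampling with at least `gap_min` (default 100, about twice an
anchor length) of random background between copies, so planted flanks are
genuinely uncorrelated.

Two deliberate details:

* *Exactness of planted statistics.* Polymorphic sites are placed so that
  interior runs equal the target exactly (first site at `target`, then every
  `target + 1`); surplus sites fall uniformly into the largest remaining run
  while one target-length run is protected. The single background base
  adjacent to each planted copy is forced to differ between copies;
  otherwise a 1-in-4 coincidence would extend the measured exact repeat
  beyond the target and the planted ground truth would drift from the spec.
  This conditions the background on a measure-zero event and does not
  change its statistics materially.
* *Linear vs circular.* Uniform sampling over a linear genome cannot cover
  the terminal K-windows (a window at position 0 is only seen by a read
  starting exactly at 0), so *exact* reconstruction benchmarks use circular
  genomes (reads wrap; the assembler spells an Euler cycle and output is
  compared up to rotation). Benchmarks judged by percent identity use
  linear genomes; the few ragged end bases are visible in the score.

## The RA-rule and its calibration

All overlap decisions use the repeat-aware (RA) rule. Two equal-length
segments RA-match iff the Hamming distance over the whole overlap is below
`alpha * W` *and* both terminal windows of length `l_iid` are below
`alpha * l_iid`. The terminal anchors are the point: for reads drawn from
different copies of a long flanked repeat the interior matches, but at
least one anchor reaches into the random flanking region where the
mismatch density is ~0.75.

`solve_liid_alpha(p, epsilon, G)` calibrates `(l_iid, alpha)` from two
budget equations: the probability that any two unrelated length-`l_iid`
segments pass (rate 3/4, `G^2` pairs) and the probability that two noisy
observations of the same segment fail (rate `2p - 4p^2/3`, `G` loci) are
each held at `epsilon/6`, so anchor errors contribute at most `epsilon/3`
overall. Both equations define a curve `l_iid(alpha)`; the solver
intersects them by bisection of their difference on
`(2p - 4p^2/3, 3/4)`, rounds `l_iid` up, and re-centres `alpha` in the
interval that keeps both residuals within budget. Typical values: for
`p = 1%`, `G = 5` Mb: `l_iid = 58`, `alpha = 0.22` — anchors of a few tens
of bases against repeats of thousands. The noiseless limit `p = 0` has an
infinite false-negative exponent; the solver then returns the
false-positive-driven `l_iid` with `alpha = 0.5 / l_iid`, which makes the
rule exact matching.

Ties are failures: the strict `<` of the rule is kept, so
`d == alpha * W` does not match.

## The three assemblers

**Greedy** (`greedy_assemble`) initialises contigs to reads and merges the
pair with the largest RA-overlap first, each read gaining at most one
successor and one predecessor, no cycles. Candidate pairs come from shared
exact 16-mers ("fingerprints"); under noise a true overlap of length `W`
still contains about `(W - 16)(1-p)^{32}` clean fingerprints. Greedy needs
every flanked repeat *bridged* (a read spanning it plus both anchors), so
its read-length requirement sits at `~l_max + 2 l_iid`.

**Multibridging** (`multibridge_assemble`) builds a De Bruijn graph over
*K-mer clusters*:

1. K-mers are extracted from reads and clustered under the RA-rule; the
   implementation unions K-mer *slots* at aligned offsets of verified
   RA-overlapping read pairs with a disjoint-set forest — the read-overlap
   approximation of all-pairs K-mer comparison (an exhaustive
   `method = "oracle"` mode exists for validation).
2. Edges connect clusters holding consecutive K-mers of some read.
3. Coverage gaps (nodes with no predecessor or successor) are repaired by a
   greedy W-descending RA-overlap search over cluster representatives; the
   joined partner may be any cluster (a repeat-boundary cluster legitimately
   keeps two neighbours) but no node gains more than one new link per
   direction. Join links are recorded as edges annotated with their overlap
   `W` rather than materialised dummy nodes — the spelled output is
   identical and the graph stays simpler.
4. Chains with out-degree 1 into in-degree 1 are condensed; short parallel
   bubbles (equal label length, shorter than `l_iid`) collapse onto the
   better-supported path; the graph is re-condensed.
5. The genome is spelled from an Euler path/cycle.

With `K = ~l_crit + 2 l_iid <= L`, K-mers bridge every repeat shorter than
`K - 2 l_iid`, so only the longest repeats survive as branch nodes and the
read-length requirement drops to `~l_crit + 2 l_iid`.

**Spelling and consensus.** A condensed node is spelled through its
clusters: the full K-mer of the first cluster, then one base per subsequent
cluster. Both use per-cluster majority consensus over the member K-mers
(the node-start K-mer column-wise, the appended base from a count
maintained during clustering); at any reasonable depth this removes the
per-read noise from spelled contigs without a separate polishing stage.
Identical inputs leave the noiseless path bit-exact.

**Euler-path ambiguity is surfaced, not guessed away.** Before spelling,
the number of Euler traversals of each component is counted exactly with
the BEST theorem (arborescence count via the Matrix-Tree determinant times
the product of `(out-degree - 1)!`). A single two-copy repeat leaves a
unique traversal and is spelled through; interleaved or triple repeats
leave several, and the component falls back to one contig per condensed
node (unitigs) for substitution data — a misassembly-free answer — or to
greedy support-ordered edge walks for indel data, where the success
criterion tolerates a few percent mismatch and longer draft contigs are the
better trade. The fallback choice is a property of the noise mode, stated
in `euler_spell(fallback=)`.

**X-phased multibridging** (`xphase_assemble`) runs the multibridging
steps, then phases every 2-in/2-out X-node — the signature of a flanked
approximate repeat whose copies the RA-rule cannot separate because the
interior polymorphism is too sparse:

* *Alignment*: reads owning K-mer slots in the node's clusters are placed
  at their majority offset; reads whose slots also touch an incoming or
  outgoing neighbour carry that flank identity.
* *Consensus*: per column, the aligned bases are modelled as an
  equiprobable two-copy mixture observed through substitution noise; the
  best of the 10 unordered base pairs is compared with the best homozygous
  explanation, and a site is called when the heterozygous explanation wins
  by `log_factor` (default 2 nats) at depth at least 4. The threshold
  guards against false sites; its regime-sensitivity at high noise is a
  known limitation (below).
* *Phasing*: `count_to_extend` lets every read spanning two consecutive
  anchors (flank, site, ..., site, flank) vote for a linking; strict
  majorities compose into a flank pairing, and any tied or voteless link
  leaves the node unresolved — the algorithm never guesses. `map_phase`
  scores all `2^(n_sites + 1)` configurations exactly under the same
  likelihood (capped at `2^20`, falling back to counting) and agrees with
  the majority vote on symmetric single-site cases.
* *Resolution*: a resolved X-node is duplicated into two parallel nodes
  wired to their paired flanks, carrying copy-specific bases at the sites;
  condensation then merges straight through, and the Euler count drops
  accordingly.

Phasing needs only reads spanning *consecutive* sites (plus an `l_iid`
margin at flank anchors), so the read-length requirement falls to
`~l_int + 2 l_iid` — the noiseless critical scale — at the price of
requiring `k = 3` spanning reads per link at `p = ~1%`.

## Indel mode

Indel-noisy reads are clustered through banded overlap alignments
(band `3 ceil((p_i + p_d) L) + 8`) with an RA-style acceptance test on the
whole overlap and both terminal `l_iid` windows of the alignment. Slots are
unioned only inside clean diagonal runs of at least 5 matched columns:
near an indel the optimal path is locally ambiguous and unguarded unions
would merge adjacent genome loci. Three artifact classes remain and are
handled explicitly:

* singleton clusters at a read's own indel positions — dropped by a
  support threshold of 2 (their loci stay represented by the main
  clusters);
* "skip" edges from deletions (a read jumps one genome window) and
  spurious interstitial clusters from coinciding insertions — removed by
  support dominance against the parallel two-step path or direct edge
  (`pop_indel_artifacts`);
* genuinely bidirectional adjacencies where quasi-periodic sequence plus
  indels merged two nearby loci into one cluster: the majority-direction
  repair (`repair_edge_directions`) removes only dominated (3x) minority
  edges and keeps near-balanced two-visit cycles for the Euler traversal
  to resolve.

The residual graph is tangled at a few hundred loci per 50 kb at
`p_i = p_d = 1.5%`; the walk fallback spells it into ~100 draft contigs
whose reference identity is ~96-97%, which is the regime the indel
benchmark measures (success = mismatch below 5%).

## Error decomposition and information requirements

The phasing failure probability decomposes as
`P(err) <= eps1 + eps2 + delta_cov`: consensus error, extension error given
`k` spanning reads per link, and the probability of having fewer than `k`.
`estimate_eps1` replays the calibration design (flanked repeat of 5000 in a
5 Mb genome, two sites at equal thirds, reads from both copies at the
genome-wide coverage) and scores a trial as failed if any site is missed,
mislocated, miscalled, or spuriously called. `estimate_eps2` draws exactly
`k` spanning reads per link and scores strict-majority outcomes; at
`p = 0.01` the observed error is ~0.04 at `k = 1` and ~0.001 at `k = 3`,
inside the published upper bounds (0.060 and 0.0036). `delta_cov` is a
Poisson union bound over links with a Monte Carlo cross-check.

The three requirement curves are `prop1_requirement` (greedy:
bridging denominator `L - ~l_max - 2 l_iid`), `prop2_requirement`
(multibridging: bridging at `~l_crit`, coverage at `L - 2 l_iid`; the
self-referential `N > G ln(3N/eps)/...` term is solved by fixed-point
iteration, which converges in a few steps because the dependence is
logarithmic), and `xphase_requirement` (Poisson probability of fewer than
`k` reads bridging the exact interior plus anchors, plus a coverage-gap
term). The X-phased asymptote sits at `l_int + 2 l_iid`, strictly left of
the multibridging asymptote whenever the flanked length exceeds the exact
length; for long reads the `k = 3` condition costs more than single
bridging and the curves cross back — both facts are asserted in the tests.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; witnesses and truth
  sidecars use the same convention.
* Exact repeat statistics come from a sort-based suffix array with the
  Kasai LCP array; maximal repeated pairs are enumerated from LCP runs with
  an explicit left-maximality filter. Circular genomes double the string
  and de-duplicate occurrences modulo `G`. Interleaved enumeration is
  restricted to maximal repeats of at least `floor_len` (default 12) and
  validated against an exhaustive oracle on small strings.
* The flanked-repeat detector extends exact seeds while the mismatch
  density in a trailing window (20 bases) stays below 0.35 — halfway
  between polymorphism-level density and the 0.75 random ratio — then
  backs off trailing mismatches and chains same-diagonal seeds. Its
  resolution is about one window; flanked statistics are treated as
  estimates, not exact targets.
* Tie-breaks are deterministic throughout: greedy merges order by
  `(W, id1, id2)`; join partners by `(W, cluster size, id)`; branch
  survivors by `(support, id)`; Hierholzer picks the lowest-id edge.
  Identical seeds give identical assemblies.
* Fingerprints are 16-mers (2-bit packed); at most 5 distinct offsets are
  kept per read pair, ordered by vote count.
* `evaluate_assembly` scores single contigs by banded global edit distance
  (band doubled adaptively from `|length difference| + 32`), locating
  contigs on circular references by fingerprint diagonal vote before
  alignment; multi-contig output is tiled greedily (longest first,
  non-overlapping placements) and scored as matched bases over `G`.

## What the benchmarks do and do not show

The synthetic benchmark conditions mirror the published experiment designs:
the substitution benchmark plants `~l_max = l_max = 500`, `~l_int = 200`,
`l_int = 100` with two sites at `p = 1.5%`; the indel benchmark uses
`G = 50000` at coverage 23.0x (`L = 200`) and 24.1x (`L = 180`) with
`p_i = p_d = 1.5%`. Replicate counts are 15 per indel point in the test
suite and 30 in `scripts/acceptance.R`; the X-phased gap experiment runs
100 rounds at `G = 5000`, and the noiseless exactness check 30 rounds at
`G = 10000`. These sizes keep the full suite within a desktop-scale run
while leaving the binomial comparisons meaningful.

The generator reproduces exactly the repeat structure the theory analyses —
one long flanked repeat, one interleaved partner, one optional triple — on
an i.i.d. background. Real genomes have repeat *families*, skewed
composition, tandem arrays and inverted repeats, none of which are
modelled; passing these benchmarks demonstrates the algorithmic claims on
the model, not production readiness on arbitrary bacteria. Known
limitations, all deliberate: no reverse-complement handling (the model
samples one strand); no consensus polishing stage beyond per-cluster
majorities; only 2-in/2-out X-nodes are phased (higher-degree nodes are
left unresolved with a warning); the consensus call threshold is a fixed
log-factor and at high noise (`p = 0.1`) with shallow coverage its false
site rate is regime-sensitive — the corresponding calibration cell is
reported as measured rather than tuned to the published value.
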