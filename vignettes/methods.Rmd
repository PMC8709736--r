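---
title: "Methods: SNP variation graphs, exact depth-limited alignment, and genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP variation graphs, exact depth-limited alignment, and genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgraph)
library(tibble)
```

## The model

A variation graph represents a reference genome together with known
variants as a sequence graph: nodes carry DNA strings over `{A,C,G,T,N}`,
directed edges connect them, and named paths spell the sequences of a
population. When the only variants are biallelic SNPs the graph has a very
particular shape that this package exploits throughout:

* each SNP is a *diamond*: two parallel one-base nodes (reference and
  alternative allele) sharing the same predecessors and successors;
* reference runs between SNPs are chunked greedily left-to-right into
  nodes of at most 32 characters (the node-length bound that graph k-mer
  indexes impose);
* node IDs are assigned sequentially in left-to-right reference order, so
  **every forward edge strictly increases the node ID**. The graph is
  acyclic, and traversing against the edges is exactly the reverse strand.

That last property is the engine of the aligner: the orientation of a seed
hit determines once and for all whether the extension walks towards higher
or lower IDs, so the search never needs global graph context.

Each chromosome contributes a reference path; every SNP contributes two
single-node alternate paths, `alt_<chrom>_<pos>_0` (reference allele) and
`alt_<chrom>_<pos>_1` (alternative allele). A single connected path cannot
contain two parallel nodes, so per-allele paths are the only walk-valid way
to mark allele nodes while keeping the property "every allele node lies on
an `alt_` path" checkable; this matches the per-allele convention of the
major graph toolkits. `vg_validate()` checks all of these invariants and
returns violations as data.

Coordinates follow the two conventions of the field and convert only at
the boundaries: VCF positions are 1-based; graph offsets are 0-based and
counted from the start of the node *in the stated orientation*.

## Seed index

The index answers one question: where does a short pattern (2–32
characters) occur *within a single node*, on either strand? Each hit
reports the query triple of graph indexes — node `id()`, the
orientation-relative `offset()`, and `rc()`, the reverse-complement flag.
Internally it is a 2-mer bucket dictionary over all node sequences and
their reverse complements with full verification of the remainder,
implemented in C++. Because nodes are at most 32 characters, this small
dictionary reproduces the full query contract of a compressed suffix-array
graph index at this scale; the compressed data structures themselves are
out of scope and deliberately not reimplemented. Patterns containing `N`
never match (no wildcard semantics — strict and testable). Occurrences
that exist only across a node boundary are by definition not index hits;
finding them is the extension phase's job.

## Alignment

Mapping is exact (no mismatches, no gaps) seed-and-extend under a
depth-limited search:

* **Seeds** anchor a terminal substring of the read: a read prefix matched
  on a node's forward strand extends towards increasing IDs; matched on
  the reverse-complement strand, towards decreasing IDs. This one uniform
  rule guarantees the unmatched remainder always lies in the traversal
  direction, and the oriented spelling of the final walk equals the read
  on both strands. Seeds must share at least 2 characters with the graph.
  Anchors are maximal within their node; ties are broken deterministically
  (longest anchor first, then ascending node ID, forward before reverse).
* **Boundary anchors.** An anchor cut to a single character by a node end
  (including reads that start inside a 1-bp allele node) is kept when its
  second character matches the start of an oriented successor — the two
  shared characters then straddle an edge. Without these, a read starting
  at the last base of one node and ending at the first base of another has
  no single-node terminal anchor at its true locus and would be
  unmappable; with them, every error-free read sampled from a haplotype
  walk maps (the completeness property the tests assert at n = 10,000).
* **Extension** is depth-first in the fixed neighbour order with two hard
  caps taken as defaults: a global budget of `2 * N` probed nodes per seed
  (N the read length) and at most 4 neighbour probes per node. Every
  probed node — matching or not — decrements the budget, and nothing is
  refunded on backtrack (the most conservative reading). On SNP-only
  graphs out-degree is at most 2 and wrong-allele branches die on their
  first character, so the true walk costs fewer than `2 * N` probes —
  which is why the budget never rejects a clean read. Backtracking within
  those same caps subsumes the no-return pseudocode variant; a strict
  `backtrack = FALSE` mode is available for fidelity experiments.
* **Early stop.** The first complete alignment traversing an allele node
  is recorded as best and ends the read's search; otherwise the first
  complete alignment found wins, and one alignment is reported per read.

Reads containing `N` or shorter than 2 bases are rejected. Qualities are
carried through but ignored — exact matching has no use for them.

## Genotyping and evaluation

The genotyper is declared plumbing: the variant-calling stage downstream
of the mapper, kept deliberately simple and swappable. Per site, allele
depths are the counts of alignments traversing the reference- or
alternative-allele node (a read spanning several SNPs contributes to each
independently; it can never support both alleles of one site since the
nodes are parallel). With total depth `d` and alternative fraction `f`:
`./.` if `d < 2`; `1/1` if `f >= 0.9`; `0/0` if `f <= 0.1`; else `0/1`.

The homozygosity threshold is calibrated a priori rather than tuned: at
20x coverage the site depth is approximately Poisson(20) and a
heterozygote's alternative count is Binomial(d, 1/2), so a 0.8 threshold
miscalls a het with probability about 1.3% — too often to recover
genotypes at 99% concordance when (under the default allele-frequency
model) roughly 80% of non-reference sites are hets. At 0.9 the two-sided
binomial tail drops to about 4 in 10,000 at depth 20, which leaves
comfortable margin; all documented behaviours of the caller (0.5 fraction
is a het, fraction 1 a hom-alt, depth 1 a no-call) are unchanged.

Evaluation is genotype-aware, keyed by `(chrom, pos, ref, alt)`: a
non-reference call is TP only if a truth record at the same key carries
the identical genotype, otherwise FP; unmatched non-reference truth
records are FN; `0/0` and `./.` calls are never counted. Precision,
sensitivity and F-measure follow with the defined-zero convention for
empty denominators. Allele-level (rather than genotype-level) matching
would shift FP/FN bookkeeping and is intentionally not implemented.

## The simulator

The simulator emulates the inputs a real study would download — reference
FASTA, population SNP catalog VCF, gold-standard truth VCF, and FASTQ
reads — at desk scale:

* reference: i.i.d. uniform `ACGT` (so GC is 0.5 and k-mers are almost
  surely unique at the sizes used);
* panel: sites without replacement at `snp_rate` per base; alternative
  alleles uniform over the other three bases; population alternative-allele
  frequencies uniform on [0.05, 0.5] — unspecified by any source, chosen
  once so heterozygotes are common and genotype recovery is informative;
* individual: genotype per site from Hardy–Weinberg proportions of its
  frequency; het alleles phased onto a random haplotype; haplotypes built
  by substitution;
* reads: `ceiling(coverage * L / read_length)` single-end reads alternating
  between the haplotypes, uniform starts and strands, i.i.d. substitution
  errors; names encode the true placement for aligner tests.

One global seed drives everything, with fixed per-stage streams so
changing read simulation never perturbs the panel; identical
configurations give byte-identical FASTA/VCF/FASTQ output.

What the simulator does *not* model — indels, quality-correlated and
context-dependent errors, repetitive sequence, linkage disequilibrium,
population structure — bounds what green tests mean: they demonstrate the
algorithmic properties (exactness, completeness on clean data, strand
symmetry, budget compliance, genotype recovery under binomial sampling),
not performance on real genomes, where repeats and indels would reduce
mappable reads and exact matching discards every read with an error.

## Problem sizes and numerical choices

The test suite exercises the pipeline at a 100 kb genome with 500–1,000
panel sites and 10,000–20,000 reads of length 100 per run — large enough
that every code path (both strands, boundary seeds, multi-SNP reads,
failed seeds) occurs thousands of times, small enough to iterate on.
`scripts/acceptance.R` uses the same sizes. Index–oracle equivalence is
checked exhaustively (every pattern of length 2–8 present in the nodes,
plus absent patterns) on 200 seeded random graphs of up to ~170 nodes.

Remaining numerical conventions: ties among equally good non-SNP
alignments go to the first seed in the deterministic order; neighbour
iteration is ascending ID forward and descending ID reverse; duplicate
edges are collapsed at index build; the JSON alignment dialect stores
per-step `from_length == to_length` edits (exact matches only) with
`identity` fixed at 1; and the on-disk "index" file is a versioned
descriptor with the graph digest, since the dictionary itself is rebuilt
deterministically from the graph in memory.

## Known limitations

Only biallelic SNPs: no indels, multiallelic sites, or structural
variants, hence no cycles and no bidirected inversion edges. Exact
matching only — any sequencing error unmaps its read, so sensitivity
degrades as `(1 - e)^N` with error rate `e`. One alignment per read, no
mapping qualities, no paired-end constraints. The threshold caller has no
likelihood model; anyone comparing against a production genotyper should
swap that stage.
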