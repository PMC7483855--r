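---
title: "Assembly and polishing in run-length space: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly and polishing in run-length space: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoasm)
```

## The problem and the representation

Nanopore long reads trade length for accuracy: raw identity around 90%,
with most of the error mass in the *lengths* of homopolymer runs rather
than in the identity of the bases. `nanoasm` therefore performs almost
every step in **run-length encoded (RLE) space**: a sequence is stored
as its distinct bases (no two adjacent equal) plus per-base repeat
counts. Two reads that disagree only about homopolymer lengths have
*identical* RLE base strings, so alignments in RLE space are far cleaner
than in raw space. Useful facts about this space, all checked by the
test suite: there are $4\cdot3^{k-1}$ valid RLE $k$-mers; on i.i.d.
uniform sequence, run lengths are geometric with mean $4/3$, the RLE
string is $3/4$ the raw length, and a $k=10$ RLE window spans about
$13.3$ raw bases.

Repeat counts are capped at 255 at ingest; a read containing a longer
run is rejected (such reads are vanishingly rare in practice), as are
reads containing ambiguity codes.

## Markers and overlap detection

Reads are summarised as ordered occurrences of **markers**: a fixed
random subset of RLE $k$-mers ($k=10$, selection probability $0.1$, so
about 7,900 of the 78,732 valid 10-mers). Selection draws each
reverse-complement pair jointly so the set is closed under reverse
complement; this makes the marker representation of a reverse
complemented read derivable from the forward one and keeps the entire
pipeline strand-symmetric. The marker sequence is roughly ten times
shorter than the RLE sequence, and is insensitive to errors outside
marker occurrences.

Candidate overlapping pairs are found with a **threshold MinHash**
("low hash") scheme over features of $m=4$ consecutive markers. Unlike
classical MinHash, which targets Jaccard similarity and therefore
penalises a short read contained in a long one (Jaccard = length
ratio), each iteration keeps *every* feature whose salted 64-bit hash
falls below 1% of the hash space, and buckets oriented reads by those
hash values. Buckets larger than 10 occupants are ignored (repeat
suppression), pairs co-bucketed in at least 2 of the 10 iterations
become candidates. The hash is a fixed splitmix64 construction, so runs
are reproducible across platforms.

One consequence worth knowing: with *error-free* reads, every read over
a locus carries identical features, so bucket sizes equal read depth
and the default cap suppresses everything above ~10x. The error-free
tests therefore raise `minhash_max_bucket_size`; real (noisy) data does
not hit this.

## Marker-space alignment

Candidates are verified by an optimal chain of matching markers,
computed by sparse dynamic programming over match cells only. Banding
heuristics: consecutive aligned markers may skip at most
`max_skip = 30` markers on either read, and on each end the chain must
come within `max_trim = 30` markers of the end of *at least one* read —
the minimum over the two reads, which is what admits dovetail overlaps
while rejecting alignments floating in the middle of both reads.
Markers occurring more than 10 times within either read are excluded
first. The objective is maximal aligned-marker count; ties break to the
smaller total skip and then the lexicographically earliest chain, so
results are deterministic. Alignments with fewer than 40 aligned
markers (a desk-scale choice; the parameter is exposed) are rejected.
An exhaustive-oracle test verifies optimality on all small instances.

## Read graph, marker graph, simplification

Each accepted alignment is an edge between oriented reads. Each vertex
ranks its incident alignments (aligned count, then skip, then partner
id) and marks its best six; an edge survives if either endpoint marks
it, so degree may exceed six. This k-nearest-neighbour filter tames
repeat-induced connectivity.

The **marker graph** starts with one vertex per marker occurrence per
oriented read; for every read-graph edge, aligned occurrences are
merged with a union–find (order-independent, tested by permutation),
together with the mirrored merges on the opposite strands. Merged
vertices with coverage outside $[10, 100]$ are removed; an edge
$v_0 \to v_1$ is created when a read contributes to both vertices with
only removed vertices in between, and the read's intervening sequence
is recoverable from stored positions.

Simplification then works purely by flagging edges as removed, always
mirroring removals on the reverse-complement edge (the mirror of any
witness path exists by symmetry, so guarantees carry over):

1. **Approximate transitive reduction** — edges with coverage at or
   below 0 are removed; coverage-1 edges whose single read skips more
   than 100 markers are removed; remaining edges below coverage 256 are
   processed by increasing coverage, and $v_0 \to v_1$ is removed iff a
   BFS avoiding it finds an alternative path of at most 30 edges.
   Reachability within the horizon is provably preserved (and
   property-tested).
2. **Leaf pruning** — 6 iterations removing edges whose source has
   in-degree 0 or target out-degree 0; removes side branches up to 6
   edges, spares cycles.
3. **Bubble/superbubble removal** at thresholds 10, 100, 1000 (in
   marker-graph edges), each iteration condensing the graph into an
   assembly graph (maximal linear chains; length = constituent edges;
   average coverage = mean of constituent coverages). Parallel assembly
   edges with all branches under the threshold keep only the
   highest-average-coverage branch (ties: longer, then smallest vertex
   sequence). Superbubbles are weak components of short edges; for each
   entry/exit pair the shortest path under edge length
   $1/\text{avg coverage}$ is kept and the other intra-cluster short
   edges removed. Two degenerate cases needed decisions: an entry that
   is also an exit contributes a valid zero-length path (this excises
   fold-back self-loops caused by chance near-tandem marker repeats —
   without it, 20–50 kb assemblies fragment), while clusters with no
   entry-to-exit path at all are left untouched.

## Consensus

One edge per reverse-complement pair of assembly edges is assembled by
walking vertex → edge → vertex. Vertices contribute their marker
sequence verbatim (all contributing reads agree by construction), with
repeat-count observations collected per position. Edges contribute by
case: overlapping adjacent markers use the most frequent overlap length
(ties to the smaller); non-overlapping markers trigger a progressive,
end-anchored profile multiple alignment of the intervening read
sequences with column-majority consensus (inputs are sorted internally
so read order does not matter; column ties prefer a base over a gap,
then the alphabetically smallest base); hybrid edges first discard the
minority kind. Repeat counts are decoded by plurality (ties to the
smaller count), and the expanded sequence is the contig. The optional
Bayesian length model is deliberately *not* used here; it belongs to
the polisher.

## Polishing

The polisher refines a draft assembly using all reads, in RLE space
throughout:

1. **Posteriors.** Each read (in its mapped orientation, guided either
   by marker-space mapping against the draft or by an external SAM) is
   aligned to its window of the assembly with a banded forward–backward
   pass of a three-state affine-gap pair-HMM, keeping sparse match,
   insertion and deletion posteriors above 0.01. Deletions at read
   boundaries are treated as probability zero. Banded equals unbanded
   when the band covers the matrix (oracle-tested). The shipped HMM
   parameters (match continuation 0.92, gap open 0.04, gap extend 0.23,
   match emission 0.96) are fixed defaults chosen so ~90%-identity
   reads align with high posterior mass in RLE space; they are
   exposed for refitting to other chemistries.
2. **Weighted POA.** Backbone weights $w(j,x)$ sum match posteriors of
   base $x$ over all reads — the expected number of observations of
   $x$ at $j$, possibly fractional. Multi-base indels are approximated
   by the minimum of their single-base posteriors (an upper bound,
   verified against exhaustive path enumeration on toys), indels are
   left-shifted to maximal extent and merged with summed weights, and
   a 100-node running window estimates local coverage.
3. **Local proposal and evaluation.** Edits with weight below
   $0.18\times$ windowed coverage are pruned; backbone nodes further
   than 5 nodes from any plausible edit are anchors; between successive
   anchors all paths and plausible substitutions are enumerated (cap 64
   alternatives, else the region is skipped with a warning) and scored
   by total read log-likelihood; the best sequence replaces the
   original only if strictly more likely, so likelihood never
   decreases. One extra refinement pass runs by default.
4. **Run-length decoding.** Per backbone position, the observed read
   run lengths (best-posterior, same-base matches) are decoded with the
   Bayesian model: $\hat y = \arg\max_y \sum_i \log P(x_i \mid y, b)$,
   ties to the smaller $y$. The model is four row-normalised 50×50
   confusion matrices trained from (true, observed) pairs.
5. **Chunking.** Chunks of 1000 RLE bases with 50-base overlaps are
   polished independently; when coverage exceeds 50x, reads are
   discarded with probability
   $1 - (\text{chunkSize} + 2\,\text{chunkBoundary})\cdot\text{maxDepth}/N_c$
   (seeded). Neighbouring chunks are stitched at the middle of the
   longest identical run of a pairwise alignment of their overlaps.

Three robustness choices matter at desk scale and are this package's
own design decisions. First, untrained confusion cells are floored at
$10^{-4}$ during decoding: a single outlier observation (a run split by
a substitution) must not veto a length supported by dozens of reads.
Second, repeat counts are only re-decoded where at least five
informative observations exist; elsewhere the draft count is kept — on
a 50 kb contig the 1–3x ends would otherwise dominate the error count.
Third, edit regions whose windowed coverage is below 4 are not
adjudicated at all. On genome-scale data these guards are nearly
inert; on small simulations they are what makes polishing a
strict improvement.

## The read simulator

The simulator is the package's test bed and defines its study
conditions: i.i.d. uniform genomes (optionally with a planted
duplicated segment), uniformly placed reads with random strand and
log-normal lengths (meanlog 9.2, sdlog 0.35, minimum 500), and a
three-channel error model applied in order: (1) each homopolymer's
observed length is resampled from a generative confusion matrix — a
discrete double-geometric centred on the true length with scale
$0.35 + 0.06y$, truncated to $\pm4$ — matching the qualitative
structure of basecaller run-length confusion (diagonal-dominant,
dispersion growing with length); (2) substitutions at 1.5%;
(3) single-base non-homopolymer indels at 0.8%. These rates were
chosen once to land the median read identity near the ~90% regime of
real nanopore data (the observed median is ≈0.886) with the error mass
dominated by homopolymer lengths, and are configuration, not ground
truth. Every read carries a full edit trace; `replay_read()`
reconstructs the read exactly, traces provide the (true, observed)
run-length pairs that close the loop with the polisher's training, and
identity is computed from the trace (errors over alignment columns).

What the simulator does *not* emulate: signal-level artefacts,
sequence-context-dependent error rates, chimeric reads, coverage
biases, and real repeat structure beyond a single planted duplication.
Passing tests therefore demonstrate the algorithms' correctness and
their behaviour under the stated error regime, not performance on any
particular real genome.

## Problem sizes and determinism

The shipped tests and the acceptance script run, per seed, 50 kb
genomes at 40x coverage for assembly (about 185 reads) and polish a
50 kb planted-error draft; statistical properties use 0.4–1 Mb of
random sequence. These sizes were chosen so the full suite completes
comfortably on one CPU while keeping every estimate's sampling error
well inside its tolerance. All randomness flows from explicit integer
seeds (marker selection, hash salts, simulator, downsampling); repeated
runs are bit-identical, and the platform-stable hash keeps them so
across machines.

## Known limitations

- The assembler targets haploid/monoploid assemblies; heterozygous
  bubbles are collapsed, not phased.
- Chance exact marker repeats within `max_skip` can merge into one
  vertex; the resulting fold-backs are excised (losing the few bases
  between the copies), visible as rare small deletions in contigs.
- Containment classification is heuristic (overhang comparison) and
  used only for reporting.
- The enumeration cap and region-span cap mean extremely dense error
  clusters are left unpolished (with warnings).
- The pair-HMM defaults are not fitted to any specific basecaller;
  refit them for real data.
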