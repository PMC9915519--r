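---
title: "Simple omnitigs: model, algorithm and evaluation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simple omnitigs: model, algorithm and evaluation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omnitigs)
```

## The model

An assembly graph here is a directed multigraph $G = (V, E)$ with $n$
nodes and $m$ arcs; parallel arcs and self-loops are allowed, and a
self-loop counts once toward the in-degree and once toward the out-degree
of its node. A *walk* $W = (w_1, \dots, w_\ell)$ is a sequence of
adjacent nodes; walks store their arc sequence explicitly so that
parallel arcs are unambiguous. A *split* is a node with at least two
outgoing arcs, a *join* one with at least two incoming arcs. A *unitig*
is a walk whose inner nodes $w_2, \dots, w_{\ell-1}$ all have in- and
out-degree one; the maximal unitigs partition the arc set and are the
conventional assembler output.

Given a walk, let $w_i$ be its first inner join (or $w_\ell$ if there is
none) and $w_j$ its last inner split (or $w_1$). When $j < i$, the
subwalk $w_j..w_i$ is the walk's *core*; a walk possessing a core is a
*simple omnitig*. Equivalently, a simple omnitig is the *univocal
extension* of its core: beyond the core it only passes through nodes
with a unique out-arc on the right and a unique in-arc on the left, so a
contig need not stop at the boundary of a repeat or a bubble but can
carry its unique flanking context along.

The sequence layer is the arc-centric de Bruijn graph of a $k$-spectrum:
nodes are $(k-1)$-mers, and each $k$-mer contributes one arc from its
$(k-1)$-prefix to its $(k-1)$-suffix. A walk *spells* the string formed
by its first node followed by the last character of each subsequent
node. The model is deliberately single-stranded: the safety statements
below are proved on the plain de Bruijn graph of the genome, and
double-stranded (GFA, bidirected) inputs enter instead through the
doubled-graph conversion described later.

## Safety

A walk is *safe* if its spelled string must occur in every genome
consistent with the graph. Under the idealised assumptions used
throughout — error-free reads with perfect coverage, so the graph is the
de Bruijn graph of the genome's own $k$-spectrum — simple omnitigs are
safe on a single circular chromosome. For linear multi-chromosome
genomes, let $L$ be the set of $(k-1)$-mers that begin or end some
chromosome (`boundary_set()`). If no *inner* node of a simple omnitig
lies in $L$, its spelled string is a substring of some chromosome: any
chromosome walk containing the core's first arc cannot enter or leave
the omnitig midway, because left of the core every inner node has a
single in-arc and right of it a single out-arc.

`verify_safety()` verifies this property constructively: it builds the
graph, enumerates all maximal simple omnitigs, marks each walk
*applicable* when its inner nodes avoid $L$, and tests the spelled
string against the chromosomes (rotation-aware for circular ones). The
condition is one-directional — non-applicable walks may still be safe
and are reported, never asserted. For walks flagged circular (isolated
cycles, below) every node is treated as inner, which is conservative and
in particular always excludes cycles spelled from a linear chromosome,
since such a cycle necessarily contains the chromosome's first
$(k-1)$-mer.
Multiplicity is ignored: one witness occurrence suffices.

## The enumeration algorithm

Maximal unitigs are found by a linear sweep: every arc whose tail is not
a degree-$(1,1)$ node starts a unitig, which is extended while the head
remains degree-$(1,1)$. Components in which *every* node has in- and
out-degree one are isolated cycles; they are reported once each as a
circular walk, broken at their smallest node id, and are excluded from
the core test (the core definitions address non-circular walks).

A maximal unitig $W = (w_1..w_\ell)$ is the core of a maximal simple
omnitig exactly when

  (a) the core of $W$ is $W$ itself (automatic for $\ell \ge 2$),
  (b) if $w_1$ has exactly one outgoing arc it has no incoming arcs, and
  (c) if $w_\ell$ has exactly one incoming arc it has no outgoing arcs.

Intuitively, a unitig failing (b) or (c) is absorbed into the univocal
extension of a neighbouring core, so emitting it separately would
produce a non-maximal omnitig. `maximal_simple_omnitigs()` therefore
iterates over the maximal unitigs, keeps those passing (a)–(c), and
outputs their univocal extensions, in time $O(m + \mathit{out})$ where
$\mathit{out}$ is the total output length.

Single-node unitigs deserve a remark: the core definition gives
length-one walks no core, while the characterisation above admits
$\ell \ge 1$. The package reconciles the two by accepting a single-node
candidate only when (b) and (c) hold *and* its univocal extension has
length at least two and itself possesses a core. In practice the arc
partition produces unitigs with $\ell \ge 2$, so the case is a guard
rather than a code path exercised by typical inputs.

### Termination and the finite semantics

The univocal extension as defined can be infinite: if a chromosome ends
inside a repeat, the graph contains a cycle that is entered but never
left, and the extension winds around it forever. Each extension
direction therefore stops just before re-traversing an arc it has
already added. The guard cannot trigger on graphs whose repeats have
branching flanks — the situation the error-free model produces for
interior repeats — and on entered cycles it yields the natural finite
answer: the entry context plus one full traversal of the cycle.

This choice fixes the package's finite semantics, and the brute-force
oracle (`brute_force_simple_omnitigs()`) is defined against the same
semantics so that the two are comparable on arbitrary graphs. The
oracle grows walks arc by arc in both directions from every single-arc
walk (any two-node walk trivially has a core), keeping exactly the
walks that (i) have a core and (ii) repeat no arc within the backward
phase together with the core, nor within the core together with the
forward phase — only the two extension phases may share an arc, which
is precisely what happens when a repeat is traversed once on each side
of its core, as in the planted-repeat example below. One can show that
every walk emitted by the algorithm satisfies this invariant, and
conversely that walks violating it are winding phases of an unbounded
extension and never maximal. Finally, the oracle discards walks whose
own core is a *non-maximal* unitig (its endpoints are degree-$(1,1)$
nodes): by definition the core of a maximal simple omnitig is a maximal
unitig, and inside entered cycles the guarded enumeration would
otherwise retain arbitrary winding phases. After a subwalk-containment
filter the oracle output provably coincides with the algorithm's; the
test suite confirms the equality on hundreds of seeded random
multigraphs with parallel arcs and self-loops.

### Worked examples

```{r fixtures}
fx <- fixtures()
# planted repeat A R B R C: the three omnitigs spell AR, RBR, RC
sapply(so_walks(maximal_simple_omnitigs(fx$G1)),
       function(w) paste(walk_node_names(fx$G1, w), collapse = ","))
# bubble A{B|D}C: both full variants are recovered
sapply(so_walks(maximal_simple_omnitigs(fx$G2)),
       function(w) paste(walk_node_names(fx$G2, w), collapse = ","))
```

## Doubled graphs

Assemblers exchange bidirected GFA graphs, where each segment can be
read in two orientations. `double_graph()` converts them to plain
directed graphs by the node-doubling convention: each segment $s$
yields nodes $s^+$ and $s^-$, and each link $(a, o_a, b, o_b)$ yields
the arc $a^{o_a} \to b^{o_b}$ plus its mirror
$b^{\bar{o_b}} \to a^{\bar{o_a}}$. Palindromic links contribute a
single self-mirrored arc, and links restated in both orientations are
deduplicated (on tail, head and overlap — genuinely parallel links with
distinct overlaps are preserved). The resulting graph records the node
and arc mirror maps, so enumeration output comes in
reverse-complement pairs; `collapse_mirror = TRUE` keeps the
lexicographically smaller walk of each proper pair. GFA overlap fields
are stored verbatim and never interpreted: tig enumeration is
topology-only. The node-doubling convention was chosen over arc
doubling because it keeps mirror symmetry a property of the node set,
which makes the pairing of walks immediate.

## Synthetic data

The generators are pure functions of their specification — the seed is
part of the spec, and the session RNG stream is left untouched. Plain
chromosomes are uniform over $\{A,C,G,T\}$; defaults follow the study
conditions used throughout the tests: 2–4 linear chromosomes of length
100–500 with $k \in \{5, 7, 11\}$ for the linear-genome safety corpus,
single circular chromosomes of the same lengths with $k = 7$ for the
circular corpus, and random multigraphs with $n \le 12$, $m \le 25$ for
the oracle corpus, where arcs are sampled uniformly with replacement so
self-loops and parallel arcs occur naturally.

Planted features build the two canonical structures: a repeat
chromosome $X\,R\,Y\,R\,Z$ (unit 30 bp, spacers 50 bp by default) and a
diploid-style bubble pair $A\,B\,C$ / $A\,D\,C$ (arms 20 bp, flanks
50 bp). Cleanliness at the caller's $k$ is enforced by rejection
sampling, capped at 1000 attempts: for repeats, every duplicated
$(k-1)$-mer must overlap a planted unit copy in all its occurrences;
for bubbles, each haplotype must be internally duplicate-free and
cross-haplotype duplicates may occur only at equal positions
overlapping the shared flanks. The stricter bubble rule matters: a
repeated $(k-1)$-mer *inside* a shared flank creates an entered cycle
at a chromosome end, exactly the lasso structure under which several
unitigs merge into one shorter omnitig and the planted contiguity gain
disappears.

What the generator does not emulate: sequencing errors, coverage gaps,
chimeric reads, heterozygosity beyond a single bubble, and
double-strandedness. Passing tests therefore demonstrate the
combinatorial guarantees under the error-free perfect-coverage model,
not robustness on real read data — on real data, missing branches can
let an omnitig extend over a node where the error-free graph would have
stopped it.

## Contiguity evaluation

When contigs may overlap — as simple omnitigs do by design — N50-style
metrics mislead, because the same reference region can be covered by
several contigs. The EA$x$max family is robust to this: for each
reference base, record the length of the *longest* alignment covering
it (zero if uncovered); sort these per-base values in descending order;
EA$x$max is the value at index $\lfloor x/100 \cdot G \rfloor$
(0-based, clamped to $G-1$), where $G$ is the total reference length.
An EA50max of $\ell$ means half the reference positions are covered by
an alignment of length at least $\ell$. Taking the maximum rather than
the average means a short contig nested inside a longer one never
lowers the score; the per-base array is concatenated across references
by default (`per_reference = TRUE` reports each separately). The
rounding rule at the percentile index is not canonical; floor-and-clamp
is the default because it is well defined for all $x$ including 0 and
100 and matches the "at least $\ell$" reading, and `index_mode =
"ceiling"` exposes the alternative.

```{r eaxmax}
aln <- alignment_records("r", c(0, 5), c(8, 10))
eaxmax(aln, c(r = 10), x = c(50, 75, 90))$values
```

Misassembly positions found by an external evaluator are merged into
*unique* misassemblies so that a single assembler error inside a unitig
is not counted once per omnitig containing it: positions are sorted and
merged greedily left to right when less than $X$ bp apart (default
$X = 3000$, the extensive-misassembly threshold for large genomes),
with the extra rule that a position also opens a new cluster when it
lies $\ge X$ from the current cluster's minimum. The second condition
keeps every cluster span below $X$ instead of transitively chaining
positions into one span much longer than $X$; the threshold comparison
is strict, so two positions exactly $X$ apart stay separate.
Misassembly *detection* and contig splitting are inputs, not
computations, of this package. Evaluation is intended to run in
homopolymer-compressed space (`hpc_compress()`, with
`hpc_coordinate_map()` lifting coordinates between raw and compressed
positions), which stabilises alignment-based evaluation of HiFi
assemblies.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally (PAF/BED convention);
1-based coordinates appear only in chromosome-naming error messages.
All enumerations are deterministic: walks are sorted by first node id,
length, then arc-id sequence, and isolated cycles are broken at their
smallest node id. The $k$-spectrum is a set — multiplicity is
discarded. Empty inputs return empty results (`eaxmax` of no alignments
is 0 everywhere; the safety report of an empty genome has zero rows);
`eaxmax` rejects $G = 0$ and records outside $[0, G)$; linear
chromosomes shorter than $k$ are an error naming the chromosome.
Randomness is confined to the synthetic module and always seeded.

## Problem sizes

The test and verification corpora use 200 random multigraphs
($n \le 12$, $m \le 25$) for oracle equivalence, 100 linear and 100
circular random genomes for the safety checks, 20 planted-repeat and 20
planted-bubble genomes for the contiguity-gain checks, 100 random
EA$x$max instances ($G \le 10^4$, up to 50 records), and 50 random
bidirected graphs (8 segments, 12 links) for mirror symmetry. These
sizes keep the full verification suite within a couple of minutes on a
single core while exercising every code path; all quantities are
recomputed from scratch by `scripts/acceptance.R`.

## Limitations

Simple omnitigs are not a complete safe-walk algorithm: safe walks
containing chromosome ends exist under more complex topological
conditions that are not implemented here, and the full omnitig
framework is out of scope. Safety under sequencing errors or coverage
gaps is explicitly outside the model. The de Bruijn layer is
single-stranded by design; canonical-$k$-mer graphs built from raw
reads are not constructed (double-stranded graphs enter as GFA through
the doubling conversion). GFA support covers the S/L subset of GFA1.
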