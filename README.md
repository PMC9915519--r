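# omnitigs

Simple omnitigs and safe-walk analysis for genome assembly graphs, in R.

Genome assemblers conventionally report **maximal unitigs**: walks in the
assembly graph whose inner nodes have in- and out-degree one. Unitigs are
safe — guaranteed substrings of the genome under an error-free,
perfect-coverage model — but they stop at every branching node, so contigs
break at the boundary of each repeat and bubble. **Simple omnitigs** relax
this: a simple omnitig is a walk with a non-branching *core* unitig, all
nodes right of the core having out-degree one and all nodes left of it
having in-degree one (its *univocal extension*). They carry unique
flanking context through repeats and bubbles, are safe for circular
chromosomes, and remain safe for linear multi-chromosome genomes whenever
their inner nodes avoid the set *L* of chromosome-end (k−1)-mers.

The package is aimed at assembly-method developers and students of
assembly theory. It provides:

- a directed multigraph model with walks, parallel arcs and self-loops
  (`omni_graph`, `omni_walk`), plus bidirected GFA graphs and their
  conversion to doubled graphs with mirror (reverse-complement) tracking
  (`read_gfa`, `double_graph`, `mirror_walk`);
- arc-centric de Bruijn graphs of k-spectra and walk spelling
  (`k_spectrum`, `build_dbg`, `spell`, `boundary_set`);
- maximal unitig and maximal simple-omnitig enumeration in
  O(m + output) time via the core characterisation — a maximal unitig
  (w1..wl) is a core iff (a) it is its own core, (b) if w1 has exactly one
  outgoing arc it has no incoming arcs, (c) if wl has exactly one incoming
  arc it has no outgoing arcs — together with an independent brute-force
  oracle (`maximal_unitigs`, `is_core_of_maximal`, `univocal_extension`,
  `maximal_simple_omnitigs`, `brute_force_simple_omnitigs`);
- safety verification against the generating genome
  (`verify_safety`, `unitig_safety_check`, `is_substring`);
- seeded synthetic genomes with planted repeats and bubbles, random
  multigraphs, and the worked-example fixtures (`generate_genome`,
  `generate_random_graph`, `fixtures`);
- contiguity evaluation robust to overlapping contigs: the EAxmax metric
  family, unique-misassembly merging, and homopolymer compression
  (`eaxmax`, `merge_misassemblies`, `hpc_compress`, `read_paf`).

## Worked example

Simulate a genome with a planted repeat `X R Y R Z` (unit 30 bp, spacers
50 bp), build its de Bruijn graph at k = 7, and compare unitigs with
simple omnitigs:

```r
library(omnitigs)

gs  <- genome_spec(n_chromosomes = 0,
                   features = list(repeat_feature(copies = 2,
                                                  unit_length = 30,
                                                  flank_length = 50)),
                   k = 7, seed = 11)
res <- generate_genome(gs)
str(tig_stats(res$genome, 7))
#> List of 5
#>  $ n_unitigs           : int 4
#>  $ n_simple_omnitigs   : int 3
#>  $ unitig_total_length : int 203
#>  $ omnitig_total_length: int 272
#>  $ gain                : num 1.34
```

The four unitigs stop at the repeat boundaries; the three simple omnitigs
spell `X R`, `R Y R` (the full span from the first to the second repeat
copy) and `R Z`, a 34% gain in total spelled sequence. All of them are
safe:

```r
verify_safety(res$genome, 7)
#> safety report: 3 walks, 3 applicable, 0 violation(s)
```

EAxmax scores each reference base by its longest covering alignment; with
a length-8 and a length-5 alignment on a 10 bp reference:

```r
aln <- alignment_records("r", start = c(0, 5), end = c(8, 10))
eaxmax(aln, c(r = 10), x = c(50, 75, 90))
#> EAxmax profile over 10 reference bases
#>     ref  x value
#>  genome 50     8
#>  genome 75     8
#>  genome 90     5
```

so 50% (and 75%) of bases are covered by an alignment of length ≥ 8, and
90% by one of length ≥ 5. Misassembly positions less than X bp apart
merge into unique misassemblies, without transitive chaining past X:

```r
merge_misassemblies(c(100, 2000, 5000, 5100), X = 3000)
#>   ref cluster representative span n_members
#> 1 ref       1            100 1900         2
#> 2 ref       2           5000  100         2
```

A command-line interface wrapping these functions (subcommands
`simulate`, `build-dbg`, `unitigs`, `simple-omnitigs`, `verify-safety`,
`double-graph`, `eaxmax`, `merge-misassemblies`, `hpc`) is installed at
`system.file("cli", "tigs.R", package = "omnitigs")`.

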