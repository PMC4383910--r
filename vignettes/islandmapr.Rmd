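---
title: "Mapping tDNA-targeted genomic islands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tDNA-targeted genomic islands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandmapr)
library(dplyr)
```

## The island signature

Genomic islands — prophages, integrative conjugative elements (ICEs)
and their satellites — most often integrate site-specifically into
tRNA or tmRNA genes (collectively, tDNAs), in a reaction catalyzed by
a tyrosine integrase acting on an island attachment site (*attP*) and
a chromosomal target (*attB*) inside the tDNA. Because *attP* carries
a copy of part of the target gene, integration splits the tDNA but
simultaneously restores it: the chromosome afterwards carries one
intact tDNA at one end of the island and a *displaced fragment* of the
same gene at the other end. The intact gene and its fragment bracket
the island exactly, so an island found this way has single-nucleotide
endpoints — unlike composition-based island finders, which blur edges
over hundreds of bases.

islandmapr searches for exactly this signature. Given a replicon
sequence, its tDNA annotations, tyrosine-integrase calls (Pfam PF00589
hits projected onto the DNA) and a table of protein-domain
projections, it:

1. admits island-capable integrases (excluding the host Xer
   recombinases and integron integrases);
2. aligns each tDNA against both strands of its own replicon with a
   seeded local-alignment search, yielding candidate displaced
   fragments;
3. treats each tDNA/fragment interval as a candidate island and passes
   it through seven filters;
4. resolves multiple surviving candidates at one tDNA into a single
   island or a tandem array;
5. names the accepted islands and reports summary statistics.

Only tyrosine-integrase-dependent, tDNA-targeted islands are found:
islands integrated by serine recombinases, at non-tDNA sites, or that
have lost their integrase or fragment are invisible to this method by
design.

## Fragment search

Each tDNA, read 5′→3′ in gene orientation, is a query against its own
replicon. Seeds are exact `word_size`-mers (default 7 nt) shared
between the query and either strand of the replicon; every seed is
extended in both directions by anchored dynamic programming under the
configured scoring, so a reported hit is the best local alignment
constrained to contain its seed word. Scoring defaults follow the
megablast-off BLASTN parameterization the search emulates: match +2,
mismatch −3, gap open 0 and gap extend 2.5 per residue (a k-residue
gap costs `gap_open + k * gap_extend`; the fractional extend penalty
is kept as a real-valued score rather than rescaled to integers).

Because an E-value calculation is out of scope, reported hits are
bounded instead by a score floor (`min_fragment_score`, default 20 ≈
ten matched bases) and a length floor (`min_fragment_len`, default
10 nt); *att* overlaps in real islands run from roughly 10 to 250 bp,
so these floors sit below everything the method should detect. Hits
whose subject intervals overlap by more than half the shorter hit are
collapsed to the higher-scoring one (ties to the leftmost), and any
alignment of the gene onto part of its own locus — the trivial
self-hit, but also partial self-matches that arise in tDNAs with
internally repeated or palindromic stretches — is removed before
candidates are built.

`local_align_oracle()` implements full Smith–Waterman/Gotoh dynamic
programming under the same scoring. It shares no code path with the
seeded search and exists so that the search can be validated against
an exhaustive reference on small instances; the test suite asserts
equality of the two whenever an exactly seeded copy is planted, and
that no hit ever exceeds the exhaustive optimum.

### Fragment side and damage

A hit is a 5′ fragment when its query span begins at gene position 0,
and a 3′ fragment when its query span ends within `damage_offset`
(default 3) bases of the gene end. The 3′ allowance exists because a
class of islands deletes a few bases just upstream of the discriminator
position in the displaced fragment; alignments for such *damaged*
fragments stop short of the 3′ terminus, and a 3′ fragment ending
before the gene end is flagged `damaged`. The 5′ terminus gets no such
allowance — only the 3′ case is biologically motivated. Everything
else is an internal fragment.

## Candidate intervals

In gene-local orientation, a fragment downstream of the tDNA defines
the island `(tDNA 3′ end, fragment distal end]`; a fragment upstream
defines `[fragment proximal start, tDNA 5′ start)`. The island thus
*includes* the displaced att copy and *excludes* the intact gene:
excising exactly this interval and rejoining the flanks leaves one
intact tDNA, which is the defining property of a precise island call.
(The literature does not fix which att copy "belongs" to the island;
this convention is the one under which excision is exact, and the
island length counts the att overlap once.)

On circular replicons all interval arithmetic is topology-aware
(internally, `start > end` marks an origin-crossing interval), and the
displacement side is read from the shorter arc between gene and
fragment — which is why the synthetic generator guarantees that no
planted island exceeds half its replicon.

## The filter cascade

Seven filters, applied in a fixed order for reporting but each a pure
predicate of one candidate, so the accepted set is order-independent:

| filter | rejects candidates that ... | default |
|---|---|---|
| integrase | lack ≥1 bp overlap with an admitted integrase ORF | — |
| cds | have fragment or tDNA overlapping a non-integrase Pfam domain projection | — |
| tdna | have the fragment fully inside another annotated full-length tDNA | — |
| length | are shorter than `min_len` or longer than `max_len` | 2 kb, 200 kb |
| internal | have an internal fragment (neither gene end) | — |
| configuration | have a 3′ fragment upstream or a 5′ fragment downstream | — |
| orientation | have fragment and tDNA in opposite orientations | — |

Notes on the less obvious choices:

* **Integrase admission.** Xer recombinases (XerC/D/S and XerD-like)
  act at *dif* sites and are not island-borne, so any call labelled
  with a Xer subfamily is excluded. Integron integrases mobilize
  cassettes, not islands; a call whose E-value against the
  integron-integrase profile is at or below
  `integron_evalue_max = 1.2e-24` is classified integron-like
  (a smaller E-value is a stronger match to the integron model) and
  excluded. The boundary is taken as inclusive: a hit exactly at the
  published segregation threshold is treated as integron-like.
* **CDS filter.** True tDNAs and their split fragments should not
  overlap conserved protein-coding sequence, so domain-projection
  overlap of either the fragment or the query gene rejects the
  candidate — with the documented exception of integrase domains,
  since some integrase genes are known to extend across *attP*.
* **tDNA filter.** Containment, not overlap, is required: a fragment
  that merely abuts a gene end is legitimate att evidence, whereas a
  "fragment" lying wholly inside another full-length tDNA is just
  conserved gene sequence.
* **Configuration filter.** Candidates without a defined end-fragment
  side (internal hits) are vacuously passed here, so that the internal
  filter is the unique rejector of internal fragments and every decoy
  class in the synthetic suite fails exactly one filter when the
  filters are evaluated in isolation.
* **Orientation filter.** True signatures are never opposite-oriented;
  because false candidates should appear in either orientation equally
  often, the rejection rate of this late filter doubles as an estimate
  of the residual false-positive load.

### att subsites

Crossovers in tRNA targets cluster in the anticodon-loop region
(subsite A) or towards the 3′ end of the gene, in the T-loop /
acceptor-stem junction region (subsite J; the two 3′ subsites are hard
to distinguish and are reported together). The crossover is taken as
the fragment's proximal query boundary, and its position as a fraction
of gene length is classified with the window
`[subsite_a_min, subsite_a_max) = [0.30, 0.60)` for A and J at or
beyond it. No published numeric boundary exists for this split; the
window places the anticodon arm around mid-gene and is configurable.
Crossovers below 0.30 — acceptor-stem-proximal, which the model does
not expect — are classified J with a warning. tmRNA targets get `NA`.

## Resolution, naming, summaries

When several candidates survive at one tDNA, they are sorted by
fragment distance (nearest first) and the spanned region is cut into
consecutive segments, each ending at its own fragment. If every
segment also carries its own admitted integrase, the group is a
*tandem array*: each segment becomes an island with `tandem_index`
k of n, member 1 nearest the gene. Tandem islands are reported as
these disjoint segments (each member's interval runs from the previous
fragment to its own fragment) rather than as nested gene-to-fragment
intervals, so that members do not overlap and each contains exactly
its own integrase and att copy. Otherwise a single winner is kept:
highest fragment score, then shortest island, then leftmost — the
strongest att evidence first, with deterministic tie-breaks.

Island names follow the nickname convention: uppercase first letter of
the genus (a leading *Candidatus* is skipped) plus the first two
letters of the species, a serial number distinguishing strains that
share a nickname, an underscore, the island length in kbp (rounded
half away from zero, so 49,591 bp → 50) and a one-letter code for the
integration site — the target tRNA isotype, or `Z` for tmRNA targets,
which have no standard one-letter code (configurable). Serial numbers
can be supplied per replicon; otherwise a purely numeric `strain`
field is used, and remaining replicons are numbered in input order
within each nickname. Distinct islands can legitimately share a name,
so files carry an additional unique `island_id`.

`summarize_islands()` reports the run-level statistics: total islands,
genomes with at least one island, mean islands per positive genome
(two decimals, half away from zero), damaged counts, the 3′/5′
partition, the A/J/NA subsite partition and tandem-array counts; the
side and subsite partitions each sum to the total by construction.

## The synthetic genome generator

Real genomes with curated island truth are not available to a test
suite, so the package generates its own: `simulate_genome()` plants
islands with known endpoints and decoys that each violate exactly one
filter, and `truth_compare()` scores a scan against the plan with
*exact-endpoint* recall (an island off by one base counts as a miss).

Design points that make the truth table exact:

* **Fixed templates.** Eleven hand-fixed 76-nt tDNA-like templates
  (one per isotype used, one for tmRNA; all ending in the
  discriminator-CCA motif) are pairwise disjoint in 7-mer content,
  including reverse complements and each template against its own
  reverse complement. The test suite asserts this. Disjointness
  guarantees that a query can only seed on copies of *its own*
  template.
* **Scrubbed background.** Background is i.i.d. with configurable GC,
  then rewritten so that no `word_size`-mer of any template or filler
  (either strand) occurs outside a planted copy; since the seeded
  search requires an exact word match, background can never produce a
  hit. The scrub is a single constraint-satisfying sweep that fixes
  each offending window by changing one or two background bases while
  keeping every window covering the changed base clean; on circular
  replicons the windows crossing the origin are cleaned the same way.
* **Extension-safe flanks.** Each planted fragment is flanked by
  fixed filler windows chosen (deterministically, by dynamic
  programming against the template continuation) so that no alignment
  extension past the planted boundary can score positive. Endpoint
  drift of even one base is therefore impossible, which is what makes
  exact-endpoint recall a fair criterion.
* **One decoy per filter.** Eight decoy classes map onto the filters:
  an island without an admitted integrase (its ORF is planted but
  labelled Xer or integron-like, exercising admission), a fragment
  inside a non-integrase domain projection, a fragment embedded in
  another full-length tDNA (a chimeric "host" gene), too-short and
  too-long islands, an internal fragment, a 5′ fragment placed
  downstream, and an opposite-orientation fragment. Each decoy passes
  the other six filters when they are evaluated in isolation, which
  the suite asserts per class.
* **Determinism.** Generation is byte-identical under the plan seed;
  the global RNG state is saved and restored. A post-generation
  verification confirms that every template word in the final sequence
  lies inside a planted copy; in the rare case a junction cannot be
  cleaned, the generator re-draws from the next substream.

What the generator does **not** emulate: realistic codon usage or
compositional bias, phage gene content, tDNA sequence diversity within
an isotype, degenerate or nested att sites, and fragments with more
mutations than the 3′-damage deletion. Passing the synthetic suite
therefore demonstrates the correctness of the algorithm's logic and
arithmetic — not sensitivity on real genomes, where fragment
divergence and annotation quality dominate.

## Problem sizes and numerical choices

The default test and validation runs use replicons of roughly 30 kb to
1.2 Mb with up to ten plants each: the property suite scans 50 seeded
genomes mixing topologies, strands, damage and decoy classes; the
alignment search is checked against the exhaustive oracle on 500
random instances (queries ≤ 100 nt, subjects ≤ 350 nt); and the
length-bound run plants islands of 1.5, 2, 50, 200, 201 and 611 kb in
one ~1.07 Mb replicon. These sizes keep a full run in a few minutes on
one CPU while exercising every code path, including origin-crossing
islands obtained by rotating circular replicons.

Other numerical conventions, in one place: internal coordinates are
0-based half-open on the forward strand and all on-disk formats are
1-based inclusive; length-filter bounds are inclusive at both ends;
the integron E-value cutoff is inclusive; kbp and the summary mean
round half away from zero; alignment tie-breaks prefer shorter
alignments and leftmost subject positions; ambiguous bases (`N`) never
match anything, including themselves, and codons containing `N` are
treated as sense codons during ORF scanning (conservative toward
keeping ORFs intact; translation table 11 stops TAA/TAG/TGA).

## Interfaces

`scan_islands()` is the in-memory entry point (tibbles in, an
`island_scan` object out, with `tidy()`, `glance()` and `autoplot()`
methods); `run_island_pipeline()` wraps it for files (FASTA +
GFF3/TSV in; GFF3, FASTA, TSV and a JSON manifest out; byte-identical
outputs for identical inputs). A thin command-line driver with
`find`, `simulate` and `summarize` subcommands ships in
`inst/cli/islandmapr.R`. External gene callers and HMM scanners
(tRNAscan-SE, ARAGORN, HMMER, pfscan) are consumed as file adapters —
their outputs are inputs here — and are deliberately not executed by
the package.

```{r example}
sim <- simulate_genome(synthetic_plan(11, c("canonical_island",
                                            "tandem_array",
                                            "decoy_no_integrase")))
scan <- scan_islands(sim$replicons, sim, quiet = TRUE)
tidy(scan)[, c("name", "start", "end", "length", "subsite",
               "tandem_index")]
glance(scan)[, 1:6]
truth_compare(scan, sim$truth)[c("recall", "precision")]
```

## Known limitations

* Sensitivity is bounded by the fragment search floors: att overlaps
  shorter than ~10 bp, or too diverged to retain a seed word, are
  missed — as they are for the underlying method generally.
* Fragments of multi-copy identical tDNAs can attribute an island to
  the wrong gene copy; the tDNA filter removes fully contained hits
  but cross-copy att assignments are inherently ambiguous.
* The A/J subsite boundary is an approximation with no published
  numeric definition; counts near the window edge should be read
  accordingly.
* Xer- and serine-recombinase-dependent islands, and islands whose
  target site has decayed, are out of scope by construction.
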