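---
title: "Mining genomes for PHA synthase genotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for PHA synthase genotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phacmine)
```

## Overview

`phacmine` screens microbial genome collections for polyhydroxyalkanoate
(PHA) synthase (PhaC) genes and summarises the taxonomic and ecological
distribution of the detected genotypes. PhaC is the polymerase of PHA
biosynthesis; its classes (I–IV) differ in subunit composition and monomer
chain-length preference, so the *class* of a detected locus is the
biologically meaningful label: class II genotypes signal potential
medium-chain-length PHA producers, class I/III/IV short-chain producers.

This vignette explains the models and procedures, the parameters that
matter, what the synthetic fixture does and does not emulate, and the
design decisions taken where several reasonable options existed.

## Reference curation

Public protein databases return a noisy mixture for any gene-name query:
true synthases, fragments, putative or ambiguous annotations, duplicated
records, and outright different proteins (depolymerases, phasins,
regulators). Curation proceeds in a fixed order:

1. **Name exclusions.** Ordered, case-insensitive substring patterns, each
   carrying a removal reason (`not_phac`, `ambiguous`, `putative`,
   `fragment_name`); the first matching pattern wins. The shipped defaults
   reconstruct a manual inspection step as reproducible patterns and are
   fully user-overridable via `curation_rules()`.
2. **Length filter.** Residue counts below 328 (bacteria) or 100 (archaea)
   are removed as fragments (`fragment_length`). Intact bacterial PhaCs are
   ~600 aa (~60 kDa), archaeal catalytic subunits can be much shorter,
   hence the domain-specific thresholds. The boundary is strict
   less-than: a 328-residue bacterial sequence is kept.
3. **Duplicate removal.** Byte-identical sequences are collapsed keeping
   the *first* in input order — determinism requires a convention, and
   keep-first preserves whichever record the upstream export listed first.
4. **Class assignment.** Word-boundary patterns on the protein name
   (`class I`…`class IV`; the class II subunit names PhaC1/PhaC2) take
   precedence; otherwise a TIGRFAM-to-class map is consulted (defaults:
   TIGR01838 → I, TIGR01839 → II, TIGR01836 → III, shipped as editable
   configuration rather than asserted ground truth); otherwise the class is
   `Unknown`. Two name patterns implying *different* classes raise an
   error rather than guessing.

Every record ends in exactly `kept` or `removed` with a reason, and the
stage order (name → length → duplicate → class) is fixed so that reports
are comparable across runs. Whether length filtering precedes name
filtering is immaterial for the kept set (both filters are pointwise), but
the reason attributed to a doubly-polluted record depends on it; the
shipped order applies name patterns first.

## Class transfer

References still `Unknown` after metadata-based assignment are classified
by sequence similarity: every classified reference is aligned against
every unclassified sequence, and each unclassified sequence adopts the
class of the query with the lowest E-value at `E ≤ 1e-10`; equal E-values
are broken by the higher bitscore, and any residual tie by the
lexicographically smallest query accession. The final tie-break is a
package addition — some total order is needed for determinism; accession
order is transparent and stable.

## Translated homology search and its statistics

The search is a self-contained TblastN-equivalent so the pipeline is fully
testable without external binaries:

* **Six-frame translation.** Whole contigs are translated in frames
  +1..+3 and −1..−3 (reverse complement) under the standard genetic code;
  stop codons stay in-sequence as `*`, codons containing `N` become `X`,
  trailing partial codons are dropped. There is no ORF calling: a
  through-frame search with stop penalties mirrors how a translated BLAST
  scans all frames.
* **Alignment.** Optimal affine-gap local alignment (Smith–Waterman;
  `Biostrings::pairwiseAlignment` supplies the dynamic program) with
  BLOSUM62, gap open 11 and gap extend 1 — the standard protein-search
  settings. A gap of length L costs `11 + (L − 1)`. `*` scores −4
  against everything, discouraging alignments from crossing in-frame stops
  without hard segmentation; `X` scores −1. A best local score that is
  not strictly positive is "no alignment".
* **Statistics.** Raw scores are normalized to bits,
  `S' = (λS − ln K)/ln 2` with the standard gapped-BLOSUM62 constants
  `λ = 0.267`, `K = 0.041`, and assessed as `E = m·n·2^(−S')` with `m` the
  query length and `n` the total translated residue count of the genome
  (or the total target residues, for protein-vs-protein search). No
  length/edge correction is applied: absolute E-values therefore differ
  from BLAST's composition-corrected values, but monotonicity in the score
  and threshold behaviour at `1e-10` are preserved, and the statistic is
  exactly reproducible in tests. The test suite pins the closed forms
  (e.g. `S = 100` → 43.13 bits; `m = 100, n = 1000`, 10 bits →
  `E = 97.65625`) and checks score equality against an independently
  written brute-force dynamic program on hundreds of random pairs.
* **Coordinates.** Aligned spans on a frame translation are mapped back to
  1-based inclusive nucleotide positions on the forward strand; spans are
  reported `min..max` with the frame's sign carrying the strand.

Heuristic seeding, HSP chaining and multi-HSP sum statistics are out of
scope: only the single optimal local alignment per query/target pair is
reported. At desk scale (tens of genomes, kilobase contigs) exhaustive
alignment is affordable and exact.

## Genotype calling

Per genome, hits from **all** queries are pooled and a single best hit is
retained — lowest E-value, then highest bitscore, then smallest query
accession — and the call carries the matched query's class. Pooling across
queries (rather than per query first) follows from wanting one
representative PhaC per genome. Genomes without a qualifying hit receive
no call, so the call table has at most one row per genome; a full hit pool
is available behind `all_hits = TRUE` for multi-locus analyses.

## Ecological tabulation

GOLD organizes ecosystem metadata as a path (ecosystem → category → type →
subtype → habitat). The environmental subset keeps rows with ecosystem
`Environmental` *and* category `Aquatic` or `Terrestrial` — conjunction,
not disjunction, since Aquatic/Terrestrial are children of Environmental
in the hierarchy — and drops rows whose ecosystem, category or type is the
missing-value token `unclassified`.

Relative abundances are `100·count/total` rounded **half-up** to one
decimal, computed in exact integer arithmetic so no floating-point
artifact can flip a final digit. Denominators follow the grouping: each
class's environmental total for class × ecosystem-type tables, each
phylum's total for phylum cross-tabs. `paper_check()` carries a versioned
fixture of published marginal counts and recomputes every printed
percentage from its printed numerator/denominator; the handful of printed
values that are internally inconsistent with their own counts (off by one
final digit, e.g. 56/204 printed 27.4 where half-up gives 27.5) are
flagged `consistent = FALSE` and reported as documented mismatches rather
than reconciled.

Extreme-environment flagging uses a descriptor table — (ecosystem type,
subtype-or-habitat pattern) rows covering hydrothermal and deep-sea marine
habitats, saline/alkaline waters, thermal springs, oil reservoirs, mud
volcanoes, acid-mine and salt geologic settings, halite pinnacles, and
creosote/desert/permafrost/saline soils. A pattern of `*` matches the
whole ecosystem type; other patterns are case-insensitive substrings
matched against both subtype and habitat. Flagged and unflagged rows
partition each class's environmental set, and subtotals are reported
against the class totals.

## Phylogeny

Trees serve to visualize whether detected genotypes cluster by class.
Distances are `1 − identity` of the optimal *global* affine-gap alignment
with gap columns counted in the denominator — a p-distance that is exact,
symmetric and needs no multiple alignment. Trees are built by classic
neighbor joining (`ape::nj`), which is exact on additive matrices; the
test suite checks that an additive 4-taxon matrix is reproduced to 1e-9
and that well-separated class families come out monophyletic. Negative
branch lengths (an NJ artifact on non-additive input) are clamped to zero
with the clamped amount reported. Maximum-likelihood inference and
multiple sequence alignment are deliberately out of scope; users who want
them can export the curated and predicted proteins and run their preferred
tools on the FASTA/Newick artifacts.

## The synthetic study fixture

`simulate_study()` generates the fixture all end-to-end tests run on.
Defaults are fixed study conditions, not tuning knobs:

* **References.** Three seed proteins of 400 aa, one per class, drawn from
  disjoint six-residue alphabets so pairwise identity is ≈ 0 (far below
  the 30% twilight zone). The alphabets are chosen with comparable mean
  BLOSUM62 diagonal scores (≈ 5–6 per residue) so that alignment scores
  are comparable across classes — an exact planted copy of one class must
  outscore a heavily mutated copy of another, which an aromatic-heavy
  alphabet would violate. Within-class families are produced at 10%
  per-site divergence; 5 clean references per class by default. Pollution
  (putative-named, sub-threshold fragments, exact duplicates, decoy
  non-PhaC proteins) is added at configurable rates with every record
  tagged in a truth manifest. The class is recorded in the protein name
  for 60% of clean references, in the TIGRFAM field for 20%, and omitted
  for the rest, exercising all three assignment paths.
* **Genomes.** 50 single-contig genomes of 3,000 nt of i.i.d. uniform
  background; 80% receive a planted gene: a reference protein mutated at
  5% per residue, reverse-translated with uniformly sampled synonymous
  codons, and written over a random window on a random strand. Mutations
  are substitutions only (indel rate 0 by default) so planted coordinates
  stay exact for coordinate tests. Uniform background makes the E-value
  calibration clean: with a 400-residue query and ~6,000 translated
  residues per genome, a chance hit needs ~55 bits (raw ≈ 130) to pass
  `1e-10`, far above the expected maximum of random local scores (~57
  raw), so negatives stay hit-free; a 5%-mutated planted gene scores in
  the thousands, so positives are unambiguous.
* **Metadata.** One GOLD path per genome sampled from a categorical
  profile spanning common aquatic/terrestrial settings, the extreme
  descriptors, host-associated/engineered genomes and `unclassified` mass
  that the environmental filter must drop.

What the fixture does **not** emulate: real genome composition (GC skew,
codon usage), multi-gene PHA operons, phylogenetically realistic taxon
sampling, indels, or database-scale search spaces. Passing tests
demonstrate that the pipeline's logic — curation bookkeeping, statistics,
tie-breaks, coordinate mapping, tabulation arithmetic — is correct under
controlled conditions; they do not certify recovery rates on real data,
where divergence, fragmentation and compositional bias are harsher.

Problem sizes were chosen for a single-CPU desk run: the default fixture
(15 queries × 400 aa against 50 × 3 kb genomes, six frames) completes the
full mining stage in about a minute.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere; frame `0` encodes "none"
  in the 13-column tabular hit format, whose first 12 columns follow the
  common tabular-hit dialect.
* Metadata is tab-separated UTF-8 with the literal lowercase token
  `unclassified` for missing values; an empty TIGRFAM cell stays empty
  (an empty identifier list is not missing information).
* E-values are serialized in scientific notation with two significand
  digits (`0.0` for exact zero); a write–read–write cycle is
  byte-identical.
* All generators take explicit integer seeds and are byte-reproducible;
  `run_pipeline()` reruns with the same configuration produce
  byte-identical tables.
* Newick output quotes labels containing `(),;:` or whitespace.

## Known limitations

* E-values are uncorrected `m·n` statistics; use them for ranking and
  thresholding, not for cross-tool comparison with BLAST output.
* One call per genome by design; genomes carrying several *pha* loci
  surface only their best hit unless `all_hits = TRUE`.
* The shipped curation patterns are a reproducible proxy for manual
  inspection and will not capture every annotation idiosyncrasy of real
  database exports; the rules object exists precisely so users can extend
  them.
* Neighbor joining on p-distances is a visualization aid, not a
  substitute for model-based phylogenetics.
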