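---
title: "Methods: structural annotation and classification of LTR-retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation and classification of LTR-retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrtrace)
```

# What this package models

`ltrtrace` re-implements, as a tested in-silico pipeline, the bench workflow
used to characterise LTR-retrotransposons in taxa without sequenced genomes:

1. **Detection** — degenerate primers written against conserved reverse
   transcriptase / RNase H protein motifs amplify short (here ~400 bp) *pol*
   fragments (`find_primer_sites()`, `in_silico_pcr()`).
2. **Family clustering** — fragments are grouped into families by a
   divergence criterion (`pairwise_p_distance()`, `partition_families()`).
3. **Reconstruction** — PCR-walking products are joined into a *chimeric
   consensus* element under explicit overlap thresholds
   (`validate_join()`, `assemble_chimeric_consensus()`).
4. **Structural annotation** — LTR pair, primer binding site (PBS),
   polypurine tract (PPT), ORFs with decay reporting, protein domain motifs,
   and a superfamily call from the *pol* domain order (`annotate_element()`).
5. **Clade assignment** — ranked similarity against a reference library with
   Karlin–Altschul E-values and a two-condition GalEa rule
   (`rank_hits()`, `assign_clade_galea()`).
6. **Phylogenetics** — JTT+Γ pairwise distances, neighbor joining,
   nonparametric bootstrap (`jtt_gamma_distance()`, `neighbor_joining()`,
   `bootstrap_support()`).

A seeded synthetic-data generator (`make_element()`, `diversify_family()`,
`plant_elements()`, `make_walk_fragments()`) plants ground-truthed elements
so every stage can be verified offline, without databases or wet lab.

# The synthetic generator: what it emulates

An element is laid out as

```
[5' LTR][gap][PBS][spacer][gag ORF][spacer][pol ORF][spacer][PPT][gap][3' LTR]
```

* **LTRs** are identical direct repeats (default 217 bp) bordered by
  configurable dinucleotides (TG..CA by default, CT..AA for the Gypsy
  preset).
* **PBS** is the reverse complement of the 3' end of a bundled tRNA
  (tRNA-Met by default), placed so its 1-based start mirrors the position a
  full annotation would print (219 for the default Copia preset).
* **PPT** is a purine-rich tract immediately (or at a preset offset)
  upstream of the 3' LTR.
* **gag/pol** are real reading frames. The *pol* domain region is a
  *canonical* amino-acid sequence fixed per superfamily, so that
  independently generated elements of one superfamily are recognisably
  homologous across their RT/RH domains — the property real clade
  classification relies on. Codon choice, spacers, gag filler and the LTRs
  are drawn from the element seed.
* **Domain order** encodes the superfamily: Copia carries
  PR–INT–RT–RH (integrase upstream of the RT), Gypsy PR–RT–RH–INT, and the
  Gmr1-like Gypsy preset has the unconventional INT-before-RT order combined
  with Gypsy-type RT/RH motifs.
* **Primer footprints** are planted as exact nucleotide expansions of the
  bundled degenerate primers. CD1/CD2/GD1/GD3 decode exactly to their motif
  codons (KARLVA, YVDD…, RMPFGL, ADALSR). The GD2 primer does not decode to
  LTTDAS codons on any frame, so its footprint is planted as an exact
  expansion of the primer's reverse complement (translating LATDAE) and the
  literal LTTDAS protein motif is planted separately a few residues
  downstream.
* **Decay defects** (premature stops, frameshifts) are planted at exact
  nucleotide positions. A frameshift is engineered so the upstream frame
  reads a stop codon precisely at the planted position, which makes the
  position recoverable from sequence alone — the convention a curator
  would adopt when no external homolog is available.

Three deliberate artificialities keep the ground truth *exactly*
recoverable, and they are the main caveat when extrapolating test results
to real data:

* **Stop guards.** Spacers, LTR bodies and *pol* filler carry fixed codon
  patterns that place stop codons in all (or all alternative) reading
  frames at short intervals. Real genomes have no such guards: real ORF
  boundaries are fuzzy, and alternative-frame pseudo-ORFs occur. The guards
  exist so that "recovers every planted coordinate exactly" is a
  well-posed test.
* **Purine-poor PPT flanks.** Sequence around the planted PPT is kept
  purine-poor so the planted tract is the unique best-scoring window. In
  real elements the PPT is usually, but not always, the best local purine
  run.
* **Neutral filler alphabet.** Inter-motif protein filler avoids C/H/D/E so
  zinc-finger, protease and DD35E patterns occur only where planted. Real
  proteins can contain chance motif-like strings; the annotation stage's
  specificity on real data is bounded by its motif patterns, not by these
  tests.

Family simulation uses uniform per-site substitution to a random different
base. Requested divergences are *pairwise* expectations: per-branch rates
are derived by Jukes–Cantor composition so that two copies of one family
have expected p-distance `intra_divergence` and copies of different
families `inter_divergence` (valid for values below 0.75). An optional
`conserved` interval set exempts positions from substitution — the analogue
of purifying selection on the catalytic motifs that degenerate-primer
screens depend on; the pipeline uses it for the CD1/CD2 footprints.

# Annotation: parameters and conventions

All user-facing coordinates are 1-based inclusive (so printed positions
like "PBS at 219" read off directly); BED output is 0-based half-open.

* **LTR detection** (`find_ltr_pair()`): exact 20-mer self-matches between
  the terminal margins (default 1000 bp) seed diagonals that are extended
  while running identity stays above `min_identity` (default 0.80), ends
  trimmed to matching positions. Identical LTRs at the element boundaries
  are recovered exactly; at ~2% divergence the detected length is within a
  couple of basepairs.
* **PBS** (`find_pbs()`): best reverse-complement match (longest, then
  fewest mismatches, then leftmost; at least 12 nt, 0 mismatches by
  default) between a 20 bp window downstream of the 5' LTR and the
  3' end of any bundled tRNA. The window default matches a PBS abutting
  the LTR; presets with distal PBS positions are annotated with a wider
  window.
* **PPT** (`find_ppt()`): highest purine-fraction window of length >= 10
  within 30 bp upstream of the 3' LTR, fraction >= 0.80; ties broken by
  longer window, then leftmost.
* **ORFs** (`find_orfs()`): maximal stop-to-stop reading frames on the
  three forward frames (candidate elements are analysed in sense
  orientation). With defect tolerance, segments down to 15 codons are
  chained by a small dynamic program: consecutive segments link when the
  gap is at most one codon, both sides contribute at least 10 codons of
  their own sequence, chains are scored by new coverage with a 25 nt cost
  per junction, and near-ties (a 12 nt band) prefer the longer predecessor
  segment. The extracted chain's span absorbs alternative-frame shadows
  (segments >= 80% covered are dropped), and `min_aa` (default 100 codons)
  applies to the stitched records. Junctions are reported as premature
  stops (same frame, in-frame stop codon) or frameshifts, each with its
  1-based nucleotide position.
* **Motifs** (`scan_protein_motifs()`): patterns over constrained positions
  with per-motif mismatch allowances; the DD35E integrase triad requires
  exactly 35 residues between the second aspartate and the glutamate. Each
  hit carries a specificity weight (constrained positions net of the
  allowance). Hits that begin inside a stitched segment's overlap with its
  predecessor are discarded as translation artifacts.
* **Superfamily** (`classify_superfamily()`): the order is read off each
  domain's most specific hit. INT before RT means Copia — unless
  Gypsy-diagnostic motifs dominate by weighted majority, in which case the
  element is called Gmr1-like Gypsy; INT after RT (and after RH when RH is
  seen) means Gypsy; anything without both INT and RT is unclassified.
  Completeness is `full_length` iff an LTR pair and all four *pol* domains
  are present.

# Family criterion

A set of groups is a valid family partition when the highest intra-family
distance is strictly below the lowest inter-family distance — disjoint
intra/inter distributions, evaluated globally (the strictest literal
reading; per-pair minima are also reported). Two boundary rules make the
criterion coherent:

* the all-singletons partition satisfies it vacuously, so a valid
  partition always exists;
* a partition consisting of a *single* family has no inter-family
  distances to compare against, so it is accepted only in the degenerate
  case of identical members. A diverse group cannot be certified as one
  family without an outgroup — a real limitation of the criterion, not of
  the implementation.

The partitioner is a single-linkage sweep ordered by distance (ties by
lexicographic id pair) that re-tests the criterion after every merge and
returns the fewest-family state that satisfied it. On random instances with
up to 8 sequences it provably returns the exhaustive minimum (tested
against full set-partition enumeration). Note that the criterion is not
refinement-monotone: splitting a tight family moves its small distances
into the inter-family set and can break global non-overlap.

# Assembly

Joins require >= 50 bp suffix/prefix overlap at >= 95% ungapped identity
(gaps are not modelled: walking products are orientation-normalised
substitution-only copies, so the exhaustive ungapped offset scan is exact at
these input sizes). Among equal-identity candidates the *shortest*
sufficient overlap wins: the suffix of an element's last walking fragment
and the prefix of its first share the entire terminal repeat at identity
1.0, so longest-overlap tie-breaking would systematically misjoin the
element ends. Disagreeing overlap columns are resolved by majority, ties by
the first-listed fragment (the choice is documented because the bench
protocol this emulates did not state one).

# Clade assignment

Scores are affine-gap local alignments (BLOSUM62, gap open 11 / extend 1;
`X` neutral; floored at 0), converted to E-values with
E = K·m·n·exp(−λS) using the standard gapped-BLOSUM62 constants
(λ = 0.267, K = 0.041) and search space = query length × summed library
length. The GalEa rule is: (i) the five best hits are exactly the five
GalEa references, and (ii) the difference between the best non-GalEa and
best GalEa E-values exceeds 1e−10. The difference is taken literally as an
arithmetic difference (the primary reading), which makes condition (ii)
approximately "the best non-GalEa hit is weaker than 1e−10"; an
orders-of-magnitude mode (`mode = "log10"`) is provided because the
phrasing is genuinely ambiguous. The bundled reference library is a
deterministic synthetic stand-in built from the generator's canonical
RT/RH regions (five GalEa references at 5% residue divergence, plus
motif-only-related Copia and Gypsy references); it is user-replaceable.

# Phylogenetics

* **Trimming** (`trim_alignment()`): a per-column filter — smoothed
  normalised Shannon entropy above 0.5 or gap fraction above 0.2 removes a
  column (window 3). This is a documented simplification of block-based
  trimmers: same intent (drop saturated or gappy sites), simpler and fully
  testable semantics.
* **Distances** (`jtt_gamma_distance()`): per-pair maximum likelihood under
  the JTT replacement matrix (rates and frequencies read at runtime from
  phangorn — the published Jones–Taylor–Thornton model data), with
  gamma-distributed rate heterogeneity as 4 discrete categories (means of
  quantile bins), pairwise deletion of gapped sites, and bounded scalar
  optimisation on [1e−6, 10] at tolerance 1e−6. The default shape
  alpha = 1.0 is a documented choice (no value is prescribed by the
  workflow this reproduces). The correction never undershoots the
  p-distance.
* **Neighbor joining** (`neighbor_joining()`): Saitou–Nei agglomeration,
  deterministic tie-breaking by smallest label pair, negative branch
  lengths clamped to zero with the deficit moved to the sister branch so
  path lengths are preserved. Additive matrices are recovered exactly
  (topology and branch lengths).
* **Bootstrap** (`bootstrap_support()`): column resampling with
  replacement, default 100 replicates, supports as percentages on internal
  edges; replicates with undefined distances are dropped with a warning and
  counted.

# Problem sizes used in the test and acceptance suites

The suites generate everything at run time: 50 elements per round-trip
sweep (all four presets in rotation), 200 random instances for the
exhaustive family-partition comparison (3–8 sequences), a 21 × 6
overlap/identity sweep for the join rule, 100 random additive matrices
(4–8 taxa) for NJ, and 20 replicates of 2000 simulated sites per true
distance for JTT+Γ recovery. The end-to-end pipeline demonstration plants
two families of three full-length Copia copies in a 60 kb background.
These sizes were chosen so each estimate is statistically meaningful while
a full run stays comfortably within a coffee break on one CPU.

# Known limitations

* The generator's guards and neutral filler make synthetic elements easier
  to annotate than real ones; passing tests demonstrate correctness of the
  implemented rules, not field-grade sensitivity on diverged genomic copies.
* Assembly does not handle reverse-complement fragment orientation (walking
  products are orientation-normalised) or indels within overlaps.
* Clade assignment uses a synthetic reference library by default; real use
  requires supplying curated reference proteins.
* The decayed-element analysis reports defects relative to maximal reading
  frames; at a few percent divergence, chance stop codons are (correctly)
  reported as additional decay, and in rare cases a heavily fragmented
  sub-piece can fall below the segment floor and silence a domain.
* `partition_families()` is exhaustive-optimal only as far as tested
  (n <= 8); the sweep itself is greedy and has no optimality proof for
  large n.
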