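---
title: "Comparative analysis of compact AT-rich circular mitogenomes"
author: "ctenomito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of compact AT-rich circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenomito)
```

# The problem

Ctenophore mitochondrial genomes are extreme outliers among animals:
roughly 10-12 kb circles that have lost *atp6*, *atp8* and every tRNA
gene, keep only 11 protein genes and 2 heavily reduced rRNAs, encode
everything on a single strand, and are ~84% AT with T alone around 60%
of all nucleotides. Their sequences diverge so fast that standard
annotation servers mislabel or miss genes, gene order is scrambled even
between families, and at least one lineage has reassigned the codon TGA
from tryptophan to serine. `ctenomito` packages the analyses this kind
of data requires — homology-guided annotation on circular coordinates,
circular gene-order comparison, composition/codon/non-coding statistics,
perfect-repeat search, read-overlap contig elongation — together with a
synthetic-genome generator so the whole pipeline can be exercised and
validated without any external download.

# Coordinates and containers

All coordinates are 0-based half-open. A feature on a circular genome
may span the origin, in which case `end > length` and the feature
occupies `[start, length) + [0, end - length)`; this single-interval
convention keeps non-coding accounting and overlap arithmetic simple.
GenBank flatfiles (1-based inclusive, `join(x..len,1..y)` for origin
spans) are converted only at the I/O boundary, and a write/read round
trip is bit-exact on the sequence and lossless on coordinates. N bases
are accepted on input but rejected with a clear error by translation and
ORF scanning: the genomes this package targets are fully resolved, and
silent handling of ambiguity would only hide assembly problems.

# Annotation model

Protein genes are found by scanning all three frames of the (possibly
doubled, for circularity) plus strand for maximal ORFs: from the first
allowed start codon after the previous in-frame stop through the stop
codon. The start-codon set defaults to the four codons observed in these
genomes (ATA, ATG, ATT, TTA); the initiator is translated as M whichever
codon is used. Only the plus strand is scanned by default because all
genes lie on one strand in the target genomes; a flag enables the
reverse strand.

Each ORF is scored against labelled reference proteins by global
alignment (BLOSUM62, affine gaps: open 10, extend 1), normalized by the
reference self-score so identity scores 1, and clamped to [0, 1]. A
configurable floor (default 0.3) decides whether a gene is called
present at all; the value is deliberately conservative and is the one
knob without a published anchor. Gene boundaries are then chosen by two
criteria applied lexicographically: (1) minimize total overlap in bp
with neighbouring features, (2) among ties, maximize the alignment score
of the implied protein, and (3) among remaining ties take the longest
ORF. The order of (1) and (2) is a design choice: the source procedure
lists both criteria without weighting, and applying them in listed order
makes the selection reproducible. Because each gene's neighbours are
themselves being refined, selection is iterated (three passes, stopping
early when stable); this resolves chains where one gene's maximal ORF
reaches upstream into its neighbour.

Incomplete stop codons (a T or TA abutting the next feature, completed
to TAA by polyadenylation) are admitted only when no in-frame complete
stop exists before the next feature start — a real phenomenon in these
genomes (e.g. *nad2*/*nad4L* of one species), not an annotation
convenience.

rRNAs have no reading frame, so they are located by fitting the whole
reference inside the doubled genome (exact match fast path, then
global-local nucleotide alignment at +1/−1 with the same gap scheme).
Covariance-model search is out of scope here; homology placement is the
fallback the source procedure itself used when the structural search
failed.

URFs (unidentified reading frames) are unassigned ORFs strictly longer
than 100 bp whose protein carries at least one predicted transmembrane
segment. TM prediction is a stated heuristic rather than an HMM: count
non-overlapping 19-residue windows with mean Kyte-Doolittle hydropathy
above 1.6, scanning greedily left to right. The ≥1-segment rule is a
filter (not merely a description): the procedure annotates URFs *that
encompass* predicted TM domains. URF starts are trimmed by the same
overlap-minimization rule (with no reference to score against), URFs are
made mutually non-overlapping greedily by length, and anything still
overlapping an annotated gene is dropped — accidental ORFs inside genes
in another frame are not URFs.

tRNA-like candidates are filtered with the published rule: reject iff
the candidate overlaps an annotated protein/rRNA *and* lacks a canonical
cloverleaf; canonical structures inside genes are kept but flagged for
review (the re-annotated *rnl* contained two such tRNA-like structures).

# Genetic-code reassignment

`detect_reassignment()` works from codon-aware alignments. A column is
*conserved* when at least a fraction (default 0.7) of non-target species
agree on one amino acid under the expected code; for every codon the
target uses at conserved columns, the consensus amino acids form a
frequency profile. A codon is flagged when its modal consensus differs
from its expected meaning, is supported by at least 5 columns, and
reaches modal frequency ≥ 0.5. The three thresholds are package
defaults chosen to flag the TGA→Ser case robustly in simulation; the
published investigation used a web service with unstated parameters, so
these values are ours, documented and configurable. The mold
(translation table 4) and TGA→Ser variant tables differ only at TGA,
and that property is tested.

# Gene-order comparison

Gene orders are circular sequences of labels. Because all genes lie on
one strand, an adjacency is the *directed* pair (g, next(g)); the
breakpoint distance BD counts adjacencies of one order absent from the
other, and BDn = BD / n shared genes (13 for the published table). A
consequence worth stating: a full reversal breaks every directed
adjacency (BDn = 1). Synteny blocks are maximal chains of conserved
adjacencies, reported anchored at the lexicographically smallest label;
identical orders yield one block of all n genes, and in every other case
the blocks cover exactly n − BD conserved adjacencies (a tested
identity). Display rounding of BDn is half-up to two decimals, matching
the published renderings 9/13 → 0.69, 11/13 → 0.85, 12/13 → 0.92;
stored values are unrounded. The published table itself prints BD 12 but
BDn 0.77 (= 10/13) for one pair; the fixture preserves both numbers
verbatim and the discrepancy is reported, not resolved.

A single-gene transposition changes at most 3 directed adjacencies.
Exhaustive enumeration at n = 13 shows the attainable BD values are
exactly {0, 3} — 0 when the gene is reinserted into the same circular
gap — so the generator's `rearrange_order()` rejects such no-op moves
and every counted move is a true transposition.

# Statistics

Non-coding (NC) accounting is the circular complement of the feature
union, computed twice: URFs treated as non-coding ("with URFs" in the NC
totals) and as coding ("without"). Tracts are counted above a strict
20 bp threshold, and a gap spanning the origin counts once. The
genome-size ~ NC-length Pearson correlation over the five published
rows is 0.9869 at full precision, which displays as 0.99; the source
text prints 0.98, presumably truncated. The package reports full
precision and the acceptance check accepts the [0.98, 0.99] band.

Perfect repeats are maximal exact repeated substrings (unit ≥ 21 bp for
a "longer than 20 bp" search) on the circularized sequence, found by
k-mer seeding plus maximal extension and verified in tests against a
quadratic brute-force oracle. Low complexity is proxied by dinucleotide
Shannon entropy < 1.5 bits (the published search used an unspecified
web-server filter); poly-T tracts fall well below this cutoff, random
84 bp AT-rich units sit near 2.9 bits.

# Contig elongation

`extend_contig()` implements the elongation contract at desk scale:
reads whose prefix exactly matches the contig suffix (or vice versa)
over ≥ 25 bp contribute overhanging bases, and the extension is the
column-wise majority consensus, stopping at the first conflicted column.
With 100 bp reads, a productive round extends an end by at least 75 bp
when a fully overhanging read exists — the published per-round
guarantee. Matching is exact (error-free reads are simulated; a
mismatch-tolerance knob exists but defaults to 0). Circularity is
declared when a suffix equals a prefix over ≥ 25 bp; the duplicated copy
is trimmed, taking the longest overlap when several qualify (which also
collapses a contig that overshot one full turn). Coverage statistics
place each read at every exact match on the doubled circle and report
mean, population SD and range.

# The synthetic generator

The generator *is* the study's data source, so its defaults are the
observed conditions: 13 canonical genes (11 proteins with realistic
length ratios summing with the rRNAs to ~11.3 kb of coding, rnl 840 nt,
rns 400 nt) on one strand of a circle, base composition T 0.60 / A 0.24
/ C 0.08 / G 0.08 (AT 0.84), start codons drawn ATT/ATG favoured, stop
TAA 9:1 over TAG, URFs of 100 and 60 aa with a planted 21-residue
hydrophobic stretch, and NC tracts (120, 60, 40, 25, 15, 10, 8, 5 bp,
recycled) carrying 6-12 bp poly-T runs. Codons are sampled by
independent base draws with stop-codon rejection, which shifts realized
composition by well under the ±1.5-point tolerance asserted in tests.
An in-frame stop is planted directly upstream of each URF so the
planted URF equals its maximal ORF. A requested perfect repeat is
placed in two dedicated NC tracts with mismatching guard bases so the
maximal repeat unit is exactly the requested length; the second copy
lands on the nearest segment boundary, so realized separation can
deviate from the request by up to about one gene length (the ledger
records the realized value). Cohorts reuse the base genome's proteins
and rRNAs (reverse-translated with AT-biased synonymous choice) so
cross-genome homology behaves like congeneric orthologs, while gene
order is rearranged by recorded transpositions and the NC budget is
scaled per genome so genome size varies with NC content.

What the generator does *not* emulate: sequencing error, chimeras,
nuclear contamination, real phylogenetic sequence divergence between
cohort members (orthologs are identical at the protein level), rRNA
secondary structure, and tRNA genes. Passing tests therefore demonstrate
the correctness of the computations under clean, known-truth conditions,
not robustness to noisy real data.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 200 compact-model genomes
(protein lengths scaled ~2.5-fold down, ~4.5 kb circles) for the
annotation-recovery rate; 1000 random circular permutations (n ≤ 8)
against the brute-force breakpoint oracle; 100 seeded alignment
simulations for reassignment recovery; and 100 seeded 1 kb / 20× /
100 bp-read trials for elongation-plus-circularization. Full-size
(~12 kb) genomes are used wherever a single genome suffices (round
trips, repeat search, the worked examples). Alignment-based steps are
deterministic; every stochastic step takes an explicit seed and the
generator restores the caller's RNG state. Ties are resolved by stated
rules throughout: boundary candidates by overlap → similarity → length,
homology labels by score → aligned span → lexicographic label,
frameshift repair by strict majority (a 50/50 split edits nothing), and
consensus extension stops at any column without a > 50% base.

# Known limitations

GenBank support covers the compact mitogenome dialect (LOCUS topology,
CDS/rRNA features, plain, complement and origin-spanning join
locations), not the full flatfile grammar. Homology scoring is global
alignment against curated references — adequate for ortholog sets of a
dozen proteins, not a database search. The repeat finder is quadratic in
the number of seed-sharing position pairs and is intended for 10-20 kb
organelle genomes. The elongation module assumes error-free reads at
modest depth; it is a contract model of the published procedure, not an
assembler.
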