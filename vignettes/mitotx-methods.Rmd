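---
title: "Inferring mitochondrial transcription units without tRNA punctuation"
author: "mitotx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mitochondrial transcription units without tRNA punctuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotx)
```

## The problem

In most animals the mitochondrial genome is transcribed as long polycistronic
precursors, and the 22 tRNA genes interspersed between the protein-coding
genes act as punctuation marks: RNases P and Z excise the tRNAs, releasing
the flanking messengers for maturation. Octocoral mitogenomes break this
model: they carry a *single* tRNA gene (tRNA-Met), 14 protein-coding genes
(including the octocoral-specific mismatch-repair gene *mtMutS*), and two
rRNAs on a circular molecule of roughly 19 kb. Cleaving one tRNA can only
linearize a precursor; it cannot release individual messengers. The mature
transcriptome of such a genome must therefore be established empirically:
which genes are co-transcribed on one mature messenger, where the 5' and 3'
ends of those messengers lie, whether genes use more than one
polyadenylation site, and which non-coding RNAs exist.

`mitotx` implements that inference as a reusable pipeline over four kinds of
evidence:

1. **Strand-aware RNA-seq coverage** over the annotated circular genome --
   read pairs spanning an intergenic region (IGR) between two same-strand
   neighbours are evidence that the two genes ride on one mature messenger.
2. **Circularized-RT (cRT-PCR) and RACE style junction reads** -- a
   self-ligated transcript sequenced across the ligation site contains the
   3' end, the poly(A) tract, and the 5' end in one molecule, pinning both
   transcript termini to single-nucleotide resolution.
3. **Sequence structure** -- stem-loops (perfect inverted repeats) and short
   conserved motifs in the IGRs that flank transcription units, used
   together with uncovered IGRs and strand-polarity switches to predict the
   control region / replication origin.
4. **qPCR measurements** (Cq + amplification efficiency per well) for
   efficiency-corrected relative quantification of alternative transcript
   isoforms, with a randomization test.

Because raw sequencing data for this kind of study is both huge and sparse
in mitochondrial reads, the package ships a first-class synthetic-data
generator: a parameterized *transcription program* over a replica octocoral
mitogenome. Every analytical stage is validated by parameter recovery
against that program's ground truth.

## Coordinates and containers

All public coordinates are 1-based inclusive positions on the circular
genome; internal arithmetic uses a 0-based shadow index modulo the genome
length `L`. A feature or interval whose `end` is numerically smaller than
its `start` wraps the origin. Fragment intervals may be stored "unwrapped"
(`end > L`) and are wrapped on use; this keeps interval arithmetic linear.
The heavy strand (H) is the strand carrying most genes, and `+` in an
annotation maps to H by default (`plus_is` in `load_annotation()`).

## Unit calling and precursor discrimination

`collect_linkage()` counts, for every same-strand adjacent gene pair, the
fragments with one mate overlapping each gene (or a single read overlapping
both). `call_units()` joins adjacencies with support at or above
`min_support` (default 1: at the very low mitochondrial read yields typical
of total-RNA libraries, any observed spanning pair is meaningful).

The danger of low-coverage data is that rare unprocessed precursor RNA also
produces spanning pairs, faking collinearity -- the classic signature is a
weakly supported junction between two genes whose expression levels differ
sharply (for instance a protein-coding gene next to an rRNA that is 20-50
times more abundant). A joined adjacency is therefore *demoted* to
`precursor_readthrough` when both hold:

* the whole-gene median depths of the two flanking genes differ by at least
  `precursor_ratio` (default 10), or a coverage breakpoint of that magnitude
  falls in the IGR; and
* the spanning support is at most
  `max(precursor_max_support, expected_spanning / precursor_ratio)`, where
  `expected_spanning` is the number of spanning fragments the junction
  *would* receive if both genes were co-transcribed at the lesser flank's
  coverage (computed from the observed fragment-length and read-length
  means).

The depth-adaptive second term is the package's own design choice. A fixed
support cap of 2 encodes the right intuition at sparse, real-data coverage
(a precursor shows up as one or two pairs), but at simulation depths of
30x a genuine polycistronic junction receives on the order of 60 spanning
pairs while a 1% precursor still yields 0-2; the expected-spanning term
scales the cap between those regimes and reduces to the constant at sparse
coverage. Whole-gene medians (rather than narrow windows beside the IGR)
are used for the flank depths because coverage ramps up over about one
fragment length at every transcript edge, which systematically dilutes
edge-window ratios.

Two structural rules complete the caller: adjacencies across a strand
switch are never joined (a polycistron is single-stranded by definition),
and tRNA genes act as punctuation boundaries -- an adjacency involving a
tRNA is recorded (`trna_boundary`) but never joined.

## End mapping, UTRs and APA

A junction read has the layout `[3' flank][A^k][5' flank]` in transcript
sense. `resolve_crtpcr_junction()` locates the maximal A-run of length at
least `min_polya` (default 5), then anchors the two flanks by exact search
of a 15-mer seed (`anchor_k`), extended maximally, over both strands of the
circular genome. Exact matching is appropriate for the clone-derived,
Sanger-quality reads this assay produces; anchors hitting more than one
genomic locus raise an `ambiguous anchor` error rather than guessing. One
intrinsic limitation is worth stating: if the genomic base immediately
upstream of the poly(A) addition site (or the first base of the 5' end) is
itself an adenine, it is indistinguishable from the tail, and the reported
end shifts by the length of that genomic A-run. This is a property of the
molecule, not the algorithm; the simulator's genome pins a non-A base at
every configured end so that closed-loop recovery is exact.

UTR lengths follow from mapped ends: the 5' UTR is the distance from the
5' end to the unit's first start codon, the 3' UTR from the unit's last
stop codon to the (pre-poly(A)) 3' end. A 5' end *downstream* of the
annotated start is reported as a first-class `truncated5` result with its
offset -- such in-CDS leaders occur naturally (the replica program includes
one, 6 nt into CytB). Ends are attributed to units by proximity to the
unit's terminal CDS boundaries (`margin` = 150 nt), which keeps a
neighbouring unit's canonical end from masquerading as a UTR.

Alternative polyadenylation sites are single-linkage clusters of 3' ends
within `cluster_tol` (default 3 nt -- mapped ends 25 nt apart are distinct
sites, near-identical ends are merged conservatively). Each cluster's
representative is its highest-support member; the in-frame flag asks
whether the representative sits on a codon boundary of the reading frame of
the gene containing it, which for truncated isoforms is how one recognizes
that the terminal codon is *not* a genuine stop.

An antisense lncRNA call requires all four of: length > 200 nt,
polyadenylation, longest ORF under `orf_threshold` (50 codons -- our
operationalization of "lacking ORFs"), and at least half the transcript
overlapping an opposite-strand gene.

## Hairpins, motifs, control region

Thermodynamic folding is deliberately replaced by perfect inverted-repeat
search (Watson-Crick plus G·U) with stem >= 6 bp and loop 3-30 nt: the
scientific claim being checked is structural presence, not folding energy,
and the geometric definition admits an exhaustive oracle that the
implementation is property-tested against. Shared motifs across IGRs are
exact k-mers (k = 8..15, descending) present in at least `min_igrs` IGRs,
reported maximally (a k-mer that is a substring of a longer reported motif
with the same IGR set is suppressed).

A control region is called for an IGR meeting, by default, all four of:
coverage absence (>= 90% of IGR positions at zero depth -- a breadth
criterion, because UTR tails of flanking transcripts legitimately cover a
few edge bases), a stem-loop, a strand-polarity inversion between the
flanking genes, and a shared motif.

## qPCR quantification

`relative_ratio()` computes the efficiency-corrected ratio
`E_t^dCq_t / E_r^dCq_r` with `dCq = mean Cq(control) - mean Cq(sample)` and
per-gene mean efficiencies (Cq and efficiency are inputs, LinRegPCR-style;
fluorescence-curve fitting is out of scope). Uncertainty is reported twice,
labelled: the delta-method SD propagated from replicate Cq variances, and
the SD of per-replicate ratios -- published "±SD of technical triplicates"
figures can mean either. The randomization test permutes condition labels
within each gene and applies the add-one correction `p = (b+1)/(n+1)`,
two-sided on the log ratio. Note the discreteness floor: with 3+3
replicates there are only `C(6,3) = 20` distinct reallocations per gene, so
the smallest attainable two-sided p is about 0.1; p-values at that floor
are the strongest evidence three technical replicates can give.
`rhapa_quantify()` expresses each amplicon's ratio relative to the
cleaved-off 3' comparator amplicon, normalized by the reference gene, which
is how RNase-H-digested APA isoform pools are compared.

## The synthetic-data generator

`default_program("A")` builds a replica arrangement-A octocoral mitogenome
together with the transcription program the simulators execute. The genome
is constructed to the published dimensions of the arrangement-A exemplar:
18,730 nt; 14 PCGs, 2 rRNAs, 1 tRNA; *mtMutS* 2,982 nt (longest PCG) and
*ATP8* 216 nt (shortest); longest IGR 112 nt between COII and COI
(wrapping the origin), shortest 4 nt between 12S and ND1; one 13 nt gene
overlap (planted at the adjacent ND5-ND4 pair); and exact base counts
(A 5,662 / C 3,096 / G 3,616 / T 6,356) whose rounded percentages are
A 30.2, C 16.5, G 19.3, T 33.9, G+C 35.8. It is a labelled synthetic
stand-in for the real accession, which cannot be bundled; what the
acceptance checks on it demonstrate is that the package's annotation
arithmetic reproduces known truth by construction, not that it re-derives
the published record.

The transcription program encodes the arrangement-A unit structure -- COI;
CytB-ND6 (5' end 6 nt inside CytB, 8 nt 3' UTR); ND3-ND4L-mtMutS (31 nt 5'
UTR, six weighted APA sites >= 10 nt apart, none on a codon boundary);
ND2-ND5-ND4 (1 nt 5' UTR, 44 nt 3' UTR); COII-ATP8-ATP6 (3 nt 5' UTR,
83 nt 3' UTR); monocistronic ND1 and COIII with undetermined ends; the two
rRNAs at `rrna_multiplier` (default 50) times baseline abundance; and a
212 nt polyadenylated antisense lncRNA inside ATP6. `default_program("C")`
encodes the alternative arrangement with a COII-ATP8-ATP6-COIII
tetracistron, ND6-ND3-ND4L, and the control region in the ND6-COI IGR.
Where the source material fixes a value (UTR lengths, unit membership,
abundance regime) the program uses it; where it does not (UTRs of units
whose ends were undetermined, APA weights, the lncRNA abundance) the
program picks one realistic value, stated here, and the tests recover
exactly that value.

Generator details that matter for closed-loop exactness:

* Protein-coding genes get `ATG`...stop with no premature in-frame stops;
  the 13 nt overlap region is written to satisfy *both* reading frames
  (the downstream start codon inside the upstream gene, the upstream stop
  inside the downstream CDS).
* The sense-strand base at every configured transcript end is pinned to a
  non-adenine (C occurs in no stop codon, so this is always safe inside a
  CDS), keeping poly(A) junctions delimited.
* Each unit-flanking IGR gets its own random-stem hairpin; only the 11 nt
  motif is shared across IGRs. Identical stems would make 15-mer anchors
  genomically ambiguous whenever a mapped end falls inside a planted
  repeat.
* The antisense interval is guaranteed ORF-free below 50 codons by
  resampling third-codon positions of the host gene.
* Base-composition repair adjusts only unconstrained positions (rRNA/tRNA
  interiors, unplanted IGR bases) to hit the target counts exactly.

`simulate_reads()` draws fragments per transcript with expected count
`depth x abundance x length / (2 x read_len)` (so an abundance-1 transcript
averages `depth` sequenced-base coverage), Gaussian fragment lengths
(250 ± 40 nt), 50 nt paired reads, and poly(A) soft-clips on 3'-terminal
fragments with a small oligo-dT-style 3'-anchoring bias (5%).
`readthrough_fraction` (default 0.01) adds one unprocessed precursor per
strand at that fraction of baseline abundance -- the "low-abundance
premature RNA" regime; a literal per-fragment read-through probability
would flood every boundary with spanning pairs at simulation depths and
contradict the discrimination rule's design regime. All randomness flows
from one seed; identical seeds give identical outputs byte for byte.

What the generator does *not* emulate -- and hence what passing tests do
not show about real data: sequencing error (substitution errors are
config-gated and default to 0), RT template switching (which produces
false deletion artifacts in long genes), GC bias, RNA degradation
intermediates, and chimeric library artifacts. Real libraries also yield
far sparser mitochondrial coverage than the 30x used in the closed loop;
the discrimination rule's constant floor (`precursor_max_support = 2`)
exists for exactly that regime.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the closed loop at depth
30x over the 18.7 kb replica (about 5 x 10^4 fragments), 50 seeded
replicates of the read-through discrimination experiment at a 20-fold
rRNA/mRNA abundance gap, 300 randomized junction constructions, oracle
property suites on inputs up to 60 nt (hairpins) and a few hundred nt
(motifs, occupancy arrays), and 500 seeded qPCR recoveries -- sizes chosen
so the whole suite completes in a few minutes on one core while every
recovery claim stays exact rather than approximate.

Numerical conventions: percentages are reported to one decimal
(composition) or two (variability); the log-scale coverage normalization
`log(depth+1)/log(max+1)` is base-invariant; medians, not means, summarize
depths (single-read spikes are common at low coverage); breakpoint
plateaus (flat max/min-median ratios around a clean step) are resolved to
their center position; ties in APA clusters go to the highest-support
member. Degenerate inputs are defined rather than fatal: an all-zero
coverage profile normalizes to zeros with a warning, `depth = 0` simulates
an empty read set with a warning, an IGR of length 0 is a valid "abutting"
record, and a 5' end inside the CDS is a flagged result, not an error.

## Known limitations

* Real-study mitochondrial read yields (thousands of mapped reads out of
  tens of millions sequenced) are not reproduced; the package consumes
  alignments and simulations, it does not model library composition.
* End mapping is exact-match; a mismatch-tolerant anchor mode is config
  material for future work and matters for non-Sanger junction evidence.
* The control-region call is a conjunction of heuristics tuned for
  octocoral-style genomes; in genomes without a polarity switch at the
  origin the criterion set should be relaxed via `min_criteria`.
* With three technical replicates the randomization test cannot produce
  p < 0.1 (discreteness floor); biological replication is the only remedy.
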