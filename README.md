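# mitotx

Mitochondrial transcription-unit calling and transcript end mapping for
tRNA-poor mitogenomes.

## The problem

Animal mitochondrial genomes are transcribed as long polycistronic
precursors that are normally diced into individual messengers at the 22
tRNA genes punctuating the genome ("tRNA punctuation"). Octocoral
mitogenomes carry a **single** tRNA gene, 14 protein-coding genes
(including the octocoral-specific mismatch-repair gene *mtMutS*) and two
rRNAs on a ~19 kb circle — cleaving one tRNA can only linearize the
precursor. How such a genome yields mature messengers is an empirical
question: which genes share a mature transcript, where the 5′/3′ ends and
UTRs lie, whether genes are alternatively polyadenylated, and which
noncoding RNAs exist.

`mitotx` answers these questions from four kinds of evidence:

* **IGR-spanning read pairs.** For adjacent same-strand genes *a*, *b*
  separated by an intergenic region (IGR), read pairs with one mate in
  each gene support a shared mature messenger. Joined junctions are
  demoted to *precursor read-through* when the flanking genes' median
  depths differ by ≥ ρ (default 10) **and** the spanning support *s*
  satisfies *s* ≤ max(2, *E*[*s*]/ρ), where *E*[*s*] is the support
  expected if both genes were co-transcribed at the lesser flank's
  coverage — the signature of rare unprocessed precursor RNA faking
  collinearity across an abundance gap. tRNA genes act as punctuation
  boundaries; strand switches are never joined.
* **Junction reads** (circularized-RT and RACE style):
  `[3′ flank][poly(A)][5′ flank]` molecules are resolved by exact 15-mer
  anchoring on the circular genome, mapping both transcript termini at
  single-nucleotide resolution; UTRs, truncated in-CDS leaders, and
  alternative polyadenylation (APA) site clusters with reading-frame
  checks follow from the mapped ends.
* **Sequence structure**: stem-loops (perfect inverted repeats, G·U
  allowed), motifs shared across unit-flanking IGRs, uncovered IGRs and
  strand-polarity inversions combine into a control-region call.
* **qPCR wells** (Cq + efficiency): efficiency-corrected ratios
  *E*<sub>t</sub><sup>ΔCq,t</sup>/*E*<sub>r</sub><sup>ΔCq,r</sup> with a
  REST-style randomization test and RHAPA-style comparison of APA
  isoform amplicons against the cleaved-off 3′ comparator.

A first-class synthetic-data generator (`default_program()`,
`simulate_reads()`, `simulate_junction_reads()`, `simulate_cq()`) encodes
an arrangement-A octocoral transcription program over a replica mitogenome
built to the published dimensions (18,730 nt; longest IGR 112 nt; one
13 nt gene overlap; base composition A 30.2 / C 16.5 / G 19.3 / T 33.9%),
so every analytical stage is verifiable by parameter recovery. See the
methods vignette (`vignettes/mitotx-methods.Rmd`) for the model,
parameters and limitations.

## Worked example

```r
library(mitotx)

b <- default_program("A", seed = 1)   # replica genome + transcription program
b$genome
#> <circular_genome> synthA_mitogenome: 18730 nt (circular)

sim <- simulate_reads(b$program, b$features, b$genome,
                      depth = 30, readthrough_fraction = 0, seed = 42)
nrow(sim$fragments)
#> [1] 51127

lk <- collect_linkage(sim$fragments, b$features, b$genome)
called <- call_units(lk, features = b$features)
called$units[, c("unit_id", "strand", "n_genes", "n_cistrons")]
#>            unit_id strand n_genes n_cistrons
#> 1              COI      H       1          1
#> 2              12S      H       1          0
#> 3              ND1      H       1          1
#> 4         CytB-ND6      H       2          2
#> 5  ND3-ND4L-mtMutS      H       3          3
#> 6              16S      H       1          0
#> 7      ND2-ND5-ND4      H       3          3
#> 8             trnM      L       1          0
#> 9            COIII      L       1          1
#> 10  COII-ATP8-ATP6      L       3          3

unlist(classify_units(called$units))
#>              n_units          n_pcg_units      n_monocistronic
#>                   10                    7                    3
#>        n_bicistronic       n_tricistronic      n_polycistronic
#>                    1                    3                    4
#> pcgs_in_polycistrons
#>                   11
```

The caller recovers the simulated program exactly: seven protein-coding
units with cistron counts {1, 2, 3, 3, 3, 1, 1} — four polycistrons
containing 11 of the 14 protein-coding genes — plus the two rRNA units and
the tRNA. A junction read then pins transcript ends:

```r
junc <- simulate_junction_reads(b$program, b$features, b$genome,
                                n_per_end = 8, seed = 43)
res <- resolve_crtpcr_junction(junc$reads[[1]], b$genome)
c(res$three_prime$position, res$five_prime$position, res$three_prime$polya_len)
#> [1] 1679   97   40
```

— the COI messenger's 3′ end one base past its stop codon, its 5′ end 4 nt
upstream of the start codon (COI starts at position 101), and a 40 nt
poly(A) tail. `run_all(run_config(...))` chains every stage (coverage →
linkage → units → ends → APA → UTRs → lncRNA → control region) and writes
a JSON report plus GFF3/TSV/bedGraph artifacts.

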