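---
title: "Methods: mini-barcode design and mixture quantification from plastome pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mini-barcode design and mixture quantification from plastome pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibar)
```

## The problem

Processed herbal products (ground seeds, extracts, infusions) carry
degraded and mixed DNA, so conventional 500-800 bp barcodes amplify poorly
and cannot resolve mixtures. A *mini-barcode* -- a 100-250 bp region whose
insert still carries several fixed differences between the target species
and its adulterant -- can be amplified from degraded templates, and, read
out by amplicon sequencing with dual sample tags, can both identify the
species present and estimate their biomass proportions from read
proportions. `minibar` implements this strategy end to end for a pair of
closely related taxa with sequenced organelle genomes, modelled on the
*Senna obtusifolia* / *S. occidentalis* seed-adulteration system: the two
packaged matK primer pairs (`senna_primers()`) and the published mixture
read counts (`senna_asv_counts()`) serve as reference points throughout
the tests.

## Screening hypervariable coding regions

Protein-coding genes are extracted from each annotated genome (GenBank
flat files; minus-strand and `join()` genes are spliced and oriented,
inverted-repeat duplicates resolved to the lower-coordinate copy), paired
by case-insensitive gene name, and each orthologous pair is globally
aligned. Nucleotide diversity per gene is the p-distance with *complete
deletion*: alignment columns containing a gap or any non-ACGT code are
excluded from the compared sites, and for two sequences

$$\pi = \frac{\text{differing compared columns}}{\text{compared columns}},$$

the mean over unordered pairs when more than two sequences are given.
Genes are ranked by $\pi$; the most variable genes (default: top 4) are
carried into primer design. Only coding regions are searched: plastid
intergenic spacers accumulate indels and length variation that destroy
primer conservation and inflate intra-specific variation, which would bias
a quantitative barcode.

### Alignment engine

Alignment is Needleman-Wunsch with affine gaps (Gotoh), match $+5$,
mismatch $-4$, and gap cost $10 + 0.5L$ for a gap of length $L$ --
a widely used DNA global-alignment convention; all four numbers are
configurable through `align_scoring()`. Traceback is deterministic: on
score ties a diagonal move is preferred, then a gap in the second
sequence, then a gap in the first. The test suite checks the
implementation against an independent exhaustive-enumeration oracle that
walks every monotone path through the edit lattice for short random
sequence pairs. Codon-aware alignment is deliberately not used; for the
substitution-dominated divergence between congeneric plastomes it would
change little and would couple the result to annotation quality.

## Primer design

Candidate primers are enumerated exhaustively from *conserved blocks*
(alignment columns identical, unambiguous and gap-free in both taxa), so a
primer binds both templates perfectly by construction. Each candidate and
pair must satisfy, with defaults chosen for short-amplicon PCR from
degraded DNA:

| parameter | default | unit | rationale |
|---|---|---|---|
| product size | 150-300 | bp | short enough for degraded DNA, long enough to carry variable sites |
| primer length | 18-30 | nt | standard specificity/kinetics window |
| Tm | 40-70 | C | wide band; pairs should also be Tm-matched downstream |
| GC | 30-70 | % | avoids extreme-composition primers |
| hairpin stem / loop | 4 / 3 | bp / nt | stems of 4+ WC pairs with a foldable loop self-prime |
| dimer run / 3' run | 8 / 4 | bp | long complementary runs, or short ones at a 3' end, extend in PCR |

Melting temperature is the nearest-neighbor thermodynamic Tm against the
perfect complement using the unified duplex parameter set (terminal A/T
and G/C initiation terms), the entropic salt correction
$\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM monovalent salt, and
an effective duplex concentration of one quarter of the 250 nM primer
concentration. Printed Tm and GC values in the source table for the
packaged primers are not used as ground truth: direct computation on the
printed primer sequences contradicts them (e.g. the 20-mer forward primer
of 478F-629R has 9 G/C, hence 45%, not the printed 33.3%), so the
package's own nearest-neighbor values, cross-checked against an
independent hand-summed oracle, are authoritative here.

Surviving pairs are ranked by insert variable-site count (more
discriminating first), then insert length (shorter survives degradation
better), then coordinate. Cross-dimer screening walks this ranking and
stops after `max_pairs` survivors; the enumeration is complete with
`max_pairs = Inf`, the cap only bounds the quadratic pair screen.

### In-silico specificity

A candidate is *specific* only if in-silico PCR yields exactly one product
per genome -- presence of the target product is not enough, a second
product anywhere (default tolerance: 2 substitutions per primer, exact
3'-terminal trinucleotide, products up to 2 kb) disqualifies the pair.
The 3'-exact rule reflects polymerase intolerance of 3' mismatches; the
uniqueness rule is this package's explicit choice of specificity check.

## Mixture quantification

The read pipeline mirrors a standard dual-tagged amplicon workflow, with
every stage conserving reads (assigned + unassigned, retained + rejected):

1. **Demultiplexing** is exact: a pair is assigned only when mate 1 starts
   with a sample's forward tag *and* mate 2 with the same sample's reverse
   tag. A valid forward tag of one sample with a valid reverse tag of
   another -- a tag jump -- is left unassigned, so tag jumps cannot
   misassign reads. Tags are short (>= 6 nt), hence no mismatch tolerance.
2. **Merging** reverse-complements mate 2 and chooses the overlap
   maximizing matching bases (minimum 20 nt, mismatch fraction <= 0.1,
   ties to the longer overlap); disagreements take the higher-quality
   base, mate 1 on ties.
3. **Primer trimming** matches both footprints with at most 2
   substitutions and no indels -- amplicon reads rarely shift in frame, and
   allowing indels would blur the insert boundary.
4. **Dereplication** pools identical inserts per sample into exact
   sequence variants (ASVs); reads containing N are discarded and counted.
5. **Denoising** is a deliberately simple abundance rule standing in for
   full error-model denoisers: per sample, ASVs below `min_count = 2` are
   removed, then, in one descending-abundance pass, an ASV within Hamming
   distance 1 of a more abundant ASV with count at most `skew = 0.05`
   times the parent's is merged into it.
6. **Assignment** globally aligns each ASV to every reference insert;
   a species call requires exactly 100% identity over the full alignment.
   97-100% is reported as `near`; equal-best ties are flagged and left
   unassigned.
7. **Proportions** are computed over species-assigned reads only, and the
   pooled reads-vs-biomass relationship is summarized by ordinary least
   squares with $R^2$ the squared Pearson correlation.

### What the simple denoiser does and does not do

The Hamming-1 collapse removes the dominant error class (single-substitution
reads) and, with the species-call-at-100% rule, leaves proportion
estimates unbiased: reads with any insert error drop out of both species'
numerators at the same per-base rate when inserts have equal length.
It does **not** remove rare ASVs at Hamming distance 2 formed when two or
more reads happen to carry the same pair of errors; at 20,000 read pairs
per mixture and a per-base error of 0.002 over a 164 bp insert, one to a
few such count-2 ASVs per mixture are expected, and the skew condition
(count <= 0.05 x parent) correctly refuses to merge them into their
low-abundance single-error neighbours. A probabilistic error model (as in
full ASV denoisers) is required to collapse those; this is a known,
documented limitation of the rule -- the surviving artifacts are `near`
calls that never contaminate species-level proportions.

## The simulators

`simulate_genome_pair()` emulates two congeneric organelle genomes:
random coding genes (default 8 x 900 bp, alternating strands, CDS
annotations) separated by shared spacers, with genome B substituted
per site at the stated divergence outside conserved flanks (default 60 bp,
so primer-sized conserved blocks exist at gene ends by construction).
Substitution-only divergence keeps planted variable-site positions exact
ground truth. `simulate_mixture_reads()` draws each read pair from a
taxon with the stated probability, prefixes tags, applies a uniform
per-base substitution error to the whole read (tags included -- tag errors
surface as unassigned pairs, as on a real flow cell), and emits constant
qualities at the Phred value implied by the error rate.

What the simulators do **not** emulate: indels and length-variable
amplicons, position- and context-dependent (quality-correlated) error
profiles, chimeras, PCR amplification bias between taxa, and
contaminating off-target DNA. Passing tests therefore demonstrate
correctness of the pipeline's bookkeeping and its statistical behaviour
under idealized errors, not robustness to primer bias -- the published
mixture data themselves show one of the two printed primer pairs
(478F-629R) suffering exactly such bias, which no amount of downstream
processing repairs.

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based inclusive only at
  the GenBank boundary and in primer-pair names (`647F-847R` style).
* Gene names are matched after whitespace trimming, case-insensitively,
  reporting the first genome's spelling; inverted-repeat duplicates
  resolve to the lower start coordinate, deterministically.
* Trans-spliced genes (segments on both strands) are excluded from
  diversity scans: their ortholog splicing depends on annotation
  conventions, not sequence.
* $\pi$ is reported to 5 decimals in reports; ties in gene ranking break
  alphabetically; genes with zero compared sites sort last with $\pi$
  undefined rather than 0.
* Degenerate-base primers are not generated; the reference primer pairs
  are exact sequences, and degeneracy would undermine the quantitative
  use of the barcode.
* The design pipeline requires exactly two genomes; the diversity and
  assignment machinery accepts more, but taxon-specific primer design
  against more than two templates is out of scope.

## Problem sizes

The shipped tests run the four-mixture study at 20,000 read pairs per
mixture with per-base error 0.002 and biomass proportions from 0.05 to
0.95, a single-mixture recovery check at 50,000 pairs and error 0.001,
alignment-oracle sweeps over 200 random short pairs, and genome-pair
simulations of 4-10 genes of 300-1000 bp -- sizes chosen so the whole
suite exercises every code path at meaningful statistical resolution
while remaining quick to run on one core. The same machinery scales to
full plastomes (about 160 kb, 77 shared genes) in minutes.
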