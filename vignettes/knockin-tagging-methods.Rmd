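---
title: "Designing and auditing NHEJ-based knock-in tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and auditing NHEJ-based knock-in tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knocktag)
```

## The problem

Homology-independent knock-in tagging inserts a tag cassette at a
Cas9-induced double-strand break by canonical non-homologous end joining
(cNHEJ), rather than by homology-directed repair. For C-terminal protein
tagging this needs three coordinated pieces: an sgRNA cutting the gene of
interest close to its stop codon (the *target selector*), an sgRNA cutting
a *universal donor* plasmid (the *frame selector*), and the donor itself,
which carries a generic cleavable site upstream of a short linker
(peptide `GGSGGSGGGS`) fused to the tag ORF. Because cNHEJ ligates blunt
ends largely unmodified, the donor is cleaved in cells and the linearized
molecule is pasted into the genomic break. The reading frame of the
resulting gene--linker--tag fusion is set at transfection time by choosing
one of three frame-selector sgRNAs that cut the donor at three adjacent
positions inside a poly-G stretch.

`knocktag` implements the computational side of this workflow:

1. **Target-site design** -- enumerate SpCas9 sites (20-nt protospacer +
   NGG PAM) whose blunt cut lies in the last coding exon near the stop
   codon, compute the ORF bases and amino acids lost, filter sites that
   would be re-cleavable after integration, and pick one optimal site per
   gene.
2. **Donor modelling** -- cut the donor at the three selector registers,
   predict the full fusion allele and fusion protein for either
   integration orientation, and choose the correct selector.
3. **Scarless inserts** -- design oligo duplexes that re-encode the lost
   codons with synonymous re-cutting protection.
4. **Junction sequencing** -- classify amplicon reads at the genome--donor
   junction into seamless/indel/frame-shift events and aggregate fidelity
   and genotyping reports.
5. **Simulation** -- generate synthetic genomes, gene models and junction
   read sets with ground truth, so the whole pipeline is testable without
   external data.

## Coordinates and cut-site arithmetic

All coordinates are 0-based, half-open; cut sites are between-base
coordinates. SpCas9 is modelled as cutting bluntly 3 nt 5' of the PAM
(between protospacer positions 17|18). For a gene with spliced ORF length
`n` and `L` ORF nucleotides retained 5' of the cut, the loss is
`orf_bases_lost = n - L` and `aa_lost = ceiling(orf_bases_lost / 3)`; a
cut exactly at the ORF/stop boundary loses nothing. The CDS excludes the
stop codon throughout, so the stop is never counted as lost sequence.
Protospacers may cross exon--intron boundaries (Cas9 cuts DNA, not mRNA);
only the cut itself must fall inside coding sequence.

## The re-cutting filter

After integration, the genomic protospacer positions 1--17 become fused to
the donor's PAM-proximal trinucleotide (from its poly-G stretch). If the
genomic trinucleotide directly upstream of the PAM (protospacer positions
18--20) resembles the donor's, the junction reconstitutes a cleavable
site and the target-selector sgRNA can cut the tagged allele again.
`recut_safe()` implements "resemble" as an exact 3/3 match by default --
the conservative reading, since single seed mismatches usually abolish
cleavage -- with a stricter 2/3 option (`resemblance_mode =
"two_of_three"`) for users who prefer a larger safety margin.

## Frame selection by translation, not arithmetic

With the packaged schematic donor, selector `+k` rescues genes whose
retained prefix satisfies `L mod 3 == k`. The package nevertheless never
uses that closed form: `choose_frame_selector()` predicts all three
forward fusion alleles, translates them, and returns the unique selector
whose protein carries the intact linker followed by the tag. This keeps
the choice correct for any user-supplied donor layout, and it exposes a
genuine edge case: when two retained prefix bases `TA` are completed by a
donor `G`, the junction codon becomes a `TAG` stop, *no* selector gives a
tagged protein, and the chooser raises the documented error. Library
design treats such sites as unusable and falls through to the next ranked
candidate (reason `junction_stop` when none remains). On random synthetic
genes this affects roughly 1--2% of candidate sites.

Site ranking is: minimal `aa_lost`, then the larger junction/donor
trinucleotide mismatch count, then the 5'-most cut in gene orientation,
then the `+` strand. The ranking is fully deterministic so a library run
is reproducible.

## Scarless insert design

A scarless donor re-encodes the ORF nucleotides between the cut and the
stop codon so the tagged protein keeps its complete wild-type C terminus.
`design_scarless_insert()` emits an annealed oligo duplex (NheI/BamHI
sticky ends by default): the coding span is exactly the lost bases --
including the partial codon completed by retained prefix bases -- followed
by the start of the linker ORF. To prevent re-cutting of the repaired
junction, lost codons overlapping the protospacer are substituted
synonymously, most PAM-proximal position first, until the seed + PAM
region (protospacer positions 9--20 plus PAM) no longer matches; if no
synonymous substitution can break the seed the insert is still emitted
with `seed_broken = FALSE` and a warning. The published ACTG1 scarless
oligos are reproduced exactly by supplying the printed donor-site scaffold
and linker fragment with recoding disabled, since that published design
relies on its scaffold context rather than recoding.

## Junction read classification

Reads are aligned to the predicted fusion references (both orientations;
plus the wild-type allele in locus--locus mode) with a global-in-read,
local-in-reference affine-gap alignment (match +2, mismatch -3, gap open
-6, gap extend -1). These defaults deliberately favour calling one
contiguous indel over scattered gaps, matching how junction events are
tabulated. Assignment is by best score with deterministic tie-breaking
(reference name order, then as-is read orientation); ties are flagged.
Scores are verified in the test suite against an independent full
quadratic dynamic-programming implementation.

Classification looks only at indels overlapping a +/-20 nt window around
the junction; isolated substitutions are treated as sequencing error.
`frame_offset = net_indel mod 3` colours events as in-frame or
frame-shifting. The recurrent single-base insertion that duplicates the
donor base at PAM position -4 (a +1 frame shift) is flagged when a 1-nt
insertion of that base falls inside the junction homopolymer run -- the
run matters because an aligner may place an equivalent gap anywhere within
it. The two amplicon readouts (locus+tag primer for integration fidelity,
locus+locus primers for mutagenesis genotyping) are modelled as separate
designs and never mixed in one report, as their read populations are not
quantitatively comparable.

Clone genotyping (`classify_locus_indels()`) pools reads by identical
event signature, supports an allele at >= 20% of classified reads, and
calls `wild-type`, `heterozygous`, `all-allelic frameshift` (every
supported allele has frame offset 1 or 2) or `in-frame`. The 20%
threshold is our choice of a conservative bound for 2--3 allele copies;
it is a parameter.

## What the simulator does and does not emulate

`simulate_reference_set()` draws intron-containing coding genes (ATG, a
sense-codon ORF, a stop codon, both strands) on separate contigs;
`simulate_junction_reads()` draws junction amplicon reads from an event
mix of seamless fusions, junction deletions (truncated geometric length
spectrum, p = 0.3, max 30 nt -- deletion sizes in real data are variable
and this spectrum is a modelling choice, not a measurement), -4-type
single-base duplications, and reverse-orientation integrations, plus a
flat per-base substitution error rate. Reads are deterministic per seed
through an isolated RNG stream.

The simulator does not model PCR amplification bias, chimeric reads,
position-dependent quality, microhomology-biased deletion spectra, or
paired-end structure. Passing the recovery tests therefore shows that the
classifier is correct *given* the event model; it does not show that real
MiSeq junction libraries are free of artefacts the model omits.

## Problem sizes and reproducibility

The shipped checks run, per invocation: 1,000 random (gene, site, donor)
triples for frame-selector uniqueness/concordance; a 150-gene simulated
genome for the library summary; 5,000 simulated junction reads (seamless
0.70 / deletion 0.20 / -4 duplication 0.10, substitution error 0.2%) for
mixture recovery; and 200 random read/reference pairs for the alignment
oracle. These sizes give binomial standard errors small enough that a 2-SE
recovery criterion is meaningful while keeping a full run in minutes on
one CPU. `scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes all headline quantities from scratch.

Two checks require external data that is not shipped: a genome-wide mean
amino-acid loss on a human GENCODE annotation, and re-analysis of the
published deposited MiSeq junction reads. The corresponding tests look for
those inputs under `refdata/` at the repository root and fail visibly when
absent rather than pretending to pass. On simulated 150-gene genomes the
mean loss is around 3 amino acids; real human genes, with their longer
ORFs, sparser PAM context around stop codons, and annotation-version
drift, are expected to land higher.

## Known limitations

* Only SpCas9 NGG sites and C-terminal tagging are supported; no
  off-target or on-target efficiency scoring is attempted.
* One transcript per gene (longest CDS, ties to the lexicographically
  smallest transcript id); isoform-aware design is out of scope.
* The schematic default donor is a compact stand-in: its site, linker,
  tag and optional selection cassette have the published layout, but real
  plasmid sequences should be supplied via `donor_template()` arguments
  for exact junction references.
* Reverse-orientation integration is modelled as unresected
  reverse-complement insertion at the same junction.
* The classifier treats isolated mismatches as noise; true single-base
  substitution editing at the junction would be invisible by design.
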